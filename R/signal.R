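#' Lambda-transformed Brownian covariance of a tree
#'
#' The Brownian-motion covariance between two tips is the shared path length
#' from the root to their most recent common ancestor. Pagel's lambda
#' multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' (root-to-tip depths) unchanged: `lambda = 0` is a star phylogeny (no
#' covariance), `lambda = 1` pure Brownian motion.
#'
#' @param tree A `"phylo"` tree.
#' @param lambda Transform parameter, >= 0.
#' @return A symmetric covariance matrix ordered by `tree$tip.label`.
#' @export
lambda_vcv <- function(tree, lambda = 1) {
  v <- ape::vcv.phylo(tree)
  v <- v[tree$tip.label, tree$tip.label]
  if (lambda != 1) {
    dg <- diag(v)
    v <- v * lambda
    diag(v) <- dg
  }
  v
}

match_traits <- function(tree, traits) {
  if (is.null(names(traits))) stop("traits must be named by species")
  if (anyDuplicated(names(traits))) stop("duplicate species in traits")
  if (anyNA(traits) || any(!is.finite(traits)))
    stop("traits must be finite")
  miss_tree <- setdiff(tree$tip.label, names(traits))
  if (length(miss_tree))
    stop("tree tips without trait values: ",
         paste(miss_tree, collapse = ", "))
  extra <- setdiff(names(traits), tree$tip.label)
  if (length(extra))
    stop("trait species not on the tree: ", paste(extra, collapse = ", "),
         "; see prune_to_traits()")
  y <- traits[tree$tip.label]
  if (length(y) < 4L) stop("need at least 4 species for signal inference")
  if (sd(y) == 0) stop("trait has zero variance")
  y
}

#' Prune a tree to the species present in a trait table
#'
#' Species on the tree that lack trait values (e.g. taxa for which the trait
#' is undefined, such as case length for caseless caddisflies) are dropped
#' from a copy of the tree, with a message listing them.
#'
#' @param tree A `"phylo"` tree.
#' @param traits Named numeric vector.
#' @return The pruned tree.
#' @export
prune_to_traits <- function(tree, traits) {
  drop <- setdiff(tree$tip.label, names(traits))
  if (length(drop)) {
    message("pruning ", length(drop), " species without trait values: ",
            paste(drop, collapse = ", "))
    tree <- ape::drop.tip(tree, drop)
  }
  tree
}

#' Profiled log-likelihood of the lambda-transformed Brownian model
#'
#' Fits, for a fixed `lambda`, the model `y ~ MVN(root * 1, sigma2 * V_lambda)`
#' with `V_lambda` from [lambda_vcv()]. The root state is profiled out as the
#' generalized-least-squares mean and `sigma2` as its maximum-likelihood
#' estimator (divide by n, not n - 1, so likelihood-ratio tests are on a
#' common ML footing).
#'
#' @param tree A `"phylo"` tree whose tips exactly match `names(traits)`.
#' @param traits Named numeric trait vector (one value per tip).
#' @param lambda Fixed transform parameter in `[0, lambda_max(tree)]`.
#' @return A list: `lnL` (profiled log-likelihood), `sigma2`, `root`.
#' @export
bm_loglik <- function(tree, traits, lambda = 1) {
  validate_tree(tree)
  y <- match_traits(tree, traits)
  v <- lambda_vcv(tree, lambda)
  n <- length(y)
  ch <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(ch))
    stop("covariance not positive definite at lambda = ", lambda,
         "; the admissible upper bound is lambda_max(tree) = ",
         signif(lambda_max(tree), 6))
  # whitened regression on the intercept: solve via the Cholesky factor
  z <- backsolve(ch, y, transpose = TRUE)
  o <- backsolve(ch, rep(1, n), transpose = TRUE)
  root <- sum(o * z) / sum(o * o)
  r <- z - root * o
  sigma2 <- sum(r * r) / n
  logdet <- 2 * sum(log(diag(ch)))
  lnL <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(lnL = lnL, sigma2 = sigma2, root = root)
}

#' Largest admissible lambda for a tree
#'
#' The lambda transform keeps the covariance positive definite for all
#' `lambda` in `[0, 1]`; beyond 1 the limit depends on the tree (for
#' ultrametric trees it exceeds 1). Found numerically by doubling then
#' bisection on Cholesky success, to a tolerance of 1e-6.
#'
#' @param tree A `"phylo"` tree.
#' @return The largest lambda keeping `lambda_vcv(tree, lambda)` positive
#'   definite.
#' @export
lambda_max <- function(tree) {
  pd <- function(l) !is.null(tryCatch(chol(lambda_vcv(tree, l)),
                                      error = function(e) NULL))
  lo <- 1
  hi <- 2
  while (pd(hi) && hi < 64) {
    lo <- hi
    hi <- hi * 2
  }
  if (hi >= 64) return(lo)
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pd(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Maximum-likelihood estimate of Pagel's lambda with a likelihood-ratio test
#'
#' Maximizes the profiled Brownian likelihood over `lambda` in
#' `[0, lambda_max]` by bounded scalar optimization (tolerance 1e-6; the
#' interval endpoints are also evaluated so boundary optima are not missed),
#' then tests the fitted lambda against the no-signal model `lambda = 0`
#' with the likelihood-ratio statistic `2 * (lnL_hat - lnL_0)` referred to a
#' chi-squared distribution with 1 degree of freedom. Because `lambda = 0`
#' sits on the parameter boundary that plain chi-squared test is mildly
#' conservative; `boundary_mix = TRUE` instead uses the 50:50
#' point-mass/chi-squared mixture (halving the p-value).
#'
#' @inheritParams bm_loglik
#' @param upper `"pd"` (default) searches up to [lambda_max()]; `"one"` caps
#'   the search at 1.
#' @param boundary_mix Use the boundary-corrected null distribution
#'   (default `FALSE`).
#' @return A list: `lambda` (the MLE), `lnL`, `lnL0`, `sigma2`, `root`,
#'   `lrt`, `p` and `identifiable` (`FALSE` when the likelihood is flat in
#'   lambda, as on a star tree).
#' @export
fit_lambda <- function(tree, traits, upper = c("pd", "one"),
                       boundary_mix = FALSE) {
  upper <- match.arg(upper)
  lmax <- if (upper == "pd") lambda_max(tree) else 1
  f <- function(l) bm_loglik(tree, traits, l)$lnL
  opt <- optimize(f, c(0, lmax), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, 0, lmax)
  lnls <- c(opt$objective, f(0), f(lmax))
  best <- which.max(lnls)
  lhat <- cand[best]
  fit <- bm_loglik(tree, traits, lhat)
  lnL0 <- if (best == 2) fit$lnL else f(0)
  lrt <- max(0, 2 * (fit$lnL - lnL0))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  if (boundary_mix) p <- p / 2
  identifiable <- diff(range(lnls)) > 1e-8
  list(lambda = lhat, lnL = fit$lnL, lnL0 = lnL0, sigma2 = fit$sigma2,
       root = fit$root, lrt = lrt, p = p, identifiable = identifiable)
}

#' Blomberg's K with a permutation test
#'
#' K compares the observed ratio of the trait's mean squared error around
#' the phylogenetically corrected mean (MSE0) to its covariance-weighted
#' mean squared error (MSE), against the ratio expected under Brownian
#' motion on the given tree:
#'
#'   K = (MSE0 / MSE)_observed / (MSE0 / MSE)_expected,
#'   (MSE0 / MSE)_expected = (trace(V) - n / sum(V^-1)) / (n - 1).
#'
#' K = 1 matches the Brownian expectation, K < 1 means less resemblance
#' among relatives than Brownian motion predicts, K > 1 more. The
#' significance test permutes trait values across tips `n_permutations`
#' times; with `statistic = "mse"` (default) the test statistic is the
#' V-weighted MSE (smaller observed values than the permutation
#' distribution indicate signal), with `statistic = "pic"` it is the
#' variance of phylogenetically independent contrasts. Both use the
#' (k + 1)/(n + 1) rank p-value.
#'
#' @inheritParams bm_loglik
#' @param n_permutations Number of tip permutations (default 1000).
#' @param seed Integer seed.
#' @param statistic Permutation statistic, `"mse"` or `"pic"`.
#' @return A list: `K`, `p`, `n_permutations`, `statistic`.
#' @export
blomberg_k <- function(tree, traits, n_permutations = 1000, seed,
                       statistic = c("mse", "pic")) {
  statistic <- match.arg(statistic)
  validate_tree(tree)
  y <- match_traits(tree, traits)
  v <- lambda_vcv(tree, 1)
  n <- length(y)
  ch <- chol(v)
  o <- backsolve(ch, rep(1, n), transpose = TRUE)
  ones_vinv_ones <- sum(o * o)

  mse_pair <- function(yy) {
    z <- backsolve(ch, yy, transpose = TRUE)
    root <- sum(o * z) / ones_vinv_ones
    mse0 <- sum((yy - root)^2) / (n - 1)
    r <- z - root * o
    mse <- sum(r * r) / (n - 1)
    c(mse0 = mse0, mse = mse)
  }
  obs <- mse_pair(y)
  expected_ratio <- (sum(diag(v)) - n / ones_vinv_ones) / (n - 1)
  k <- (obs["mse0"] / obs["mse"]) / expected_ratio

  stat_fun <- if (statistic == "mse") {
    function(yy) mse_pair(yy)["mse"]
  } else {
    function(yy) {
      names(yy) <- tree$tip.label
      var(ape::pic(yy, tree))
    }
  }
  obs_stat <- stat_fun(y)
  with_seed(seed, {
    perm <- vapply(seq_len(n_permutations), function(i) {
      yp <- sample(unname(y))
      names(yp) <- names(y)
      stat_fun(yp)
    }, numeric(1))
  })
  p <- (sum(perm <= obs_stat) + 1) / (n_permutations + 1)
  list(K = unname(k), p = p, n_permutations = n_permutations,
       statistic = statistic)
}

#' Full phylogenetic-signal summary for one trait on one tree
#'
#' Convenience wrapper running [blomberg_k()] and [fit_lambda()] on the same
#' (pruned, see [prune_to_traits()]) tree/trait pair.
#'
#' @inheritParams blomberg_k
#' @param trait_name Label carried into the result row.
#' @param ... Passed on to [fit_lambda()].
#' @return A one-row data frame: `trait`, `n_species`, `K`, `p_K`,
#'   `lambda`, `lnL`, `lnL0`, `p_lambda`, `sigma2`, `root`.
#' @export
signal_summary <- function(tree, traits, trait_name = "trait",
                           n_permutations = 1000, seed,
                           statistic = c("mse", "pic"), ...) {
  tree <- prune_to_traits(tree, traits)
  traits <- traits[tree$tip.label]
  kk <- blomberg_k(tree, traits, n_permutations = n_permutations,
                   seed = seed, statistic = statistic)
  ll <- fit_lambda(tree, traits, ...)
  data.frame(trait = trait_name, n_species = length(tree$tip.label),
             K = kk$K, p_K = kk$p, lambda = ll$lambda, lnL = ll$lnL,
             lnL0 = ll$lnL0, p_lambda = ll$p, sigma2 = ll$sigma2,
             root = ll$root, stringsAsFactors = FALSE)
}

#' Read a species trait table from CSV
#'
#' Dialect: two columns, `species` and `value` (header required; extra
#' columns ignored with a message).
#'
#' @param path CSV file path.
#' @return A named numeric vector.
#' @export
read_trait_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "value") %in% names(df)))
    stop("trait CSV needs 'species' and 'value' columns")
  setNames(as.numeric(df$value), df$species)
}
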