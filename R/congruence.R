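# Unfold the strict upper triangle of a distance matrix into a vector,
# after reordering rows/columns to a common label order.
unfold_upper <- function(d, labels) {
  d <- d[labels, labels]
  d[upper.tri(d)]
}

common_labels <- function(matrices) {
  labs <- rownames(matrices[[1]])
  for (i in seq_along(matrices)) {
    li <- rownames(matrices[[i]])
    if (!setequal(li, labs)) {
      dd <- union(setdiff(labs, li), setdiff(li, labs))
      stop("matrices do not share a label set; symmetric difference: ",
           paste(dd, collapse = ", "))
    }
  }
  sort(labs)
}

# Kendall's W across m rank vectors (rows of `ranks`), with the standard
# correction for ties: W = 12 S / (m^2 (p^3 - p) - m T).
kendall_w <- function(ranks) {
  m <- nrow(ranks)
  p <- ncol(ranks)
  rsum <- colSums(ranks)
  s <- sum((rsum - m * (p + 1) / 2)^2)
  tie <- sum(apply(ranks, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  12 * s / (m^2 * (p^3 - p) - m * tie)
}

relabel <- function(d, perm) {
  out <- d[perm, perm]
  dimnames(out) <- dimnames(d)
  out
}

#' Congruence among distance matrices (CADM)
#'
#' Tests whether two or more distance matrices over the same taxa rank the
#' taxon pairs concordantly. Each matrix's strict upper triangle is unfolded
#' and rank-transformed (average ranks for ties); Kendall's coefficient of
#' concordance W (tie-corrected) measures agreement, with the Friedman-type
#' statistic `chi2 = m (p - 1) W` for m matrices and p = n(n-1)/2 pairs.
#' The permutation test holds the first (reference) matrix fixed and
#' relabels the taxa of every other matrix independently, recomputing W;
#' the p-value is (count of permuted W >= observed + 1)/(n_permutations + 1)
#' against the null hypothesis of incongruence.
#'
#' A-posteriori pairwise Mantel correlations on the rank-transformed
#' distances ([mantel_rank()]) identify which matrices agree;
#' `pairwise = "reference"` (default) compares every matrix to the first,
#' `"all"` compares all pairs, `"none"` skips them.
#'
#' @param matrices Named list of at least 2 labelled distance matrices over
#'   identical taxon sets (internally reordered to a common order).
#' @param n_permutations Permutations for the global and Mantel tests
#'   (default 999).
#' @param seed Integer seed.
#' @param pairwise Which a-posteriori Mantel comparisons to run.
#' @return A list of class `"cadm"`: `W`, `chi2`, `p_global`,
#'   `n_permutations`, and `pairwise` (data frame with `matrix_a`,
#'   `matrix_b`, `mantel_r`, `p`).
#' @export
cadm_global <- function(matrices, n_permutations = 999, seed,
                        pairwise = c("reference", "all", "none")) {
  pairwise <- match.arg(pairwise)
  if (length(matrices) < 2L) stop("need at least 2 matrices")
  if (is.null(names(matrices)))
    names(matrices) <- paste0("matrix", seq_along(matrices))
  matrices <- lapply(matrices, validate_distance_matrix)
  labs <- common_labels(matrices)
  n <- length(labs)
  m <- length(matrices)
  vecs <- lapply(matrices, unfold_upper, labels = labs)
  ranks <- do.call(rbind, lapply(vecs, rank))
  w_obs <- kendall_w(ranks)
  p_pairs <- ncol(ranks)

  with_seed(seed, {
    w_perm <- vapply(seq_len(n_permutations), function(i) {
      rp <- ranks
      for (j in seq_len(m)[-1]) {
        perm <- sample(n)
        rp[j, ] <- rank(unfold_upper(relabel(matrices[[j]], perm), labs))
      }
      kendall_w(rp)
    }, numeric(1))
    p_global <- (sum(w_perm >= w_obs) + 1) / (n_permutations + 1)
    pw <- NULL
    if (pairwise != "none") {
      idx <- if (pairwise == "reference")
        cbind(1L, seq_len(m)[-1])
      else t(utils::combn(m, 2))
      pw <- do.call(rbind, lapply(seq_len(nrow(idx)), function(k) {
        a <- idx[k, 1]
        b <- idx[k, 2]
        mt <- mantel_rank(matrices[[a]], matrices[[b]],
                          n_permutations = n_permutations,
                          seed = sample.int(.Machine$integer.max, 1))
        data.frame(matrix_a = names(matrices)[a],
                   matrix_b = names(matrices)[b],
                   mantel_r = mt$r, p = mt$p, stringsAsFactors = FALSE)
      }))
    }
  })
  out <- list(W = w_obs, chi2 = m * (p_pairs - 1) * w_obs,
              p_global = p_global, n_permutations = n_permutations,
              pairwise = pw)
  class(out) <- "cadm"
  out
}

#' @export
print.cadm <- function(x, ...) {
  cat("CADM congruence test\n")
  cat(sprintf("  W = %.4f, chi2 = %.2f, permutation p = %.4g (%d perms)\n",
              x$W, x$chi2, x$p_global, x$n_permutations))
  if (!is.null(x$pairwise)) {
    cat("  a-posteriori Mantel correlations (rank-transformed):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Mantel correlation on rank-transformed distances
#'
#' Pearson correlation between the rank-transformed unfolded upper triangles
#' of two distance matrices over the same taxa (equivalently a Spearman
#' matrix correlation). The permutation test relabels the taxa of `b`
#' (simultaneous row/column permutation); the default alternative is
#' one-tailed for positive association, the natural direction when testing
#' congruence.
#'
#' @param a,b Labelled distance matrices over identical taxon sets.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A list: `r`, `p`, `n_permutations`.
#' @export
mantel_rank <- function(a, b, n_permutations = 999, seed,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- validate_distance_matrix(a)
  b <- validate_distance_matrix(b)
  labs <- common_labels(list(a, b))
  n <- length(labs)
  ra <- rank(unfold_upper(a, labs))
  rb <- rank(unfold_upper(b, labs))
  if (sd(ra) == 0 || sd(rb) == 0)
    stop("constant distance vector; Mantel correlation undefined")
  r_obs <- cor(ra, rb)
  with_seed(seed, {
    r_perm <- vapply(seq_len(n_permutations), function(i) {
      perm <- sample(n)
      cor(ra, rank(unfold_upper(relabel(b, perm), labs)))
    }, numeric(1))
  })
  k <- if (alternative == "greater") sum(r_perm >= r_obs)
       else sum(abs(r_perm) >= abs(r_obs))
  list(r = r_obs, p = (k + 1) / (n_permutations + 1),
       n_permutations = n_permutations)
}
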