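#' Build and validate a binary community matrix
#'
#' A community matrix records which species occur at which sites: rows are
#' sites (e.g. one row per site x sampling month), columns are species,
#' entries 0/1. Species that occur nowhere carry no information for any
#' co-occurrence metric and are dropped with a warning.
#'
#' @param x A numeric matrix or data frame of 0/1 values with unique row
#'   (site) and column (species) names.
#' @return An integer matrix with the class attribute untouched; empty
#'   species columns removed.
#' @export
as_community_matrix <- function(x) {
  m <- as.matrix(x)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community matrix needs site row names and species column names")
  if (anyDuplicated(rownames(m))) stop("duplicate site ids")
  if (anyDuplicated(colnames(m))) stop("duplicate species names")
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stop("community matrix entries must be 0 or 1")
  empty <- colSums(m) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " species occurring in no site: ",
            paste(colnames(m)[empty], collapse = ", "))
    m <- m[, !empty, drop = FALSE]
  }
  if (ncol(m) == 0L) stop("community matrix has no occupied species")
  m
}

#' Read a community matrix from CSV
#'
#' Expected dialect: first column holds site ids, header row holds species
#' names, cells are 0/1. [write_community_csv()] emits the same dialect.
#'
#' @param path CSV file path.
#' @return A validated binary community matrix.
#' @export
read_community_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("community CSV needs a site column plus species")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  as_community_matrix(m)
}

#' @rdname read_community_csv
#' @param m A community matrix.
#' @export
write_community_csv <- function(m, path) {
  df <- data.frame(site = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop communities below a richness threshold
#'
#' Sites with fewer than `min_richness` species are removed (standard
#' practice: the co-occurrence metrics MPD and MNTD need at least one species
#' pair). Site order is preserved.
#'
#' @param m Binary community matrix.
#' @param min_richness Minimum species count per retained site (default 2).
#' @return The filtered matrix; errors if no site survives.
#' @export
filter_communities <- function(m, min_richness = 2) {
  m <- as_community_matrix(m)
  keep <- rowSums(m) >= min_richness
  if (!any(keep)) stop("no community reaches richness ", min_richness)
  m[keep, , drop = FALSE]
}

check_members <- function(d, members) {
  if (length(members) < 2L) stop("need at least 2 member species")
  if (anyDuplicated(members)) stop("duplicate member species")
  unknown <- setdiff(members, rownames(d))
  if (length(unknown))
    stop("species not in distance matrix: ", paste(unknown, collapse = ", "))
}

#' Mean pairwise distance of a species set
#'
#' @param d Labelled distance matrix.
#' @param members Character vector of at least 2 species, all present in `d`.
#' @return Mean of `d[i, j]` over all unordered member pairs.
#' @export
mpd <- function(d, members) {
  check_members(d, members)
  sub <- d[members, members]
  mean(sub[lower.tri(sub)])
}

#' Mean nearest taxon distance of a species set
#'
#' For each member, the distance to its closest other member, averaged over
#' members. Always less than or equal to [mpd()] on the same set.
#'
#' @inheritParams mpd
#' @export
mntd <- function(d, members) {
  check_members(d, members)
  sub <- d[members, members]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}

#' Independent-swap randomization of a community matrix
#'
#' Performs `n_swaps` successful checkerboard swaps: a 2x2 submatrix
#' `[[1,0],[0,1]]` is exchanged with `[[0,1],[1,0]]` at uniformly chosen row
#' and column pairs. Swaps preserve every row sum (site richness) and column
#' sum (species frequency) exactly, which is what makes this the null model
#' of choice when species prevalence must be held fixed. Candidate
#' positions are drawn until `n_swaps` succeed or
#' `max_attempts_factor * n_swaps` attempts have been made; if no swappable
#' checkerboard exists (e.g. nested matrices) the input is returned
#' unchanged with a warning.
#'
#' @param m Binary community matrix.
#' @param n_swaps Number of successful swaps to perform.
#' @param seed Integer seed (deterministic output).
#' @param max_attempts_factor Attempt budget per requested swap (default
#'   100).
#' @return A matrix with the same dimnames, row sums and column sums;
#'   attribute `swaps` records the number of successful swaps.
#' @export
independent_swap <- function(m, n_swaps, seed,
                             max_attempts_factor = 100) {
  m <- as_community_matrix(m)
  with_seed(seed, {
    res <- independent_swap_cpp(m, as.integer(n_swaps),
                                max_attempts_factor * as.double(n_swaps))
  })
  out <- res$matrix
  dimnames(out) <- dimnames(m)
  if (res$swaps < n_swaps)
    warning("only ", res$swaps, " of ", n_swaps, " swaps achieved in ",
            format(res$attempts, big.mark = ","), " attempts; ",
            if (res$swaps == 0) "matrix returned unchanged"
            else "matrix under-randomized")
  attr(out, "swaps") <- res$swaps
  out
}

#' NRI and NTI under the independent-swap null model
#'
#' For every community (row), computes observed MPD and MNTD from the
#' supplied distance matrix, then a null distribution of each from
#' `n_randomizations` independently swapped matrices. The net relatedness
#' index and nearest taxon index are the negated standardized effect sizes
#'
#'   NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)
#'   NTI = -(MNTD_obs - mean(MNTD_null)) / sd(MNTD_null)
#'
#' so increasingly positive values indicate phylogenetic clustering and
#' negative values overdispersion. Rank p-values use the (k + 1)/(n + 1)
#' estimator with k the number of null values at or below the observation
#' (small p therefore flags clustering).
#'
#' By default the null matrices form a Markov chain: each randomization
#' applies `n_swaps` further swaps to the previous null matrix.
#' `chained = FALSE` instead restarts each randomization from the observed
#' matrix.
#'
#' @param d Labelled distance matrix covering (at least) all matrix species.
#' @param m Binary community matrix, every row with richness >= 2 (see
#'   [filter_communities()]).
#' @param n_randomizations Null draws per community (default 1000).
#' @param n_swaps Successful swaps between consecutive null matrices
#'   (default 1000).
#' @param seed Integer seed.
#' @param chained Chain the null matrices (default) or restart each from the
#'   observed matrix.
#' @param prune_missing If `TRUE`, species in the matrix but absent from the
#'   distance matrix are dropped with a warning; the default is an error
#'   listing them, so name mismatches surface instead of silently changing
#'   the analysis.
#' @param max_attempts_factor Attempt budget per swap (see
#'   [independent_swap()]).
#' @return A data frame of class `"comm_structure"`, one row per community:
#'   `site`, `richness`, `mpd_obs`, `mpd_null_mean`, `mpd_null_sd`, `nri`,
#'   `p_mpd`, `mntd_obs`, `mntd_null_mean`, `mntd_null_sd`, `nti`, `p_mntd`,
#'   `reason` (`NA` or a code such as `"null_sd_zero"` where NRI/NTI are
#'   undefined). Attributes record `n_randomizations`, `n_swaps`, `seed`,
#'   `chained`.
#' @export
ses_structure <- function(d, m, n_randomizations = 1000, n_swaps = 1000,
                          seed, chained = TRUE, prune_missing = FALSE,
                          max_attempts_factor = 100) {
  d <- validate_distance_matrix(d)
  m <- as_community_matrix(m)
  missing <- setdiff(colnames(m), rownames(d))
  if (length(missing)) {
    if (!prune_missing)
      stop("species in community matrix but not in distance matrix: ",
           paste(missing, collapse = ", "),
           " (set prune_missing = TRUE to drop them)")
    warning("pruning ", length(missing),
            " species absent from the distance matrix: ",
            paste(missing, collapse = ", "))
    m <- as_community_matrix(m[, setdiff(colnames(m), missing), drop = FALSE])
  }
  if (any(rowSums(m) < 2L))
    stop("all communities must have richness >= 2; run filter_communities()")
  dsub <- d[colnames(m), colnames(m)]
  obs_mpd <- mpd_rows_cpp(m, dsub)
  obs_mntd <- mntd_rows_cpp(m, dsub)

  nsite <- nrow(m)
  null_mpd <- matrix(NA_real_, n_randomizations, nsite)
  null_mntd <- matrix(NA_real_, n_randomizations, nsite)
  budget <- max_attempts_factor * as.double(n_swaps)
  short <- 0L
  with_seed(seed, {
    cur <- m
    for (r in seq_len(n_randomizations)) {
      res <- independent_swap_cpp(if (chained) cur else m,
                                  as.integer(n_swaps), budget)
      cur <- res$matrix
      if (res$swaps < n_swaps) short <- short + 1L
      null_mpd[r, ] <- mpd_rows_cpp(cur, dsub)
      null_mntd[r, ] <- mntd_rows_cpp(cur, dsub)
    }
  })
  if (short > 0L)
    warning(short, " randomization(s) achieved fewer than ", n_swaps,
            " swaps")

  summarize <- function(obs, null) {
    mu <- colMeans(null)
    sdv <- apply(null, 2, sd)
    z <- ifelse(sdv > 0, -(obs - mu) / sdv, NA_real_)
    p <- (colSums(sweep(null, 2, obs, "<=")) + 1) / (n_randomizations + 1)
    list(mean = mu, sd = sdv, z = z, p = p)
  }
  smpd <- summarize(obs_mpd, null_mpd)
  smntd <- summarize(obs_mntd, null_mntd)
  reason <- ifelse(smpd$sd == 0 | smntd$sd == 0, "null_sd_zero", NA_character_)

  out <- data.frame(
    site = rownames(m),
    richness = as.integer(rowSums(m)),
    mpd_obs = obs_mpd, mpd_null_mean = smpd$mean, mpd_null_sd = smpd$sd,
    nri = smpd$z, p_mpd = smpd$p,
    mntd_obs = obs_mntd, mntd_null_mean = smntd$mean,
    mntd_null_sd = smntd$sd, nti = smntd$z, p_mntd = smntd$p,
    reason = reason,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_randomizations") <- n_randomizations
  attr(out, "n_swaps") <- n_swaps
  attr(out, "seed") <- seed
  attr(out, "chained") <- chained
  class(out) <- c("comm_structure", "data.frame")
  out
}
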