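#' Linear regression through the origin
#'
#' No-intercept least squares of `y` on `x`: `slope = sum(xy) / sum(x^2)`
#' with the uncentered coefficient of determination
#' `r2 = sum(xy)^2 / (sum(x^2) sum(y^2))`. Used to ask how faithfully one
#' phylogeny's community metrics reproduce another's: a slope near 1 with
#' high r2 means the candidate tree recovers both the scale and the ordering
#' of the baseline values. Pairs in which either value is undefined (`NA`)
#' are dropped listwise and counted.
#'
#' @param x Baseline metric values.
#' @param y Candidate metric values (same length).
#' @return A list: `slope`, `r2`, `n_points`, `n_dropped`.
#' @export
origin_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2L) stop("fewer than 2 valid pairs")
  sxx <- sum(x^2)
  if (sxx == 0) stop("sum(x^2) is zero; slope undefined")
  sxy <- sum(x * y)
  syy <- sum(y^2)
  list(slope = sxy / sxx,
       r2 = if (syy == 0) NA_real_ else sxy^2 / (sxx * syy),
       n_points = length(x), n_dropped = n_dropped)
}

#' Compare community-structure metrics across candidate phylogenies
#'
#' Given [ses_structure()] results computed from a baseline tree and from
#' one or more candidate trees on the same communities, regresses each
#' candidate's NRI and NTI through the origin against the baseline's. Rows
#' where either tree leaves the metric undefined are dropped listwise.
#'
#' @param baseline A `"comm_structure"` data frame from the baseline tree.
#' @param candidates Named list of `"comm_structure"` data frames from the
#'   candidate trees, on exactly the same community set.
#' @return A data frame with one row per candidate x metric: `tree`,
#'   `metric` (`"nri"`/`"nti"`), `slope`, `r2`, `n`, `n_dropped`.
#' @export
compare_trees <- function(baseline, candidates) {
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be a named list")
  rows <- lapply(names(candidates), function(nm) {
    cand <- candidates[[nm]]
    if (!identical(cand$site, baseline$site)) {
      dd <- union(setdiff(cand$site, baseline$site),
                  setdiff(baseline$site, cand$site))
      stop("community sets differ for candidate '", nm, "': ",
           if (length(dd)) paste(dd, collapse = ", ")
           else "same sites in different order")
    }
    do.call(rbind, lapply(c("nri", "nti"), function(metric) {
      reg <- origin_regression(baseline[[metric]], cand[[metric]])
      data.frame(tree = nm, metric = metric, slope = reg$slope, r2 = reg$r2,
                 n = reg$n_points, n_dropped = reg$n_dropped,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
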