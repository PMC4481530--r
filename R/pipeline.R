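# Tiny rolling hash of a string; used only to stamp outputs with a
# fingerprint of the run configuration.
config_fingerprint <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full cross-phylogeny comparison workflow
#'
#' Orchestrates the complete analysis on a set of candidate phylogenies for
#' one community dataset: (1) converts every tree to a patristic distance
#' matrix and tests their congruence (CADM with a-posteriori Mantel tests
#' against the baseline tree); (2) computes NRI and NTI for every community
#' under every tree with the independent-swap null; (3) regresses each
#' candidate tree's metrics through the origin against the baseline's;
#' (4) computes Blomberg's K and Pagel's lambda for each trait on each tree;
#' and (5) records full provenance (parameters, seed, package version,
#' config fingerprint). The same seed is used for the null model under every
#' tree, so all trees face an identical sequence of swapped matrices.
#'
#' @param trees Named list of `"phylo"` trees; must include `baseline`.
#' @param baseline Name of the reference tree.
#' @param communities Binary community matrix (filtered internally to
#'   richness >= `min_richness`).
#' @param traits Named list of named numeric trait vectors (may be empty).
#'   Species missing from a tree are pruned per [prune_to_traits()].
#' @param n_randomizations,n_swaps Null-model effort for [ses_structure()].
#' @param n_permutations Permutations for congruence and K tests.
#' @param seed Integer seed governing every randomized stage.
#' @param min_richness Community filter threshold (default 2).
#' @param outdir Optional directory; when given, writes
#'   `congruence.tsv`, `structure_<tree>.tsv`, `comparison.tsv`,
#'   `signal.tsv` and `provenance.json`.
#' @param ... Further arguments passed to [ses_structure()] (e.g.
#'   `prune_missing`, `chained`).
#' @return A list: `congruence` (data frame, one row per candidate tree:
#'   Mantel r and p vs the baseline, plus global W/chi2/p as attributes),
#'   `structure` (named list of `"comm_structure"` frames), `comparison`
#'   (origin-regression table), `signal` (K and lambda per trait per tree),
#'   `provenance`.
#' @export
run_pipeline <- function(trees, baseline, communities, traits = list(),
                         n_randomizations = 1000, n_swaps = 1000,
                         n_permutations = 999, seed, min_richness = 2,
                         outdir = NULL, ...) {
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    stop("trees must be a named list")
  if (!baseline %in% names(trees))
    stop("baseline '", baseline, "' not among tree labels: ",
         paste(names(trees), collapse = ", "))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, started) {
    message(sprintf("[%s] done in %.1fs", what,
                    proc.time()[["elapsed"]] - started))
  }

  comm <- filter_communities(communities, min_richness = min_richness)
  dists <- lapply(trees, patristic_matrix)

  s <- proc.time()[["elapsed"]]
  ordered <- c(baseline, setdiff(names(trees), baseline))
  cad <- cadm_global(dists[ordered], n_permutations = n_permutations,
                     seed = seed, pairwise = "reference")
  congr <- data.frame(tree = cad$pairwise$matrix_b,
                      mantel_r = cad$pairwise$mantel_r,
                      p = cad$pairwise$p, stringsAsFactors = FALSE)
  attr(congr, "W") <- cad$W
  attr(congr, "chi2") <- cad$chi2
  attr(congr, "p_global") <- cad$p_global
  stage("congruence", s)

  s <- proc.time()[["elapsed"]]
  structure_res <- lapply(dists, function(d)
    ses_structure(d, comm, n_randomizations = n_randomizations,
                  n_swaps = n_swaps, seed = seed, ...))
  stage("community structure", s)

  s <- proc.time()[["elapsed"]]
  comparison <- compare_trees(structure_res[[baseline]],
                              structure_res[setdiff(names(trees), baseline)])
  stage("comparison", s)

  signal <- NULL
  if (length(traits)) {
    s <- proc.time()[["elapsed"]]
    signal <- do.call(rbind, lapply(names(trees), function(tn) {
      do.call(rbind, lapply(names(traits), function(trn) {
        row <- signal_summary(trees[[tn]], traits[[trn]], trait_name = trn,
                              n_permutations = n_permutations, seed = seed)
        cbind(tree = tn, row, stringsAsFactors = FALSE)
      }))
    }))
    stage("trait signal", s)
  }

  config <- list(trees = names(trees), baseline = baseline,
                 n_communities = nrow(comm),
                 n_species = ncol(comm),
                 traits = names(traits),
                 n_randomizations = n_randomizations, n_swaps = n_swaps,
                 n_permutations = n_permutations, seed = seed,
                 min_richness = min_richness)
  provenance <- c(config, list(
    package = "commphylo",
    version = as.character(packageVersion("commphylo")),
    config_hash = config_fingerprint(
      as.character(jsonlite::toJSON(config, auto_unbox = TRUE))),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2)))

  out <- list(congruence = congr, structure = structure_res,
              comparison = comparison, signal = signal,
              provenance = provenance)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(congr, file.path(outdir, "congruence.tsv"))
    for (tn in names(structure_res))
      write_tsv(structure_res[[tn]],
                file.path(outdir, paste0("structure_", tn, ".tsv")))
    write_tsv(comparison, file.path(outdir, "comparison.tsv"))
    if (!is.null(signal)) write_tsv(signal, file.path(outdir, "signal.tsv"))
    jsonlite::write_json(provenance, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
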