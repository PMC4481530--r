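#' Simulate a pure-birth (Yule) species tree
#'
#' Grows a tree from a root bifurcation under a constant birth rate until it
#' has exactly `n_tips` lineages, extending all pending branches through the
#' final waiting interval, so trees are ultrametric by construction and the
#' expected root-to-tip depth is `sum(1 / (k * birth_rate))` for
#' `k = 2, ..., n_tips`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per unit time (> 0).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An ultrametric `"phylo"` tree with tips `t1 ... tn`.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  with_seed(seed, {
    root <- -1L
    n_int <- 1L
    active_parent <- c(root, root)
    active_len <- c(0, 0)
    ep <- integer(0)   # closed edges: provisional parent
    ec <- integer(0)   #               provisional child
    el <- numeric(0)
    k <- 2L
    repeat {
      dt <- rexp(1, birth_rate * k)
      active_len <- active_len + dt
      if (k == n_tips) break
      i <- sample.int(k, 1)
      n_int <- n_int + 1L
      node <- -n_int
      ep <- c(ep, active_parent[i])
      ec <- c(ec, node)
      el <- c(el, active_len[i])
      active_parent <- c(active_parent[-i], node, node)
      active_len <- c(active_len[-i], 0, 0)
      k <- k + 1L
    }
    tip_order <- sample.int(n_tips)  # detach tip labels from birth order
  })
  n_tip_edges <- length(active_parent)
  ep <- c(ep, active_parent)
  ec <- c(ec, tip_order)            # tips get ids 1..n directly
  el <- c(el, active_len)
  # provisional internal id -j -> n + j
  remap <- function(x) ifelse(x < 0, n_tips - x, x)
  tree <- list(edge = cbind(remap(ep), remap(ec)), edge.length = el,
               tip.label = paste0("t", seq_len(n_tips)), Nnode = n_int)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_tree(tree)
  tree
}

#' Assign family labels by cutting a tree at a fixed depth
#'
#' Slices an ultrametric tree at the shallowest depth yielding exactly
#' `n_families` clades and labels each tip by its clade, emulating a
#' family-structured species pool. Used to feed
#' [stretch_deep_branches()] on simulated trees.
#'
#' @param tree An ultrametric `"phylo"` tree.
#' @param n_families Desired number of families (between 2 and the number
#'   of tips).
#' @return Named character vector: tip label -> family name (`F01`, ...).
#' @export
cut_families <- function(tree, n_families) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  stopifnot(n_families >= 2, n_families <= n)
  nd <- ape::node.depth.edgelength(tree)       # depth from root, all nodes
  total <- max(nd[seq_len(n)])
  # crossing a horizontal cut after k internal nodes leaves k + 1 clades,
  # so cut between the (n_families - 1)th and n_families-th internal depth
  ds <- sort(nd[(n + 1):(n + tree$Nnode)])
  cut_at <- if (n_families - 1 < length(ds))
    (ds[n_families - 1] + ds[n_families]) / 2
  else
    (ds[length(ds)] + total) / 2
  edges <- which(nd[tree$edge[, 1]] < cut_at & nd[tree$edge[, 2]] >= cut_at)
  fam <- setNames(rep(NA_character_, n), tree$tip.label)
  for (i in seq_along(edges)) {
    child <- tree$edge[edges[i], 2]
    tips <- if (child <= n) child else which_tips_under(tree, child)
    fam[tree$tip.label[tips]] <- sprintf("F%02d", i)
  }
  fam
}

which_tips_under <- function(tree, node) {
  n <- length(tree$tip.label)
  under <- which_nodes_under(tree, node)
  sort(under[under <= n])
}

#' Simulate continuous traits under lambda-transformed Brownian motion
#'
#' Draws one trait value per tip from the multivariate normal with mean
#' `root_state` and covariance `sigma2 * V_lambda` (see [lambda_vcv()]).
#' With `lambda_true = 1` this is plain Brownian motion; `lambda_true = 0`
#' gives independent values with variance `sigma2 * depth(tip)`.
#'
#' @param tree A `"phylo"` tree.
#' @param sigma2 Brownian rate (trait variance per unit branch length, > 0).
#' @param lambda_true Transform parameter in `[0, 1]`.
#' @param root_state Ancestral trait value.
#' @param seed Integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, lambda_true = 1,
                               root_state = 0, seed) {
  stopifnot(sigma2 > 0, lambda_true >= 0, lambda_true <= 1)
  validate_tree(tree)
  v <- lambda_vcv(tree, lambda_true) * sigma2
  ch <- tryCatch(chol(v), error = function(e)
    stop("trait covariance not positive definite"))
  with_seed(seed, {
    z <- rnorm(nrow(v))
  })
  y <- drop(crossprod(ch, z)) + root_state
  setNames(y, rownames(v))
}

#' Simulate community assembly on a phylogeny
#'
#' Generates a binary site x species matrix with known assembly structure:
#'
#' * `"random"` -- each community is a uniform draw of species.
#' * `"clustered"` -- each community starts from one uniformly chosen seed
#'   species; the remaining members are drawn without replacement with
#'   weights proportional to `exp(-strength * d(i, seed))`, so communities
#'   concentrate in clades (environmental filtering caricature).
#' * `"overdispersed"` -- members are added sequentially with weights
#'   proportional to `exp(+strength * min d(i, selected))`, pushing each new
#'   member away from those already present (competition caricature).
#'
#' `strength = 0` collapses every mode to the random one.
#'
#' @param tree A `"phylo"` tree (distances taken from
#'   [patristic_matrix()]).
#' @param n_communities Number of sites to draw.
#' @param richness_range Integer vector `c(min, max)` of per-site richness;
#'   min >= 2, max <= number of tips. Richness is uniform on the range.
#' @param mode Assembly mode (see above).
#' @param strength Selection intensity (>= 0), in units of 1/distance.
#' @param seed Integer seed.
#' @return A binary community matrix with rows `c001, c002, ...`.
#' @export
simulate_communities <- function(tree, n_communities,
                                 richness_range = c(2, 20),
                                 mode = c("random", "clustered",
                                          "overdispersed"),
                                 strength = 0, seed) {
  mode <- match.arg(mode)
  stopifnot(strength >= 0, n_communities >= 1)
  d <- patristic_matrix(tree)
  sp <- rownames(d)
  ns <- length(sp)
  rmin <- as.integer(richness_range[1])
  rmax <- as.integer(richness_range[2])
  if (rmin < 2 || rmax > ns || rmin > rmax)
    stop("infeasible richness range [", rmin, ", ", rmax, "] for ", ns,
         " species")
  m <- matrix(0L, n_communities, ns,
              dimnames = list(sprintf("c%03d", seq_len(n_communities)), sp))
  with_seed(seed, {
    for (i in seq_len(n_communities)) {
      k <- if (rmin == rmax) rmin else sample(rmin:rmax, 1)
      members <- if (mode == "random" || strength == 0) {
        sample(ns, k)
      } else if (mode == "clustered") {
        seed_sp <- sample(ns, 1)
        pool <- setdiff(seq_len(ns), seed_sp)
        w <- exp(-strength * d[pool, seed_sp])
        c(seed_sp, sample(pool, k - 1, prob = w / sum(w)))
      } else {
        sel <- sample(ns, 1)
        while (length(sel) < k) {
          pool <- setdiff(seq_len(ns), sel)
          mind <- apply(d[pool, sel, drop = FALSE], 1, min)
          w <- exp(strength * (mind - max(mind)))  # rescaled for stability
          sel <- c(sel, sample(pool, 1, prob = w / sum(w)))
        }
        sel
      }
      m[i, members] <- 1L
    }
  })
  as_community_matrix(m)
}

#' A synthetic caddisfly-style survey bundle
#'
#' Builds a complete demonstration dataset shaped like a subarctic
#' stream-and-pond insect survey: an ultrametric 46-species tree grouped
#' into family-like clades; a site x month occurrence table from 75
#' freshwater sites each visited in three months (225 site-month records,
#' of which 101 hold two or more species and thus survive
#' [filter_communities()]); and two body-size traits in millimetres (body
#' length for all species, case length missing for four caseless species)
#' evolved under lambda-transformed Brownian motion. All components are
#' synthetic -- generated by this package's simulators from the given seed --
#' and emulate the design of a real survey without reproducing any real
#' data.
#'
#' Communities are assembled in `"clustered"` mode (the regime such surveys
#' typically detect), with below-threshold site-months (0 or 1 species)
#' interleaved at seeded positions so the load-filter step has something to
#' do.
#'
#' @param seed Integer seed (default 20100605).
#' @param n_species Number of species (default 46).
#' @param n_sites Number of sites (default 75), each sampled in 3 months.
#' @param n_analyzable Number of site-months with richness >= 2
#'   (default 101).
#' @param strength Clustering strength passed to
#'   [simulate_communities()] (default 2).
#' @return A list: `tree`, `families`, `communities` (the full 225-row
#'   matrix including sparse site-months), `traits` (list with
#'   `body_length`, `case_length`), `seed`.
#' @export
synthetic_churchill <- function(seed = 20100605, n_species = 46,
                                n_sites = 75, n_analyzable = 101,
                                strength = 2) {
  n_records <- n_sites * 3
  stopifnot(n_analyzable <= n_records)
  tree <- simulate_yule(n_species, birth_rate = 1, seed = seed)
  families <- cut_families(tree, n_families = 12)
  rich <- simulate_communities(tree, n_communities = n_analyzable,
                               richness_range = c(2, 16),
                               mode = "clustered", strength = strength,
                               seed = seed + 1)
  sp <- tree$tip.label
  months <- c("jun", "jul", "aug")
  ids <- as.vector(t(outer(sprintf("site%02d", seq_len(n_sites)), months,
                           paste, sep = "_")))
  full <- matrix(0L, n_records, n_species, dimnames = list(ids, sp))
  with_seed(seed + 2, {
    analyzable_rows <- sort(sample(n_records, n_analyzable))
    # sparse records: mostly empty, some singletons
    sparse_rows <- setdiff(seq_len(n_records), analyzable_rows)
    singleton <- sample(sparse_rows, length(sparse_rows) %/% 2)
    for (r in singleton) full[r, sample(n_species, 1)] <- 1L
  })
  full[analyzable_rows, ] <- rich
  # every species in the pool was observed at least once in the survey:
  # park any species the assembly draw missed in otherwise-empty records
  absent <- which(colSums(full) == 0L)
  if (length(absent)) {
    empty_rows <- which(rowSums(full) == 0L)
    stopifnot(length(empty_rows) >= length(absent))
    full[cbind(empty_rows[seq_along(absent)], absent)] <- 1L
  }
  body <- simulate_bm_traits(tree, sigma2 = 8, lambda_true = 0.45,
                             root_state = 15, seed = seed + 3)
  body <- pmax(body, 2)                       # lengths stay positive, in mm
  caseless <- with_seed(seed + 4, sample(sp, 4))
  case <- simulate_bm_traits(tree, sigma2 = 12, lambda_true = 0.5,
                             root_state = 20, seed = seed + 5)
  case <- pmax(case, 3)[setdiff(sp, caseless)]
  list(tree = tree, families = families, communities = full,
       traits = list(body_length = body, case_length = case),
       caseless = caseless, seed = seed)
}
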