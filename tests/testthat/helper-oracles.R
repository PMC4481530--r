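# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (and ape's distance functions) wherever they act
# as the reference.

# Path-sum patristic distances computed from first principles: walk each
# tip's edge path to the root, then sum the symmetric difference.
naive_patristic <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  path_edges <- function(tip) {
    edges <- character(0)
    node <- tip
    while (node != root) {
      edges <- c(edges, as.character(node))
      node <- parent[node]
    }
    edges
  }
  paths <- lapply(seq_len(n), path_edges)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sym <- c(setdiff(paths[[i]], paths[[j]]), setdiff(paths[[j]], paths[[i]]))
    d[i, j] <- sum(plen[as.integer(sym)])
  }
  d
}

brute_mpd <- function(d, members) {
  pairs <- combn(members, 2)
  mean(apply(pairs, 2, function(p) d[p[1], p[2]]))
}

brute_mntd <- function(d, members) {
  mean(vapply(members, function(m)
    min(d[m, setdiff(members, m)]), numeric(1)))
}

# A random rooted binary tree with branch lengths, via ape, fixed seed.
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("s", seq_len(n))
  tr
}

# Hand transcription of the TN93 closed form for one pair of sequences
# (base frequencies from the two sequences pooled, matching pooled
# empirical frequencies on the compared sites).
tn93_pair_oracle <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  f <- table(factor(c(a, b), levels = c("A", "C", "G", "T"))) / (2 * n)
  pa <- f[["A"]]; pc <- f[["C"]]; pg <- f[["G"]]; pt <- f[["T"]]
  pr <- pa + pg; py <- pc + pt
  is_ts_ag <- (a == "A" & b == "G") | (a == "G" & b == "A")
  is_ts_ct <- (a == "C" & b == "T") | (a == "T" & b == "C")
  p1 <- mean(is_ts_ag)
  p2 <- mean(is_ts_ct)
  q <- mean(a != b & !is_ts_ag & !is_ts_ct)
  k1 <- 2 * pa * pg / pr
  k2 <- 2 * pt * pc / py
  k3 <- 2 * (pr * py - pa * pg * py / pr - pt * pc * pr / py)
  -k1 * log(1 - p1 / k1 - q / (2 * pr)) -
    k2 * log(1 - p2 / k2 - q / (2 * py)) -
    k3 * log(1 - q / (2 * pr * py))
}

# Direct (dense solve + determinant) multivariate-normal log density.
dmvnorm_log <- function(y, mu, sigma) {
  n <- length(y)
  r <- y - mu
  q <- drop(crossprod(r, solve(sigma, r)))
  -0.5 * (n * log(2 * pi) + determinant(sigma, logarithm = TRUE)$modulus + q)
}

# Brownian covariance from first principles: shared root-to-MRCA depth.
naive_bm_vcv <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  anc <- function(tip) {
    nodes <- tip
    while (nodes[length(nodes)] != root)
      nodes <- c(nodes, parent[nodes[length(nodes)]])
    nodes
  }
  depth <- function(node) {
    tot <- 0
    while (node != root) {
      tot <- tot + plen[node]
      node <- parent[node]
    }
    tot
  }
  v <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mrca <- intersect(anc(i), anc(j))[1]
    v[i, j] <- depth(mrca)
  }
  diag(v) <- vapply(seq_len(n), depth, numeric(1))
  v
}

# Random binary community matrix; every species occurs at least once so
# validation does not reshape it.
random_binary_matrix <- function(nr, nc, fill = 0.3,
                                 species = paste0("c", seq_len(nc))) {
  m <- matrix(rbinom(nr * nc, 1, fill), nr, nc,
              dimnames = list(paste0("r", seq_len(nr)), species))
  for (j in which(colSums(m) == 0)) m[sample(nr, 1), j] <- 1
  storage.mode(m) <- "integer"
  m
}

# Reverse the distance ranks of a matrix while keeping it a valid
# distance matrix (max + min - d on the off-diagonal).
rank_reverse <- function(d) {
  v <- d[upper.tri(d)]
  out <- max(v) + min(v) - d
  diag(out) <- 0
  out
}
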