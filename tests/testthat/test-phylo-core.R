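test_that("Newick parsing reads structure, labels and lengths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])
  expect_length(root, 1)
  expect_equal(sum(tr$edge[, 1] == root), 2)

  tr2 <- parse_newick("(A:1,B:1);")
  expect_equal(sort(tr2$tip.label), c("A", "B"))
  expect_equal(unname(tr2$edge.length), c(1, 1))

  q <- parse_newick("((A:1,'sp. nov.':1):1,C:2);")
  expect_true("sp. nov." %in% q$tip.label)
})

test_that("malformed or invalid Newick fails informatively", {
  expect_error(parse_newick("((A:1,B:1):1,C:2"), "character")
  expect_error(parse_newick("(A:1,B:1)):1;"), "character 10")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate")
  expect_warning(tr <- parse_newick("((A:1,B):1,C:2);"), "missing")
  expect_equal(sum(tr$edge.length == 0), 1)
})

test_that("Newick write/parse round trip is lossless", {
  for (seed in 1:20) {
    tr <- random_tree(8, seed)
    back <- parse_newick(write_newick(tr))
    expect_equal(back$tip.label, tr$tip.label)
    expect_equal(back$edge, tr$edge)
    expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-14)
  }
  # quoted labels survive a round trip
  s <- "((A:1,'sp. nov.':1):0.5,C:2);"
  out <- write_newick(parse_newick(s))
  expect_match(out, "'sp. nov.'", fixed = TRUE)
  expect_true("sp. nov." %in% parse_newick(out)$tip.label)
  # internal support labels retained
  tr <- parse_newick("((A:1,B:1)0.95:1,C:2);")
  expect_true("0.95" %in% tr$node.label)
  expect_match(write_newick(tr), ")0.95:", fixed = TRUE)
})

test_that("patristic distances equal hand path sums and the naive oracle", {
  d <- patristic_matrix(parse_newick("((A:1,B:1):1,C:2);"))
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (seed in 1:25) {
    tr <- random_tree(10, seed)
    expect_equal(patristic_matrix(tr), naive_patristic(tr))
  }
})

test_that("patristic distances are invariant to rerooting", {
  tr <- random_tree(8, 42)
  d0 <- patristic_matrix(tr)
  for (node in c(3L, 5L, 7L)) {
    rr <- ape::root(tr, outgroup = node, resolve.root = TRUE)
    dr <- patristic_matrix(rr)[rownames(d0), colnames(d0)]
    expect_equal(dr, d0, tolerance = 1e-12)
  }
})

test_that("TN93 distances match an independent closed-form transcription", {
  base <- paste(rep("ACGT", 25), collapse = "")
  same <- c(x = base, y = base)
  expect_equal(unname(tn93_distance(same)["x", "y"]), 0)

  s2 <- base
  substr(s2, 1, 1) <- "G"   # one A->G transition among 100 sites
  d <- tn93_distance(c(x = base, y = s2))
  expect_equal(unname(d["x", "y"]), tn93_pair_oracle(base, s2),
               tolerance = 1e-10)

  # a messier pair with transitions and transversions
  s3 <- base
  substr(s3, 2, 2) <- "T"; substr(s3, 5, 5) <- "G"; substr(s3, 12, 12) <- "A"
  d3 <- tn93_distance(c(x = base, y = s3))
  expect_equal(unname(d3["x", "y"]), tn93_pair_oracle(base, s3),
               tolerance = 1e-10)

  # enormous gamma shape reproduces the uncorrected distance
  dg <- tn93_distance(c(x = base, y = s3), gamma_shape = 1e7)
  expect_equal(unname(dg["x", "y"]), unname(d3["x", "y"]), tolerance = 1e-6)
})

test_that("TN93 handles gaps, saturation and empty overlap as specified", {
  base <- paste(rep("ACGT", 25), collapse = "")
  gappy <- sub("^....", "----", base)
  d <- tn93_distance(c(x = base, y = gappy))  # pairwise deletion: identical
  expect_equal(unname(d["x", "y"]), 0)

  expect_error(
    tn93_distance(c(x = paste0("AC", strrep("-", 8)),
                    y = paste0(strrep("-", 8), "AC"))),
    "no comparable sites")

  # an all-transversion pair saturates every log term
  base <- paste(rep("ACGT", 25), collapse = "")
  flip <- chartr("ACGT", "CATG", base)
  near <- base
  substr(near, 1, 1) <- "G"
  expect_warning(ds <- tn93_distance(c(x = base, y = flip, z = near)),
                 "saturation")
  expect_true(is.na(ds["x", "y"]))
  expect_gte(nrow(attr(ds, "undefined_pairs")), 1L)
  expect_error(neighbor_joining(ds), "undefined")
})

test_that("neighbour joining solves the 3-taxon path equations", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d3)
  tip_len <- tr$edge.length[match(seq_len(3), tr$edge[, 2])]
  expect_equal(setNames(tip_len, tr$tip.label)[c("A", "B", "C")],
               c(A = 1, B = 1, C = 3))
  expect_true(attr(tr, "unrooted"))
  expect_error(neighbor_joining(d3[1:2, 1:2]), "at least 3")
})

test_that("neighbour joining exactly recovers additive trees", {
  for (n in 4:8) {
    tr <- random_tree(n, 100 + n)
    d <- patristic_matrix(tr)
    rec <- neighbor_joining(d)
    drec <- patristic_matrix(rec)[rownames(d), colnames(d)]
    expect_lt(max(abs(drec - d)), 1e-9)
    expect_equal(
      ape::dist.topo(ape::unroot(tr), ape::unroot(rec)), 0,
      ignore_attr = TRUE)
  }
})

test_that("negative NJ branch lengths are clamped with a warning", {
  d <- matrix(c(0, 1, 6, 1, 0, 2, 6, 2, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # violates additivity strongly enough to force a negative estimate
  d["A", "C"] <- d["C", "A"] <- 0.5
  expect_warning(tr <- neighbor_joining(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("deep-branch stretching rescales only between-family paths", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  fam <- c(A = "f1", B = "f1", C = "f2", D = "f2")
  expect_equal(patristic_matrix(stretch_deep_branches(tr, fam, 1)),
               patristic_matrix(tr))
  d2 <- patristic_matrix(stretch_deep_branches(tr, fam, 2))
  expect_equal(d2["A", "C"], 6)
  expect_equal(d2["A", "B"], 2)

  # property on random family-structured trees: within-family distances
  # invariant; between-family distances equal within part + f * deep part
  for (seed in 1:10) {
    tr <- commphylo::simulate_yule(16, 1, seed = seed)
    fam <- commphylo::cut_families(tr, 4)
    d0 <- patristic_matrix(tr)
    f <- 2.5
    df <- patristic_matrix(stretch_deep_branches(tr, fam, f))
    same <- outer(fam[rownames(d0)], fam[colnames(d0)], "==")
    expect_equal(df[same], d0[same])
    expect_true(all(df[!same] >= d0[!same]))
    # decomposition: the deep part of each between-family path is the
    # difference from the unstretched matrix, and scales linearly in f
    deep0 <- patristic_matrix(stretch_deep_branches(tr, fam, 2)) - d0
    expect_equal(df - d0, deep0 * (f - 1), tolerance = 1e-12)
  }
})

test_that("stem-only stretching touches exactly the family stems", {
  tr <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,E:4);")
  fam <- c(A = "f1", B = "f1", C = "f2", D = "f2", E = "f3")
  d0 <- patristic_matrix(tr)
  ds <- patristic_matrix(stretch_deep_branches(tr, fam, 3, which = "stems"))
  expect_equal(ds["A", "B"], d0["A", "B"])       # inside f1
  expect_equal(ds["A", "C"], d0["A", "C"] + 2 * 2)  # two stems of length 1
  expect_equal(ds["A", "E"], d0["A", "E"] + 2 + 2 * 4)  # f1 stem + E stem
})

test_that("non-monophyletic families are rejected with the offending tips", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  bad <- c(A = "f1", C = "f1", B = "f2", D = "f2")
  expect_error(stretch_deep_branches(tr, bad, 2), "not monophyletic")
  expect_error(stretch_deep_branches(tr, c(A = "f1", B = "f1", C = "f2"), 2),
               "without family")
})

test_that("tip shuffling permutes labels but not the distance multiset", {
  tr <- random_tree(12, 9)
  s1 <- shuffle_tips(tr, seed = 5)
  s2 <- shuffle_tips(tr, seed = 5)
  expect_identical(s1$tip.label, s2$tip.label)
  expect_false(identical(s1$tip.label, shuffle_tips(tr, seed = 6)$tip.label))
  d0 <- patristic_matrix(tr)
  d1 <- patristic_matrix(s1)
  expect_equal(sort(d0[upper.tri(d0)]), sort(d1[upper.tri(d1)]))
  expect_equal(s1$edge, tr$edge)
  expect_equal(s1$edge.length, tr$edge.length)

  two <- parse_newick("(A:1,B:2);")
  labs <- shuffle_tips(two, seed = 3)$tip.label
  expect_true(identical(labs, c("A", "B")) || identical(labs, c("B", "A")))
})
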