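make_comm <- function(rows, species) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0("site", seq_along(rows)), species)
  storage.mode(m) <- "integer"
  m
}

test_that("community matrix validation enforces the binary contract", {
  m <- make_comm(list(c(1, 0, 1), c(0, 1, 1)), c("A", "B", "C"))
  expect_silent(as_community_matrix(m))
  bad <- m; bad[1, 1] <- 2L
  expect_error(as_community_matrix(bad), "0 or 1")
  empty <- cbind(m, D = c(0L, 0L))
  expect_warning(out <- as_community_matrix(empty), "no site")
  expect_equal(colnames(out), c("A", "B", "C"))
})

test_that("richness filter keeps exactly the sites with enough species", {
  m <- make_comm(list(c(1, 0, 0, 0, 0), c(1, 1, 0, 0, 0), c(1, 1, 1, 1, 1)),
                 paste0("s", 1:5))
  f <- filter_communities(m)
  expect_equal(rownames(f), c("site2", "site3"))
  expect_equal(filter_communities(m, min_richness = 1), m)
  expect_error(filter_communities(m, min_richness = 6), "no community")
})

test_that("community CSV round trips through the documented dialect", {
  m <- make_comm(list(c(1, 0, 1), c(0, 1, 1)), c("A", "B", "C"))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_community_csv(m, path)
  expect_equal(read_community_csv(path), m)
})

test_that("MPD and MNTD match exhaustive enumeration on all small subsets", {
  d <- patristic_matrix(parse_newick("((A:1,B:1):1,C:2);"))
  expect_equal(mpd(d, c("A", "B")), 2)
  expect_equal(mpd(d, c("A", "B", "C")), 10 / 3)
  expect_equal(mntd(d, c("A", "B")), 2)
  expect_equal(mntd(d, c("A", "B", "C")), 8 / 3)
  expect_error(mpd(d, c("A", "Z")), "Z")

  tr <- random_tree(10, 77)
  dd <- patristic_matrix(tr)
  for (k in 2:6) {
    subsets <- combn(rownames(dd), k)
    for (j in seq_len(ncol(subsets))) {
      mem <- subsets[, j]
      expect_equal(mpd(dd, mem), brute_mpd(dd, mem))
      expect_equal(mntd(dd, mem), brute_mntd(dd, mem))
      expect_lte(mntd(dd, mem), mpd(dd, mem))
    }
  }
})

test_that("independent swap flips the unique checkerboard and skips", {
  m <- make_comm(list(c(1, 0), c(0, 1)), c("A", "B"))
  s <- independent_swap(m, 1, seed = 1)
  expect_equal(unname(s), matrix(c(0L, 1L, 1L, 0L), 2), ignore_attr = TRUE)
  nochecker <- make_comm(list(c(1, 1), c(1, 0)), c("A", "B"))
  expect_warning(u <- independent_swap(nochecker, 1, seed = 1,
                                       max_attempts_factor = 50),
                 "unchanged")
  expect_equal(unname(u), unname(nochecker), ignore_attr = TRUE)
})

test_that("independent swap preserves margins and is seed-deterministic", {
  set.seed(99)
  for (i in 1:100) {
    m <- random_binary_matrix(sample(3:12, 1), sample(3:12, 1))
    s <- independent_swap(m, 50, seed = i)
    expect_identical(rowSums(s), rowSums(m))
    expect_identical(colSums(s), colSums(m))
  }
  m <- random_binary_matrix(8, 8)
  expect_identical(unclass(independent_swap(m, 100, seed = 7)),
                   unclass(independent_swap(m, 100, seed = 7)))
})

test_that("NRI/NTI sign convention: sister-tip communities are clustered", {
  # A and B are near-identical sisters; all other species are far apart
  tr <- parse_newick(
    "((A:0.1,B:0.1):10,((C:5,D:5):5,(E:5,(F:5,G:5):5):5):10);")
  d <- patristic_matrix(tr)
  set.seed(42)
  filler <- t(replicate(30, {
    r <- rep(0L, 7)
    r[sample(7, sample(2:4, 1))] <- 1L
    r
  }))
  m <- rbind(c(1L, 1L, rep(0L, 5)), filler)
  dimnames(m) <- list(paste0("site", 0:30), rownames(d))
  m <- filter_communities(m)
  res <- ses_structure(d, m, n_randomizations = 200, n_swaps = 100,
                       seed = 11)
  target <- res[res$site == "site0", ]
  expect_gt(target$nri, 0)
  expect_gt(target$nti, 0)
  expect_lt(target$p_mpd, 0.25)
})

test_that("ses_structure is reproducible and flags degenerate nulls", {
  tr <- random_tree(8, 3)
  d <- patristic_matrix(tr)
  set.seed(12)
  m <- random_binary_matrix(10, 8, species = rownames(d))
  m <- filter_communities(m)
  r1 <- ses_structure(d, m, 50, 50, seed = 4)
  r2 <- ses_structure(d, m, 50, 50, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(r1$richness >= 2))
  expect_equal(r1$nri,
               -(r1$mpd_obs - r1$mpd_null_mean) / r1$mpd_null_sd)

  # a single site containing every species cannot vary under the null
  all_in <- matrix(1L, 1, 8, dimnames = list("only", rownames(d)))
  expect_warning(deg <- ses_structure(d, all_in, 20, 20, seed = 5),
                 "swaps")
  expect_true(is.na(deg$nri))
  expect_equal(deg$reason, "null_sd_zero")
})

test_that("species missing from the distance matrix abort unless pruned", {
  tr <- random_tree(6, 8)
  d <- patristic_matrix(tr)
  set.seed(6)
  m <- do.call(rbind, replicate(6, {
    r <- rep(0L, 6)
    r[sample(6, 3)] <- 1L
    r
  }, simplify = FALSE))
  m <- cbind(m, 1L)
  dimnames(m) <- list(paste0("s", 1:6), c(rownames(d), "ghost"))
  expect_error(ses_structure(d, m, 10, 10, seed = 1), "ghost")
  expect_warning(ok <- ses_structure(d, m, 10, 10, seed = 1,
                                     prune_missing = TRUE), "pruning")
  expect_equal(nrow(ok), 6)
  expect_true(all(ok$richness == 3))
})

test_that("chained and restarted nulls are both valid but differ", {
  tr <- random_tree(10, 21)
  d <- patristic_matrix(tr)
  set.seed(31)
  m <- filter_communities(random_binary_matrix(12, 10,
                                               species = rownames(d)))
  a <- ses_structure(d, m, 50, 50, seed = 9, chained = TRUE)
  b <- ses_structure(d, m, 50, 50, seed = 9, chained = FALSE)
  expect_false(identical(a$mpd_null_mean, b$mpd_null_mean))
  expect_equal(a$mpd_obs, b$mpd_obs)
})
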