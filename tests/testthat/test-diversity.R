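test_that("p-distance counts differing columns under pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), list(distance = 0, sites = 4L))
  expect_equal(p_distance("AAAA", "TTTT"), list(distance = 1, sites = 4L))
  expect_equal(p_distance("AC-T", "ACGT"), list(distance = 0, sites = 3L))
  expect_equal(p_distance("ACGT", "ACGA"), list(distance = 0.25, sites = 4L))
  expect_equal(p_distance("ANGT", "ACRT")$sites, 2L)
  expect_error(p_distance("A-", "-A"), "undefined-distance")
  expect_error(p_distance("ACG", "AC"), "alignment error")
})

test_that("p-distance matrix agrees with ape's raw pairwise-deletion distance", {
  withr::local_seed(11)
  seqs <- random_alignment(8, 200, miss_rate = 0.05)
  s <- make_set(seqs)
  ours <- pdistance_matrix(s)$distance
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(seqs), ""), identity)))
  theirs <- as.matrix(ape::dist.dna(bin, model = "raw",
                                    pairwise.deletion = TRUE))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("APD matches hand-enumerated and brute-force oracles", {
  s5 <- make_set(rep("ACGTACGT", 5), groups = "g")
  expect_equal(apd(s5, "g"), 0)

  s3 <- make_set(c("AAAA", "AAAT", "AATT"), groups = "g")
  expect_equal(apd(s3, "g"), mean(c(0.25, 0.5, 0.25)) * 100)

  expect_error(apd(make_set("ACGT", groups = "g"), "g"), "insufficient-data")

  withr::local_seed(42)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    L <- sample(20:400, 1)
    seqs <- random_alignment(n, L, miss_rate = runif(1, 0, 0.15))
    s <- make_set(seqs, groups = "g")
    expect_equal(apd(s, "g"), brute_apd_oracle(seqs), tolerance = 1e-12)
  }
})

test_that("APD is invariant to sequence order and column relabeling", {
  withr::local_seed(7)
  seqs <- random_alignment(10, 120, miss_rate = 0.05)
  s <- make_set(seqs, groups = "g")
  base <- apd(s, "g")

  perm <- sample(10)
  expect_equal(apd(make_set(seqs[perm], groups = "g"), "g"), base)

  colperm <- sample(120)
  shuffled <- vapply(seqs, function(x) {
    paste(strsplit(x, "")[[1]][colperm], collapse = "")
  }, character(1))
  expect_equal(apd(make_set(shuffled, groups = "g"), "g"), base)
})

test_that("merging two identical-composition subgroups preserves APD", {
  # Duplicating every sequence once adds n twin pairs at distance zero and
  # doubles every other pair count, so the merged mean obeys the exact
  # combinatorial identity below and converges to the subgroup APD as n grows.
  withr::local_seed(3)
  n <- 8
  seqs <- random_alignment(n, 100)
  d_one <- apd(make_set(seqs, groups = "g"), "g")
  merged <- aligned_seq_set(c(seqs, seqs), names = paste0("s", 1:(2 * n)),
                            groups = "g")
  expect_equal(apd(merged, "g"), d_one * 2 * (n - 1) / (2 * n - 1),
               tolerance = 1e-12)
  # subgroup labels recover the original APD exactly
  g2 <- aligned_seq_set(c(seqs, seqs), names = paste0("s", 1:(2 * n)),
                        groups = setNames(rep(c("a", "b"), each = n),
                                          paste0("s", 1:(2 * n))))
  expect_equal(apd(g2, "a"), d_one)
  expect_equal(apd(g2, "b"), d_one)
})

test_that("between-group APD enumerates all cross pairs", {
  s <- aligned_seq_set(c(a1 = "AAAA", a2 = "AAAT", b1 = "TTTT"),
                       groups = c(a1 = "A", a2 = "A", b1 = "B"))
  expect_equal(apd_between(s, "A", "B"), mean(c(1, 0.75)) * 100)

  ident <- aligned_seq_set(c(x = "ACGT", y = "ACGT"),
                           groups = c(x = "A", y = "B"))
  expect_equal(apd_between(ident, "A", "B"), 0)
  expect_equal(apd_between(make_set(c(a = "AAAA", b = "TTTT"),
                                    groups = c(a = "A", b = "B")), "A", "B"),
               100)
  expect_error(apd_between(ident, "A", "C"), "insufficient-data|empty")
})

test_that("distance summary reports per-group and cross-group APD with sites", {
  withr::local_seed(9)
  seqs <- random_alignment(9, 90, miss_rate = 0.02)
  grp <- rep(c("x", "y", "z"), each = 3)
  s <- make_set(seqs, groups = setNames(grp, paste0("s", 1:9)))
  ds <- distance_summary(s)
  expect_equal(ds$apd_within[["x"]], apd(s, "x"))
  expect_equal(ds$apd_between[["x|y"]], apd_between(s, "x", "y"))
  expect_equal(unname(ds$n_per_group), c(3L, 3L, 3L))
  expect_true(all(ds$comparable_sites <= s$length))
  expect_true(isSymmetric(ds$matrix))
})

test_that("subsampled APD is exact at k = n, zero for identical sets, unbiased", {
  withr::local_seed(5)
  seqs <- random_alignment(12, 150)
  s <- make_set(seqs, groups = "g")
  full <- apd(s, "g")

  expect_true(all(subsample_apd(s, "g", k = 12, reps = 5, seed = 2) == full))
  ident <- make_set(rep("ACGT", 6), groups = "g")
  expect_true(all(subsample_apd(ident, "g", k = 3, reps = 10, seed = 2) == 0))
  expect_error(subsample_apd(s, "g", k = 1, reps = 2, seed = 1),
               "parameter error")

  for (k in c(2L, 5L, 11L)) {
    reps <- subsample_apd(s, "g", k = k, reps = 1000, seed = 7)
    mc_se <- stats::sd(reps) / sqrt(length(reps))
    expect_lt(abs(mean(reps) - full), 3 * mc_se + 1e-9)
  }
})
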