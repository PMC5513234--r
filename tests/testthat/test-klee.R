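test_that("indicator encoding is one-hot with all-zero missing columns", {
  expect_equal(indicator_encode("A"), c(1, 0, 0, 0))
  expect_equal(indicator_encode("N"), c(0, 0, 0, 0))
  expect_equal(indicator_encode("-"), c(0, 0, 0, 0))
  expect_equal(indicator_encode("ACGT"),
               as.vector(diag(4)))
  expect_length(indicator_encode(strrep("A", 648)), 2592L)
})

test_that("indicator correlation matches hand computation and is symmetric", {
  s <- make_set(c(a = "AAAA", b = "CCCC"))
  cc <- correlation_matrix(indicator_matrix(s))
  expect_equal(cc["a", "b"], -1 / 3, tolerance = 1e-12)

  ident <- make_set(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  ci <- correlation_matrix(indicator_matrix(ident))
  expect_true(all(abs(ci - 1) < 1e-12))

  withr::local_seed(4)
  s2 <- make_set(random_alignment(6, 80, miss_rate = 0.1))
  c2 <- correlation_matrix(indicator_matrix(s2))
  expect_equal(c2, t(c2), tolerance = 1e-12)
  expect_equal(unname(diag(c2)), rep(1, 6), tolerance = 1e-9)

  degenerate <- make_set(c(good = "ACGT", allmiss = "NNNN"))
  expect_error(correlation_matrix(indicator_matrix(degenerate)),
               "degenerate-input.*allmiss")
})

test_that("for gap-free pairs correlation decreases strictly with p-distance", {
  # closed form: r = 1 - 4p/3 for sequences without missing data
  withr::local_seed(8)
  L <- 300
  anc <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  ps <- c()
  rs <- c()
  for (k in c(0, 5, 20, 60, 150, 300)) {
    mutated <- strsplit(anc, "")[[1]]
    idx <- seq_len(k)
    mutated[idx] <- vapply(mutated[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    s <- make_set(c(a = anc, b = paste(mutated, collapse = "")))
    p <- p_distance(s$seqs[[1]], s$seqs[[2]])$distance
    r <- correlation_matrix(indicator_matrix(s))[1, 2]
    expect_equal(r, 1 - 4 * p / 3, tolerance = 1e-9)
    ps <- c(ps, p); rs <- c(rs, r)
  }
  expect_true(all(diff(rs[order(ps)]) < 0))
})

test_that("UPGMA ordering matches hclust average-linkage heights", {
  withr::local_seed(12)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    pd <- pdistance_matrix(make_set(random_alignment(n, 150)))$distance
    ours <- order_sequences(pd)
    hc <- stats::hclust(stats::as.dist(pd), method = "average")
    expect_equal(sort(vapply(ours$nodes, `[[`, numeric(1), "height")) * 2,
                 sort(hc$height), tolerance = 1e-12)
    tr <- ape::read.tree(text = ours$tree)
    expect_setequal(tr$tip.label, rownames(pd))
    expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  }
})

test_that("UPGMA order is deterministic and tie-breaks reproducibly", {
  expect_equal(order_sequences(matrix(0, 1, 1))$order, 1L)
  expect_error(order_sequences(matrix(c(0, 1, 2, 0), 2, 2)), "matrix error")
  expect_error(order_sequences(matrix(c(0, -1, -1, 0), 2, 2)), "matrix error")

  # all-equal distances: fully tied; must not error and must be a permutation
  tied <- matrix(0.5, 4, 4); diag(tied) <- 0
  o <- order_sequences(tied)
  expect_setequal(o$order, 1:4)
  expect_identical(order_sequences(tied)$order, o$order)

  # a duplicate sequence lands adjacent to its twin
  withr::local_seed(21)
  seqs <- random_alignment(6, 200)
  seqs <- c(seqs, seqs[3])
  pd <- pdistance_matrix(make_set(seqs))$distance
  ord <- order_sequences(pd)$order
  expect_equal(abs(which(ord == 3) - which(ord == 7)), 1L)
})

test_that("planted clusters occupy contiguous blocks of the UPGMA order", {
  withr::local_seed(31)
  for (rep in 1:100) {
    K <- sample(2:5, 1)
    sizes <- sample(3:6, K, replace = TRUE)
    labels <- rep(seq_len(K), sizes)
    n <- length(labels)
    d <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d[i, j] <- if (labels[i] == labels[j]) runif(1, 5e-4, 15e-4)
      else runif(1, 0.045, 0.055)
    }
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
    diag(d) <- 0
    ord <- order_sequences(d)$order
    blocks <- rle(labels[ord])
    expect_length(blocks$lengths, K)
  }
})

test_that("klee result re-indexes correlations by the tree order", {
  withr::local_seed(14)
  sim <- simulate_set(sim_params(n_seqs = 18, d = 0.002, K = 3,
                                 cluster_sizes = c(8, 6, 4), D = 0.0125,
                                 p_ns = 0.1, seed = 14))
  kb <- klee(extract_region(sim$set, synthetic_barcode_region()))
  expect_setequal(kb$order, seq_along(sim$set$names))
  expect_equal(unname(diag(kb$corr)), rep(1, 18), tolerance = 1e-9)
  expect_equal(kb$corr, t(kb$corr), tolerance = 1e-12)
  expect_identical(kb$labels, sim$set$names[kb$order])
  # tree leaves and display order agree
  tr <- ape::read.tree(text = kb$tree)
  expect_setequal(tr$tip.label, kb$labels)
  # clusters form contiguous blocks
  blocks <- rle(unname(sim$set$groups[kb$order]))
  expect_length(blocks$lengths, 3L)
})

test_that("rendered Klee artifacts round-trip and show diagonal blocks", {
  dir <- withr::local_tempdir()
  s <- make_set(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                  c = "TGCATGCAGT", d = "TGCATGCAGT"))
  k <- klee(s)
  files <- render_klee(k, file.path(dir, "toy"))
  expect_true(all(file.exists(files)))
  m <- read_matrix(files[["matrix"]])
  expect_equal(unname(m), unname(k$corr), tolerance = 1e-12)
  # the two identical pairs form 2x2 unit blocks
  lab <- readLines(files[["order"]])
  twin1 <- which(lab %in% c("a", "b")); twin2 <- which(lab %in% c("c", "d"))
  expect_equal(unname(m[twin1, twin1]), matrix(1, 2, 2), tolerance = 1e-9)
  expect_equal(unname(m[twin2, twin2]), matrix(1, 2, 2), tolerance = 1e-9)
  expect_true(mean(m[twin1, twin1]) > mean(m[twin1, twin2]))

  # simulated 3-cluster set: within-block mean correlation beats off-block
  withr::local_seed(19)
  sim <- simulate_set(sim_params(n_seqs = 15, d = 0.002, K = 3,
                                 cluster_sizes = c(5, 5, 5), D = 0.0125,
                                 seed = 19))
  kk <- klee(extract_region(sim$set, synthetic_barcode_region()))
  f2 <- render_klee(kk, file.path(dir, "clusters"))
  mm <- read_matrix(f2[["matrix"]])
  grp <- unname(sim$set$groups[kk$order])
  for (g in unique(grp)) {
    inside <- mean(mm[grp == g, grp == g])
    outside <- mean(mm[grp == g, grp != g])
    expect_gt(inside, outside)
  }
})
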