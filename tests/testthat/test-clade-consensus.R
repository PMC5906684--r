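sim_tab <- function(values, measure, labels = letters[seq_len(nrow(values))]) {
  dimnames(values) <- list(labels, labels)
  similarity_table(values, measure, labels)
}

test_that("evidence channels transform, symmetrize and handle missing cells", {
  e <- matrix(1e-5, 3, 3); diag(e) <- NA
  ch <- build_channel(sim_tab(e, "evalue"))
  expect_equal(ch$similarity[1, 2], 5)
  expect_equal(unname(diag(ch$distances)), rep(0, 3))
  expect_true(isSymmetric(ch$distances))

  # one-sided missing keeps the present value
  z <- matrix(NA_real_, 3, 3)
  z[1, 2] <- 8; z[1, 3] <- 2; z[3, 1] <- 4; z[2, 3] <- 1; z[3, 2] <- 1
  ch2 <- build_channel(sim_tab(z, "zscore"))
  expect_equal(ch2$similarity[1, 2], 8)
  expect_equal(ch2$similarity[2, 1], 8)
  expect_equal(ch2$similarity[1, 3], 3)   # mean(2, 4)

  # both-sided missing -> similarity 0 (maximal distance)
  z3 <- matrix(NA_real_, 3, 3); z3[1, 2] <- z3[2, 1] <- 6
  ch3 <- build_channel(sim_tab(z3, "zscore"))
  expect_equal(ch3$similarity[1, 3], 0)
  expect_equal(ch3$distances[1, 3], 6)

  # E = 0 underflow is capped at 300; E > 1 clips to similarity 0
  e2 <- matrix(c(NA, 0, 5, NA), 2, 2)
  ch4 <- build_channel(sim_tab(e2, "evalue"))
  expect_equal(max(ch4$similarity), 150)  # mean(300, 0-clipped -log10(5))

  allna <- matrix(NA_real_, 3, 3)
  expect_error(build_channel(sim_tab(allna, "zscore")), "missing")
})

test_that("noise-free planted blocks give exactly two off-diagonal distances", {
  pair <- simulate_similarity_pair(clade_sim_spec(noise_sd = 0,
                                                  missing_frac = 0, seed = 1))
  ch <- build_channel(pair$zscore)
  off <- row(ch$distances) != col(ch$distances)
  expect_equal(length(unique(round(ch$distances[off], 9))), 2L)
})

test_that("single linkage merges hand-computable cases deterministically", {
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  dend2 <- single_linkage(d2)
  expect_length(dend2$merges, 1L)
  expect_equal(dend2$merges[[1]]$height, 3)

  d4 <- matrix(5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d4["a", "b"] <- d4["b", "a"] <- 1
  d4["c", "d"] <- d4["d", "c"] <- 1
  diag(d4) <- 0
  dend4 <- single_linkage(d4)
  expect_equal(dendrogram_clades(dend4)[[1]], c("a", "b"))  # tie-break: a first
  expect_equal(dendrogram_clades(dend4)[[2]], c("c", "d"))
  expect_equal(vapply(dend4$merges, `[[`, numeric(1), "height"), c(1, 1, 5))
})

test_that("single linkage heights are non-decreasing and match hclust", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    m <- matrix(runif(n * n, 1, 50), n, n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("L", seq_len(n)), paste0("L", seq_len(n)))
    dend <- single_linkage(d)
    h <- vapply(dend$merges, `[[`, numeric(1), "height")
    expect_true(all(diff(h) >= -1e-12))
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    expect_equal(sort(h), sort(hc$height), tolerance = 1e-12)
    # same clade sets (tie-free random matrices): rebuild hclust's clusters
    members <- list()
    for (k in seq_len(nrow(hc$merge))) {
      get <- function(x) if (x < 0) hc$labels[-x] else members[[x]]
      members[[k]] <- sort(c(get(hc$merge[k, 1]), get(hc$merge[k, 2])))
    }
    hc_keys <- vapply(members, paste, character(1), collapse = "|")
    expect_setequal(clade_keys(dend), hc_keys)
  }
})

test_that("dendrogram topology is invariant under rank-preserving transforms", {
  set.seed(29)
  n <- 7
  m <- matrix(runif(n * n, 1, 9), n, n)
  z <- (m + t(m)) / 2; diag(z) <- NA
  dimnames(z) <- list(letters[1:n], letters[1:n])
  t1 <- sim_tab(z, "zscore", letters[1:n])
  dend1 <- single_linkage(build_channel(t1))
  # monotone transform of the similarities preserves ranks
  z2 <- z^1.7 / 3
  t2 <- sim_tab(z2, "zscore", letters[1:n])
  dend2 <- single_linkage(build_channel(t2))
  expect_setequal(clade_keys(dend1), clade_keys(dend2))
})

test_that("strict consensus intersects clade sets exactly", {
  d4 <- matrix(5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d4["a", "b"] <- d4["b", "a"] <- 1
  d4["c", "d"] <- d4["d", "c"] <- 2
  diag(d4) <- 0
  dend_bal <- single_linkage(d4)         # ((a,b),(c,d))
  cat4 <- matrix(c(0, 1, 2, 3,
                   1, 0, 2, 3,
                   2, 2, 0, 3,
                   3, 3, 3, 0), 4, 4, byrow = TRUE,
                 dimnames = list(letters[1:4], letters[1:4]))
  dend_cat <- single_linkage(cat4)       # (((a,b),c),d)

  # idempotence
  self <- strict_consensus(dend_bal, dend_bal)
  expect_setequal(tree_clade_keys(self), clade_keys(dend_bal))

  cons <- strict_consensus(dend_cat, dend_bal)
  expect_setequal(tree_clade_keys(cons),
                  intersect(clade_keys(dend_cat), clade_keys(dend_bal)))
  expect_setequal(tree_clade_keys(cons), c("a|b", "a|b|c|d"))

  # differing leaf sets are rejected with the symmetric difference named
  d3 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "x"), c("a", "x")))
  expect_error(strict_consensus(dend_bal, single_linkage(d3)), "x")
})

test_that("consensus pipeline recovers planted partitions and degenerate cases", {
  # noise-free: both channels identical -> binary tree with all planted clades
  pair0 <- simulate_similarity_pair(clade_sim_spec(noise_sd = 0,
                                                   missing_frac = 0, seed = 2))
  tree0 <- build_clade_tree(pair0$evalue, pair0$zscore)
  keys0 <- tree_clade_keys(tree0)
  for (grp in clade_sim_spec()$planted_partition) {
    expect_true(paste(sort(grp), collapse = "|") %in% keys0)
  }

  # label-order invariance: permuting the matrix rows/cols changes nothing
  perm <- sample(length(pair0$evalue$labels))
  ev_p <- similarity_table(pair0$evalue$values[perm, perm], "evalue")
  zs_p <- similarity_table(pair0$zscore$values[perm, perm], "zscore")
  expect_setequal(tree_clade_keys(build_clade_tree(ev_p, zs_p)), keys0)

  # one channel all-missing -> error
  allna <- pair0$evalue
  allna$values[] <- NA
  expect_error(build_clade_tree(allna, pair0$zscore), "missing")

  # contradictory plants -> star (root only)
  zA <- matrix(1, 4, 4); zA[1, 2] <- zA[2, 1] <- 9; zA[3, 4] <- zA[4, 3] <- 9
  zB <- matrix(1, 4, 4); zB[1, 3] <- zB[3, 1] <- 9; zB[2, 4] <- zB[4, 2] <- 9
  diag(zA) <- diag(zB) <- NA
  dA <- single_linkage(build_channel(sim_tab(zA, "zscore", letters[1:4])))
  dB <- single_linkage(build_channel(sim_tab(zB, "zscore", letters[1:4])))
  star <- strict_consensus(dA, dB)
  expect_equal(tree_clade_keys(star), "a|b|c|d")
})
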