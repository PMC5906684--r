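test_that("knuckle scanner scores the consensus and degenerate windows", {
  hits <- find_knuckles(seq_record("a", "CPKCG"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pattern_score, 4L)
  expect_true(hits$cys1 && hits$cys2)
  expect_equal(hits$matched_text, "CPKCG")

  expect_equal(nrow(find_knuckles(seq_record("a", "AAAAA"))), 0L)
  expect_equal(nrow(find_knuckles(seq_record("a", "AAA"))), 0L)

  # one-cysteine and bonus-only windows
  h2 <- find_knuckles(seq_record("a", "SPKCG"))
  expect_equal(h2$pattern_score, 3L)
  expect_false(h2$cys1); expect_true(h2$cys2)
})

test_that("knuckle scanner equals the exhaustive window oracle", {
  set.seed(31)
  for (rep in 1:50) {
    s <- random_seq(60)
    got <- find_knuckles(seq_record("x", s))
    want <- brute_knuckles(s)
    expect_equal(got$start, want$start)
    expect_equal(got$pattern_score, want$pattern_score)
  }
})

test_that("chelation calls follow the cysteine count invariant", {
  cc <- classify_chelation(seq_record("a", "MAACPKCGAAAAAAAAAAAACPHCGAA"))
  expect_equal(cc$state, "intact")
  expect_equal(cc$n_cys, 4L)
  expect_equal(nrow(cc$knuckles), 2L)

  expect_equal(classify_chelation(seq_record("a", strrep("A", 40)))$state, "lost")
  expect_equal(classify_chelation(seq_record("a", "MK"))$state, "lost")

  # one intact + one degraded knuckle -> partial
  cc2 <- classify_chelation(seq_record("a", "MAACPKCGAAAAAAAAAAAASPHCGAA"))
  expect_equal(cc2$state, "partial")
  expect_equal(cc2$n_cys, 3L)

  # single knuckle only: two cysteines -> partial
  cc3 <- classify_chelation(seq_record("a", "MAACPKCGAAAAAAAAAAAAAAAAAAA"))
  expect_equal(cc3$state, "partial")
  expect_equal(cc3$n_cys, 2L)
})

test_that("chelation call is invariant to flanking sequence outside the window", {
  core <- "CPKCGAAAAAAAAAAAACPHCG"
  base <- classify_chelation(seq_record("a", paste0("MM", core, "MM")))
  set.seed(8)
  for (rep in 1:10) {
    flank1 <- random_seq(sample(0:15, 1), setdiff(strsplit("ADEFGHIKLMNQRSTVWY", "")[[1]], "C"))
    flank2 <- random_seq(sample(0:15, 1), setdiff(strsplit("ADEFGHIKLMNQRSTVWY", "")[[1]], "C"))
    cc <- classify_chelation(seq_record("a", paste0(flank1, core, flank2)))
    expect_equal(cc$state, base$state)
    expect_equal(cc$n_cys, base$n_cys)
    expect_equal(cc$spacing, base$spacing)
  }
})

test_that("classifier recovers planted chelation states", {
  sim <- simulate_knuckle_sequences(knuckle_sim_spec(n_sequences = 300, seed = 21))
  pred <- vapply(sim$records, function(r) classify_chelation(r)$state, character(1))
  expect_equal(mean(pred == sim$true_states), 1)
})

test_that("global alignment identity matches closed forms and the DP oracle", {
  r <- global_align_identity(seq_record("a", "WKLV"), seq_record("b", "WKLV"))
  expect_equal(r$identity, 100)
  expect_equal(r$coverage, 1)
  expect_equal(global_align_identity(seq_record("a", "AAAA"),
                                     seq_record("b", "TTTT"))$identity, 0)

  set.seed(17)
  for (rep in 1:25) {
    sa <- random_seq(30); sb <- random_seq(sample(20:35, 1))
    got <- global_align_identity(seq_record("a", sa), seq_record("b", sb))
    want <- oracle_align(sa, sb)
    expect_equal(got$identity, want$identity)
    expect_equal(got$coverage, want$coverage)
  }
})

test_that("identity clustering handles the degenerate regimes", {
  same <- lapply(1:4, function(i) seq_record(paste0("s", i), "MKVAWDEQ"))
  cl <- cluster_by_identity(same, cluster_params(50, 0.9))
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members, paste0("s", 1:4))

  set.seed(5)
  distinct <- lapply(1:5, function(i) seq_record(paste0("d", i), random_seq(40)))
  cl2 <- cluster_by_identity(distinct, cluster_params(100, 0.9))
  expect_length(cl2, 5L)
})

test_that("identity clustering recovers a planted two-family partition", {
  set.seed(41)
  make_family <- function(tag, seed_seq, n, rate = 0.1) {
    lapply(seq_len(n), function(i) {
      ch <- strsplit(seed_seq, "")[[1]]
      mut <- runif(length(ch)) < rate
      ch[mut] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        sum(mut), replace = TRUE)
      seq_record(paste0(tag, i), paste(ch, collapse = ""))
    })
  }
  famA <- make_family("a", random_seq(60), 8)
  famB <- make_family("b", random_seq(60), 8)
  cl <- cluster_by_identity(c(famA, famB), cluster_params(50, 0.9))
  expect_length(cl, 2L)
  groups <- lapply(cl, function(x) sort(substr(x$members, 1, 1)))
  expect_setequal(vapply(groups, function(g) paste(unique(g), collapse = ""),
                         character(1)), c("a", "b"))

  # output partitions the input
  all_members <- sort(unlist(lapply(cl, `[[`, "members")))
  expect_equal(all_members, sort(vapply(c(famA, famB), `[[`, character(1), "id")))
})

test_that("raising the identity threshold never merges clusters", {
  set.seed(77)
  seqs <- lapply(1:10, function(i) seq_record(paste0("s", i), random_seq(30)))
  # make some related pairs
  seqs[[2]]$residues <- sub("^.{5}", "WWWWW", seqs[[1]]$residues)
  seqs[[4]]$residues <- seqs[[3]]$residues
  memb <- function(S) {
    cl <- cluster_by_identity(seqs, cluster_params(S, 0.5))
    assign <- rep(seq_along(cl), vapply(cl, function(x) length(x$members), integer(1)))
    names(assign) <- unlist(lapply(cl, `[[`, "members"))
    assign
  }
  low <- memb(40); high <- memb(70)
  ids <- names(low)
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      # together at high threshold implies together at low threshold
      if (high[ids[i]] == high[ids[j]]) {
        expect_equal(unname(low[ids[i]]), unname(low[ids[j]]))
      }
    }
  }
})
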