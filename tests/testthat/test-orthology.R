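test_that("best hits use rounded bitscores, ties become co-best", {
  tb <- mock_hit_table("A", "B", data.frame(
    query_id = c("a1", "a1", "a2", "a2"),
    subject_id = c("b1", "b2", "b1", "b2"),
    bitscore = c(100.0, 90.0, 100.04, 100.01),
    stringsAsFactors = FALSE))
  bh <- best_hits(tb)
  expect_equal(bh[["a1"]], "b1")
  expect_equal(bh[["a2"]], c("b1", "b2"))  # both round to 100.0
})

test_that("best hits equal an exhaustive max-scan oracle", {
  set.seed(11)
  for (i in 1:20) {
    case <- random_hits_case(i)
    if (is.null(case)) next
    expect_equal(best_hits(case$tab_ab), oracle_best_hits(case$tab_ab$hits))
  }
})

test_that("unique reciprocal bests pair; asymmetry and co-bests do not", {
  pair <- function(ab, ba) brh_unique(ab, ba)
  # mutual unique bests
  expect_equal(nrow(pair(list(a1 = "b1"), list(b1 = "a1"))), 1L)
  # b's best is a different gene
  expect_equal(nrow(pair(list(a1 = "b1"), list(b1 = "a2"))), 0L)
  # co-best is deferred, not paired here
  expect_equal(nrow(pair(list(a1 = c("b1", "b2")),
                         list(b1 = "a1", b2 = "a1"))), 0L)
})

test_that("tandem duplicates resolve to the synteny-supported copy", {
  # genome A: a1 a2 a3; genome B: b1 b2a b2b b3 where b2a/b2b are co-best
  # partners of a2; the seed pair (a1, b1) anchors a2 -> b2a
  ga <- mock_genome("A", 3)
  gb <- mock_genome("B", 4)
  cand <- data.frame(feature_a = c("A_02", "A_02"),
                     feature_b = c("B_02", "B_03"),
                     stringsAsFactors = FALSE)
  seed <- data.frame(feature_a = "A_01", feature_b = "B_01",
                     stage = "brh_unique", stringsAsFactors = FALSE)
  out <- resolve_ties_by_synteny(cand, seed, ga, gb, max_gap = 2L)
  res <- out[out$stage == "synteny_resolved", ]
  expect_equal(res$feature_a, "A_02")
  expect_equal(res$feature_b, "B_02")
})

test_that("candidates without any anchored neighbor stay unpaired", {
  ga <- mock_genome("A", 12)
  gb <- mock_genome("B", 12)
  cand <- data.frame(feature_a = c("A_06", "A_06"),
                     feature_b = c("B_06", "B_07"),
                     stringsAsFactors = FALSE)
  seed <- data.frame(feature_a = "A_01", feature_b = "B_01",
                     stage = "brh_unique", stringsAsFactors = FALSE)
  out <- resolve_ties_by_synteny(cand, seed, ga, gb, max_gap = 2L)
  expect_equal(sum(out$stage == "synteny_resolved"), 0L)
})

test_that("resolution is deterministic across repeated runs", {
  case <- random_hits_case(99)
  expect_false(is.null(case))
  runs <- lapply(1:3, function(k) {
    om <- ortholog_map(case$tab_ab, case$tab_ba, case$ga, case$gb)
    om$pairs
  })
  expect_identical(runs[[1]], runs[[2]])
  expect_identical(runs[[1]], runs[[3]])
})

test_that("orthology equals the brute-force resolution oracle (spot check)", {
  for (seed in 1:40) {
    case <- random_hits_case(seed)
    if (is.null(case)) next
    om <- ortholog_map(case$tab_ab, case$tab_ba, case$ga, case$gb)
    ra <- setNames(case$ga$features$rank, case$ga$features$feature_id)
    rb <- setNames(case$gb$features$rank, case$gb$features$feature_id)
    orc <- oracle_orthology(case$tab_ab$hits, case$tab_ba$hits, ra, rb)
    got <- om$pairs[order(om$pairs$feature_a), ]
    rownames(got) <- rownames(orc) <- NULL
    expect_equal(got, orc, info = paste("seed", seed))
  }
})

test_that("ortholog maps are one-to-one and reciprocal co-best", {
  for (seed in c(3, 17)) {
    case <- random_hits_case(seed)
    if (is.null(case)) next
    om <- ortholog_map(case$tab_ab, case$tab_ba, case$ga, case$gb)
    expect_false(anyDuplicated(om$pairs$feature_a) > 0)
    expect_false(anyDuplicated(om$pairs$feature_b) > 0)
    ba <- best_hits(case$tab_ab); bb <- best_hits(case$tab_ba)
    for (i in seq_len(nrow(om$pairs))) {
      a <- om$pairs$feature_a[i]; b <- om$pairs$feature_b[i]
      expect_true(b %in% ba[[a]])
      expect_true(a %in% bb[[b]])
    }
  }
})

test_that("unique-ortholog simulations are fully recovered by BRH alone", {
  sim <- simulate_pair(sim_spec(n_genes = 50, divergence = 90, seed = 13))
  det <- run_detection(sim)
  p <- det$om$pairs
  expect_equal(sum(p$stage == "brh_unique"), nrow(sim$truth$orthologs))
  expect_setequal(paste(p$feature_a, p$feature_b),
                  paste(sim$truth$orthologs$feature_a,
                        sim$truth$orthologs$feature_b))
})

test_that("paralog sets are symmetric, irreflexive and closure-complete", {
  # two-gene mutual pair
  tb <- mock_hit_table("A", "A", data.frame(
    query_id = c("A_01", "A_02"), subject_id = c("A_02", "A_01"),
    stringsAsFactors = FALSE))
  ps <- detect_paralogs(tb)
  expect_equal(ps[["A_01"]], "A_02")
  expect_equal(ps[["A_02"]], "A_01")
  # self-hits alone yield nothing
  tb2 <- mock_hit_table("A", "A", data.frame(
    query_id = "A_01", subject_id = "A_01", stringsAsFactors = FALSE))
  expect_length(detect_paralogs(tb2), 0L)
  # 5-member family: every member has the other 4, in either direction only
  fam <- t(combn(sprintf("F_%d", 1:5), 2))
  tb3 <- mock_hit_table("A", "A", data.frame(
    query_id = fam[, 1], subject_id = fam[, 2], stringsAsFactors = FALSE))
  ps3 <- detect_paralogs(tb3)
  for (g in sprintf("F_%d", 1:5)) {
    expect_setequal(ps3[[g]], setdiff(sprintf("F_%d", 1:5), g))
    expect_false(g %in% ps3[[g]])
  }
})
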