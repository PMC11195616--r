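AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

test_that("tabular hit files parse, reject bad dialects, allow empty", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g1\th1\t100.0\t50\t0\t0\t1\t50\t1\t50\t1e-30\t100.0", path)
  tb <- read_hit_table(path, "A", "B")
  expect_s3_class(tb, "hit_table")
  expect_equal(tb$hits$identity_pct, 100)
  expect_equal(tb$hits$evalue, 1e-30)
  expect_equal(tb$hits$s_end, 50L)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_equal(nrow(read_hit_table(empty, "A", "B")$hits), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  rows <- rep("q\ts\t90\t40\t4\t0\t1\t40\t1\t40\t1e-20\t80", 10)
  rows[7] <- "q\ts\t90\t40"
  writeLines(rows, bad)
  expect_error(read_hit_table(bad, "A", "B"), "line 7")
})

test_that("rows referencing unknown ids are dropped with a message", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\th1\t90\t40\t4\t0\t1\t40\t1\t40\t1e-20\t80",
               "gX\th1\t90\t40\t4\t0\t1\t40\t1\t40\t1e-20\t80"), path)
  expect_message(tb <- read_hit_table(path, "A", "B",
                                      known_ids = c("g1", "h1")), "1 hit")
  expect_equal(nrow(tb$hits), 1L)
})

test_that("identical sequences align end to end at 100% identity", {
  set.seed(1)
  p <- paste(sample(AA, 100, TRUE), collapse = "")
  h <- align_pair(p, p)
  expect_equal(h$identity_pct, 100)
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(1L, 100L, 1L, 100L))
  expect_equal(h$aln_len, 100L)
})

test_that("one substitution in 50 aligned residues gives 98% identity", {
  set.seed(2)
  p <- paste(sample(AA, 50, TRUE), collapse = "")
  q <- p
  substr(q, 25, 25) <- if (substr(p, 25, 25) == "W") "Y" else "W"
  h <- align_pair(p, q)
  expect_equal(h$aln_len, 50L)
  expect_equal(h$identity_pct, 98)
})

test_that("alignment scores equal an independent quadratic DP oracle", {
  set.seed(3)
  for (i in 1:25) {
    a <- paste(sample(AA, sample(20:60, 1), TRUE), collapse = "")
    b <- if (i %% 3 == 0) {
      # related pair: mutate a so gaps and mismatches both appear
      mutate_protein(a, 70)
    } else {
      paste(sample(AA, sample(20:60, 1), TRUE), collapse = "")
    }
    got <- align_pair(a, b)$raw_score
    expect_equal(got, oracle_sw_score(a, b), info = paste("case", i))
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  set.seed(4)
  for (i in 1:10) {
    a <- paste(sample(AA, 80, TRUE), collapse = "")
    b <- mutate_protein(a, sample(c(50, 70, 90), 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    expect_equal(align_pair(a, b)$raw_score, Biostrings::score(ref))
  }
})

test_that("bitscores are symmetric in the sequence order", {
  set.seed(5)
  for (i in 1:8) {
    a <- paste(sample(AA, 60, TRUE), collapse = "")
    b <- paste(sample(AA, 70, TRUE), collapse = "")
    expect_equal(align_pair(a, b)$bitscore, align_pair(b, a)$bitscore)
  }
})

test_that("an unrelated reversed sequence scores below retention", {
  set.seed(6)
  a <- paste(sample(AA, 120, TRUE), collapse = "")
  b <- paste(rev(sample(AA, 120, TRUE)), collapse = "")
  h <- align_pair(a, b, db_size = 1e7 * 1e7)
  cfg <- pipeline_config()
  cov <- 100 * (h$q_end - h$q_start + 1) / 120
  retained <- h$evalue < cfg$evalue_max &&
    h$identity_pct > cfg$identity_min_pct && cov >= cfg$coverage_min_pct
  expect_false(retained)
})

test_that("non-amino-acid input is rejected", {
  expect_error(align_pair("MK1L", "MKL"), "non-amino-acid")
  expect_error(align_pair("", "MKL"), "empty")
})

test_that("retention filters follow the configured thresholds exactly", {
  lens <- c(q = 100L, s = 120L)
  mk <- function(identity, evalue, q_end) {
    mock_hit_table("A", "B", data.frame(
      query_id = "q", subject_id = "s", identity_pct = identity,
      aln_len = q_end, q_start = 1L, q_end = q_end, s_start = 1L,
      s_end = q_end, evalue = evalue, bitscore = 100,
      stringsAsFactors = FALSE))
  }
  cfg <- pipeline_config()
  keep <- function(tb) nrow(filter_hits(tb, cfg, lens)$hits) == 1L
  expect_false(keep(mk(39, 1e-50, 90)))    # identity below 40
  expect_false(keep(mk(80, 1e-50, 39)))    # 39% of the shorter protein
  expect_false(keep(mk(80, 1e-9, 90)))     # E-value too large
  expect_true(keep(mk(80, 1e-11, 90)))
})

test_that("filtering is a subset operation and idempotent", {
  set.seed(7)
  n <- 40
  hits <- data.frame(
    query_id = sprintf("q%02d", sample(10, n, TRUE)),
    subject_id = sprintf("s%02d", sample(10, n, TRUE)),
    identity_pct = runif(n, 20, 100), aln_len = 50L,
    q_start = 1L, q_end = sample(20:50, n, TRUE),
    s_start = 1L, s_end = sample(20:50, n, TRUE),
    evalue = 10^runif(n, -40, -5), bitscore = runif(n, 40, 200),
    stringsAsFactors = FALSE)
  tb <- mock_hit_table("A", "B", hits)
  lens <- setNames(rep(50L, 20), c(sprintf("q%02d", 1:10), sprintf("s%02d", 1:10)))
  f1 <- filter_hits(tb, lengths = lens)
  expect_true(all(paste(f1$hits$query_id, f1$hits$subject_id, f1$hits$evalue)
                  %in% paste(hits$query_id, hits$subject_id, hits$evalue)))
  f2 <- filter_hits(f1, lengths = lens)
  expect_identical(f1$hits, f2$hits)
})

test_that("all_vs_all produces n^2 tables including self-pairs", {
  sim1 <- simulate_pair(sim_spec(n_genes = 12, seed = 21))
  av2 <- all_vs_all(list(sim1$genome_a, sim1$genome_b))
  expect_setequal(names(av2), c("simA->simA", "simA->simB",
                                "simB->simA", "simB->simB"))
  g3 <- sim1$genome_a
  g3$genome_id <- "simC"
  g3$features$feature_id <- sub("SIMA", "SIMC", g3$features$feature_id)
  av3 <- all_vs_all(list(sim1$genome_a, sim1$genome_b, g3))
  expect_length(av3, 9L)
  # mirrored direction carries the same scores with swapped coordinates
  ab <- av2[["simA->simB"]]$hits
  ba <- av2[["simB->simA"]]$hits
  key_ab <- paste(ab$query_id, ab$subject_id)
  key_ba <- paste(ba$subject_id, ba$query_id)
  m <- match(key_ab, key_ba)
  expect_false(anyNA(m))
  expect_equal(ab$bitscore, ba$bitscore[m])
  expect_equal(ab$q_start, ba$s_start[m])
})

test_that("every implanted ortholog is the top hit in both directions", {
  sim <- simulate_pair(sim_spec(n_genes = 40, islands = list(
    list(insert_after_rank = 19, n_genes = 4)), divergence = 75, seed = 8))
  av <- all_vs_all(list(sim$genome_a, sim$genome_b))
  ba <- best_hits(av[["simA->simB"]])
  bb <- best_hits(av[["simB->simA"]])
  tr <- sim$truth$orthologs
  for (i in seq_len(nrow(tr))) {
    expect_equal(ba[[tr$feature_a[i]]], tr$feature_b[i])
    expect_equal(bb[[tr$feature_b[i]]], tr$feature_a[i])
  }
})
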