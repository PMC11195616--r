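test_that("an insertion >= 3 genes yields exactly one island, 2 genes none", {
  sim3 <- simulate_pair(sim_spec(n_genes = 30, islands = list(
    list(insert_after_rank = 14, n_genes = 3)), seed = 61))
  det3 <- run_detection(sim3)
  expect_equal(nrow(det3$islands), 1L)
  expect_equal(det3$islands$n_cds_a, 3L)
  expect_equal(det3$islands$n_cds_b, 0L)
  expect_equal(det3$islands$a_lo, sim3$truth$islands$rank_lo)
  expect_equal(det3$islands$a_hi, sim3$truth$islands$rank_hi)

  sim2 <- simulate_pair(sim_spec(n_genes = 30, islands = list(
    list(insert_after_rank = 14, n_genes = 2)), seed = 61))
  det2 <- run_detection(sim2)
  expect_equal(nrow(det2$islands), 0L)
})

test_that("a 5-gene insertion reports its exact interval and counts", {
  sim <- simulate_pair(sim_spec(n_genes = 40, islands = list(
    list(insert_after_rank = 19, n_genes = 5)), seed = 62))
  det <- run_detection(sim)
  expect_equal(nrow(det$islands), 1L)
  expect_equal(det$islands$n_cds_a, 5L)
  expect_equal(det$islands$n_cds_b, 0L)
  expect_true(is.na(det$islands$b_lo))
})

test_that("stray interior blocks are absorbed into the surrounding break", {
  # A: blocks L (genes 1-6) and R (13-18); between them genes 7-12 where
  # 9-10 map to a distant B segment (a stray 2-ortholog block, not
  # consecutive in both genomes with anything)
  ga <- mock_genome("A", 18)
  gb <- mock_genome("B", 30)
  m <- mock_map(ga, gb, c(1:6, 9:10, 13:18), c(1:6, 25:26, 7:12))
  sb <- synteny_blocks(m, ga, gb)
  expect_equal(nrow(sb$blocks), 3L)
  isl <- detect_breaks(sb, ga, gb)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$a_lo, 6L)   # ranks 6..11 strictly between L and R
  expect_equal(isl$a_hi, 11L)
  expect_equal(isl$n_cds_a, 6L)
  expect_match(isl$interior_blocks, ".+")
})

test_that("islands between oppositely oriented blocks are not called", {
  ga <- mock_genome("A", 20); gb <- mock_genome("B", 20)
  m <- mock_map(ga, gb, c(1:4, 9:12), c(1:4, 12:9))
  sb <- synteny_blocks(m, ga, gb)
  expect_equal(sort(sb$blocks$orientation), c(-1L, 1L))
  expect_equal(nrow(detect_breaks(sb, ga, gb)), 0L)
})

test_that("island metrics count orthology, paralogy, tRNA and GC signals", {
  sim <- simulate_pair(sim_spec(n_genes = 60, islands = list(
    list(insert_after_rank = 29, n_genes = 5, gc_shift = 0,
         with_trna = TRUE)), seed = 63))
  det <- run_detection(sim)
  isl <- det$islands
  expect_equal(nrow(isl), 1L)
  met <- measure_island(isl[1, ], sim$genome_a, sim$genome_b, det$om)
  expect_equal(met$n_cds_a, 5L)
  expect_equal(met$n_no_ortholog_a, 5L)   # island genes have no partners
  expect_equal(met$n_paralog_a, 0L)
  expect_true(met$trna_a)
  expect_false(met$trna_b)
  expect_lt(abs(met$delta_gc_a), 1.5)     # no GC shift requested
  expect_true(is.na(met$delta_gc_b))      # empty side reported as absent

  # an island gene with an ortholog elsewhere is counted in n_cds but not
  # in n_no_ortholog
  om2 <- det$om
  extra <- data.frame(
    feature_a = sim$genome_a$features$feature_id[
      sim$genome_a$features$rank == isl$a_lo + 1L &
      !is.na(sim$genome_a$features$rank)][1],
    feature_b = "simB_far", stage = "brh_unique", stringsAsFactors = FALSE)
  om2$pairs <- rbind(om2$pairs, extra)
  met2 <- measure_island(isl[1, ], sim$genome_a, sim$genome_b, om2)
  expect_equal(met2$n_cds_a, 5L)
  expect_equal(met2$n_no_ortholog_a, 4L)

  # paralog sets feed the paralogy count
  ids <- sim$genome_a$features$feature_id[
    !is.na(sim$genome_a$features$rank) &
    sim$genome_a$features$rank %in% c(isl$a_lo + 1L, isl$a_hi)]
  ps <- setNames(list(ids[2], ids[1]), ids)
  met3 <- measure_island(isl[1, ], sim$genome_a, sim$genome_b, det$om,
                         paralogs_a = ps)
  expect_equal(met3$n_paralog_a, 2L)
})

test_that("tRNA immediately beyond the boundary still flags the island", {
  sim <- simulate_pair(sim_spec(n_genes = 40, islands = list(
    list(insert_after_rank = 19, n_genes = 4, with_trna = TRUE)), seed = 64))
  det <- run_detection(sim)
  isl <- det$islands[1, ]
  # move the interval past the tRNA (tRNA sits at a_lo): within vicinity 2
  isl$a_lo <- isl$a_lo + 1L
  met <- measure_island(isl, sim$genome_a, sim$genome_b, det$om)
  expect_true(met$trna_a)
  # far outside the vicinity the flag drops
  isl$a_lo <- isl$a_lo + 3L
  met2 <- measure_island(isl, sim$genome_a, sim$genome_b, det$om,
                         config = pipeline_config(trna_vicinity_cds = 1L))
  expect_false(met2$trna_a)
})

test_that("keyword annotation matches configured substrings per gene", {
  sim <- simulate_pair(sim_spec(n_genes = 40, islands = list(
    list(insert_after_rank = 19, n_genes = 4, with_mobility_gene = TRUE)),
    seed = 65))
  det <- run_detection(sim)
  kw <- annotate_keywords(det$islands[1, ], sim$genome_a, sim$genome_b)
  expect_equal(unique(kw$class), "mobility")
  expect_equal(unique(kw$keyword), "integrase")

  # interest keyword against a product string seen in real annotations
  ga <- sim$genome_a
  idx <- which(!is.na(ga$features$rank) &
               ga$features$rank == det$islands$a_lo[1] + 1L)
  ga$features$product[idx] <- "Beta-ketoacyl-ACP synthase III"
  kw2 <- annotate_keywords(det$islands[1, ], ga, sim$genome_b)
  expect_true(any(kw2$class == "interest" & kw2$keyword == "synthase"))

  # no products matching -> empty tag set
  cfg <- pipeline_config(mobility_keywords = "retrohoming",
                         interest_keywords = "terpene")
  kw3 <- annotate_keywords(det$islands[1, ], sim$genome_a, sim$genome_b, cfg)
  expect_equal(nrow(kw3), 0L)
})

test_that("island display filter keeps partner-side passes, rejects min < 3", {
  isl <- data.frame(island_id = c("x", "y", "z"),
                    n_cds_a = c(0L, 16L, 4L), n_cds_b = c(20L, 2L, 4L))
  expect_error(filter_islands(isl, 2), "at least 3")
  expect_equal(filter_islands(isl, 3)$island_id, c("x", "y", "z"))
  expect_equal(filter_islands(isl, 15)$island_id, c("x", "y"))
})

test_that("ranking normalizes metrics and orders deterministically", {
  isl <- data.frame(
    island_id = c("aa", "bb", "cc"),
    n_cds_a = c(10L, 5L, 20L), n_cds_b = c(0L, 0L, 0L),
    n_no_ortholog_a = c(10L, 5L, 20L), n_no_ortholog_b = 0L,
    n_paralog_a = 0L, n_paralog_b = 0L,
    trna_a = c(TRUE, FALSE, FALSE), trna_b = FALSE,
    delta_gc_a = c(-5, 2, 0), delta_gc_b = NA_real_,
    stringsAsFactors = FALSE)
  # weight only on n_cds_a: largest island first
  r1 <- rank_islands(isl, c(n_cds_a = 1))
  expect_equal(r1$island_id, c("cc", "aa", "bb"))
  expect_equal(r1$rank_score, c(1, 1 / 3, 0))
  # all-zero weights: scores 0, order falls back to island id
  r0 <- rank_islands(isl, c(n_cds_a = 0, trna_a = 0))
  expect_equal(r0$island_id, c("aa", "bb", "cc"))
  expect_true(all(r0$rank_score == 0))
  # single island: degenerate normalization gives 0
  rs <- rank_islands(isl[1, ], c(n_cds_a = 1, delta_gc_a = 2))
  expect_equal(rs$rank_score, 0)
  # invariance under affine rescaling of one metric
  isl2 <- isl
  isl2$delta_gc_a <- isl2$delta_gc_a * 7 + 3
  w <- c(n_cds_a = 1, delta_gc_a = 1, trna_a = 0.5)
  expect_equal(rank_islands(isl, w)$island_id,
               rank_islands(isl2, w)$island_id)
  expect_error(rank_islands(isl, c(bogus = 1)), "unknown ranking metric")
})

test_that("GOC is 1 under perfect conservation, 0 without orthologs, and
           dips inside an island", {
  sim <- simulate_pair(sim_spec(n_genes = 100, islands = list(
    list(insert_after_rank = 49, n_genes = 10)), divergence = 95, seed = 66))
  det <- run_detection(sim)
  prof <- goc_profile(det$om, sim$genome_a, sim$genome_b)
  expect_true(all(prof$goc >= 0 & prof$goc <= 1))
  pa <- prof[prof$genome_id == "simA", ]
  # the minimum of the profile falls inside the island's bp span
  fa <- sim$genome_a$features
  isl_feats <- fa[!is.na(fa$rank) & fa$rank >= det$islands$a_lo &
                  fa$rank <= det$islands$a_hi, ]
  span <- c(min(isl_feats$start), max(isl_feats$end))
  wmin <- pa$window_center_bp[which.min(pa$goc)]
  expect_gte(wmin, span[1] - 20000)
  expect_lte(wmin, span[2] + 20000)
  expect_lt(min(pa$goc), 1)
  # direct window-count oracle agreement
  orc <- oracle_goc(sim$genome_a, sim$genome_b, det$om$pairs)
  expect_equal(pa$goc, orc$goc)
  expect_equal(pa$window_start_bp, orc$window_start_bp)
})

test_that("island intervals are disjoint and CDS counts conserved", {
  spec <- random_recovery_spec(1201)
  sim <- simulate_pair(spec)
  det <- run_detection(sim)
  isl <- det$islands
  a_ok <- !is.na(isl$a_lo)
  if (sum(a_ok) > 1) {
    iv <- isl[a_ok, c("a_lo", "a_hi")]
    iv <- iv[order(iv$a_lo), ]
    expect_true(all(iv$a_lo[-1] > iv$a_hi[-nrow(iv)]))
  }
  expect_lte(sum(isl$n_cds_a), sim$genome_a$n_cds)
  expect_lte(sum(isl$n_cds_b), sim$genome_b$n_cds)
})
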