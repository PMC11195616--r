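# Hand-built multi-genome fixtures: a 30-gene reference and satellite
# genomes whose islands anchor between chosen reference genes.

ref <- mock_genome("R", 30)

isl_row <- function(id, carrier, left, right, ref_left, ref_right,
                    n_a = 5L, n_b = 0L) {
  data.frame(island_id = id, genome_a = carrier, genome_b = "R",
             repl_a = paste0(carrier, "_chr"), repl_b = "R_chr",
             left_block = "lb", right_block = "rb", interior_blocks = "",
             left_a = left, right_a = right,
             left_b = ref_left, right_b = ref_right,
             a_lo = 10L, a_hi = 14L, b_lo = NA_integer_, b_hi = NA_integer_,
             n_cds_a = n_a, n_cds_b = n_b, stringsAsFactors = FALSE)
}

map_to_ref <- function(gid, pairs_from, pairs_to) {
  structure(list(genome_a = gid, genome_b = "R",
                 pairs = data.frame(feature_a = pairs_from,
                                    feature_b = pairs_to,
                                    stage = "brh_unique",
                                    stringsAsFactors = FALSE)),
            class = "ortholog_map")
}

four_genome_site <- function() {
  genomes <- sprintf("G%d", 1:4)
  islands <- do.call(rbind, lapply(seq_along(genomes), function(i) {
    g <- genomes[i]
    isl_row(paste0("isl", i), g, paste0(g, "_05"), paste0(g, "_06"),
            "R_10", "R_11")
  }))
  maps <- setNames(lapply(genomes, function(g) {
    map_to_ref(g, paste0(g, c("_05", "_06")), c("R_10", "R_11"))
  }), paste(genomes, "R", sep = "|"))
  list(genomes = c(genomes, "R", "lone"), islands = islands, maps = maps)
}

test_that("anchor signatures are the reference orthologs of the boundaries", {
  fx <- four_genome_site()
  sig <- anchor_signature(fx$islands[1, ], "a", "R", fx$maps, ref)
  expect_equal(sig$left, "R_10")
  expect_equal(sig$right, "R_11")
  expect_equal(sig$key, "R_10|R_11")
  # an island at a different locus gets a different signature
  other <- isl_row("isl9", "G1", "G1_20", "G1_21", "R_25", "R_26")
  maps2 <- fx$maps
  maps2[["G1|R"]]$pairs <- rbind(maps2[["G1|R"]]$pairs,
                                 data.frame(feature_a = c("G1_20", "G1_21"),
                                            feature_b = c("R_25", "R_26"),
                                            stage = "brh_unique"))
  sig2 <- anchor_signature(other, "a", "R", maps2, ref)
  expect_false(sig2$key == sig$key)
  # a boundary without a reference ortholog leaves the signature undefined
  orphan <- isl_row("isl8", "G1", "G1_27", "G1_28", NA, NA)
  expect_null(anchor_signature(orphan, "a", "R", fx$maps, ref))
})

test_that("shared locations give diversity = genomes carrying an island", {
  fx <- four_genome_site()
  bg <- build_break_graph(fx$islands, fx$maps, "R", ref, fx$genomes)
  expect_equal(nrow(bg$locations), 1L)
  expect_equal(bg$locations$diversity, 4L)
  expect_equal(nrow(bg$edges), choose(4, 2))
  deg <- igraph::degree(bg$graph)
  expect_equal(unname(deg[c("lone", "R")]), c(0, 0))
  expect_true(all(deg[sprintf("G%d", 1:4)] == 3))
})

test_that("an island-free genome set gives an empty break graph", {
  bg <- build_break_graph(four_genome_site()$islands[0, ], list(), "R", ref,
                          c("R", "lone"))
  expect_equal(nrow(bg$edges), 0L)
  expect_equal(nrow(bg$locations), 0L)
  expect_equal(igraph::vcount(bg$graph), 2L)
})

test_that("two integration sites form two disjoint hotspot groups", {
  fx <- four_genome_site()
  east <- rbind(
    isl_row("e1", "G1", "G1_20", "G1_21", "R_25", "R_26"),
    isl_row("e2", "G2", "G2_20", "G2_21", "R_25", "R_26"))
  maps <- fx$maps
  for (g in c("G1", "G2")) {
    maps[[paste0(g, "|R")]]$pairs <- rbind(
      maps[[paste0(g, "|R")]]$pairs,
      data.frame(feature_a = paste0(g, c("_20", "_21")),
                 feature_b = c("R_25", "R_26"), stage = "brh_unique"))
  }
  bg <- build_break_graph(rbind(fx$islands, east), maps, "R", ref, fx$genomes)
  expect_equal(nrow(bg$locations), 2L)
  expect_setequal(bg$locations$diversity, c(4L, 2L))
})

test_that("overlap groups are transitive closures excluding exact matches", {
  mk <- function(id, g, refl, refr) {
    i <- isl_row(id, g, paste0(g, "_05"), paste0(g, "_06"), refl, refr)
    i
  }
  gset <- sprintf("H%d", 1:4)
  maps <- setNames(lapply(seq_along(gset), function(k) {
    anchors <- list(c("R_10", "R_11"), c("R_09", "R_12"),
                    c("R_11", "R_14"), c("R_13", "R_16"))[[k]]
    map_to_ref(gset[k], paste0(gset[k], c("_05", "_06")), anchors)
  }), paste(gset, "R", sep = "|"))

  # staggered chain: (10,11), (9,12), (11,14), (13,16) -> one group of 4?
  # (10,11)-(9,12) overlap; (9,12)-(11,14) overlap; (11,14)-(13,16) overlap;
  # (10,11)-(11,14) only touch at the anchor -> transitive closure joins all
  islands <- do.call(rbind, lapply(seq_along(gset), function(k) {
    anchors <- list(c("R_10", "R_11"), c("R_09", "R_12"),
                    c("R_11", "R_14"), c("R_13", "R_16"))[[k]]
    mk(paste0("ov", k), gset[k], anchors[1], anchors[2])
  }))
  ov <- find_overlapping_islands(islands, maps, "R", ref)
  expect_length(ov, 1L)
  expect_setequal(ov[[1]]$island_id, paste0("ov", 1:4))

  # disjoint intervals form no group
  ov2 <- find_overlapping_islands(islands[c(1, 4), ], maps, "R", ref)
  expect_length(ov2, 0L)

  # identical signatures are "same location", not overlapping
  twin_maps <- setNames(lapply(c("T1", "T2"), function(g) {
    map_to_ref(g, paste0(g, c("_05", "_06")), c("R_10", "R_11"))
  }), c("T1|R", "T2|R"))
  twins <- rbind(mk("t1", "T1", "R_10", "R_11"),
                 mk("t2", "T2", "R_10", "R_11"))
  expect_length(find_overlapping_islands(twins, twin_maps, "R", ref), 0L)
})
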