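# Programmatic fixtures shared across tests. Mock genomes are bare lists
# with the fields the ordering/orthology/synteny code consumes (feature
# table with ranks); sequence-level tests use the simulator or hand-written
# flat files instead.

mock_genome <- function(id, n, kinds = rep("CDS", n), prefix = id) {
  ids <- sprintf("%s_%02d", prefix, seq_len(n))
  feats <- data.frame(
    feature_id = ids, genome_id = id, replicon_id = paste0(id, "_chr"),
    start = seq_len(n) * 1000L - 999L, end = seq_len(n) * 1000L - 100L,
    strand = 1L, kind = kinds, product = "",
    translation = ifelse(kinds == "CDS", strrep("M", 50), NA_character_),
    rank = seq_len(n) - 1L, gc_fraction = 0.5,
    stringsAsFactors = FALSE)
  list(genome_id = id,
       replicons = data.frame(replicon_id = paste0(id, "_chr"),
                              length_bp = n * 1000L, gc_fraction = 0.5,
                              topology = "linear", stringsAsFactors = FALSE),
       features = feats,
       n_cds = sum(kinds == "CDS"), n_trna = sum(kinds == "tRNA"))
}

mock_hit_table <- function(genome_a, genome_b, hits) {
  defaults <- data.frame(identity_pct = 80, aln_len = 50L, mismatches = 10L,
                         gap_opens = 0L, q_start = 1L, q_end = 50L,
                         s_start = 1L, s_end = 50L, evalue = 1e-30,
                         bitscore = 100, stringsAsFactors = FALSE)
  for (col in names(defaults)) {
    if (is.null(hits[[col]])) hits[[col]] <- defaults[[col]]
  }
  structure(list(genome_a = genome_a, genome_b = genome_b,
                 hits = hits, provenance = "external_file"),
            class = "hit_table")
}

# ortholog map between two mock genomes given (index_a, index_b) pairs
mock_map <- function(ga, gb, ia, ib, stage = "brh_unique") {
  structure(list(
    genome_a = ga$genome_id, genome_b = gb$genome_id,
    pairs = data.frame(feature_a = ga$features$feature_id[ia],
                       feature_b = gb$features$feature_id[ib],
                       stage = stage, stringsAsFactors = FALSE)),
    class = "ortholog_map")
}

# random one-to-one ortholog map over mock genomes (for chaining oracles)
random_map_case <- function(seed) {
  set.seed(seed)
  na <- sample(6:15, 1); nb <- sample(6:15, 1)
  ga <- mock_genome("A", na); gb <- mock_genome("B", nb)
  m <- sample(2:min(na, nb), 1)
  ia <- sort(sample(na, m)); ib <- sample(nb, m)
  list(ga = ga, gb = gb, map = mock_map(ga, gb, ia, ib))
}

# random reciprocal hit tables with score ties (for orthology oracles)
random_hits_case <- function(seed) {
  set.seed(seed)
  na <- sample(5:12, 1); nb <- sample(5:12, 1)
  ga <- mock_genome("A", na); gb <- mock_genome("B", nb)
  rows <- list()
  for (i in seq_len(na)) {
    k <- sample(0:min(3, nb), 1)
    if (k == 0) next
    js <- sample(nb, k)
    for (j in js) {
      rows[[length(rows) + 1]] <- data.frame(
        query_id = ga$features$feature_id[i],
        subject_id = gb$features$feature_id[j],
        bitscore = sample(seq(50, 56, by = 0.5), 1),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  ab <- do.call(rbind, rows)
  ba <- data.frame(query_id = ab$subject_id, subject_id = ab$query_id,
                   bitscore = ab$bitscore, stringsAsFactors = FALSE)
  list(ga = ga, gb = gb,
       tab_ab = mock_hit_table("A", "B", ab),
       tab_ba = mock_hit_table("B", "A", ba))
}

# sampled simulation specs used by the recovery studies: 1-5 islands of
# 3-30 genes at distinct backbone positions (pairwise spacing >= 4 backbone
# genes, >= 3 from either end), divergence 60-95%
random_recovery_spec <- function(seed) {
  set.seed(seed)
  n <- sample(100:500, 1)
  k <- sample(1:5, 1)
  pos <- integer(0)
  avail <- 3:(n - 4)
  for (i in seq_len(k)) {
    ok <- avail[vapply(avail, function(p) all(abs(p - pos) >= 4), logical(1))]
    if (!length(ok)) break
    pos <- c(pos, sample(ok, 1))
  }
  islands <- lapply(pos, function(p) {
    list(insert_after_rank = p, n_genes = sample(3:30, 1),
         gc_shift = sample(-8:8, 1), with_trna = runif(1) < 0.5,
         with_mobility_gene = runif(1) < 0.3,
         target_genome = sample(c("A", "B"), 1))
  })
  sim_spec(n_genes = n, islands = islands,
           divergence = runif(1, 60, 95), seed = seed)
}

# run the detection pipeline on a simulated pair and return the islands
run_detection <- function(sim, config = pipeline_config()) {
  ga <- sim$genome_a; gb <- sim$genome_b
  lens <- c(setNames(nchar(ga$features$translation), ga$features$feature_id),
            setNames(nchar(gb$features$translation), gb$features$feature_id))
  lens <- lens[!is.na(lens)]
  av <- all_vs_all(list(ga, gb), config = config)
  om <- ortholog_map(
    filter_hits(av[[paste0(ga$genome_id, "->", gb$genome_id)]], config, lens),
    filter_hits(av[[paste0(gb$genome_id, "->", ga$genome_id)]], config, lens),
    ga, gb, config)
  sb <- synteny_blocks(om, ga, gb, config)
  list(om = om, blocks = sb,
       islands = detect_breaks(sb, ga, gb, config))
}

# detected (genome, lo, hi) intervals vs truth intervals
island_interval_sets <- function(islands, truth) {
  det <- character(0)
  for (i in seq_len(nrow(islands))) {
    if (!is.na(islands$a_lo[i])) {
      det <- c(det, paste(islands$genome_a[i], islands$a_lo[i],
                          islands$a_hi[i]))
    }
    if (!is.na(islands$b_lo[i])) {
      det <- c(det, paste(islands$genome_b[i], islands$b_lo[i],
                          islands$b_hi[i]))
    }
  }
  tru <- paste(truth$genome_id, truth$rank_lo, truth$rank_hi)
  list(detected = sort(det), truth = sort(tru))
}
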