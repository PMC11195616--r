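# End-to-end orchestration: parse -> hits -> orthology -> blocks -> islands
# -> hotspots for every genome pair, collected into a single relational
# object (`island_db`) whose tables are exportable as CSV/JSON with a config
# snapshot hash for provenance. Given identical inputs and configuration the
# whole pipeline is deterministic, so exports are byte-identical across runs.

#' Build an island database for a set of genomes
#'
#' Runs the full pipeline for every unordered genome pair: all-vs-all
#' protein comparison (built-in aligner or external hit files), retention
#' filtering, best-reciprocal-hit orthology with synteny resolution, paralog
#' detection from self-comparisons, synteny block chaining, island calling
#' with metrics and keyword tags, gene-order-conservation profiles, and
#' per-location diversity factors.
#'
#' @param genomes List of `genome_record` objects or genome file paths
#'   (GenBank), 2 to `config$max_genomes` genomes.
#' @param config A [pipeline_config()].
#' @param backend Hits backend, see [all_vs_all()].
#' @param hits_dir Directory of external hit files when
#'   `backend = "external_file"`.
#' @return An object of class `island_db`.
#' @export
build_database <- function(genomes, config = pipeline_config(),
                           backend = c("builtin", "external_file"),
                           hits_dir = NULL) {
  backend <- match.arg(backend)
  genomes <- lapply(genomes, function(g) {
    if (is.character(g)) parse_genome(g, format = "genbank") else g
  })
  stopifnot(all(vapply(genomes, inherits, logical(1), "genome_record")))
  if (length(genomes) < 2) stop("at least 2 genomes are required")
  if (length(genomes) > config$max_genomes) {
    stop("more than ", config$max_genomes, " genomes (", length(genomes),
         "); raise max_genomes explicitly if intended")
  }
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(genomes) <- ids

  tables <- all_vs_all(genomes, backend = backend, hits_dir = hits_dir,
                       config = config)
  lengths_of <- lapply(genomes, function(g) {
    p <- proteome(g); setNames(nchar(p), names(p))
  })
  filt <- list()
  for (key in names(tables)) {
    tb <- tables[[key]]
    lens <- c(lengths_of[[tb$genome_a]], lengths_of[[tb$genome_b]])
    filt[[key]] <- filter_hits(tb, config, lens)
  }

  paralogs <- lapply(ids, function(g) {
    detect_paralogs(filt[[paste0(g, "->", g)]], config)
  })
  names(paralogs) <- ids

  maps <- list(); blocks_all <- list(); members_all <- list()
  islands_all <- list(); goc_all <- list()
  for (ii in seq_along(ids)) {
    for (jj in seq_along(ids)) {
      if (jj <= ii) next
      a <- ids[ii]; b <- ids[jj]
      om <- ortholog_map(filt[[paste0(a, "->", b)]],
                         filt[[paste0(b, "->", a)]],
                         genomes[[a]], genomes[[b]], config)
      key <- paste(sort(c(a, b)), collapse = "|")
      maps[[key]] <- om
      sb <- synteny_blocks(om, genomes[[a]], genomes[[b]], config)
      blocks_all[[key]] <- sb$blocks
      members_all[[key]] <- sb$members
      isl <- call_islands(sb, genomes[[a]], genomes[[b]], om,
                          paralogs[[a]], paralogs[[b]], config)
      islands_all[[key]] <- isl
      goc <- goc_profile(om, genomes[[a]], genomes[[b]], config)
      goc$pair <- key
      goc_all[[key]] <- goc
    }
  }

  islands <- if (length(islands_all)) do.call(rbind, islands_all) else
    empty_islands()
  rownames(islands) <- NULL

  db <- structure(list(
    genomes = genomes,
    config = config,
    config_hash = config_hash(config),
    hit_tables = filt,
    paralogs = paralogs,
    maps = maps,
    blocks = if (length(blocks_all)) do.call(rbind, blocks_all) else NULL,
    members = members_all,
    islands = islands,
    goc = if (length(goc_all)) do.call(rbind, goc_all) else NULL,
    input_digests = vapply(genomes, function(g) {
      stable_id(g$genome_id, g$n_cds,
                paste(g$replicons$length_bp, collapse = ","), n = 8)
    }, character(1))),
    class = "island_db")
  db$islands <- add_diversity(db)
  db
}

# diversity factor per island side: number of distinct genomes carrying an
# island at the same anchored location, taking each island's own genome as
# the reference coordinate system.
add_diversity <- function(db) {
  isl <- db$islands
  if (!nrow(isl)) {
    isl$diversity_a <- integer(0); isl$diversity_b <- integer(0)
    return(isl)
  }
  isl$diversity_a <- NA_integer_
  isl$diversity_b <- NA_integer_
  for (ref in names(db$genomes)) {
    bg <- build_break_graph(isl, db$maps, ref, db$genomes[[ref]],
                            names(db$genomes), min_cds = 1L)
    ent <- bg$entries
    if (!nrow(ent)) next
    div <- setNames(bg$locations$diversity, bg$locations$signature)
    for (k in seq_len(nrow(ent))) {
      i <- which(isl$island_id == ent$island_id[k] &
                 isl[[paste0("genome_", ent$side[k])]] == ent$genome_id[k])
      col <- paste0("diversity_", ent$side[k])
      # keep the maximum across reference frames (locations coincide for
      # every reference that can express them; NA-safe max)
      isl[i, col] <- pmax(isl[i, col], div[[ent$signature[k]]], na.rm = TRUE)
    }
  }
  isl
}

#' @export
print.island_db <- function(x, ...) {
  cat("island_db: ", length(x$genomes), " genome(s), ",
      length(x$maps), " pair(s), ",
      if (is.null(x$blocks)) 0 else nrow(x$blocks), " block(s), ",
      nrow(x$islands), " island(s) [config ", x$config_hash, "]\n", sep = "")
  for (key in names(x$maps)) {
    cat("  ", key, ": ", nrow(x$maps[[key]]$pairs), " orthologs, ",
        sum(x$blocks$genome_a == x$maps[[key]]$genome_a &
            x$blocks$genome_b == x$maps[[key]]$genome_b), " blocks, ",
        nrow(x$islands[x$islands$genome_a == x$maps[[key]]$genome_a &
                       x$islands$genome_b == x$maps[[key]]$genome_b, ]),
        " islands\n", sep = "")
  }
  invisible(x)
}

write_csv_report <- function(df, path, hash) {
  con <- file(path, open = "wt")
  writeLines(paste0("# islandbreak config ", hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  close(con)
  path
}

#' Read back an exported report CSV
#'
#' @param path Path written by [export_reports()].
#' @return Data frame (the provenance header line is skipped).
#' @export
read_report_csv <- function(path) {
  utils::read.table(path, sep = ",", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Export database reports
#'
#' Writes the island summary (all metrics plus diversity), ortholog pairs,
#' blocks and GOC series as CSV, a per-island gene detail table, and one
#' dotplot JSON per genome pair (ortholog points as rank pairs, blocks as
#' segments, islands as rectangles, GOC series). Every file carries the
#' configuration snapshot hash in a header comment.
#'
#' @param db An `island_db`.
#' @param dir Output directory (created if needed).
#' @param min_cds Island display filter (see [filter_islands()]).
#' @return Character vector of files written, invisibly.
#' @export
export_reports <- function(db, dir, min_cds = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- db$config_hash
  files <- character(0)

  isl <- filter_islands(db$islands, min_cds)
  files <- c(files, write_csv_report(isl, file.path(dir, "islands.csv"), h))

  ortho <- do.call(rbind, lapply(names(db$maps), function(key) {
    p <- db$maps[[key]]$pairs
    p$pair <- key
    p
  }))
  files <- c(files, write_csv_report(ortho, file.path(dir, "ortho_pairs.csv"), h))
  if (!is.null(db$blocks)) {
    files <- c(files, write_csv_report(db$blocks,
                                       file.path(dir, "blocks.csv"), h))
  }
  if (!is.null(db$goc)) {
    files <- c(files, write_csv_report(db$goc, file.path(dir, "goc.csv"), h))
  }

  # per-island gene detail: flanking blocks and island content of both sides
  detail <- list()
  for (i in seq_len(nrow(isl))) {
    row <- isl[i, , drop = FALSE]
    ga <- db$genomes[[row$genome_a]]; gb <- db$genomes[[row$genome_b]]
    key <- paste(sort(c(row$genome_a, row$genome_b)), collapse = "|")
    mem <- db$members[[key]]
    for (part in c("left_block", "island_a", "island_b", "right_block")) {
      f <- switch(part,
        left_block = ga$features[ga$features$feature_id %in%
                                 mem[[row$left_block]]$feature_a, , drop = FALSE],
        right_block = ga$features[ga$features$feature_id %in%
                                  mem[[row$right_block]]$feature_a, , drop = FALSE],
        island_a = island_features(row, ga, "a"),
        island_b = island_features(row, gb, "b"))
      if (!nrow(f)) next
      detail[[length(detail) + 1L]] <- data.frame(
        island_id = row$island_id, part = part,
        feature_id = f$feature_id, genome_id = f$genome_id,
        start = f$start, end = f$end, strand = f$strand, kind = f$kind,
        rank = f$rank, product = f$product,
        gc_fraction = round(f$gc_fraction, 4), stringsAsFactors = FALSE)
    }
  }
  detail <- if (length(detail)) do.call(rbind, detail) else
    data.frame(island_id = character(0), part = character(0),
               feature_id = character(0), genome_id = character(0),
               start = integer(0), end = integer(0), strand = integer(0),
               kind = character(0), rank = integer(0), product = character(0),
               gc_fraction = numeric(0), stringsAsFactors = FALSE)
  files <- c(files, write_csv_report(detail,
                                     file.path(dir, "island_genes.csv"), h))

  for (key in names(db$maps)) {
    om <- db$maps[[key]]
    ga <- db$genomes[[om$genome_a]]; gb <- db$genomes[[om$genome_b]]
    d <- ortho_rank_frame(om, ga, gb)
    blk <- db$blocks[db$blocks$genome_a == om$genome_a &
                     db$blocks$genome_b == om$genome_b, , drop = FALSE]
    pisl <- isl[isl$genome_a == om$genome_a & isl$genome_b == om$genome_b, ,
                drop = FALSE]
    goc <- db$goc[db$goc$pair == key, , drop = FALSE]
    dot <- list(
      pair = key, config = h,
      points = d[, c("feature_a", "feature_b", "rank_a", "rank_b")],
      blocks = blk[, c("block_id", "rank_a_lo", "rank_a_hi", "rank_b_lo",
                       "rank_b_hi", "orientation")],
      islands = pisl[, c("island_id", "a_lo", "a_hi", "b_lo", "b_hi")],
      goc = goc[, c("genome_id", "window_center_bp", "goc")])
    f <- file.path(dir, paste0("dotplot_", gsub("[^A-Za-z0-9_-]", "_", key),
                               ".json"))
    write_json(dot, f, auto_unbox = TRUE, digits = 8, na = "null")
    files <- c(files, f)
  }
  invisible(files)
}

#' Export the hotspot break graph and overlapping island groups
#'
#' @param db An `island_db`.
#' @param reference Reference genome id.
#' @param dir Output directory.
#' @param min_cds Minimum CDS count for a genome to count as carrying an
#'   island at a location.
#' @return Files written, invisibly.
#' @export
export_hotspots <- function(db, reference, dir, min_cds = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bg <- build_break_graph(db$islands, db$maps, reference,
                          db$genomes[[reference]], names(db$genomes), min_cds)
  f1 <- write_csv_report(bg$edges,
                         file.path(dir, paste0("break_graph_", reference,
                                               ".csv")), db$config_hash)
  f2 <- file.path(dir, paste0("break_graph_", reference, ".json"))
  write_json(list(reference = reference, config = db$config_hash,
                  locations = bg$locations, edges = bg$edges),
             f2, auto_unbox = TRUE, digits = 8, na = "null")
  ov <- find_overlapping_islands(db$islands, db$maps, reference,
                                 db$genomes[[reference]], min_cds = min_cds)
  ov_df <- if (length(ov)) {
    do.call(rbind, lapply(seq_along(ov), function(k) {
      g <- ov[[k]]; g$group <- k; g
    }))
  } else {
    data.frame(island_id = character(0), genome_id = character(0),
               signature = character(0), group = integer(0),
               stringsAsFactors = FALSE)
  }
  f3 <- write_csv_report(ov_df,
                         file.path(dir, paste0("overlapping_islands_",
                                               reference, ".csv")),
                         db$config_hash)
  invisible(c(f1, f2, f3))
}
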