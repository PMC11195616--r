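# Integration hotspots across a multi-genome database: islands anchored at
# the exact same chromosomal location (identical boundary orthologs in a
# reference genome) form a break graph with a per-location diversity factor;
# islands occupying the same reference region with shifted boundaries are
# grouped as overlapping islands.

# partner feature in `to` for features of genome `from`, via the stored
# pairwise ortholog maps (keyed "A|B" with A < B).
orth_partner <- function(maps, from, to, feature_ids) {
  if (from == to) return(setNames(feature_ids, feature_ids))
  key <- paste(sort(c(from, to)), collapse = "|")
  m <- maps[[key]]
  if (is.null(m)) return(setNames(rep(NA_character_, length(feature_ids)),
                                  feature_ids))
  p <- m$pairs
  if (m$genome_a == from) {
    setNames(p$feature_b[match(feature_ids, p$feature_a)], feature_ids)
  } else {
    setNames(p$feature_a[match(feature_ids, p$feature_b)], feature_ids)
  }
}

#' Anchor signature of an island in a reference genome
#'
#' The ordered pair of reference-genome orthologs of the island's boundary
#' genes (last gene of the left flanking block, first gene of the right
#' flanking block), oriented by ascending reference rank. `NA` when a
#' boundary gene has no ortholog in the reference.
#'
#' @param island One island row (from [call_islands()]).
#' @param side `"a"` or `"b"`: which genome of the pair carries the island.
#' @param reference Reference genome id.
#' @param maps Named list of `ortholog_map`s, keys `"A|B"` with sorted ids.
#' @param ref_genome The reference `genome_record` (for ranks).
#' @return List with `left`, `right` (reference feature ids) and `key`
#'   (signature string), or `NULL` when undefined.
#' @export
anchor_signature <- function(island, side, reference, maps, ref_genome) {
  g <- island[[paste0("genome_", side)]]
  bnd <- c(island[[paste0("left_", side)]], island[[paste0("right_", side)]])
  refs <- unname(orth_partner(maps, g, reference, bnd))
  if (anyNA(refs)) return(NULL)
  rk <- setNames(ref_genome$features$rank, ref_genome$features$feature_id)
  r <- rk[refs]
  if (anyNA(r)) return(NULL)
  if (r[1] > r[2]) { refs <- rev(refs); r <- rev(r) }
  list(left = refs[1], right = refs[2], rank_left = unname(r[1]),
       rank_right = unname(r[2]),
       key = paste(refs[1], refs[2], sep = "|"))
}

# one row per (island, carrying genome) anchored in the reference
hotspot_entries <- function(islands, maps, reference, ref_genome, min_cds = 1L) {
  rows <- list()
  for (i in seq_len(nrow(islands))) {
    isl <- islands[i, , drop = FALSE]
    for (side in c("a", "b")) {
      if (isl[[paste0("n_cds_", side)]] < min_cds) next
      sig <- anchor_signature(isl, side, reference, maps, ref_genome)
      if (is.null(sig)) next
      rows[[length(rows) + 1L]] <- data.frame(
        island_id = isl$island_id, genome_id = isl[[paste0("genome_", side)]],
        partner_id = isl[[paste0("genome_", if (side == "a") "b" else "a")]],
        side = side, signature = sig$key,
        ref_left = sig$left, ref_right = sig$right,
        ref_rank_lo = sig$rank_left, ref_rank_hi = sig$rank_right,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(island_id = character(0), genome_id = character(0),
                      partner_id = character(0), side = character(0),
                      signature = character(0), ref_left = character(0),
                      ref_right = character(0), ref_rank_lo = integer(0),
                      ref_rank_hi = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Break graph of shared island locations
#'
#' Groups islands by identical anchor signature in a reference genome; the
#' genomes of each group are linked pairwise, and each location's diversity
#' factor is the number of distinct genomes carrying an island there.
#'
#' @param islands Island data frame across all genome pairs.
#' @param maps Named list of pairwise `ortholog_map`s (keys `"A|B"`).
#' @param reference Reference genome id.
#' @param ref_genome The reference `genome_record`.
#' @param genomes Character vector of all genome ids (graph vertices).
#' @param min_cds Minimum CDS count for a genome to count as carrying an
#'   island at a location.
#' @return List: `locations` (signature, diversity, genome list), `edges`
#'   (genome_i, genome_j, signature), `entries`, and the igraph `graph`.
#' @export
build_break_graph <- function(islands, maps, reference, ref_genome,
                              genomes, min_cds = 1L) {
  ent <- hotspot_entries(islands, maps, reference, ref_genome, min_cds)
  locs <- list(); edges <- list()
  for (sig in unique(ent$signature)) {
    grp <- ent[ent$signature == sig, , drop = FALSE]
    gset <- sort(unique(grp$genome_id))
    locs[[length(locs) + 1L]] <- data.frame(
      signature = sig, diversity = length(gset),
      genomes = paste(gset, collapse = ","), stringsAsFactors = FALSE)
    if (length(gset) >= 2) {
      cmb <- t(combn(gset, 2))
      edges[[length(edges) + 1L]] <- data.frame(
        genome_i = cmb[, 1], genome_j = cmb[, 2], signature = sig,
        stringsAsFactors = FALSE)
    }
  }
  locations <- if (length(locs)) do.call(rbind, locs) else
    data.frame(signature = character(0), diversity = integer(0),
               genomes = character(0), stringsAsFactors = FALSE)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(genome_i = character(0), genome_j = character(0),
               signature = character(0), stringsAsFactors = FALSE)
  graph <- if (nrow(edges)) {
    graph_from_data_frame(edges[, c("genome_i", "genome_j")],
                          directed = FALSE,
                          vertices = data.frame(name = genomes))
  } else {
    g <- make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(genomes), name = genomes)
    g
  }
  list(locations = locations, edges = edges, entries = ent, graph = graph)
}

#' Overlapping islands with shifted boundaries
#'
#' Islands projected into the reference coordinate system whose open anchor
#' intervals intersect but whose anchor signatures differ are grouped by
#' transitive closure (connected components of the interval-intersection
#' graph); exact-signature matches are excluded from these groups.
#'
#' @inheritParams build_break_graph
#' @return List of groups; each group is a data frame of entries (island id,
#'   genome, signature, reference rank interval).
#' @export
find_overlapping_islands <- function(islands, maps, reference, ref_genome,
                                     genomes = NULL, min_cds = 1L) {
  ent <- hotspot_entries(islands, maps, reference, ref_genome, min_cds)
  n <- nrow(ent)
  if (n < 2) return(list())
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (ent$signature[i] == ent$signature[j]) next
      if (max(ent$ref_rank_lo[i], ent$ref_rank_lo[j]) <
          min(ent$ref_rank_hi[i], ent$ref_rank_hi[j])) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(pairs)) return(list())
  em <- do.call(rbind, pairs)
  g <- graph_from_data_frame(data.frame(from = as.character(em[, 1]),
                                        to = as.character(em[, 2])),
                             directed = FALSE,
                             vertices = data.frame(name = as.character(seq_len(n))))
  comp <- components(g)
  grps <- split(seq_len(n), comp$membership)
  grps <- grps[vapply(grps, length, integer(1)) >= 2]
  unname(lapply(grps, function(ix) {
    ent[sort(ix), , drop = FALSE]
  }))
}
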