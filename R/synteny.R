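# Synteny blocks: maximal colinear runs of ortholog pairs, tolerating up to
# max_gap intervening non-orthologous CDS/tRNA ranks per genome. Consecutive
# ortholog pairs are linked when they are adjacent among the mapped genes of
# both genomes (an orthologous gene inside the gap breaks the link) and the
# non-orthologous gap on each side is within tolerance; blocks are maximal
# constant-direction runs of links, so every block is strictly monotonic in
# both genomes.

ortho_rank_frame <- function(orthologs, genome_a, genome_b) {
  pairs <- if (inherits(orthologs, "ortholog_map")) orthologs$pairs else orthologs
  fa <- genome_a$features; fb <- genome_b$features
  ia <- match(pairs$feature_a, fa$feature_id)
  ib <- match(pairs$feature_b, fb$feature_id)
  if (anyNA(ia) || anyNA(ib)) stop("ortholog pairs reference unknown features")
  d <- data.frame(feature_a = pairs$feature_a, feature_b = pairs$feature_b,
                  repl_a = fa$replicon_id[ia], repl_b = fb$replicon_id[ib],
                  rank_a = fa$rank[ia], rank_b = fb$rank[ib],
                  stringsAsFactors = FALSE)
  d <- d[order(d$repl_a, d$rank_a), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Link consecutive ortholog pairs
#'
#' Two ortholog pairs are linked when, in each genome, their genes are
#' adjacent among the mapped genes of that replicon (no orthologous gene in
#' between) and separated by at most `max_gap` non-orthologous CDS/tRNA
#' ranks. Links never cross replicon boundaries.
#'
#' @param orthologs An `ortholog_map` (or its `pairs` data frame).
#' @param genome_a,genome_b The two `genome_record`s.
#' @param max_gap Gap tolerance.
#' @return List with `pairs` (ranked ortholog table, sorted along genome A)
#'   and `links` (data frame `from`, `to` row indices into `pairs`, and
#'   `sign` of the step in genome B).
#' @export
link_consecutive <- function(orthologs, genome_a, genome_b, max_gap = 2L) {
  d <- ortho_rank_frame(orthologs, genome_a, genome_b)
  n <- nrow(d)
  links <- data.frame(from = integer(0), to = integer(0), sign = integer(0))
  if (n >= 2) {
    # adjacency position of each pair among mapped genes of its B replicon
    pos_b <- stats::ave(d$rank_b, d$repl_b, FUN = rank)
    i <- seq_len(n - 1L); j <- i + 1L
    same_repl <- d$repl_a[i] == d$repl_a[j] & d$repl_b[i] == d$repl_b[j]
    gap_a <- d$rank_a[j] - d$rank_a[i] - 1L
    gap_b <- abs(d$rank_b[j] - d$rank_b[i]) - 1L
    adj_b <- abs(pos_b[j] - pos_b[i]) == 1
    ok <- same_repl & gap_a <= max_gap & gap_b <= max_gap & adj_b
    links <- data.frame(from = i[ok], to = j[ok],
                        sign = sign(d$rank_b[j[ok]] - d$rank_b[i[ok]]))
  }
  list(pairs = d, links = links)
}

#' Merge links into synteny blocks
#'
#' Blocks are maximal runs of links with a constant direction in genome B
#' (so every block is strictly increasing along genome A and strictly
#' monotonic in genome B); runs are split where the direction changes.
#' Blocks need at least two ortholog pairs.
#'
#' @param linked Output of [link_consecutive()].
#' @param genome_pair Character vector of the two genome ids (used in block
#'   ids).
#' @return List with `blocks` (one row per block: id, replicons, rank
#'   intervals in both genomes, orientation, pair count) and `members`
#'   (block id -> ortholog pairs in block order).
#' @export
merge_blocks <- function(linked, genome_pair = c(NA, NA)) {
  d <- linked$pairs; L <- linked$links
  blocks <- list(); members <- list()
  if (nrow(L)) {
    # runs of consecutive links (to == next from) with equal sign
    brk <- c(TRUE, L$from[-1] != L$to[-nrow(L)] | L$sign[-1] != L$sign[-nrow(L)])
    run_id <- cumsum(brk)
    for (g in split(seq_len(nrow(L)), run_id)) {
      rows <- c(L$from[g[1]], L$to[g])
      bd <- d[rows, , drop = FALSE]
      ori <- L$sign[g[1]]
      bid <- stable_id(genome_pair[1], genome_pair[2],
                       bd$feature_a[1], bd$feature_a[nrow(bd)], n = 8)
      blocks[[length(blocks) + 1L]] <- data.frame(
        block_id = bid,
        genome_a = genome_pair[1], genome_b = genome_pair[2],
        repl_a = bd$repl_a[1], repl_b = bd$repl_b[1],
        n_pairs = nrow(bd),
        rank_a_lo = min(bd$rank_a), rank_a_hi = max(bd$rank_a),
        rank_b_lo = min(bd$rank_b), rank_b_hi = max(bd$rank_b),
        orientation = ori, stringsAsFactors = FALSE)
      members[[bid]] <- bd
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = character(0), genome_a = character(0),
               genome_b = character(0), repl_a = character(0),
               repl_b = character(0), n_pairs = integer(0),
               rank_a_lo = integer(0), rank_a_hi = integer(0),
               rank_b_lo = integer(0), rank_b_hi = integer(0),
               orientation = integer(0), stringsAsFactors = FALSE)
  rownames(blocks) <- NULL
  list(blocks = blocks, members = members)
}

#' Number blocks along each genome
#'
#' Assigns dense 0-based ordinals per replicon: `ordinal_a` by ascending
#' rank interval start in genome A, `ordinal_b` likewise in genome B.
#'
#' @param blocks The `blocks` data frame from [merge_blocks()].
#' @return The data frame with `ordinal_a` and `ordinal_b` columns.
#' @export
number_blocks <- function(blocks) {
  blocks$ordinal_a <- rep(NA_integer_, nrow(blocks))
  blocks$ordinal_b <- rep(NA_integer_, nrow(blocks))
  for (rep in unique(blocks$repl_a)) {
    sel <- which(blocks$repl_a == rep)
    blocks$ordinal_a[sel[order(blocks$rank_a_lo[sel])]] <- seq_along(sel) - 1L
  }
  for (rep in unique(blocks$repl_b)) {
    sel <- which(blocks$repl_b == rep)
    blocks$ordinal_b[sel[order(blocks$rank_b_lo[sel])]] <- seq_along(sel) - 1L
  }
  blocks
}

#' Synteny blocks for a genome pair
#'
#' Convenience wrapper: [link_consecutive()], [merge_blocks()],
#' [number_blocks()].
#'
#' @inheritParams link_consecutive
#' @param config A [pipeline_config()].
#' @return List with numbered `blocks` and `members` (see [merge_blocks()]).
#' @export
synteny_blocks <- function(orthologs, genome_a, genome_b,
                           config = pipeline_config()) {
  linked <- link_consecutive(orthologs, genome_a, genome_b,
                             max_gap = config$max_gap)
  mb <- merge_blocks(linked, genome_pair = c(genome_a$genome_id,
                                             genome_b$genome_id))
  mb$blocks <- number_blocks(mb$blocks)
  mb
}
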