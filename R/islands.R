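# Synteny breaks (genomic islands): regions between two synteny blocks that
# are consecutive in both genomes and share orientation. Stray blocks -- not
# ordinal-consecutive in both genomes with any other block -- are absorbed
# into the surrounding break, tolerating orthology-detection noise.

#' Detect synteny breaks between consecutive blocks
#'
#' An island is called between two blocks i, j (i before j in genome A, same
#' replicon pair, same orientation) when every block strictly between them in
#' genome A is a stray -- not consecutive in both genomes with any other
#' block, where "consecutive in both" is orientation-consistent (the block
#' following in A must follow in B in the blocks' shared direction) -- and
#' i, j are adjacent in genome B in that direction once the strays are
#' ignored. The island's gene interval in each genome is the ranks strictly
#' between the facing boundary orthologs of the flanking blocks; absorbed
#' stray blocks are recorded as interior. Only breaks with at least
#' `config$min_break_cds` CDSs in one of the genomes are reported, and
#' breaks never overlap (first call along genome A wins).
#'
#' @param blocks_obj Output of [synteny_blocks()] (numbered blocks plus
#'   members).
#' @param genome_a,genome_b The two `genome_record`s.
#' @param config A [pipeline_config()].
#' @return Data frame of islands: id, flanking block ids, interior
#'   (absorbed) block ids, boundary gene ids and rank intervals in both
#'   genomes (`NA` bounds encode an empty side), CDS counts.
#' @export
detect_breaks <- function(blocks_obj, genome_a, genome_b,
                          config = pipeline_config()) {
  b <- blocks_obj$blocks
  members <- blocks_obj$members
  out <- empty_islands()
  n <- nrow(b)
  if (n < 2) return(out)

  oa <- dense_ordinal(b$repl_a, b$rank_a_lo)
  ob <- dense_ordinal(b$repl_b, b$rank_b_lo)
  # consecutiveness on the full block set: same-orientation neighbors must
  # follow in B in the blocks' shared direction; an opposite-orientation
  # block adjacent in both genomes (an inversion flank) also counts
  cb_adj <- vapply(seq_len(n), function(k) {
    same_repl <- b$repl_a == b$repl_a[k] & b$repl_b == b$repl_b[k]
    same_ori <- same_repl & b$orientation == b$orientation[k]
    o <- b$orientation[k]
    any(same_ori & ((oa - oa[k] == 1 & ob - ob[k] == o) |
                    (oa[k] - oa == 1 & ob[k] - ob == o))) ||
      any(same_repl & b$orientation != b$orientation[k] &
          abs(oa - oa[k]) == 1 & abs(ob - ob[k]) == 1)
  }, logical(1))

  fa <- genome_a$features; fb <- genome_b$features
  rows <- list()
  for (repl in unique(b$repl_a)) {
    sel <- which(b$repl_a == repl)
    sel <- sel[order(b$rank_a_lo[sel])]
    last_a_hi <- -1L  # greedy non-overlap along genome A
    for (p in seq_len(length(sel) - 1L)) {
      i <- sel[p]
      for (q in (p + 1L):length(sel)) {
        j <- sel[q]
        interior <- if (q > p + 1L) sel[(p + 1L):(q - 1L)] else integer(0)
        if (length(interior) && !all(!cb_adj[interior])) break
        if (b$repl_b[i] != b$repl_b[j]) next
        if (b$orientation[i] != b$orientation[j]) next
        o <- b$orientation[i]
        # facing bounds in genome B, in the blocks' direction
        if (o == 1L) {
          if (b$rank_b_lo[j] <= b$rank_b_hi[i]) next
          bb_lo <- b$rank_b_hi[i] + 1L; bb_hi <- b$rank_b_lo[j] - 1L
        } else {
          if (b$rank_b_hi[j] >= b$rank_b_lo[i]) next
          bb_lo <- b$rank_b_hi[j] + 1L; bb_hi <- b$rank_b_lo[i] - 1L
        }
        # no block beyond i, j and the A-side interiors may sit in the B gap
        others <- setdiff(which(b$repl_b == b$repl_b[i]), c(i, j, interior))
        if (bb_hi >= bb_lo && length(others) &&
            any(b$rank_b_hi[others] >= bb_lo & b$rank_b_lo[others] <= bb_hi)) {
          next
        }
        a_lo <- b$rank_a_hi[i] + 1L; a_hi <- b$rank_a_lo[j] - 1L
        if (a_lo <= last_a_hi) break
        empty_a <- a_hi < a_lo; empty_b <- bb_hi < bb_lo
        n_cds_a <- if (empty_a) 0L else
          sum(fa$replicon_id == b$repl_a[i] & !is.na(fa$rank) &
              fa$rank >= a_lo & fa$rank <= a_hi & fa$kind == "CDS")
        n_cds_b <- if (empty_b) 0L else
          sum(fb$replicon_id == b$repl_b[i] & !is.na(fb$rank) &
              fb$rank >= bb_lo & fb$rank <= bb_hi & fb$kind == "CDS")
        if (max(n_cds_a, n_cds_b) >= config$min_break_cds) {
          mi <- members[[b$block_id[i]]]; mj <- members[[b$block_id[j]]]
          left_a <- mi$feature_a[which.max(mi$rank_a)]
          right_a <- mj$feature_a[which.min(mj$rank_a)]
          if (o == 1L) {
            left_b <- mi$feature_b[which.max(mi$rank_b)]
            right_b <- mj$feature_b[which.min(mj$rank_b)]
          } else {
            left_b <- mj$feature_b[which.max(mj$rank_b)]
            right_b <- mi$feature_b[which.min(mi$rank_b)]
          }
          rows[[length(rows) + 1L]] <- data.frame(
            island_id = stable_id(genome_a$genome_id, genome_b$genome_id,
                                  left_a, right_a),
            genome_a = genome_a$genome_id, genome_b = genome_b$genome_id,
            repl_a = b$repl_a[i], repl_b = b$repl_b[i],
            left_block = b$block_id[i], right_block = b$block_id[j],
            interior_blocks = paste(b$block_id[interior], collapse = ","),
            left_a = left_a, right_a = right_a,
            left_b = left_b, right_b = right_b,
            a_lo = if (empty_a) NA_integer_ else a_lo,
            a_hi = if (empty_a) NA_integer_ else a_hi,
            b_lo = if (empty_b) NA_integer_ else bb_lo,
            b_hi = if (empty_b) NA_integer_ else bb_hi,
            n_cds_a = n_cds_a, n_cds_b = n_cds_b,
            stringsAsFactors = FALSE)
          last_a_hi <- max(last_a_hi, a_hi)
        }
        break  # nearest eligible j only; further j would skip a usable flank
      }
    }
  }
  if (!length(rows)) return(out)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

dense_ordinal <- function(repl, lo) {
  out <- integer(length(repl))
  for (rep in unique(repl)) {
    sel <- which(repl == rep)
    out[sel[order(lo[sel])]] <- seq_along(sel) - 1L
  }
  out
}

empty_islands <- function() {
  data.frame(island_id = character(0), genome_a = character(0),
             genome_b = character(0), repl_a = character(0),
             repl_b = character(0), left_block = character(0),
             right_block = character(0), interior_blocks = character(0),
             left_a = character(0), right_a = character(0),
             left_b = character(0), right_b = character(0),
             a_lo = integer(0), a_hi = integer(0),
             b_lo = integer(0), b_hi = integer(0),
             n_cds_a = integer(0), n_cds_b = integer(0),
             stringsAsFactors = FALSE)
}

island_features <- function(island, genome, side = c("a", "b")) {
  side <- match.arg(side)
  lo <- island[[paste0(side, "_lo")]]; hi <- island[[paste0(side, "_hi")]]
  repl <- island[[paste0("repl_", side)]]
  f <- genome$features
  if (is.na(lo)) return(f[0, , drop = FALSE])
  f[f$replicon_id == repl & !is.na(f$rank) & f$rank >= lo & f$rank <= hi, ,
    drop = FALSE]
}

#' Measure a genomic island
#'
#' Computes the island's scoring criteria for both genomes: CDS counts,
#' number of CDSs without an ortholog anywhere in the partner genome, number
#' of CDSs with at least one paralog in their own genome, tRNA presence
#' within the island or within `trna_vicinity_cds` ranks of either boundary,
#' and the GC difference (percentage points) between the island's contiguous
#' nucleotide span and its replicon.
#'
#' @param island A one-row island data frame (from [detect_breaks()]).
#' @param genome_a,genome_b The two `genome_record`s.
#' @param orthologs The pair's `ortholog_map`.
#' @param paralogs_a,paralogs_b Paralog sets from [detect_paralogs()].
#' @param config A [pipeline_config()].
#' @return One-row data frame of metrics.
#' @export
measure_island <- function(island, genome_a, genome_b, orthologs,
                           paralogs_a = list(), paralogs_b = list(),
                           config = pipeline_config()) {
  pairs <- if (inherits(orthologs, "ortholog_map")) orthologs$pairs else orthologs
  side_metrics <- function(genome, side, mapped, paralogs) {
    f <- island_features(island, genome, side)
    cds <- f[f$kind == "CDS", , drop = FALSE]
    lo <- island[[paste0(side, "_lo")]]; hi <- island[[paste0(side, "_hi")]]
    repl <- island[[paste0("repl_", side)]]
    if (is.na(lo)) {
      trna <- FALSE
    } else {
      v <- config$trna_vicinity_cds
      ft <- genome$features
      trna <- any(ft$replicon_id == repl & !is.na(ft$rank) & ft$kind == "tRNA" &
                  ft$rank >= lo - v & ft$rank <= hi + v)
    }
    delta_gc <- NA_real_
    if (nrow(f)) {
      span_gc <- gc_fraction_ranges(genome$seqs[[repl]],
                                    min(f$start), max(f$end))
      repl_gc <- genome$replicons$gc_fraction[
        genome$replicons$replicon_id == repl]
      delta_gc <- 100 * (span_gc - repl_gc)
    }
    list(n_cds = nrow(cds),
         n_no_ortholog = sum(!(cds$feature_id %in% mapped)),
         n_paralog = sum(vapply(cds$feature_id, function(id) {
           length(paralogs[[id]]) > 0
         }, logical(1))),
         trna = trna, delta_gc = delta_gc)
  }
  ma <- side_metrics(genome_a, "a", pairs$feature_a, paralogs_a)
  mb <- side_metrics(genome_b, "b", pairs$feature_b, paralogs_b)
  data.frame(island_id = island$island_id,
             n_cds_a = ma$n_cds, n_cds_b = mb$n_cds,
             n_no_ortholog_a = ma$n_no_ortholog,
             n_no_ortholog_b = mb$n_no_ortholog,
             n_paralog_a = ma$n_paralog, n_paralog_b = mb$n_paralog,
             trna_a = ma$trna, trna_b = mb$trna,
             delta_gc_a = ma$delta_gc, delta_gc_b = mb$delta_gc,
             stringsAsFactors = FALSE)
}

#' Keyword annotation of an island
#'
#' Case-insensitive substring match of the configured mobility and interest
#' keywords against the product annotation of every island gene.
#'
#' @inheritParams measure_island
#' @return Data frame `feature_id`, `genome_id`, `class`
#'   (mobility/interest), `keyword`; zero rows when nothing matches.
#' @export
annotate_keywords <- function(island, genome_a, genome_b,
                              config = pipeline_config()) {
  scan <- function(genome, side) {
    f <- island_features(island, genome, side)
    if (!nrow(f)) return(NULL)
    hits <- list()
    for (class in c("mobility", "interest")) {
      kws <- config[[paste0(class, "_keywords")]]
      for (kw in kws) {
        m <- grepl(kw, f$product, ignore.case = TRUE, fixed = FALSE)
        if (any(m)) {
          hits[[length(hits) + 1L]] <- data.frame(
            feature_id = f$feature_id[m], genome_id = genome$genome_id,
            class = class, keyword = kw, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(hits)) do.call(rbind, hits) else NULL
  }
  out <- rbind(scan(genome_a, "a"), scan(genome_b, "b"))
  if (is.null(out)) {
    out <- data.frame(feature_id = character(0), genome_id = character(0),
                      class = character(0), keyword = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

keyword_tags <- function(kw_df) {
  if (!nrow(kw_df)) return("")
  paste(sort(unique(paste0(kw_df$class, ":", kw_df$keyword))), collapse = ";")
}

#' Call and measure all islands of a genome pair
#'
#' Runs [detect_breaks()], [measure_island()] and [annotate_keywords()] and
#' returns one table with all metrics.
#'
#' @inheritParams detect_breaks
#' @inheritParams measure_island
#' @return Island data frame with metric and `keywords` columns.
#' @export
call_islands <- function(blocks_obj, genome_a, genome_b, orthologs,
                         paralogs_a = list(), paralogs_b = list(),
                         config = pipeline_config()) {
  isl <- detect_breaks(blocks_obj, genome_a, genome_b, config)
  if (!nrow(isl)) {
    m <- cbind(empty_islands(),
               data.frame(n_no_ortholog_a = integer(0),
                          n_no_ortholog_b = integer(0),
                          n_paralog_a = integer(0), n_paralog_b = integer(0),
                          trna_a = logical(0), trna_b = logical(0),
                          delta_gc_a = numeric(0), delta_gc_b = numeric(0),
                          keywords = character(0)))
    return(m)
  }
  mets <- do.call(rbind, lapply(seq_len(nrow(isl)), function(i) {
    measure_island(isl[i, , drop = FALSE], genome_a, genome_b, orthologs,
                   paralogs_a, paralogs_b, config)
  }))
  kw <- vapply(seq_len(nrow(isl)), function(i) {
    keyword_tags(annotate_keywords(isl[i, , drop = FALSE], genome_a, genome_b,
                                   config))
  }, character(1))
  stopifnot(all(mets$island_id == isl$island_id),
            all(mets$n_cds_a == isl$n_cds_a))
  cbind(isl, mets[, setdiff(names(mets), c("island_id", "n_cds_a", "n_cds_b")),
                  drop = FALSE],
        data.frame(keywords = kw, stringsAsFactors = FALSE))
}

#' Filter islands by minimum CDS count
#'
#' Retains islands whose larger side has at least `min_cds` CDSs; an island
#' whose own side has 0-2 CDSs is retained when the partner side passes.
#'
#' @param islands Island data frame.
#' @param min_cds Minimum CDS count, at least 3.
#' @return The filtered data frame.
#' @export
filter_islands <- function(islands, min_cds = 3L) {
  if (min_cds < 3) stop("min_cds must be at least 3")
  islands[pmax(islands$n_cds_a, islands$n_cds_b) >= min_cds, , drop = FALSE]
}

rankable_metrics <- c("n_cds_a", "n_cds_b", "n_no_ortholog_a",
                      "n_no_ortholog_b", "n_paralog_a", "n_paralog_b",
                      "trna_a", "trna_b", "delta_gc_a", "delta_gc_b")

#' Rank islands with user-defined weights
#'
#' Each numeric metric is min-max normalized to `[0, 1]` across the island
#' set (booleans as 0/1, GC differences by absolute value, degenerate
#' normalization yields 0, absent values contribute 0); the rank score is the
#' weighted sum and islands are sorted by descending score, ties broken by
#' island id.
#'
#' @param islands Island data frame with metric columns.
#' @param weights Named numeric vector over a subset of the metric names
#'   (`n_cds_a`, ..., `delta_gc_b`); `NULL` means weight 1 everywhere.
#' @return The data frame with a `rank_score` column, sorted.
#' @export
rank_islands <- function(islands, weights = NULL) {
  if (is.null(weights)) {
    weights <- setNames(rep(1, length(rankable_metrics)), rankable_metrics)
  }
  bad <- setdiff(names(weights), rankable_metrics)
  if (length(bad)) stop("unknown ranking metric(s): ", paste(bad, collapse = ", "))
  if (!nrow(islands)) {
    islands$rank_score <- numeric(0)
    return(islands)
  }
  score <- numeric(nrow(islands))
  for (m in names(weights)) {
    v <- islands[[m]]
    if (is.logical(v)) v <- as.numeric(v)
    if (startsWith(m, "delta_gc")) v <- abs(v)
    v[is.na(v)] <- 0
    rng <- range(v)
    norm <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else
      rep(0, length(v))
    score <- score + weights[[m]] * norm
  }
  islands$rank_score <- score
  islands[order(-islands$rank_score, islands$island_id), , drop = FALSE]
}

#' Gene-order-conservation profile of a genome pair
#'
#' For each genome of the pair, the fraction of CDSs in a sliding window
#' whose neighbor relationship is conserved: a CDS counts as an "adjacent
#' ortholog" when it has an ortholog and the next CDS of its genome has one
#' whose partner is rank-adjacent in the other genome. The window measures
#' `goc_window_frac` of the replicon length (default 3%) and slides by a
#' quarter window; the last CDS of a replicon is excluded from both
#' numerator and denominator; windows without CDSs are omitted.
#'
#' @param orthologs The pair's `ortholog_map` (or pairs data frame).
#' @param genome_a,genome_b The two `genome_record`s.
#' @param config A [pipeline_config()].
#' @return Data frame `genome_id`, `replicon_id`, `window_start_bp`,
#'   `window_center_bp`, `n_cds`, `goc` in `[0, 1]`.
#' @export
goc_profile <- function(orthologs, genome_a, genome_b,
                        config = pipeline_config()) {
  pairs <- if (inherits(orthologs, "ortholog_map")) orthologs$pairs else orthologs
  one_side <- function(gme, partner, own_col, partner_col) {
    part <- setNames(pairs[[partner_col]], pairs[[own_col]])
    prank <- setNames(partner$features$rank, partner$features$feature_id)
    prepl <- setNames(partner$features$replicon_id, partner$features$feature_id)
    out <- list()
    for (ri in seq_len(nrow(gme$replicons))) {
      repl <- gme$replicons$replicon_id[ri]
      len <- gme$replicons$length_bp[ri]
      f <- gme$features
      cds <- f[f$replicon_id == repl & f$kind == "CDS" & !is.na(f$rank), ,
               drop = FALSE]
      cds <- cds[order(cds$rank), , drop = FALSE]
      n <- nrow(cds)
      if (n < 2) next
      pid <- unname(part[cds$feature_id])
      has <- !is.na(pid)
      nxt <- c(seq_len(n)[-1], NA)
      adjacent <- rep(FALSE, n)
      for (k in seq_len(n - 1L)) {
        if (has[k] && has[k + 1L] &&
            prepl[[pid[k]]] == prepl[[pid[k + 1L]]] &&
            abs(prank[[pid[k + 1L]]] - prank[[pid[k]]]) == 1L) {
          adjacent[k] <- TRUE
        }
      }
      countable <- seq_len(n - 1L)  # last CDS excluded
      mid <- (cds$start + cds$end) / 2
      w <- max(1, round(config$goc_window_frac * len))
      step <- max(1, round(w / 4))
      starts <- seq(1L, max(1L, len - w + 1L), by = step)
      for (s in starts) {
        inw <- countable[mid[countable] >= s & mid[countable] <= s + w - 1]
        if (!length(inw)) next
        out[[length(out) + 1L]] <- data.frame(
          genome_id = gme$genome_id, replicon_id = repl,
          window_start_bp = s, window_center_bp = s + w / 2,
          n_cds = length(inw),
          goc = sum(adjacent[inw]) / length(inw),
          stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  res <- rbind(one_side(genome_a, genome_b, "feature_a", "feature_b"),
               one_side(genome_b, genome_a, "feature_b", "feature_a"))
  if (is.null(res)) {
    res <- data.frame(genome_id = character(0), replicon_id = character(0),
                      window_start_bp = numeric(0),
                      window_center_bp = numeric(0),
                      n_cds = integer(0), goc = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
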