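# One-to-one orthology per genome pair: best reciprocal hits on the filtered
# tables, with ambiguous (co-best) hits resolved by gene-order context, and
# paralogy from the self-comparison of each proteome.

#' Best hits per query
#'
#' For each query, the subject(s) with maximal bitscore. Bitscores are
#' compared after rounding to one decimal, so near-equal scores are co-best.
#'
#' @param table A filtered `hit_table`.
#' @return Named list: query id -> character vector of co-best subject ids.
#' @export
best_hits <- function(table) {
  stopifnot(inherits(table, "hit_table"))
  h <- table$hits
  if (!nrow(h)) return(structure(list(), names = character(0)))
  sc <- round(h$bitscore, 1)
  mx <- tapply(sc, h$query_id, max)
  keep <- sc == unname(mx[h$query_id])
  out <- split(h$subject_id[keep], h$query_id[keep])
  lapply(out, function(v) sort(unique(v)))
}

#' Unique best-reciprocal-hit ortholog pairs
#'
#' Pair (a, b) is accepted when b is the single best hit of a and a is the
#' single best hit of b. Genes with several co-best partners are deferred to
#' synteny resolution.
#'
#' @param bests_ab,bests_ba Best-hit maps from [best_hits()] in the two
#'   directions.
#' @return Data frame `feature_a`, `feature_b`, `stage = "brh_unique"`.
#' @export
brh_unique <- function(bests_ab, bests_ba) {
  a_ids <- names(bests_ab)[lengths(bests_ab) == 1L]
  pairs <- data.frame(feature_a = as.character(a_ids),
                      feature_b = as.character(unlist(bests_ab[a_ids],
                                                      use.names = FALSE)),
                      stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    back <- bests_ba[pairs$feature_b]
    ok <- vapply(seq_len(nrow(pairs)), function(i) {
      v <- back[[i]]
      !is.null(v) && length(v) == 1L && v == pairs$feature_a[i]
    }, logical(1))
    pairs <- pairs[ok, , drop = FALSE]
  }
  pairs$stage <- rep("brh_unique", nrow(pairs))
  rownames(pairs) <- NULL
  pairs
}

# Reciprocal co-best pairs that are not in the unique BRH set: these are the
# candidates for synteny resolution.
reciprocal_candidates <- function(bests_ab, bests_ba, seed_pairs) {
  if (!length(bests_ab)) {
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      stringsAsFactors = FALSE))
  }
  all_pairs <- data.frame(
    feature_a = rep(names(bests_ab), lengths(bests_ab)),
    feature_b = unlist(bests_ab, use.names = FALSE),
    stringsAsFactors = FALSE)
  recip <- vapply(seq_len(nrow(all_pairs)), function(i) {
    v <- bests_ba[[all_pairs$feature_b[i]]]
    !is.null(v) && all_pairs$feature_a[i] %in% v
  }, logical(1))
  all_pairs <- all_pairs[recip, , drop = FALSE]
  seed_key <- paste(seed_pairs$feature_a, seed_pairs$feature_b, sep = "\x1f")
  key <- paste(all_pairs$feature_a, all_pairs$feature_b, sep = "\x1f")
  out <- all_pairs[!(key %in% seed_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve co-best hit ambiguities with synteny context
#'
#' Candidate pairs (reciprocal co-best hits that are not unique) are accepted
#' iteratively: a pair (a, b) is anchored when an already-accepted ortholog
#' pair lies within `max_gap + 1` gene ranks of a and, on the partner side,
#' within `max_gap + 1` ranks of b (on the same replicons; either side, so
#' both colinear and inverted neighborhoods anchor). In each pass genes of
#' genome A are scanned in ascending rank order and a candidate is accepted
#' when it is the gene's uniquely nearest anchored option (anchor distance =
#' the larger of the two rank offsets to the nearest anchor) and its partner
#' is still free; passes repeat to a fixpoint, with anchors frozen at each
#' pass start. Genes whose anchored candidates tie at the fixpoint are left
#' unpaired, mirroring the rule that a gene with several surviving best hits
#' gets no ortholog.
#'
#' @param candidates Data frame `feature_a`, `feature_b` of candidate pairs.
#' @param seed_map Data frame of accepted pairs (from [brh_unique()]).
#' @param genome_a,genome_b The two `genome_record`s.
#' @param max_gap Gap tolerance, see [pipeline_config()].
#' @return Data frame of pairs: the seed map plus rows with stage
#'   `"synteny_resolved"`.
#' @export
resolve_ties_by_synteny <- function(candidates, seed_map, genome_a, genome_b,
                                    max_gap = 2L) {
  rank_a <- setNames(genome_a$features$rank, genome_a$features$feature_id)
  rank_b <- setNames(genome_b$features$rank, genome_b$features$feature_id)
  repl_a <- setNames(genome_a$features$replicon_id, genome_a$features$feature_id)
  repl_b <- setNames(genome_b$features$replicon_id, genome_b$features$feature_id)
  g1 <- max_gap + 1L

  accepted <- seed_map[, c("feature_a", "feature_b"), drop = FALSE]
  resolved <- list()
  if (nrow(candidates)) {
    cand <- candidates
    used_a <- accepted$feature_a
    used_b <- accepted$feature_b
    # candidates involving genes already uniquely paired cannot fire
    cand <- cand[!(cand$feature_a %in% used_a) & !(cand$feature_b %in% used_b), ,
                 drop = FALSE]
    repeat {
      if (!nrow(cand)) break
      acc_ra <- unname(rank_a[accepted$feature_a])
      acc_rb <- unname(rank_b[accepted$feature_b])
      acc_pa <- unname(repl_a[accepted$feature_a])
      acc_pb <- unname(repl_b[accepted$feature_b])
      anchor_dist <- function(a, b) {
        da <- abs(acc_ra - rank_a[[a]])
        db <- abs(acc_rb - rank_b[[b]])
        ok <- da > 0 & da <= g1 & db > 0 & db <= g1 &
          acc_pa == repl_a[[a]] & acc_pb == repl_b[[b]]
        if (!any(ok)) return(Inf)
        min(pmax(da[ok], db[ok]))
      }
      changed <- FALSE
      for (a in unique(cand$feature_a[order(rank_a[cand$feature_a])])) {
        bs <- cand$feature_b[cand$feature_a == a]
        if (!length(bs)) next
        d <- vapply(bs, anchor_dist, numeric(1), a = a)
        ok <- is.finite(d) & d == min(d)
        if (sum(ok) == 1L) {
          b <- bs[ok]
          accepted <- rbind(accepted,
                            data.frame(feature_a = a, feature_b = b,
                                       stringsAsFactors = FALSE))
          resolved[[length(resolved) + 1L]] <- c(a, b)
          cand <- cand[cand$feature_a != a & cand$feature_b != b, , drop = FALSE]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  res <- if (length(resolved)) {
    m <- do.call(rbind, resolved)
    data.frame(feature_a = m[, 1], feature_b = m[, 2],
               stage = "synteny_resolved", stringsAsFactors = FALSE)
  } else {
    data.frame(feature_a = character(0), feature_b = character(0),
               stage = character(0), stringsAsFactors = FALSE)
  }
  out <- rbind(seed_map[, c("feature_a", "feature_b", "stage")], res)
  out <- out[order(rank_a[out$feature_a]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-to-one ortholog map for a genome pair
#'
#' Convenience wrapper: best hits in both directions, unique best reciprocal
#' hits, then synteny resolution of co-best ambiguities.
#'
#' @param table_ab,table_ba Filtered `hit_table`s in the two directions.
#' @param genome_a,genome_b The two `genome_record`s.
#' @param config A [pipeline_config()].
#' @return An object of class `ortholog_map`: list with `genome_a`,
#'   `genome_b` and `pairs` (data frame `feature_a`, `feature_b`, `stage`).
#' @export
ortholog_map <- function(table_ab, table_ba, genome_a, genome_b,
                         config = pipeline_config()) {
  bests_ab <- best_hits(table_ab)
  bests_ba <- best_hits(table_ba)
  seed <- brh_unique(bests_ab, bests_ba)
  cand <- reciprocal_candidates(bests_ab, bests_ba, seed)
  pairs <- resolve_ties_by_synteny(cand, seed, genome_a, genome_b,
                                   max_gap = config$max_gap)
  stopifnot(!anyDuplicated(pairs$feature_a), !anyDuplicated(pairs$feature_b))
  structure(list(genome_a = genome_a$genome_id, genome_b = genome_b$genome_id,
                 pairs = pairs),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("ortholog_map ", x$genome_a, " <-> ", x$genome_b, ": ", nrow(x$pairs),
      " pair(s) (", sum(x$pairs$stage == "synteny_resolved"),
      " synteny-resolved)\n", sep = "")
  invisible(x)
}

#' Paralog sets from a genome self-comparison
#'
#' Paralogs of a gene are all other genes of the same genome with a retained
#' hit in either direction (symmetrized). Trivial self-hits are dropped.
#'
#' @param self_table The filtered self-pair `hit_table` of a genome.
#' @param config A [pipeline_config()] (unused thresholds are already applied
#'   by [filter_hits()]; kept for interface symmetry).
#' @return Named list: feature id -> character vector of paralog ids. Genes
#'   without paralogs are absent.
#' @export
detect_paralogs <- function(self_table, config = pipeline_config()) {
  stopifnot(inherits(self_table, "hit_table"),
            self_table$genome_a == self_table$genome_b)
  h <- self_table$hits
  h <- h[h$query_id != h$subject_id, , drop = FALSE]
  if (!nrow(h)) return(structure(list(), names = character(0)))
  edges <- unique(rbind(data.frame(a = h$query_id, b = h$subject_id,
                                   stringsAsFactors = FALSE),
                        data.frame(a = h$subject_id, b = h$query_id,
                                   stringsAsFactors = FALSE)))
  out <- lapply(split(edges$b, edges$a), function(v) sort(unique(v)))
  out[order(names(out))]
}
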