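# Acquisition and filtering of the all-vs-all protein comparison.
#
# Hit tables are either read from externally computed 12-column tabular
# alignment files (the de facto standard tabular dialect: query, subject,
# %identity, alignment length, mismatches, gap opens, q.start, q.end,
# s.start, s.end, evalue, bitscore) or computed with the built-in
# Smith-Waterman aligner at desk scale. External tables are authoritative
# when reproducing results obtained with a full search engine; the built-in aligner's E-values are
# approximate (Karlin-Altschul with fixed lambda = 0.267, K = 0.041).

KA_LAMBDA <- 0.267
KA_K <- 0.041

hit_cols <- c("query_id", "subject_id", "identity_pct", "aln_len",
              "mismatches", "gap_opens", "q_start", "q_end",
              "s_start", "s_end", "evalue", "bitscore")

new_hit_table <- function(genome_a, genome_b, hits, provenance) {
  stopifnot(all(hit_cols %in% names(hits)))
  rownames(hits) <- NULL
  structure(list(genome_a = genome_a, genome_b = genome_b,
                 hits = hits[, union(hit_cols, names(hits)), drop = FALSE],
                 provenance = provenance),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat("hit_table ", x$genome_a, " -> ", x$genome_b, ": ", nrow(x$hits),
      " hit(s) [", x$provenance, "]\n", sep = "")
  invisible(x)
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             identity_pct = numeric(0), aln_len = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read a tabular protein hit file
#'
#' Parses the 12-column tab-separated alignment dialect produced by standard
#' all-vs-all protein search tools. Rows whose query or subject id is not
#' among `known_ids` (when given) are dropped with a message.
#'
#' @param path File path. An empty file yields an empty table.
#' @param genome_a,genome_b Genome ids of the query and subject proteomes.
#' @param known_ids Optional character vector of valid feature ids.
#' @return A `hit_table`.
#' @export
read_hit_table <- function(path, genome_a = NA_character_,
                           genome_b = NA_character_, known_ids = NULL) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines) || all(!nzchar(lines))) {
    return(new_hit_table(genome_a, genome_b, empty_hits(), "external_file"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop("hit table dialect error in ", path, " at line ", bad, ": expected ",
         "12 tab-separated columns, found ", nf[bad])
  }
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     identity_pct = as.numeric(m[, 3]),
                     aln_len = as.integer(m[, 4]),
                     mismatches = as.integer(m[, 5]),
                     gap_opens = as.integer(m[, 6]),
                     q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
                     s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
                     evalue = as.numeric(m[, 11]),
                     bitscore = as.numeric(m[, 12]),
                     stringsAsFactors = FALSE)
  if (anyNA(hits$identity_pct) || anyNA(hits$evalue) || anyNA(hits$bitscore)) {
    bad <- which(is.na(hits$identity_pct) | is.na(hits$evalue) |
                 is.na(hits$bitscore))[1]
    stop("hit table dialect error in ", path, " at line ", bad,
         ": non-numeric value in a numeric column")
  }
  if (!is.null(known_ids)) {
    ok <- hits$query_id %in% known_ids & hits$subject_id %in% known_ids
    if (any(!ok)) {
      message("dropping ", sum(!ok), " hit row(s) referencing unknown feature ids")
      hits <- hits[ok, , drop = FALSE]
    }
  }
  new_hit_table(genome_a, genome_b, hits, "external_file")
}

raw_to_bitscore <- function(raw) {
  round((KA_LAMBDA * raw - log(KA_K)) / log(2), 1)
}

raw_to_evalue <- function(raw, db_size) {
  KA_K * db_size * exp(-KA_LAMBDA * raw)
}

check_aa <- function(x, what) {
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYBXZJUO*]", toupper(x))
  if (any(bad)) {
    stop(what, ": non-amino-acid symbols in sequence(s) ",
         paste(utils::head(which(bad), 3), collapse = ", "))
  }
  if (any(!nzchar(x))) stop(what, ": empty sequence")
  toupper(x)
}

#' Align two protein sequences
#'
#' Local alignment under BLOSUM62 with affine gap penalties (open 11,
#' extend 1). The bitscore is Karlin-Altschul scaled and the E-value is the
#' approximation `K * m * n * exp(-lambda * S)` where `m * n` defaults to the
#' product of the two sequence lengths; pass `db_size` (product of total
#' residues in the two proteomes) for proteome-scale statistics.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @param db_size Search-space size `m * n` for the E-value.
#' @return A one-row data frame with the standard hit columns.
#' @export
#' @examples
#' p <- paste(rep("MKTAYIAKQR", 5), collapse = "")
#' align_pair(p, p)$identity_pct
align_pair <- function(seq_a, seq_b, db_size = NULL) {
  seq_a <- check_aa(seq_a, "align_pair")
  seq_b <- check_aa(seq_b, "align_pair")
  if (is.null(db_size)) db_size <- as.numeric(nchar(seq_a)) * nchar(seq_b)
  r <- .sw_align_batch(seq_a, seq_b, blosum62_lookup(), 11L, 1L)
  data.frame(query_id = if (!is.null(names(seq_a))) names(seq_a) else NA_character_,
             subject_id = if (!is.null(names(seq_b))) names(seq_b) else NA_character_,
             identity_pct = ifelse(r$aln_len > 0,
                                   100 * r$nmatch / r$aln_len, 0),
             aln_len = r$aln_len, mismatches = r$mismatches,
             gap_opens = r$gap_opens,
             q_start = r$q_start, q_end = r$q_end,
             s_start = r$s_start, s_end = r$s_end,
             evalue = raw_to_evalue(r$raw_score, db_size),
             bitscore = raw_to_bitscore(r$raw_score),
             raw_score = r$raw_score,
             stringsAsFactors = FALSE)
}

# Candidate pairs sharing enough k-mers; avoids the quadratic alignment of
# unrelated proteins. Orthologs at the identity levels the pipeline retains
# (>40%) share many k-mers; unrelated random proteins share almost none.
kmer_candidates <- function(aa_a, aa_b, k = 4L, self = FALSE) {
  # k-mers integer-encoded in base 26; candidate pairs share at least
  # max(6, 2% of the shorter length) k-mers
  index_of <- function(aa) {
    n <- nchar(aa)
    keys <- lapply(seq_along(aa), function(i) {
      if (n[i] < k) return(integer(0))
      s <- utf8ToInt(aa[[i]]) - 65L
      m <- length(s) - k + 1L
      code <- s[seq_len(m)]
      for (d in 1:(k - 1L)) code <- code * 26L + s[seq_len(m) + d]
      unique(code)
    })
    list(key = unlist(keys), seq = rep.int(seq_along(aa), lengths(keys)))
  }
  ia <- index_of(aa_a)
  ib <- if (self) ia else index_of(aa_b)
  if (!length(ia$key) || !length(ib$key)) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  # bucket both sides by k-mer, cross-join occurrences per shared k-mer
  fa <- split(ia$seq, ia$key)
  fb <- if (self) fa else split(ib$seq, ib$key)
  common <- intersect(names(fa), names(fb))
  if (!length(common)) return(data.frame(i = integer(0), j = integer(0)))
  la <- fa[common]; lb <- fb[common]
  na <- lengths(la); nb <- lengths(lb)
  A <- unlist(la, use.names = FALSE); B <- unlist(lb, use.names = FALSE)
  i_vec <- rep(A, times = rep.int(nb, na))
  off <- rep(cumsum(c(0L, nb[-length(nb)])), na)
  j_vec <- B[sequence(rep.int(nb, na)) + rep(off, rep.int(nb, na))]
  code <- (i_vec - 1) * length(aa_b) + (j_vec - 1)
  ncode <- length(aa_a) * length(aa_b)
  if (ncode <= 2e7) {
    tab <- tabulate(as.integer(code) + 1L, nbins = ncode)
    nz <- which(tab > 0L)
    out <- data.frame(i = as.integer((nz - 1L) %/% length(aa_b)) + 1L,
                      j = as.integer((nz - 1L) %% length(aa_b)) + 1L,
                      shared = tab[nz])
  } else {
    r <- rle(sort(code))
    out <- data.frame(i = as.integer(r$values %/% length(aa_b)) + 1L,
                      j = as.integer(r$values %% length(aa_b)) + 1L,
                      shared = r$lengths)
  }
  min_len <- pmin(nchar(aa_a)[out$i], nchar(aa_b)[out$j])
  thr <- pmax(6, round(0.02 * min_len))
  out <- out[out$shared >= thr, , drop = FALSE]
  if (self) out <- out[out$i < out$j, , drop = FALSE]
  out <- out[order(out$i, out$j), , drop = FALSE]
  out[, c("i", "j")]
}

align_candidates <- function(aa_a, aa_b, cand, db_size) {
  if (!nrow(cand)) return(empty_hits())
  r <- .sw_align_batch(unname(aa_a[cand$i]), unname(aa_b[cand$j]),
                       blosum62_lookup(), 11L, 1L)
  data.frame(query_id = names(aa_a)[cand$i], subject_id = names(aa_b)[cand$j],
             identity_pct = ifelse(r$aln_len > 0, 100 * r$nmatch / r$aln_len, 0),
             aln_len = r$aln_len, mismatches = r$mismatches,
             gap_opens = r$gap_opens,
             q_start = r$q_start, q_end = r$q_end,
             s_start = r$s_start, s_end = r$s_end,
             evalue = raw_to_evalue(r$raw_score, db_size),
             bitscore = raw_to_bitscore(r$raw_score),
             stringsAsFactors = FALSE)
}

mirror_hits <- function(hits) {
  data.frame(query_id = hits$subject_id, subject_id = hits$query_id,
             identity_pct = hits$identity_pct, aln_len = hits$aln_len,
             mismatches = hits$mismatches, gap_opens = hits$gap_opens,
             q_start = hits$s_start, q_end = hits$s_end,
             s_start = hits$q_start, s_end = hits$q_end,
             evalue = hits$evalue, bitscore = hits$bitscore,
             stringsAsFactors = FALSE)
}

#' All-vs-all protein comparison for a set of genomes
#'
#' Produces one hit table per ordered genome pair and per genome self-pair
#' (self-pairs feed paralog detection). The `builtin` backend aligns
#' k-mer-prescreened candidate pairs with the built-in Smith-Waterman
#' aligner; the `external_file` backend reads precomputed tabular files named
#' `<A>_vs_<B>.tsv` from `hits_dir`.
#'
#' @param genomes A list of `genome_record` objects.
#' @param backend `"builtin"` or `"external_file"`.
#' @param hits_dir Directory of external hit files (external backend).
#' @param config A [pipeline_config()].
#' @return Named list of `hit_table` objects, keys `"A->B"`.
#' @export
all_vs_all <- function(genomes, backend = c("builtin", "external_file"),
                       hits_dir = NULL, config = pipeline_config()) {
  backend <- match.arg(backend)
  stopifnot(length(genomes) >= 1)
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  names(genomes) <- ids
  out <- list()
  if (backend == "external_file") {
    if (is.null(hits_dir)) stop("external_file backend requires hits_dir")
    for (a in ids) for (b in ids) {
      path <- file.path(hits_dir, paste0(a, "_vs_", b, ".tsv"))
      if (!file.exists(path)) stop("missing external hit file for pair ",
                                   a, " -> ", b, ": ", path)
      known <- c(names(proteome(genomes[[a]])), names(proteome(genomes[[b]])))
      out[[paste0(a, "->", b)]] <- read_hit_table(path, a, b, known_ids = known)
    }
    return(out)
  }
  prot <- lapply(genomes, proteome)
  for (ii in seq_along(ids)) {
    for (jj in ii:length(ids)) {
      a <- ids[ii]; b <- ids[jj]
      if (length(prot[[a]]) * length(prot[[b]]) > config$builtin_budget) {
        stop("builtin aligner budget exceeded for pair ", a, " x ", b,
             "; provide external hit files")
      }
      db <- as.numeric(sum(nchar(prot[[a]]))) * sum(nchar(prot[[b]]))
      if (a == b) {
        cand <- kmer_candidates(prot[[a]], prot[[a]], self = TRUE)
        h <- align_candidates(prot[[a]], prot[[a]], cand, db)
        h <- rbind(h, mirror_hits(h))
        h <- h[order(h$query_id, h$subject_id), , drop = FALSE]
        out[[paste0(a, "->", a)]] <- new_hit_table(a, a, h, "builtin_aligner")
      } else {
        cand <- kmer_candidates(prot[[a]], prot[[b]])
        h <- align_candidates(prot[[a]], prot[[b]], cand, db)
        h <- h[order(h$query_id, h$subject_id), , drop = FALSE]
        out[[paste0(a, "->", b)]] <- new_hit_table(a, b, h, "builtin_aligner")
        hm <- mirror_hits(h)
        hm <- hm[order(hm$query_id, hm$subject_id), , drop = FALSE]
        out[[paste0(b, "->", a)]] <- new_hit_table(b, a, hm, "builtin_aligner")
      }
    }
  }
  out
}

#' Apply the retention filters to a hit table
#'
#' A hit is retained when its E-value is below `evalue_max` (strict), its
#' identity exceeds `identity_min_pct` (strict) and its aligned span covers
#' at least `coverage_min_pct` of the shorter of the two proteins. Coverage
#' is the aligned span (end - start + 1) on the shorter sequence divided by
#' that sequence's length. Only the best-scoring hit per (query, subject)
#' pair is kept, and self-hits of a protein to itself are dropped.
#'
#' @param table A `hit_table`.
#' @param config A [pipeline_config()].
#' @param lengths Named integer vector of protein lengths for every feature
#'   id appearing in the table.
#' @return The filtered `hit_table`.
#' @export
filter_hits <- function(table, config = pipeline_config(), lengths) {
  stopifnot(inherits(table, "hit_table"))
  h <- table$hits
  if (!nrow(h)) return(table)
  miss <- setdiff(unique(c(h$query_id, h$subject_id)), names(lengths))
  if (length(miss)) {
    stop("filter_hits: missing protein lengths for ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  h <- h[h$query_id != h$subject_id, , drop = FALSE]
  if (nrow(h)) {
    # best HSP per (query, subject)
    ord <- order(h$query_id, h$subject_id, -h$bitscore, h$evalue)
    h <- h[ord, , drop = FALSE]
    h <- h[!duplicated(paste(h$query_id, h$subject_id, sep = "\x1f")), ,
           drop = FALSE]
    qlen <- unname(lengths[h$query_id])
    slen <- unname(lengths[h$subject_id])
    span_q <- h$q_end - h$q_start + 1L
    span_s <- h$s_end - h$s_start + 1L
    cov_short <- ifelse(qlen <= slen, 100 * span_q / qlen, 100 * span_s / slen)
    keep <- h$evalue < config$evalue_max &
      h$identity_pct > config$identity_min_pct &
      cov_short >= config$coverage_min_pct
    h <- h[keep, , drop = FALSE]
  }
  new_hit_table(table$genome_a, table$genome_b, h,
                paste0(table$provenance, "+filtered"))
}
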