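#' GC fraction of a nucleotide sequence
#'
#' Fraction (G + C) / (number of unambiguous bases). Ambiguous IUPAC symbols
#' (including N) are excluded from both numerator and denominator.
#'
#' @param x A character vector of nucleotide sequences, a [Biostrings::DNAString]
#'   or a [Biostrings::DNAStringSet].
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
#' @examples
#' gc_fraction(c("GGCC", "ATAT", "GATC"))
gc_fraction <- function(x) {
  if (is(x, "DNAString")) x <- DNAStringSet(x)
  if (is.character(x)) {
    if (any(!nzchar(x))) stop("gc_fraction: empty sequence")
    x <- DNAStringSet(toupper(x))
  }
  freq <- letterFrequency(x, letters = c("A", "C", "G", "T"))
  unamb <- rowSums(freq)
  if (any(unamb == 0)) {
    stop("gc_fraction: sequence with no unambiguous bases (undefined value)")
  }
  unname((freq[, "C"] + freq[, "G"]) / unamb)
}

# GC fraction per (start, end) interval of one sequence, vectorized.
gc_fraction_ranges <- function(seq, start, end) {
  if (length(start) == 0) return(numeric(0))
  v <- Views(seq, start = start, end = end)
  freq <- letterFrequency(v, letters = c("A", "C", "G", "T"))
  unamb <- rowSums(freq)
  ifelse(unamb == 0, NA_real_, (freq[, "C"] + freq[, "G"]) / unamb)
}

# Gene-order ranks: CDS and tRNA features get 0..n-1 per replicon, ordered by
# ascending start (ties: ascending end, then feature_id); other features NA.
assign_ranks <- function(features) {
  features$rank <- NA_integer_
  for (rep in unique(features$replicon_id)) {
    sel <- which(features$replicon_id == rep & features$kind %in% c("CDS", "tRNA"))
    if (!length(sel)) next
    ord <- sel[order(features$start[sel], features$end[sel],
                     features$feature_id[sel])]
    features$rank[ord] <- seq_along(ord) - 1L
  }
  features
}

# Shared constructor: takes raw feature rows + replicon sequences, validates,
# drops CDSs without usable translation, assigns ranks and GC statistics.
new_genome_record <- function(genome_id, features, seqs, topology = NULL,
                              source_path = NA_character_, quiet = FALSE) {
  stopifnot(is.data.frame(features), is(seqs, "DNAStringSet"))
  dup <- unique(features$feature_id[duplicated(features$feature_id)])
  if (length(dup)) {
    stop("duplicate locus tags in genome '", genome_id, "': ",
         paste(dup, collapse = ", "))
  }
  bad <- !(features$replicon_id %in% names(seqs))
  if (any(bad)) {
    stop("features reference unknown replicons: ",
         paste(unique(features$replicon_id[bad]), collapse = ", "))
  }
  lens <- setNames(width(seqs), names(seqs))
  if (any(features$start < 1) || any(features$end < features$start) ||
      any(features$end > lens[features$replicon_id])) {
    off <- features$feature_id[features$start < 1 | features$end < features$start |
                               features$end > lens[features$replicon_id]]
    stop("feature coordinates outside replicon bounds: ",
         paste(off, collapse = ", "))
  }

  drop <- features$kind == "CDS" &
    (is.na(features$translation) | !nzchar(features$translation))
  if (any(drop) && !quiet) {
    message("excluding ", sum(drop), " CDS feature(s) without translation: ",
            paste(utils::head(features$feature_id[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
  }
  features <- features[!drop, , drop = FALSE]
  features <- features[order(match(features$replicon_id, names(seqs)),
                             features$start, features$end,
                             features$feature_id), , drop = FALSE]
  features <- assign_ranks(features)
  features$gc_fraction <- NA_real_
  for (rep in names(seqs)) {
    sel <- which(features$replicon_id == rep)
    if (length(sel)) {
      features$gc_fraction[sel] <-
        gc_fraction_ranges(seqs[[rep]], features$start[sel], features$end[sel])
    }
  }
  rownames(features) <- NULL

  if (is.null(topology)) topology <- setNames(rep("linear", length(seqs)), names(seqs))
  replicons <- data.frame(
    replicon_id = names(seqs),
    length_bp = unname(width(seqs)),
    gc_fraction = gc_fraction(seqs),
    topology = unname(topology[names(seqs)]),
    stringsAsFactors = FALSE)

  structure(list(genome_id = genome_id,
                 replicons = replicons,
                 seqs = seqs,
                 features = features,
                 n_cds = sum(features$kind == "CDS"),
                 n_trna = sum(features$kind == "tRNA"),
                 source_path = source_path),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("genome_record '", x$genome_id, "': ", nrow(x$replicons),
      " replicon(s), ", x$n_cds, " CDS, ", x$n_trna, " tRNA\n", sep = "")
  invisible(x)
}

#' Parse an annotated genome
#'
#' Reads a GenBank flat file, or a GFF3 annotation plus genomic FASTA, into a
#' `genome_record`: per-replicon sequences, a feature table with gene-order
#' ranks (CDS and tRNA features only), per-feature GC and protein
#' translations. Pseudo-genes and CDSs without a given or derivable
#' translation are excluded (with a message). Compound (join) locations are
#' collapsed to their outer span; circular replicons are linearized at the
#' annotation origin.
#'
#' @param path Path to the GenBank file, or to the GFF3 file when
#'   `format = "gff3"`.
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta Path to the genomic FASTA (required for `format = "gff3"`).
#' @param genome_id Identifier for the genome; defaults to the file base name.
#' @param quiet Suppress exclusion messages.
#' @return A `genome_record`.
#' @export
parse_genome <- function(path, format = c("genbank", "gff3"), fasta = NULL,
                         genome_id = NULL, quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gbk|gb|gbff|genbank|gff|gff3)$", "",
                     basename(path), ignore.case = TRUE)
  }
  if (format == "genbank") {
    parse_genome_genbank(path, genome_id, quiet = quiet)
  } else {
    if (is.null(fasta)) stop("format = 'gff3' requires a genomic FASTA via 'fasta'")
    parse_genome_gff3(path, fasta, genome_id, quiet = quiet)
  }
}

derive_translation <- function(seq, start, end, strand) {
  span <- subseq(seq, start, end)
  if (strand < 0) span <- reverseComplement(span)
  if (nchar(span) < 6 || nchar(span) %% 3 != 0) return(NA_character_)
  aa <- as.character(suppressWarnings(
    translate(span, genetic.code = getGeneticCode("11"), if.fuzzy.codon = "X")))
  aa <- sub("\\*$", "", aa)
  if (grepl("\\*", aa) || !nzchar(aa)) return(NA_character_)
  aa
}

parse_genome_gff3 <- function(path, fasta, genome_id, quiet = FALSE) {
  seqs <- readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  keep <- md$type %in% c("CDS", "tRNA")
  md <- md[keep, , drop = FALSE]
  if (!nrow(md)) stop("no CDS or tRNA features in ", path)

  get_attr <- function(col, default = NA_character_) {
    if (col %in% names(md)) {
      v <- md[[col]]
      if (is.list(v)) v <- vapply(v, function(e) {
        if (length(e)) as.character(e[[1]]) else NA_character_
      }, character(1))
      as.character(v)
    } else rep(default, nrow(md))
  }
  locus <- get_attr("locus_tag")
  idattr <- get_attr("ID")
  nameattr <- get_attr("Name")
  fid <- ifelse(!is.na(locus) & nzchar(locus), locus,
         ifelse(!is.na(idattr) & nzchar(idattr), idattr, nameattr))
  product <- get_attr("product", "")
  product[is.na(product)] <- ""
  pseudo <- rep(FALSE, nrow(md))
  if ("pseudo" %in% names(md)) pseudo <- !is.na(md$pseudo)

  df <- data.frame(feature_id = fid,
                   replicon_id = as.character(md$seqnames),
                   start = md$start, end = md$end,
                   strand = ifelse(as.character(md$strand) == "-", -1L, 1L),
                   kind = as.character(md$type),
                   product = product,
                   pseudo = pseudo,
                   stringsAsFactors = FALSE)
  # collapse multi-span CDSs (same feature id) to their outer span
  if (anyDuplicated(df$feature_id)) {
    df <- do.call(rbind, lapply(split(df, df$feature_id), function(d) {
      d$start[1] <- min(d$start); d$end[1] <- max(d$end); d[1, , drop = FALSE]
    }))
    df <- df[order(df$replicon_id, df$start), , drop = FALSE]
  }
  df <- df[!df$pseudo, , drop = FALSE]
  df$pseudo <- NULL
  missing_id <- is.na(df$feature_id) | !nzchar(df$feature_id)
  df$feature_id[missing_id] <- sprintf("%s_f%04d", df$replicon_id[missing_id],
                                       which(missing_id))
  df$genome_id <- genome_id
  df$translation <- NA_character_
  cds <- which(df$kind == "CDS")
  for (i in cds) {
    df$translation[i] <- derive_translation(seqs[[df$replicon_id[i]]],
                                            df$start[i], df$end[i], df$strand[i])
  }
  new_genome_record(genome_id, df, seqs, source_path = path, quiet = quiet)
}

#' Write the proteome of a genome as FASTA
#'
#' One record per retained CDS, header = feature id (locus tag), ordered by
#' replicon and gene rank. This is the input expected by external all-vs-all
#' protein comparison tools.
#'
#' @param genome A `genome_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(genome, path) {
  f <- genome$features
  f <- f[f$kind == "CDS", , drop = FALSE]
  f <- f[order(match(f$replicon_id, genome$replicons$replicon_id), f$rank), ,
         drop = FALSE]
  aa <- AAStringSet(setNames(f$translation, f$feature_id))
  writeXStringSet(aa, filepath = path)
  invisible(path)
}

# Proteins of a genome as a named character vector (CDS only, rank order).
proteome <- function(genome) {
  f <- genome$features
  f <- f[f$kind == "CDS", , drop = FALSE]
  f <- f[order(match(f$replicon_id, genome$replicons$replicon_id), f$rank), ,
         drop = FALSE]
  setNames(f$translation, f$feature_id)
}
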