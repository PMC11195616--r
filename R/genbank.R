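# GenBank flat-file reading and writing. Only the subset of the format that
# annotated bacterial genomes use is supported: LOCUS, FEATURES (CDS, tRNA and
# other keys with locus_tag/product/translation/pseudo qualifiers, simple and
# complement/join locations) and ORIGIN. Compound locations collapse to their
# outer span on the recorded strand.

parse_genome_genbank <- function(path, genome_id, quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "//")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1) + 1L)

  feats <- list(); seq_list <- list(); topo <- character(0)
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    rec <- rec[nzchar(trimws(rec)) | seq_along(rec) == 1]
    locus_line <- grep("^LOCUS", rec, value = TRUE)
    if (!length(locus_line)) {
      if (all(!nzchar(trimws(rec)))) next
      stop("malformed GenBank record (no LOCUS line) in ", path,
           " near line ", starts[r])
    }
    toks <- strsplit(trimws(locus_line[1]), "\\s+")[[1]]
    replicon_id <- toks[2]
    topo[replicon_id] <- if ("circular" %in% toks) "circular" else "linear"

    fstart <- grep("^FEATURES", rec)
    ostart <- grep("^ORIGIN", rec)
    if (!length(fstart)) {
      stop("GenBank record '", replicon_id, "' has no FEATURES table")
    }
    fend <- if (length(ostart)) ostart[1] - 1L else length(rec)
    ftab <- rec[(fstart[1] + 1L):fend]
    ftab <- ftab[!grepl("^(BASE COUNT|CONTIG)", ftab)]

    # sequence
    if (length(ostart)) {
      seq_lines <- rec[(ostart[1] + 1L):length(rec)]
      seq_lines <- seq_lines[trimws(seq_lines) != "//"]
      seq_chr <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    } else {
      stop("GenBank record '", replicon_id,
           "' has no ORIGIN sequence; a sequence is required")
    }
    seq_list[[replicon_id]] <- seq_chr

    feats[[replicon_id]] <- parse_genbank_features(ftab, replicon_id, path)
  }

  seqs <- DNAStringSet(unlist(seq_list))
  df <- do.call(rbind, feats)
  if (is.null(df) || !nrow(df)) stop("no features parsed from ", path)
  df$genome_id <- genome_id

  # fill translations for CDSs lacking the qualifier
  need <- which(df$kind == "CDS" & (is.na(df$translation) | !nzchar(df$translation)) &
                !df$pseudo)
  for (i in need) {
    df$translation[i] <- derive_translation(seqs[[df$replicon_id[i]]],
                                            df$start[i], df$end[i], df$strand[i])
  }
  if (any(df$pseudo) && !quiet) {
    message("excluding ", sum(df$pseudo), " pseudo-gene feature(s)")
  }
  df <- df[!df$pseudo, , drop = FALSE]
  df$pseudo <- NULL
  new_genome_record(genome_id, df, seqs,
                    topology = topo, source_path = path, quiet = quiet)
}

parse_genbank_features <- function(ftab, replicon_id, path) {
  if (!length(ftab)) {
    return(data.frame(feature_id = character(0), replicon_id = character(0),
                      start = integer(0), end = integer(0), strand = integer(0),
                      kind = character(0), product = character(0),
                      translation = character(0), pseudo = logical(0),
                      stringsAsFactors = FALSE))
  }
  key <- substr(ftab, 6, 20)
  is_new <- nzchar(trimws(key)) & !grepl("^\\s*/", ftab)
  idx <- cumsum(is_new)
  out <- list()
  for (g in split(seq_along(ftab), idx)) {
    if (idx[g[1]] == 0) next
    kind_raw <- trimws(substr(ftab[g[1]], 6, 20))
    # container/duplicate records: source spans the replicon, gene mirrors
    # its CDS/tRNA (same locus tag)
    if (kind_raw %in% c("source", "gene")) next
    body <- trimws(substr(ftab[g], 22, nchar(ftab[g])))
    # location: lines up to the first qualifier
    qual_at <- which(startsWith(body, "/"))
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(body)
    loc <- paste(body[seq_len(loc_end)], collapse = "")
    pos <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
    if (!length(pos)) {
      stop("unparseable location for a '", kind_raw, "' feature on ",
           replicon_id, " in ", path, ": ", loc)
    }
    pos <- as.numeric(pos)
    strand <- if (grepl("complement", loc)) -1L else 1L

    quals <- list()
    if (length(qual_at)) {
      qidx <- cumsum(startsWith(body, "/")) * (seq_along(body) >= qual_at[1])
      for (q in split(seq_along(body)[qidx > 0], qidx[qidx > 0])) {
        qtxt <- body[q]
        first <- sub("^/", "", qtxt[1])
        if (grepl("=", first)) {
          qname <- sub("=.*$", "", first)
          val <- sub("^[^=]*=", "", first)
          if (length(qtxt) > 1) {
            sep <- if (qname == "translation") "" else " "
            val <- paste(c(val, qtxt[-1]), collapse = sep)
          }
          quals[[qname]] <- gsub("\"", "", val)
        } else {
          quals[[first]] <- TRUE
        }
      }
    }
    kind <- if (kind_raw %in% c("CDS", "tRNA")) kind_raw else "other"
    fid <- quals$locus_tag
    if (is.null(fid)) fid <- quals$protein_id
    if (is.null(fid)) fid <- sprintf("%s_f%05d", replicon_id, min(pos))
    out[[length(out) + 1L]] <- data.frame(
      feature_id = fid, replicon_id = replicon_id,
      start = as.integer(min(pos)), end = as.integer(max(pos)),
      strand = strand, kind = kind,
      product = if (is.null(quals$product)) "" else quals$product,
      translation = if (is.null(quals$translation)) NA_character_
                    else quals$translation,
      pseudo = isTRUE(quals$pseudo) || isTRUE(quals$pseudogene) ||
               is.character(quals$pseudogene),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a genome record as a GenBank flat file
#'
#' Emits one GenBank record per replicon, with CDS/tRNA features carrying
#' locus_tag, product and (for CDSs) translation qualifiers, and the full
#' ORIGIN sequence. Output re-parses with [parse_genome()].
#'
#' @param genome A `genome_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  wrap_qual <- function(text) {
    # wrap qualifier continuation lines at column 80 with 21-space indent
    chunk <- 58L
    starts <- seq(1L, nchar(text), by = chunk)
    vapply(starts, function(s) substr(text, s, min(nchar(text), s + chunk - 1L)),
           character(1))
  }
  for (i in seq_len(nrow(genome$replicons))) {
    rep_id <- genome$replicons$replicon_id[i]
    len <- genome$replicons$length_bp[i]
    topo <- genome$replicons$topology[i]
    writeLines(sprintf("LOCUS       %-16s %10d bp    DNA     %-8s BCT %s",
                       rep_id, len, topo, format(Sys.Date(), "%d-%b-%Y")), con)
    writeLines(sprintf("DEFINITION  %s %s.", genome$genome_id, rep_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", len), con)
    writeLines(sprintf("                     /organism=\"%s\"", genome$genome_id),
               con)
    f <- genome$features[genome$features$replicon_id == rep_id, , drop = FALSE]
    f <- f[order(f$start, f$end), , drop = FALSE]
    for (j in seq_len(nrow(f))) {
      loc <- sprintf("%d..%d", f$start[j], f$end[j])
      if (f$strand[j] < 0) loc <- sprintf("complement(%s)", loc)
      key <- if (f$kind[j] %in% c("CDS", "tRNA")) f$kind[j] else "misc_feature"
      writeLines(sprintf("     %-15s %s", key, loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         f$feature_id[j]), con)
      if (nzchar(f$product[j])) {
        writeLines(paste0("                     ",
                          wrap_qual(sprintf("/product=\"%s\"", f$product[j]))),
                   con)
      }
      if (f$kind[j] == "CDS" && !is.na(f$translation[j])) {
        writeLines(paste0("                     ",
                          wrap_qual(sprintf("/translation=\"%s\"",
                                            f$translation[j]))), con)
      }
    }
    writeLines("ORIGIN", con)
    s <- as.character(genome$seqs[[rep_id]])
    pos <- seq(1L, nchar(s), by = 60L)
    for (p in pos) {
      blocks <- vapply(seq(p, min(p + 59L, nchar(s)), by = 10L), function(b) {
        substr(s, b, min(b + 9L, nchar(s)))
      }, character(1))
      writeLines(sprintf("%9d %s", p, tolower(paste(blocks, collapse = " "))),
                 con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write a genome record as GFF3 plus genomic FASTA
#'
#' @param genome A `genome_record`.
#' @param gff_path,fasta_path Output paths.
#' @return `gff_path`, invisibly.
#' @export
write_gff3 <- function(genome, gff_path, fasta_path) {
  con <- file(gff_path, open = "wt")
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genome$replicons))) {
    writeLines(sprintf("##sequence-region %s 1 %d",
                       genome$replicons$replicon_id[i],
                       genome$replicons$length_bp[i]), con)
  }
  f <- genome$features
  esc <- function(x) gsub(";", "%3B", gsub("=", "%3D", x))
  for (j in seq_len(nrow(f))) {
    attrs <- sprintf("ID=%s;locus_tag=%s", f$feature_id[j], f$feature_id[j])
    if (nzchar(f$product[j])) {
      attrs <- paste0(attrs, ";product=", esc(f$product[j]))
    }
    type <- if (f$kind[j] %in% c("CDS", "tRNA")) f$kind[j] else "region"
    writeLines(paste(f$replicon_id[j], "islandbreak", type,
                     f$start[j], f$end[j], ".",
                     if (f$strand[j] < 0) "-" else "+",
                     if (type == "CDS") "0" else ".",
                     attrs, sep = "\t"), con)
  }
  close(con)
  writeXStringSet(genome$seqs, filepath = fasta_path)
  invisible(gff_path)
}
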