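# Seeded simulator: annotated genome pairs with a shared, colinear backbone
# of ortholog genes (mutated to a target protein identity) and implanted
# islands of foreign genes, with full truth tables. Island proteins are drawn
# independently of the backbone so they produce no retained hits at the
# pipeline's thresholds; nucleotide sequences are synthesized with codon
# choices steered to a GC target, so island GC shifts are controlled.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

# one low-GC and one high-GC codon per residue (bacterial/standard code 11)
CODON_LO <- c(A = "GCA", R = "AGA", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATA",
              L = "TTA", K = "AAA", M = "ATG", F = "TTT", P = "CCA",
              S = "TCA", T = "ACA", V = "GTA", W = "TGG", Y = "TAT")
CODON_HI <- c(A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC",
              Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
              L = "CTC", K = "AAG", M = "ATG", F = "TTC", P = "CCG",
              S = "AGC", T = "ACC", V = "GTC", W = "TGG", Y = "TAC")
GC_LO <- c(A = 2, R = 1, N = 0, D = 1, C = 1, Q = 1, E = 1, G = 2, H = 1,
           I = 0, L = 0, K = 0, M = 1, F = 0, P = 2, S = 1, T = 1, V = 1,
           W = 2, Y = 0)
GC_HI <- c(A = 3, R = 3, N = 1, D = 2, C = 2, Q = 2, E = 2, G = 3, H = 2,
           I = 1, L = 2, K = 1, M = 1, F = 1, P = 3, S = 2, T = 2, V = 2,
           W = 2, Y = 1)

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Simulation specification
#'
#' Describes a simulated genome pair: a colinear backbone of `n_genes`
#' ortholog genes at `divergence` percent protein identity, plus implanted
#' islands of foreign genes.
#'
#' @param n_genes Number of backbone (ortholog) genes.
#' @param mean_gene_len_bp Mean gene length in bp (lengths vary +-30%).
#' @param intergenic_len_bp Intergenic spacer length in bp.
#' @param backbone_gc Target GC fraction of the backbone (the codon scheme
#'   can realize roughly 0.30-0.63 for coding sequence).
#' @param islands List of island descriptors, each a list/row with
#'   `insert_after_rank` (0-based backbone gene index after which the island
#'   is inserted), `n_genes`, `gc_shift` (percentage points relative to
#'   `backbone_gc`), `with_trna`, `with_mobility_gene`, `target_genome`
#'   (`"A"` or `"B"`).
#' @param divergence Target protein identity (%) of backbone ortholog pairs.
#' @param inversions Optional list of `c(start_rank, n_genes)` backbone
#'   segments inverted in genome B.
#' @param seed Random seed; the whole simulation is deterministic given the
#'   spec.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 200L, mean_gene_len_bp = 900L,
                     intergenic_len_bp = 150L, backbone_gc = 0.55,
                     islands = list(), divergence = 80,
                     inversions = NULL, seed = 1L) {
  stopifnot(n_genes >= 10, mean_gene_len_bp >= 90, intergenic_len_bp >= 0,
            backbone_gc > 0, backbone_gc < 1,
            divergence > 0, divergence <= 100)
  islands <- lapply(islands, function(isl) {
    isl <- as.list(isl)
    defaults <- list(gc_shift = 0, with_trna = FALSE,
                     with_mobility_gene = FALSE, target_genome = "A")
    for (nm in names(defaults)) {
      if (is.null(isl[[nm]])) isl[[nm]] <- defaults[[nm]]
    }
    stopifnot(!is.null(isl$insert_after_rank), !is.null(isl$n_genes),
              isl$target_genome %in% c("A", "B"),
              isl$insert_after_rank >= 1,
              isl$insert_after_rank <= n_genes - 3,
              isl$n_genes >= 1)
    isl
  })
  for (tg in c("A", "B")) {
    pos <- sort(vapply(Filter(function(i) i$target_genome == tg, islands),
                       function(i) i$insert_after_rank, numeric(1)))
    if (anyDuplicated(pos)) {
      stop("two islands in genome ", tg, " at the same backbone position")
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 mean_gene_len_bp = as.integer(mean_gene_len_bp),
                 intergenic_len_bp = as.integer(intergenic_len_bp),
                 backbone_gc = backbone_gc, islands = islands,
                 divergence = divergence, inversions = inversions,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

#' Mutate a protein to a target identity
#'
#' Substitutes exactly `round((100 - target) / 100 * nchar(seq))` positions,
#' chosen uniformly, never to the original residue.
#'
#' @param seq Amino-acid string.
#' @param target_identity_pct Target identity in (0, 100].
#' @param seed Optional seed for reproducibility.
#' @return The mutated sequence.
#' @export
mutate_protein <- function(seq, target_identity_pct, seed = NULL) {
  stopifnot(target_identity_pct > 0, target_identity_pct <= 100)
  run <- function() {
    n <- nchar(seq)
    k <- round((100 - target_identity_pct) / 100 * n)
    if (k == 0) return(seq)
    pos <- sample.int(n, k)
    chars <- strsplit(seq, "")[[1]]
    repl <- sample(AA20, k, replace = TRUE)
    coll <- repl == chars[pos]
    while (any(coll)) {  # never substitute to the original residue
      repl[coll] <- sample(AA20, sum(coll), replace = TRUE)
      coll <- repl == chars[pos]
    }
    chars[pos] <- repl
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# reverse-translate steering codon choice toward a GC target; exact to
# within one base per sequence inside the feasible band.
reverse_translate <- function(protein, target_gc) {
  aa <- strsplit(protein, "")[[1]]
  lo <- GC_LO[aa]; hi <- GC_HI[aa]
  n_bases <- 3L * (length(aa) + 1L)
  target <- round(target_gc * n_bases)
  gain <- hi - lo  # 0, 1 or 2 GC bases gained by the high-GC codon
  deficit <- target - sum(lo)
  use_hi <- rep(FALSE, length(aa))
  stop_codon <- "TAA"
  if (deficit > 0) {
    idx2 <- which(gain == 2L); idx1 <- which(gain == 1L)
    k2 <- min(length(idx2), deficit %/% 2L)
    if (k2 > 0) use_hi[idx2[seq_len(k2)]] <- TRUE
    rem <- deficit - 2L * k2
    k1 <- min(length(idx1), rem)
    if (k1 > 0) use_hi[idx1[seq_len(k1)]] <- TRUE
    rem <- rem - k1
    if (rem > 0) {
      stop_codon <- "TAG"  # absorb the last +-1 in the stop codon
      rem <- rem - 1L
    }
    if (rem > 0 && k2 < length(idx2)) use_hi[idx2[k2 + 1L]] <- TRUE
  }
  codons <- ifelse(use_hi, CODON_HI[aa], CODON_LO[aa])
  paste0(paste(codons, collapse = ""), stop_codon)
}

revcomp_chr <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s))))
}

random_dna <- function(len, gc) {
  if (len <= 0) return("")
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate an annotated genome pair with implanted islands
#'
#' Generates genomes A and B from a shared ancestor proteome: backbone genes
#' are one-to-one orthologs mutated to the spec's divergence, islands are
#' inserted into the target genome with independently drawn proteins and a
#' GC shift, optionally led by a tRNA gene and a mobility-annotated gene.
#'
#' @param spec A [sim_spec()].
#' @return List with `genome_a`, `genome_b` (`genome_record`s), `truth`
#'   (list: `orthologs` data frame, `islands` data frame with rank
#'   intervals, `paralogs`), and `spec`.
#' @export
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    aa_len <- pmax(30L, round(spec$mean_gene_len_bp / 3 *
                              stats::runif(n, 0.7, 1.3)))
    anc <- vapply(aa_len, random_protein, character(1))
    prot_a <- anc
    prot_b <- vapply(anc, function(p) {
      mutate_protein(p, spec$divergence)
    }, character(1), USE.NAMES = FALSE)

    # backbone order in B: apply inversions (reverse gene order and strand)
    order_b <- seq_len(n)
    strand <- sample(c(1L, -1L), n, replace = TRUE)
    strand_b <- strand
    for (inv in spec$inversions) {
      ix <- (inv[1] + 1L):(inv[1] + inv[2])
      order_b[ix] <- rev(order_b[ix])
      strand_b[ix] <- -strand_b[ix]
    }

    isl_proteins <- lapply(spec$islands, function(isl) {
      vapply(pmax(30L, round(spec$mean_gene_len_bp / 3 *
                             stats::runif(isl$n_genes, 0.7, 1.3))),
             random_protein, character(1))
    })

    build <- function(which_genome) {
      prot <- if (which_genome == "A") prot_a else prot_b
      ordv <- if (which_genome == "A") seq_len(n) else order_b
      strv <- if (which_genome == "A") strand else strand_b
      isls <- which(vapply(spec$islands, function(i) i$target_genome,
                           character(1)) == which_genome)
      ins_after <- vapply(spec$islands[isls], function(i) i$insert_after_rank,
                          numeric(1))
      # order of emission: backbone genes, islands inserted after position k
      elements <- list()
      for (k in seq_len(n)) {
        bb <- ordv[k]
        elements[[length(elements) + 1L]] <-
          list(type = "backbone", idx = bb, strand = strv[k])
        hit <- isls[ins_after == k - 1L]  # insert_after_rank is 0-based
        for (ii in hit) {
          isl <- spec$islands[[ii]]
          if (isTRUE(isl$with_trna)) {
            elements[[length(elements) + 1L]] <-
              list(type = "trna", island = ii)
          }
          for (gi in seq_along(isl_proteins[[ii]])) {
            elements[[length(elements) + 1L]] <-
              list(type = "island", island = ii, idx = gi,
                   strand = sample(c(1L, -1L), 1),
                   mobility = isTRUE(isl$with_mobility_gene) && gi == 1L)
          }
        }
      }
      gid <- paste0("sim", which_genome)
      repl <- paste0(gid, "_chr")
      ne <- length(elements)
      chunks <- character(2L * ne + 1L)
      v_start <- integer(ne); v_end <- integer(ne); v_strand <- integer(ne)
      v_kind <- character(ne); v_product <- character(ne)
      v_transl <- rep(NA_character_, ne)
      v_island <- rep(NA_integer_, ne); v_bb <- rep(NA_integer_, ne)
      pos <- 0L
      for (k in seq_len(ne)) {
        e <- elements[[k]]
        ig_gc <- if (e$type %in% c("island", "trna")) {
          spec$backbone_gc + spec$islands[[e$island]]$gc_shift / 100
        } else spec$backbone_gc
        ig_gc <- min(0.99, max(0.01, ig_gc))
        spacer <- random_dna(spec$intergenic_len_bp, ig_gc)
        chunks[2L * k - 1L] <- spacer
        pos <- pos + nchar(spacer)
        if (e$type == "trna") {
          dna <- random_dna(76L, ig_gc)
          v_start[k] <- pos + 1L; v_end[k] <- pos + nchar(dna)
          v_strand[k] <- 1L; v_kind[k] <- "tRNA"; v_product[k] <- "tRNA-Ser"
          v_island[k] <- e$island
          chunks[2L * k] <- dna
          pos <- pos + nchar(dna)
          next
        }
        p <- if (e$type == "backbone") prot[e$idx] else
          isl_proteins[[e$island]][e$idx]
        cds_dna <- reverse_translate(p, ig_gc)
        if (e$strand < 0) cds_dna <- revcomp_chr(cds_dna)
        v_start[k] <- pos + 1L; v_end[k] <- pos + nchar(cds_dna)
        v_strand[k] <- e$strand; v_kind[k] <- "CDS"
        v_product[k] <- if (e$type == "backbone") "conserved hypothetical protein"
          else if (isTRUE(e$mobility)) "putative integrase"
          else "hypothetical protein"
        v_transl[k] <- p
        if (e$type == "island") v_island[k] <- e$island else v_bb[k] <- e$idx
        chunks[2L * k] <- cds_dna
        pos <- pos + nchar(cds_dna)
      }
      chunks[2L * ne + 1L] <- random_dna(spec$intergenic_len_bp,
                                         spec$backbone_gc)
      df <- data.frame(feature_id = NA_character_, replicon_id = repl,
                       start = v_start, end = v_end, strand = v_strand,
                       kind = v_kind, product = v_product,
                       translation = v_transl, island = v_island,
                       backbone_idx = v_bb, stringsAsFactors = FALSE)
      df$feature_id <- sprintf("SIM%s_%04d", which_genome, seq_len(nrow(df)))
      df$rank_tmp <- seq_len(nrow(df)) - 1L
      seqs <- DNAStringSet(setNames(paste(chunks, collapse = ""), repl))
      list(df = df, seqs = seqs, gid = gid)
    }

    ga <- build("A"); gb <- build("B")

    mk_record <- function(g) {
      df <- g$df
      feats <- df[, c("feature_id", "replicon_id", "start", "end", "strand",
                      "kind", "product", "translation")]
      feats$genome_id <- g$gid
      new_genome_record(g$gid, feats, g$seqs, quiet = TRUE)
    }
    genome_a <- mk_record(ga)
    genome_b <- mk_record(gb)

    # truth tables
    ia <- ga$df[!is.na(ga$df$backbone_idx), c("feature_id", "backbone_idx")]
    ib <- gb$df[!is.na(gb$df$backbone_idx), c("feature_id", "backbone_idx")]
    orth <- merge(ia, ib, by = "backbone_idx", suffixes = c("_a", "_b"))
    orth <- orth[order(orth$backbone_idx), c("feature_id_a", "feature_id_b")]
    names(orth) <- c("feature_a", "feature_b")
    rownames(orth) <- NULL

    isl_truth <- list()
    for (ii in seq_along(spec$islands)) {
      isl <- spec$islands[[ii]]
      df <- if (isl$target_genome == "A") ga$df else gb$df
      sel <- which(!is.na(df$island) & df$island == ii)
      if (!length(sel)) next
      isl_truth[[length(isl_truth) + 1L]] <- data.frame(
        genome_id = if (isl$target_genome == "A") ga$gid else gb$gid,
        replicon_id = df$replicon_id[sel[1]],
        rank_lo = min(df$rank_tmp[sel]), rank_hi = max(df$rank_tmp[sel]),
        n_cds = sum(df$kind[sel] == "CDS"),
        gc_shift = isl$gc_shift, with_trna = isTRUE(isl$with_trna),
        with_mobility_gene = isTRUE(isl$with_mobility_gene),
        stringsAsFactors = FALSE)
    }
    islands_truth <- if (length(isl_truth)) do.call(rbind, isl_truth) else
      data.frame(genome_id = character(0), replicon_id = character(0),
                 rank_lo = integer(0), rank_hi = integer(0),
                 n_cds = integer(0), gc_shift = numeric(0),
                 with_trna = logical(0), with_mobility_gene = logical(0),
                 stringsAsFactors = FALSE)

    list(genome_a = genome_a, genome_b = genome_b,
         truth = list(orthologs = orth, islands = islands_truth,
                      paralogs = list()),
         spec = spec)
  })
}

#' Write a simulated pair to disk
#'
#' Emits both genomes as GenBank files plus GFF3 + FASTA, and the truth
#' tables as CSV.
#'
#' @param sim Output of [simulate_pair()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
sim_write <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in list(sim$genome_a, sim$genome_b)) {
    write_genbank(g, file.path(dir, paste0(g$genome_id, ".gbk")))
    write_gff3(g, file.path(dir, paste0(g$genome_id, ".gff3")),
               file.path(dir, paste0(g$genome_id, ".fna")))
  }
  utils::write.csv(sim$truth$orthologs,
                   file.path(dir, "truth_orthologs.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$islands,
                   file.path(dir, "truth_islands.csv"), row.names = FALSE)
  invisible(dir)
}
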