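#' Pipeline configuration
#'
#' Bundles every tunable threshold of the island-detection pipeline. The
#' defaults are the standard operating point for closely related genomes: protein hits are
#' retained when the E-value is below `1e-10`, sequence identity is above 40%
#' and the alignment covers at least 40% of the shorter protein; synteny
#' blocks tolerate up to two intervening non-orthologous CDSs; a synteny
#' break is reported when at least one genome contributes three or more CDSs.
#'
#' @param evalue_max Retain hits with `evalue < evalue_max`.
#' @param identity_min_pct Retain hits with `identity_pct > identity_min_pct`.
#' @param coverage_min_pct Retain hits whose aligned span covers at least this
#'   percentage of the shorter of the two proteins.
#' @param max_gap Maximum number of non-orthologous CDS/tRNA ranks allowed
#'   between consecutive ortholog pairs of a synteny block, per genome.
#' @param min_break_cds Minimum CDS count (in at least one genome) for a
#'   synteny break to be reported as a genomic island.
#' @param goc_window_frac Sliding-window length for the gene-order
#'   conservation profile, as a fraction of the replicon length in bp.
#' @param trna_vicinity_cds A tRNA within this many gene ranks of an island
#'   boundary counts as "in the immediate vicinity".
#' @param mobility_keywords,interest_keywords Keyword lists matched
#'   (case-insensitive substrings) against product annotations of island
#'   genes; mobility keywords flag mobile-element machinery, interest
#'   keywords flag biosynthesis/resistance functions.
#' @param rank_weights Optional named numeric vector of default ranking
#'   weights (see [rank_islands()]); `NULL` means equal weight 1 for every
#'   metric.
#' @param random_seed Seed recorded for simulation-driven workflows.
#' @param builtin_budget Maximum product of proteome sizes (number of
#'   proteins in genome A times genome B) accepted by the built-in aligner
#'   backend of [all_vs_all()].
#' @param max_genomes Maximum number of genomes accepted by
#'   [build_database()].
#'
#' @return An object of class `pipeline_config` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config(min_break_cds = 5)
#' cfg$evalue_max
pipeline_config <- function(evalue_max = 1e-10,
                            identity_min_pct = 40,
                            coverage_min_pct = 40,
                            max_gap = 2L,
                            min_break_cds = 3L,
                            goc_window_frac = 0.03,
                            trna_vicinity_cds = 2L,
                            mobility_keywords = c("insertion", "mobile element",
                                                  "integrase", "transposase"),
                            interest_keywords = c("resistance", "synthase",
                                                  "synthetase", "polyketide",
                                                  "nonribosomal"),
                            rank_weights = NULL,
                            random_seed = 1L,
                            builtin_budget = 1e7,
                            max_genomes = 20L) {
  stopifnot(evalue_max > 0, identity_min_pct > 0, coverage_min_pct > 0,
            max_gap >= 0, min_break_cds > 0,
            goc_window_frac > 0, goc_window_frac < 1,
            trna_vicinity_cds >= 0, builtin_budget > 0, max_genomes >= 2)
  cfg <- list(evalue_max = evalue_max,
              identity_min_pct = identity_min_pct,
              coverage_min_pct = coverage_min_pct,
              max_gap = as.integer(max_gap),
              min_break_cds = as.integer(min_break_cds),
              goc_window_frac = goc_window_frac,
              trna_vicinity_cds = as.integer(trna_vicinity_cds),
              mobility_keywords = mobility_keywords,
              interest_keywords = interest_keywords,
              rank_weights = rank_weights,
              random_seed = as.integer(random_seed),
              builtin_budget = builtin_budget,
              max_genomes = as.integer(max_genomes))
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  flat <- vapply(config, function(x) paste(format(x, digits = 15), collapse = ","),
                 character(1))
  stable_id(paste(names(flat), flat, sep = "=", collapse = ";"), n = 8)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("islandbreak pipeline configuration [", config_hash(x), "]\n", sep = "")
  for (nm in names(x)) {
    cat("  ", format(nm, width = 18), ": ",
        paste(format(x[[nm]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

as_pipeline_config <- function(config) {
  if (is.null(config)) return(pipeline_config())
  if (inherits(config, "pipeline_config")) return(config)
  do.call(pipeline_config, config)
}
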