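#' Configuration for the synthetic screen generator
#'
#' Bundles every tunable of the synthetic-data module: genome geometry, gene
#' structure, insertion counts, read simulation, and the restriction enzyme
#' used for in-silico splinkerette digestion. Defaults emulate the study
#' conditions of a piggyBac promoter-trap screen read out by 50-nt paired-end
#' RNA-seq: roughly half the genes carry a 5'-UTR intron, and the distance
#' from transcription start to the ORF +1 of those genes spans 183-44882 bp.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length length of each scaffold (bp).
#' @param n_genes number of genes placed across scaffolds.
#' @param frac_utr_intron fraction of genes carrying a 5'-UTR intron; the
#'   realised count is exactly `round(frac_utr_intron * n_genes)`.
#' @param intron_length_range low/high bounds (bp) for coding-intron lengths.
#' @param utr_intron_5p_distance_range low/high bounds (bp) for the distance
#'   from transcription start to the ORF +1 in genes with a 5'-UTR intron;
#'   the 5'-UTR intron absorbs most of this span.
#' @param n_insertions_per_construct planted insertions per construct
#'   (IRES and non-IRES), so total planted is twice this.
#' @param read_length read length in nt (paired-end).
#' @param n_read_pairs total read pairs emitted per simulated library.
#' @param chimera_fraction fraction of pairs that are reporter-fusion
#'   chimeras at planted splice acceptors.
#' @param enzyme restriction enzyme for splinkerette fragments:
#'   `"BstYI"` (RGATCY) or `"BglII"` (AGATCT).
#' @param error_rate per-base substitution rate for simulated reads.
#'   Default 0: the downstream classifier is exact-match.
#' @return An object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(seed = 1, n_genes = 8, scaffold_length = 6e4)
#' @export
synthetic_config <- function(seed = 1L,
                             n_scaffolds = 4L,
                             scaffold_length = 200000L,
                             n_genes = 24L,
                             frac_utr_intron = 0.5,
                             intron_length_range = c(80L, 3000L),
                             utr_intron_5p_distance_range = c(183L, 44882L),
                             n_insertions_per_construct = 20L,
                             read_length = 50L,
                             n_read_pairs = 4000L,
                             chimera_fraction = 0.05,
                             enzyme = c("BstYI", "BglII"),
                             error_rate = 0) {
  enzyme <- match.arg(enzyme)
  cfg <- list(
    seed = as.integer(seed),
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_length = as.integer(scaffold_length),
    n_genes = as.integer(n_genes),
    frac_utr_intron = as.numeric(frac_utr_intron),
    intron_length_range = as.integer(intron_length_range),
    utr_intron_5p_distance_range = as.integer(utr_intron_5p_distance_range),
    n_insertions_per_construct = as.integer(n_insertions_per_construct),
    read_length = as.integer(read_length),
    n_read_pairs = as.integer(n_read_pairs),
    chimera_fraction = as.numeric(chimera_fraction),
    enzyme = enzyme,
    error_rate = as.numeric(error_rate)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c("n_scaffolds", "scaffold_length", "n_genes",
              "n_insertions_per_construct", "read_length", "n_read_pairs")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("'%s' must be a non-negative count", f))
    }
  }
  for (f in c("frac_utr_intron", "chimera_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("'%s' must lie in [0, 1]", f))
    }
  }
  for (f in c("intron_length_range", "utr_intron_5p_distance_range")) {
    r <- cfg[[f]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1) {
      stop(sprintf("'%s' must be an ordered pair low <= high", f))
    }
  }
  if (cfg$error_rate < 0 || cfg$error_rate > 1) stop("'error_rate' must lie in [0, 1]")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:\n")
  cat(sprintf("  genome: %d scaffold(s) x %d bp, %d genes (%.0f%% with 5'-UTR intron)\n",
              x$n_scaffolds, x$scaffold_length, x$n_genes, 100 * x$frac_utr_intron))
  cat(sprintf("  insertions: %d per construct; reads: %d pairs x %d nt, chimera fraction %.3f\n",
              x$n_insertions_per_construct, x$n_read_pairs, x$read_length,
              x$chimera_fraction))
  cat(sprintf("  splinkerette enzyme: %s; seed: %d\n", x$enzyme, x$seed))
  invisible(x)
}
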