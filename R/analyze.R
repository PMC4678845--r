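#' Run the full amplicon bisulfite-seq analysis on a set of reads
#'
#' The standard workflow in one call: align every read against the
#' in-silico converted reference ([align_bisulfite()]), drop reads below the
#' collapsed-identity threshold (the "high-quality read" filter; discarded
#' reads are counted, not hidden), pile up the surviving original bases
#' ([build_pileup()]), and derive the per-CpG methylation report, the
#' non-CpG conversion efficiency and the error-rate report with its
#' exclusion rules.
#'
#' @param reads a `DNAStringSet` or character vector of reads.
#' @param ref a [insilico_convert()] result (or a [methylated_template] /
#'   sequence, converted on the fly).
#' @param total_cycles total number of PCR cycles behind the library, used
#'   for the per-cycle error rate.
#' @param min_identity minimum collapsed identity for a read to be kept.
#' @param min_depth minimum informative depth for an unflagged CpG fraction.
#' @param band aligner band half-width.
#' @return An object of class `bs_analysis`: `methylation`
#'   ([cpg_methylation()] report), `errors` ([error_rates()] report),
#'   `pileup`, and the read accounting `n_reads`, `n_aligned`,
#'   `n_filtered`.
#' @examples
#' ref <- insilico_convert("ACGTACCTGATTGA")
#' analyze_reads(c("ATGTATTTGATTGA", "ACGTATTTGATTGA"), ref, total_cycles = 70)
#' @export
analyze_reads <- function(reads, ref, total_cycles = 70L,
                          min_identity = 0.9, min_depth = 10L, band = 16L) {
  if (!inherits(ref, "converted_reference")) ref <- insilico_convert(ref)
  reads <- as.character(reads)
  n_reads <- length(reads)
  alns <- list()
  n_filtered <- 0L
  for (rd in reads) {
    a <- align_bisulfite(rd, ref, band = band)
    if (a$identity >= min_identity) alns[[length(alns) + 1L]] <- a
    else n_filtered <- n_filtered + 1L
  }
  pile <- build_pileup(alns, ref)
  structure(list(methylation = cpg_methylation(pile, min_depth = min_depth),
                 errors = if (sum(pile$depth) > 0)
                   error_rates(pile, total_cycles) else NULL,
                 pileup = pile,
                 n_reads = n_reads,
                 n_aligned = length(alns),
                 n_filtered = n_filtered),
            class = "bs_analysis")
}

#' @export
print.bs_analysis <- function(x, ...) {
  cat(sprintf("bs_analysis: %d reads, %d aligned, %d below identity filter\n",
              x$n_reads, x$n_aligned, x$n_filtered))
  if (!is.null(x$errors)) print(x$errors)
  print(x$methylation)
  invisible(x)
}
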