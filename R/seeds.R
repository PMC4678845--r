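#' Derive a reproducible substream seed from a master seed
#'
#' A single master seed governs an entire simulation run, but the individual
#' stages (template construction, bisulfite treatment, PCR, read generation,
#' analysis) each draw from their own named substream so that, e.g., changing
#' the read-sampling seed leaves the treatment output byte-identical.
#'
#' @param master integer master seed.
#' @param stream one of `"template"`, `"treatment"`, `"pcr"`, `"reads"`,
#'   `"analysis"`.
#' @return An integer seed, always below 2^31, deterministic in
#'   `(master, stream)`.
#' @examples
#' substream_seed(1, "treatment")
#' @export
substream_seed <- function(master, stream = c("template", "treatment",
                                              "pcr", "reads", "analysis")) {
  stream <- match.arg(stream)
  offs <- c(template = 11L, treatment = 29L, pcr = 47L,
            reads = 83L, analysis = 131L)
  master <- as.integer(master)
  if (is.na(master)) stop("master seed must be an integer")
  base <- master %% 16381L
  (base * 131071L + offs[[stream]]) %% 2147483647L
}
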