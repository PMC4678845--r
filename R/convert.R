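#' In-silico bisulfite conversion of a reference amplicon
#'
#' Produces the reference that bisulfite reads are aligned against: every C
#' of the untreated amplicon replaced by T, with the original sequence and
#' the CpG positions retained for base calling.
#'
#' @param amplicon DNA string over `ACGT` (or a [methylated_template], whose
#'   sequence is used).
#' @param name reference name.
#' @return An object of class `converted_reference` with fields `name`,
#'   `original`, `converted`, `cpg_sites` (0-based).
#' @examples
#' insilico_convert("ACGTCC")   # converted "ATGTTT", CpG at 1
#' @export
insilico_convert <- function(amplicon, name = NULL) {
  if (inherits(amplicon, "methylated_template")) {
    if (is.null(name)) name <- amplicon$name
    amplicon <- amplicon$seq
  }
  if (is.null(name)) name <- "amplicon"
  if (!is.character(amplicon) || length(amplicon) != 1L || nchar(amplicon) == 0L)
    stop("amplicon must be a single non-empty string")
  amplicon <- toupper(amplicon)
  ch <- seq_chars(amplicon)
  bad <- which(!ch %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop("ambiguity/non-ACGT character(s) at 0-based position(s): ",
         paste(head(bad - 1L, 10L), collapse = ", "))
  structure(list(name = name,
                 original = amplicon,
                 converted = chartr("C", "T", amplicon),
                 cpg_sites = find_cpg_sites(amplicon)),
            class = "converted_reference")
}

#' @export
print.converted_reference <- function(x, ...) {
  cat(sprintf("converted_reference '%s': %d nt, %d C, %d CpG\n",
              x$name, nchar(x$original),
              sum(seq_chars(x$original) == "C"), length(x$cpg_sites)))
  invisible(x)
}
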