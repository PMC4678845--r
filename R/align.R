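#' Bisulfite-aware read alignment
#'
#' Aligns one read against an in-silico converted reference using banded
#' dynamic programming on three-letter collapsed sequences: C is replaced by
#' T in both read and reference for scoring, so a fully converted read
#' matches the reference without penalty while the asymmetric C-to-T
#' uncertainty never counts as a mismatch. The original read bases are
#' preserved for base calling. The alignment is global in the read and local
#' in the reference (free reference overhangs), with linear gap penalties
#' and a band of `band` diagonals around the best ungapped seed diagonal;
#' ties are broken toward the leftmost reference offset.
#'
#' @param read DNA string over `ACGT` (original, uncollapsed bases).
#' @param ref a [insilico_convert()] result.
#' @param band band half-width in diagonals.
#' @param match,mismatch,gap scoring parameters (defaults +1/-2/-3).
#' @param allow_rc also try the reverse complement of the read and keep the
#'   better-scoring orientation (off by default: amplicon reads are
#'   forward-oriented by design).
#' @return An object of class `bs_alignment`: `offset` (0-based reference
#'   start), `score`, `ref_pos`/`read_pos` (0-based aligned columns, gap
#'   columns omitted), `read` (original bases, reverse-complemented if the
#'   reverse orientation won), `identity` (collapsed identity over the read),
#'   `rc`.
#' @examples
#' ref <- insilico_convert("ACGTACCTGA")
#' align_bisulfite("ATGTATTTGA", ref)$offset  # 0; C-to-T tolerated
#' @export
align_bisulfite <- function(read, ref, band = 16L, match = 1L,
                            mismatch = -2L, gap = -3L, allow_rc = FALSE) {
  stopifnot(inherits(ref, "converted_reference"))
  if (!is.character(read) || length(read) != 1L || nchar(read) == 0L)
    stop("read must be a single non-empty string (empty reads are rejected)")
  read <- toupper(read)
  if (nchar(read) > nchar(ref$converted))
    stop("read length exceeds reference length")
  aln_one <- function(rd) {
    a <- .align_banded_cpp(chartr("C", "T", rd), ref$converted,
                           as.integer(band), as.integer(match),
                           as.integer(mismatch), as.integer(gap))
    a$identity <- a$n_match / nchar(rd)
    a
  }
  a <- aln_one(read)
  rc <- FALSE
  if (allow_rc) {
    rdrc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
    b <- aln_one(rdrc)
    if (b$score > a$score) { a <- b; read <- rdrc; rc <- TRUE }
  }
  structure(list(offset = a$offset, score = a$score,
                 ref_pos = a$ref_pos, read_pos = a$read_pos,
                 read = read, identity = a$identity, rc = rc,
                 ref_name = ref$name),
            class = "bs_alignment")
}

#' @export
print.bs_alignment <- function(x, ...) {
  cat(sprintf("bs_alignment vs '%s': offset %d, score %d, identity %.3f\n",
              x$ref_name, x$offset, x$score, x$identity))
  invisible(x)
}
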