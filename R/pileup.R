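#' Build a base-count pileup from alignments
#'
#' Accumulates the original (uncollapsed) read bases at each reference
#' position, mpileup-style: every aligned read/reference base pair adds one
#' count; gap columns contribute nothing. The pileup carries the original
#' (untreated) reference base and CpG membership at each position, which is
#' what the downstream methylation, conversion and error statistics key on.
#'
#' @param alignments list of [align_bisulfite()] results (all against `ref`).
#' @param ref the [insilico_convert()] result the alignments refer to.
#' @return An object of class `bs_pileup`: a data frame with columns `pos0`,
#'   `ref_base` (original), `is_cpg`, `A`, `C`, `G`, `T`, `depth`, plus the
#'   reference attached as an attribute.
#' @examples
#' ref <- insilico_convert("ACGTAC")
#' aln <- align_bisulfite("ATGTAT", ref)
#' build_pileup(list(aln), ref)
#' @export
build_pileup <- function(alignments, ref) {
  stopifnot(inherits(ref, "converted_reference"))
  n <- nchar(ref$original)
  counts <- matrix(0L, nrow = n, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (a in alignments) {
    if (!inherits(a, "bs_alignment"))
      stop("alignments must be bs_alignment objects")
    if (length(a$ref_pos) == 0L) next
    if (min(a$ref_pos) < 0L || max(a$ref_pos) >= n)
      stop("alignment out of reference bounds")
    bases <- seq_chars(a$read)[a$read_pos + 1L]
    bi <- match(bases, c("A", "C", "G", "T"))
    ok <- !is.na(bi)
    idx <- cbind(a$ref_pos[ok] + 1L, bi[ok])
    # accumulate (duplicate idx rows are impossible within one alignment)
    counts[idx] <- counts[idx] + 1L
  }
  df <- data.frame(pos0 = 0:(n - 1L),
                   ref_base = seq_chars(ref$original),
                   is_cpg = (0:(n - 1L)) %in% ref$cpg_sites,
                   counts,
                   depth = rowSums(counts),
                   stringsAsFactors = FALSE)
  structure(df, class = c("bs_pileup", "data.frame"), ref = ref)
}

#' Merge pileup shards
#'
#' Adds the base counts of pileups built against the same reference; the
#' methylation and conversion statistics are invariant to how reads were
#' sharded before piling.
#'
#' @param ... `bs_pileup` objects over the same reference.
#' @return The merged `bs_pileup`.
#' @export
merge_pileups <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1L]]) && !inherits(ps[[1L]], "bs_pileup"))
    ps <- ps[[1L]]
  stopifnot(length(ps) >= 1L,
            all(vapply(ps, inherits, logical(1), "bs_pileup")))
  out <- ps[[1L]]
  refname <- attr(out, "ref")$name
  for (p in ps[-1L]) {
    if (!identical(attr(p, "ref")$name, refname) || nrow(p) != nrow(out))
      stop("pileups must share the same reference")
    for (b in c("A", "C", "G", "T")) out[[b]] <- out[[b]] + p[[b]]
  }
  out$depth <- out$A + out$C + out$G + out$T
  out
}

#' @export
print.bs_pileup <- function(x, ...) {
  cat(sprintf("bs_pileup over '%s': %d positions, total depth %g\n",
              attr(x, "ref")$name, nrow(x), sum(x$depth)))
  invisible(x)
}

# Construct a pileup directly from per-position counts (used by tests to
# craft exact scenarios without reads).
#' Craft a pileup from explicit base counts
#'
#' Mostly a testing and teaching device: builds a `bs_pileup` from a matrix
#' of A/C/G/T counts instead of from alignments, so exclusion rules and
#' arithmetic can be verified on exactly known inputs.
#'
#' @param ref a [insilico_convert()] result.
#' @param counts numeric matrix with one row per reference position and
#'   columns `A`, `C`, `G`, `T`.
#' @return A `bs_pileup`.
#' @export
pileup_from_counts <- function(ref, counts) {
  stopifnot(inherits(ref, "converted_reference"),
            nrow(counts) == nchar(ref$original),
            all(c("A", "C", "G", "T") %in% colnames(counts)))
  counts <- counts[, c("A", "C", "G", "T"), drop = FALSE]
  n <- nrow(counts)
  df <- data.frame(pos0 = 0:(n - 1L),
                   ref_base = seq_chars(ref$original),
                   is_cpg = (0:(n - 1L)) %in% ref$cpg_sites,
                   counts,
                   depth = rowSums(counts),
                   stringsAsFactors = FALSE)
  structure(df, class = c("bs_pileup", "data.frame"), ref = ref)
}
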