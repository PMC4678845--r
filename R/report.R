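#' Per-CpG methylation report
#'
#' At each CpG cytosine of the reference, a C observation reports a
#' methylated (protected) molecule and a T observation a converted
#' (unmethylated) one; the methylation fraction is `C / (C + T)`. A and G
#' observations are sequencing/PCR noise, counted as `other` and excluded
#' from the fraction's denominator. Sites below `min_depth` informative
#' observations are flagged, never silently dropped. CpG sites are numbered
#' from the amplicon 5' end (1-based, for display).
#'
#' @param pileup a [build_pileup()] result.
#' @param min_depth minimum `C + T` count for an unflagged fraction.
#' @return An object of class `methylation_report`: `sites` data frame
#'   (`cpg_index`, `pos0`, `meth_count`, `unmeth_count`, `other`, `fraction`,
#'   `low_depth`) and `global` (depth-weighted mean fraction). Empty `sites`
#'   if the reference has no CpG.
#' @examples
#' ref <- insilico_convert("ACGTACGT")
#' m <- matrix(0, 8, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
#' m[2, "C"] <- 7; m[2, "T"] <- 3    # first CpG: 70% methylated
#' cpg_methylation(pileup_from_counts(ref, m), min_depth = 5)
#' @export
cpg_methylation <- function(pileup, min_depth = 10L) {
  stopifnot(inherits(pileup, "bs_pileup"))
  cp <- pileup[pileup$is_cpg, , drop = FALSE]
  if (!nrow(cp)) {
    sites <- data.frame(cpg_index = integer(0), pos0 = integer(0),
                        meth_count = numeric(0), unmeth_count = numeric(0),
                        other = numeric(0), fraction = numeric(0),
                        low_depth = logical(0))
    return(structure(list(sites = sites, global = NA_real_,
                          amplicon = attr(pileup, "ref")$name),
                     class = "methylation_report"))
  }
  informative <- cp$C + cp$T
  sites <- data.frame(cpg_index = seq_len(nrow(cp)),
                      pos0 = cp$pos0,
                      meth_count = cp$C,
                      unmeth_count = cp$T,
                      other = cp$A + cp$G,
                      fraction = ifelse(informative > 0, cp$C / informative,
                                        NA_real_),
                      low_depth = informative < min_depth)
  global <- if (sum(informative) > 0) sum(cp$C) / sum(informative) else NA_real_
  structure(list(sites = sites, global = global,
                 amplicon = attr(pileup, "ref")$name),
            class = "methylation_report")
}

#' @export
print.methylation_report <- function(x, ...) {
  cat(sprintf("methylation_report for '%s': %d CpG site(s), global methylation %s\n",
              x$amplicon, nrow(x$sites),
              ifelse(is.na(x$global), "NA", sprintf("%.3f", x$global))))
  if (nrow(x$sites)) print(utils::head(x$sites, 20L))
  invisible(x)
}

#' Bisulfite conversion efficiency
#'
#' The conversion statistic of amplicon bisulfite sequencing: the percentage
#' of observations at non-CpG original-cytosine positions that read as T.
#' Only cytosines outside CpG context enter the calculation -- they are
#' assumed unmethylated, so any residual C there reflects incomplete
#' conversion rather than biology; CpG positions contribute nothing.
#'
#' @param pileup a [build_pileup()] result.
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) when the
#'   pileup holds no informative observation at an eligible position.
#' @examples
#' ref <- insilico_convert("ACTACT")
#' m <- matrix(0, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
#' m[c(2, 5), "T"] <- 49; m[c(2, 5), "C"] <- 1
#' conversion_rate(pileup_from_counts(ref, m))  # 98
#' @export
conversion_rate <- function(pileup) {
  stopifnot(inherits(pileup, "bs_pileup"))
  el <- pileup$ref_base == "C" & !pileup$is_cpg
  if (!any(el))
    stop("pileup has no non-CpG cytosine position; conversion is undefined")
  tt <- sum(pileup$T[el]); cc <- sum(pileup$C[el])
  if (tt + cc == 0) {
    warning("no informative observation at non-CpG cytosines; conversion undefined")
    return(NA_real_)
  }
  100 * tt / (tt + cc)
}

#' Substitution error rates with bisulfite exclusion rules
#'
#' Computes the sequencing/PCR error statistics of an amplicon bisulfite
#' experiment. Because a T at an original-C position is indistinguishable
#' from legitimate bisulfite conversion (or methylation heterogeneity), all
#' C-to-T observations are excluded from the error calculation -- removed
#' from both the numerator and the denominator. The per-nucleotide breakdown
#' is computed only at positions whose original (untreated) base is G, A or
#' T; for T that automatically restricts to genomic Ts, where no conversion
#' event can contribute. The cumulative error is also expressed per PCR
#' cycle by dividing by the total number of cycles the molecules went
#' through.
#'
#' @param pileup a [build_pileup()] result.
#' @param total_cycles total PCR cycles across all rounds (>= 1).
#' @return An object of class `error_report`: `conversion_pct`,
#'   `overall_error_pct`, `per_base_error` (named percentages for `A`, `G`,
#'   `T`), `per_cycle_rate` (fraction per cycle; `per_cycle_rate *
#'   total_cycles` equals the cumulative error fraction exactly),
#'   `total_cycles`, `n_counted`.
#' @examples
#' ref <- insilico_convert("AGTAGTAGTA")
#' m <- matrix(0, 10, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
#' m[cbind(1:10, match(strsplit("AGTAGTAGTA", "")[[1]],
#'         c("A", "C", "G", "T")))] <- 100
#' m[1, "G"] <- 4; m[1, "A"] <- 96   # 4 errors in 1000 observations
#' error_rates(pileup_from_counts(ref, m), total_cycles = 70)
#' @export
error_rates <- function(pileup, total_cycles) {
  stopifnot(inherits(pileup, "bs_pileup"))
  total_cycles <- as.integer(total_cycles)
  if (is.na(total_cycles) || total_cycles < 1L)
    stop("total_cycles must be at least 1")
  bases <- c("A", "C", "G", "T")
  counts <- as.matrix(pileup[, bases])
  ref_base <- pileup$ref_base
  match_count <- counts[cbind(seq_len(nrow(counts)), match(ref_base, bases))]
  mism <- pileup$depth - match_count
  counted <- pileup$depth
  # exclusion rule: C-to-T events at original-C positions leave the
  # calculation entirely (numerator and denominator)
  at_c <- ref_base == "C"
  mism[at_c] <- mism[at_c] - counts[at_c, "T"]
  counted[at_c] <- counted[at_c] - counts[at_c, "T"]
  n_counted <- sum(counted)
  overall <- if (n_counted > 0) 100 * sum(mism) / n_counted else NA_real_
  per_base <- vapply(c("A", "G", "T"), function(b) {
    sel <- ref_base == b
    d <- sum(pileup$depth[sel])
    if (d == 0) return(NA_real_)
    100 * (d - sum(counts[sel, b])) / d
  }, numeric(1))
  conv <- tryCatch(conversion_rate(pileup), error = function(e) NA_real_,
                   warning = function(w) NA_real_)
  structure(list(conversion_pct = conv,
                 overall_error_pct = overall,
                 per_base_error = per_base,
                 per_cycle_rate = (overall / 100) / total_cycles,
                 total_cycles = total_cycles,
                 n_counted = n_counted,
                 amplicon = attr(pileup, "ref")$name),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error_report for '%s' (%d cycles):\n", x$amplicon,
              x$total_cycles))
  cat(sprintf("  conversion: %s%%\n", fmt_pct(x$conversion_pct)))
  cat(sprintf("  overall error (C-to-T excluded): %s%%  (%s /cycle)\n",
              fmt_pct(x$overall_error_pct), fmt_rate(x$per_cycle_rate)))
  cat(sprintf("  per-base error: A %s%%  G %s%%  T %s%%\n",
              fmt_pct(x$per_base_error[["A"]]),
              fmt_pct(x$per_base_error[["G"]]),
              fmt_pct(x$per_base_error[["T"]])))
  invisible(x)
}

# display conventions: percentages to 1 decimal, rates to 2 significant
# figures (only for printing; stored values are never rounded)
fmt_pct <- function(x) if (is.na(x)) "NA" else sprintf("%.1f", x)
fmt_rate <- function(x) if (is.na(x)) "NA" else formatC(signif(x, 2L),
                                                        format = "g")

#' Cytosine content of a sequence
#'
#' @param seq DNA string.
#' @param window optional 0-based half-open `c(start, end)` interval.
#' @return list with `count`, `pct` (raw percentage) and `pct_display`
#'   (rounded to 1 decimal).
#' @examples
#' c_content(strrep("ACTG", 5))  # 25%
#' @export
c_content <- function(seq, window = NULL) {
  if (inherits(seq, "methylated_template")) seq <- seq$seq
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("seq must be a single non-empty string")
  ch <- seq_chars(seq)
  if (!is.null(window)) {
    window <- as.integer(window)
    if (length(window) != 2L || window[1L] < 0L || window[2L] > length(ch) ||
        window[1L] >= window[2L])
      stop("window must be a non-empty 0-based half-open interval in bounds")
    ch <- ch[(window[1L] + 1L):window[2L]]
  }
  count <- sum(ch == "C")
  pct <- 100 * count / length(ch)
  list(count = count, pct = pct, pct_display = round(pct, 1L))
}

#' Summarize per-locus amplification success
#'
#' Turns a vector of per-locus amplification outcomes (one per genomic
#' region attempted) into the success fraction and display percentage; a
#' union summary across several enzyme blends is supported by passing a
#' logical matrix (loci in rows, blends in columns), in which a locus counts
#' as amplified if any blend amplified it.
#'
#' @param outcomes logical vector (or 0/1), or a logical matrix for the
#'   union summary.
#' @return list with `successes`, `total`, `fraction`, `percent` (1
#'   decimal).
#' @examples
#' locus_success_summary(c(rep(TRUE, 15), rep(FALSE, 9)))$percent  # 62.5
#' @export
locus_success_summary <- function(outcomes) {
  if (is.matrix(outcomes)) outcomes <- apply(outcomes > 0, 1L, any)
  outcomes <- as.logical(outcomes)
  if (!length(outcomes) || anyNA(outcomes))
    stop("outcomes must be a non-empty logical vector")
  s <- sum(outcomes); n <- length(outcomes)
  list(successes = s, total = n, fraction = s / n,
       percent = round(100 * s / n, 1L))
}
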