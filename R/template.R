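#' @useDynLib bsamplicon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Split a sequence string into a character vector of single bases.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Locate CpG sites on the top strand
#'
#' @param seq DNA string over ACGT.
#' @return 0-based positions of the C in each CpG dinucleotide.
#' @export
find_cpg_sites <- function(seq) {
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n < 2L) return(integer(0))
  which(ch[-n] == "C" & ch[-1L] == "G") - 1L
}

#' Construct a methylated amplicon template
#'
#' A `methylated_template` is the ground-truth epigenome of one amplicon: a
#' top-strand DNA sequence together with a per-cytosine methylation
#' probability. CpG sites are detected automatically; non-CpG cytosines are
#' assumed unmethylated unless a probability is supplied for them (the
#' conversion-efficiency statistic relies on that assumption).
#'
#' @param seq uppercase DNA string over `ACGT`.
#' @param name template identifier.
#' @param meth named numeric vector: names are 0-based cytosine positions,
#'   values are methylation probabilities in `[0, 1]` (1 = methylated,
#'   0 = unmethylated). Positions not listed default to `cpg_meth` at CpG
#'   sites and 0 elsewhere.
#' @param cpg_meth default methylation probability applied to CpG cytosines
#'   absent from `meth`.
#' @param primer_start 0-based position where the 3' primer-binding region
#'   begins; positions at and beyond it are not part of the extension span of
#'   [extend_primer()]. Default: the full sequence is the extension span.
#' @param region optional 0-based half-open `c(start, end)` window marking the
#'   segment whose base composition is of interest (used by benchmark
#'   templates; [c_content()] can be pointed at it).
#' @return An object of class `methylated_template` with fields `name`, `seq`,
#'   `meth` (probability for every cytosine), `cpg_sites`, `primer_start`,
#'   `region`.
#' @examples
#' tpl <- methylated_template("ACGTCCAT", meth = c(`1` = 1))
#' tpl$cpg_sites   # 1
#' @export
methylated_template <- function(seq, name = "template", meth = NULL,
                                cpg_meth = 0, primer_start = NULL,
                                region = NULL) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("seq must be a single non-empty string")
  seq <- toupper(seq)
  ch <- seq_chars(seq)
  bad <- which(!ch %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop("non-ACGT character(s) at 0-based position(s): ",
         paste(head(bad - 1L, 5L), collapse = ", "))
  c_pos <- which(ch == "C") - 1L
  cpg <- find_cpg_sites(seq)
  m <- setNames(rep(0, length(c_pos)), as.character(c_pos))
  m[as.character(cpg)] <- cpg_meth
  if (!is.null(meth)) {
    if (is.null(names(meth))) stop("meth must be named by 0-based position")
    p <- as.integer(names(meth))
    if (anyNA(p) || !all(p %in% c_pos))
      stop("every meth position must index a C in seq")
    v <- as.numeric(meth)
    if (any(v < 0 | v > 1)) stop("methylation probabilities must lie in [0, 1]")
    m[as.character(p)] <- v
  }
  if (is.null(primer_start)) primer_start <- nchar(seq)
  primer_start <- as.integer(primer_start)
  if (primer_start < 0L || primer_start > nchar(seq))
    stop("primer_start out of range")
  structure(list(name = name, seq = seq, meth = m, cpg_sites = cpg,
                 primer_start = primer_start, region = region),
            class = "methylated_template")
}

#' @export
print.methylated_template <- function(x, ...) {
  cat(sprintf("methylated_template '%s': %d nt, %d C (%d CpG), extension span %d nt\n",
              x$name, nchar(x$seq), length(x$meth), length(x$cpg_sites),
              x$primer_start))
  invisible(x)
}

# C-free tail used as the primer-binding region of benchmark templates
# (starts with A so a template region ending in C never gains a CpG).
.PRIMER_TAIL <- "ATTAGGTGAAGT"

#' Generate benchmark amplicon templates
#'
#' Builds the synthetic templates used throughout the package's test bench:
#'
#' * `T1`: a 20 nt cytosine-rich region (8 C over 20 bases, i.e. 40% C,
#'   arranged as three single C, one CC duplet and one CCC triplet) followed
#'   by a C-free 3' primer-binding tail.
#' * `T2`: a 5' run of eight consecutive C (dC8) followed by a C-free tail.
#' * `T3`: the pre-converted analogue of `T2` -- the dC8 run replaced by a
#'   dU8 run -- returned as a [treated_strand] rather than a template.
#' * `custom`: a random template of given `length` with exactly `n_c`
#'   cytosines, of which `n_cpg` sit in CpG context.
#'
#' @param kind `"T1"`, `"T2"`, `"T3"` or `"custom"`.
#' @param length,n_c,n_cpg composition constraints for `kind = "custom"`:
#'   total length, number of cytosines, number of CpG sites among them.
#' @param cpg_meth methylation probability assigned to CpG cytosines.
#' @param seed integer seed controlling the random arrangement.
#' @param name template name (defaults to `kind`).
#' @return A `methylated_template` (or a `treated_strand` for `T3`). The
#'   returned object is re-scanned by an internal validator; constraint
#'   violations are an error.
#' @examples
#' t1 <- make_benchmark_template("T1", seed = 1)
#' c_content(t1$seq, window = t1$region)
#' @export
make_benchmark_template <- function(kind = c("T1", "T2", "T3", "custom"),
                                    length = 100L, n_c = 25L, n_cpg = 0L,
                                    cpg_meth = 0, seed = 1L, name = NULL) {
  kind <- match.arg(kind)
  if (is.null(name)) name <- kind
  set.seed(substream_seed(seed, "template"))
  if (kind == "T1") {
    tpl <- .make_t1(name, cpg_meth)
    v <- validate_benchmark(tpl)
    if (v$c_count != 8L || !identical(sort(v$run_lengths), c(1L, 1L, 1L, 2L, 3L)) ||
        abs(v$c_fraction - 40) > 1e-9 || !v$primer_cfree)
      stop("T1 validator failed")
    return(tpl)
  }
  if (kind == "T2") {
    seq <- paste0(strrep("C", 8L), .PRIMER_TAIL)
    tpl <- methylated_template(seq, name = name, primer_start = 8L,
                               region = c(0L, 8L))
    if (validate_benchmark(tpl)$c_count != 8L) stop("T2 validator failed")
    return(tpl)
  }
  if (kind == "T3") {
    states <- paste0(strrep("U", 8L), .PRIMER_TAIL)
    return(treated_strand(states, source = name,
                          fragments = list(c(0L, nchar(states))),
                          primer_start = 8L))
  }
  .make_custom(length, n_c, n_cpg, cpg_meth, name)
}

.make_t1 <- function(name, cpg_meth) {
  # 8 Cs as runs {3, 2, 1, 1, 1} separated by non-C spacers within 20 nt,
  # then a C-free primer tail. 12 non-C bases inside the region.
  runs <- sample(c(3L, 2L, 1L, 1L, 1L))
  spacer_pool <- c("A", "T", "G")
  # 6 spacer slots (before, between, after runs); 12 non-C bases total.
  sizes <- as.vector(stats::rmultinom(1L, 12L - 4L, rep(1 / 6, 6L))) +
    c(0L, rep(1L, 4L), 0L)  # at least 1 base between adjacent runs
  piece <- function(k) paste(sample(spacer_pool, k, replace = TRUE),
                             collapse = "")
  parts <- character(0)
  for (i in seq_along(runs)) {
    parts <- c(parts, piece(sizes[i]), strrep("C", runs[i]))
  }
  region <- paste0(paste(parts, collapse = ""), piece(sizes[6L]))
  # avoid a G immediately after any C (keeps the template CpG-free)
  ch <- seq_chars(region)
  g_after_c <- which(ch == "G" & c("X", head(ch, -1L)) == "C")
  ch[g_after_c] <- "A"
  region <- paste(ch, collapse = "")
  seq <- paste0(region, .PRIMER_TAIL)
  methylated_template(seq, name = name, cpg_meth = cpg_meth,
                      primer_start = 20L, region = c(0L, 20L))
}

.make_custom <- function(length, n_c, n_cpg, cpg_meth, name) {
  length <- as.integer(length); n_c <- as.integer(n_c)
  n_cpg <- as.integer(n_cpg)
  if (n_cpg > n_c) stop("n_cpg cannot exceed n_c")
  if (n_c > 0L && length < 2L * n_c)
    stop("unsatisfiable constraints: ", n_c, " C sites do not fit in ",
         length, " nt")
  ch <- sample(c("A", "T"), length, replace = TRUE)
  # anchor positions >= 2 apart (each C owns the following base), sampled
  # uniformly via the gap-insertion bijection
  anchors <- integer(0)
  if (n_c > 0L) {
    dom <- (length - 1L) - (n_c - 1L)
    if (dom < n_c) stop("unsatisfiable constraints: cannot place C sites")
    anchors <- sort(sample.int(dom, n_c)) + 0:(n_c - 1L)
  }
  is_cpg <- rep(FALSE, n_c)
  if (n_cpg > 0L) is_cpg[sample.int(n_c, n_cpg)] <- TRUE
  for (i in seq_len(n_c)) {
    ch[anchors[i]] <- "C"
    ch[anchors[i] + 1L] <- if (is_cpg[i]) "G" else sample(c("A", "T"), 1L)
  }
  # sprinkle G into remaining A/T positions not preceded by a C
  free <- which(ch %in% c("A", "T"))
  free <- free[free == 1L | ch[pmax(free - 1L, 1L)] != "C"]
  ng <- round(0.25 * length(free))
  if (ng > 0L) ch[sample(free, ng)] <- "G"
  # a G draw could have created a new CpG; revert those
  bad <- which(ch == "G" & c("X", head(ch, -1L)) == "C")
  keep_g <- anchors[is_cpg] + 1L
  bad <- setdiff(bad, keep_g)
  ch[bad] <- "A"
  seq <- paste(ch, collapse = "")
  tpl <- methylated_template(seq, name = name, cpg_meth = cpg_meth)
  v <- validate_benchmark(tpl)
  if (v$c_count != n_c || length(tpl$cpg_sites) != n_cpg)
    stop("custom template validator failed: got ", v$c_count, " C and ",
         length(tpl$cpg_sites), " CpG")
  tpl
}

#' Re-scan a benchmark template and report its composition
#'
#' Independent validator used by [make_benchmark_template()]: counts
#' cytosines, measures C-run lengths within the template's region of
#' interest, and checks that the primer-binding tail is C-free.
#'
#' @param template a `methylated_template`.
#' @return list with `c_count` (whole sequence), `run_lengths` (C runs within
#'   `region`, or the whole sequence if no region), `c_fraction` (percent C in
#'   the region), `primer_cfree`.
#' @export
validate_benchmark <- function(template) {
  ch <- seq_chars(template$seq)
  reg <- template$region
  rg <- if (is.null(reg)) ch else ch[(reg[1L] + 1L):reg[2L]]
  r <- rle(rg == "C")
  runs <- r$lengths[r$values]
  tail_ok <- template$primer_start >= length(ch) ||
    !any(ch[(template$primer_start + 1L):length(ch)] == "C")
  list(c_count = sum(ch == "C"),
       run_lengths = as.integer(runs),
       c_fraction = 100 * mean(rg == "C"),
       primer_cfree = tail_ok)
}
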