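#' Bisulfite treatment condition
#'
#' A treatment condition bundles the four per-molecule event probabilities of
#' the bisulfite reaction model: sulfonation of a reactive (unmethylated)
#' cytosine to the dhU6S intermediate (`p_conv`), resolution of that
#' intermediate to uracil during desulphonation (`p_desulf`), acquisition of
#' a blocking lesion at any position (`p_lesion`) and strand scission at any
#' phosphodiester bond (`p_frag`).
#'
#' The named presets follow the usual laboratory regimes: `BS1` is the
#' standard alkaline desulphonation; `BS1T` adds a hot (95 degC) step that
#' pushes desulphonation to near-completion at the cost of more damage;
#' `BS2` is a mild, unheated protocol that leaves much of the intermediate
#' sulfonated; `BS3` is a high-pH variant close to complete; `WATER` skips
#' desulphonation entirely, leaving every converted position as dhU6S. The
#' numeric values are modelling conventions chosen to reproduce the relative
#' harshness ordering of those regimes, not measured efficiencies, and every
#' one can be overridden.
#'
#' @param name preset name (`"BS1"`, `"BS1T"`, `"BS2"`, `"BS3"`, `"WATER"`)
#'   or `"CUSTOM"`.
#' @param p_conv,p_desulf,p_lesion,p_frag probabilities in `[0, 1]`;
#'   override preset values when supplied.
#' @return An object of class `treatment_condition`.
#' @examples
#' treatment_condition("BS2")
#' treatment_condition("CUSTOM", p_conv = 0.995, p_desulf = 1)
#' @export
treatment_condition <- function(name = "CUSTOM", p_conv = NULL,
                                p_desulf = NULL, p_lesion = NULL,
                                p_frag = NULL) {
  presets <- list(
    #              p_conv p_desulf p_lesion p_frag   (heated => damage > 0)
    BS1   = list(0.99, 0.99,  0.001, 0.0002),
    BS1T  = list(0.99, 0.999, 0.002, 0.0004),
    BS2   = list(0.99, 0.50,  0,     0),
    BS3   = list(0.99, 0.95,  0.001, 0.0002),
    WATER = list(0.99, 0,     0,     0),
    CUSTOM = list(1, 1, 0, 0)
  )
  name <- toupper(name)
  if (!name %in% names(presets)) stop("unknown condition preset: ", name)
  p <- presets[[name]]
  val <- c(p_conv = if (is.null(p_conv)) p[[1L]] else p_conv,
           p_desulf = if (is.null(p_desulf)) p[[2L]] else p_desulf,
           p_lesion = if (is.null(p_lesion)) p[[3L]] else p_lesion,
           p_frag = if (is.null(p_frag)) p[[4L]] else p_frag)
  if (any(!is.finite(val)) || any(val < 0) || any(val > 1))
    stop("treatment probabilities must lie in [0, 1]")
  if (name == "WATER" && val[["p_desulf"]] != 0)
    stop("the WATER condition performs no desulphonation (p_desulf must be 0)")
  structure(as.list(c(list(name = name), as.list(val))),
            class = "treatment_condition")
}

#' @export
print.treatment_condition <- function(x, ...) {
  cat(sprintf(
    "treatment_condition %s: p_conv=%.3g p_desulf=%.3g p_lesion=%.3g p_frag=%.3g\n",
    x$name, x$p_conv, x$p_desulf, x$p_lesion, x$p_frag))
  invisible(x)
}

#' Construct a treated strand
#'
#' Low-level constructor for the per-position chemical state of one
#' bisulfite-treated molecule. States are `A/C/G/T` (untouched), `U`
#' (converted and desulphonated), `S` (the dhU6S sulfonate intermediate) and
#' `X` (a blocking lesion). Most users obtain these from [apply_bisulfite()].
#'
#' @param states string over `ACGTUSX`.
#' @param source name of the originating template.
#' @param fragments list of 0-based half-open intervals that survived
#'   fragmentation; defaults to one full-length fragment.
#' @param primer_start 0-based start of the 3' primer-binding region.
#' @param count number of identical molecules this strand represents.
#' @return An object of class `treated_strand`.
#' @export
treated_strand <- function(states, source = "template", fragments = NULL,
                           primer_start = NULL, count = 1) {
  if (!is.character(states) || length(states) != 1L || nchar(states) == 0L)
    stop("states must be a single non-empty string")
  ch <- seq_chars(states)
  if (any(!ch %in% c("A", "C", "G", "T", "U", "S", "X")))
    stop("treated-strand states must be over the ACGTUSX alphabet")
  n <- length(ch)
  if (is.null(fragments)) fragments <- list(c(0L, n))
  fragments <- lapply(fragments, as.integer)
  starts <- vapply(fragments, `[`, integer(1), 1L)
  ends <- vapply(fragments, `[`, integer(1), 2L)
  if (any(starts < 0L) || any(ends > n) || any(starts >= ends))
    stop("fragment intervals must be non-empty and within sequence bounds")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(head(ends, -1L) > tail(starts, -1L)))
    stop("fragment intervals must be disjoint")
  if (is.null(primer_start)) primer_start <- n
  structure(list(states = states, source = source,
                 fragments = Map(c, starts, ends),
                 primer_start = as.integer(primer_start),
                 count = count),
            class = "treated_strand")
}

#' @export
print.treated_strand <- function(x, ...) {
  ch <- seq_chars(x$states)
  cat(sprintf("treated_strand from '%s': %d nt (%d U, %d S, %d X), %d fragment(s)\n",
              x$source, length(ch), sum(ch == "U"), sum(ch == "S"),
              sum(ch == "X"), length(x$fragments)))
  invisible(x)
}

#' Simulate bisulfite treatment of one molecule
#'
#' Applies the two-step bisulfite reaction to a single template molecule.
#' Each cytosine is first assigned a methylation state by a Bernoulli draw on
#' its per-position probability; methylated cytosines are protected and stay
#' `C`. Each unmethylated cytosine is sulfonated to the dhU6S intermediate
#' (`S`) with probability `p_conv`, and each `S` is independently resolved to
#' uracil (`U`) with probability `p_desulf`. Collateral damage is applied
#' last: any position becomes a blocking lesion (`X`) with probability
#' `p_lesion`, and each phosphodiester bond breaks with probability
#' `p_frag`, partitioning the molecule into surviving fragments.
#'
#' All events are independent Bernoulli draws; the function is deterministic
#' for a fixed `seed` (conversion draws are consumed first, then
#' desulphonation, methylation, lesion and fragmentation draws, in that
#' order).
#'
#' @param template a [methylated_template].
#' @param cond a [treatment_condition].
#' @param seed integer seed (expanded through the `"treatment"` substream).
#' @return A [treated_strand].
#' @examples
#' tpl <- make_benchmark_template("T2", seed = 1)
#' apply_bisulfite(tpl, treatment_condition("BS1"), seed = 1)
#' @export
apply_bisulfite <- function(template, cond, seed = 1L) {
  stopifnot(inherits(template, "methylated_template"),
            inherits(cond, "treatment_condition"))
  set.seed(substream_seed(seed, "treatment"))
  ch <- seq_chars(template$seq)
  n <- length(ch)
  c_pos <- as.integer(names(template$meth)) + 1L  # 1-based
  nc <- length(c_pos)
  # draw order: conversion, desulphonation, methylation, lesion, fragmentation
  conv_draw <- stats::runif(nc) < cond$p_conv
  des_draw <- stats::runif(nc) < cond$p_desulf
  meth_draw <- stats::runif(nc) < as.numeric(template$meth)
  reactive <- !meth_draw
  sulf <- reactive & conv_draw
  ch[c_pos[sulf]] <- "S"
  ch[c_pos[sulf & des_draw]] <- "U"
  if (cond$p_lesion > 0) {
    les <- stats::runif(n) < cond$p_lesion
    ch[les] <- "X"
  }
  frags <- list(c(0L, n))
  if (cond$p_frag > 0 && n > 1L) {
    brk <- which(stats::runif(n - 1L) < cond$p_frag)  # break after position i
    if (length(brk)) {
      bounds <- c(0L, brk, n)
      frags <- Map(c, head(bounds, -1L), tail(bounds, -1L))
    }
  }
  treated_strand(paste(ch, collapse = ""), source = template$name,
                 fragments = frags, primer_start = template$primer_start)
}
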