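#' Polymerase bypass profile
#'
#' A `polymerase_profile` parameterizes how a polymerase copes with the
#' non-canonical template states left behind by bisulfite treatment:
#'
#' * `bypass` -- per-encounter read-through probability opposite template
#'   uracil (`U`), the dhU6S sulfonate intermediate (`S`) and blocking
#'   lesions (`X`); canonical bases are always copied.
#' * `homopolymer_penalty` -- multiplier (< 1 for a stalling enzyme) applied
#'   per additional consecutive `U`/`S` beyond the first, so long converted
#'   runs are harder than the same number of isolated sites.
#' * `time_boost` -- strength of the extension-time effect: longer
#'   annealing/extension gives the enzyme more chances at each obstacle
#'   (see Details).
#' * `error_per_cycle` -- substitution probability per incorporated base per
#'   copying event, uniform over the three alternative bases.
#' * `insert_opposite` -- base inserted opposite each non-canonical state
#'   when read-through occurs; both presets follow the A-rule and insert `A`
#'   opposite `U` and `S`, which is what makes converted positions read as
#'   `T` on the sequenced strand.
#'
#' The effective per-encounter bypass at extension time `t` minutes is
#' `1 - (1 - b)^f(t)` with `f(t) = 1 + time_boost * (log1p(t) - log1p(0.5))`,
#' i.e. the per-attempt failure probability shrinks as a power of the time
#' factor, normalized so that the nominal `bypass` values apply at the
#' standard 30 s (0.5 min) extension step.
#'
#' Two presets are provided. `"TAQ"` is a conventional Taq-like enzyme:
#' tolerable on isolated uracil, stalls on uracil runs, essentially blocked
#' by dhU6S and lesions, low error rate. `"P5D4"` is an engineered
#' lesion-bypass enzyme: reads through uracil runs at full speed, bypasses
#' most dhU6S adducts and a fraction of lesions, at the cost of a higher
#' per-cycle error rate. The numeric values are calibration conventions (the
#' underlying experiments report gel band intensities and qPCR curves, not
#' per-encounter rates) and can all be overridden.
#'
#' @param name `"TAQ"`, `"P5D4"` or `"CUSTOM"`.
#' @param bypass named numeric vector with entries `U`, `S`, `X`.
#' @param homopolymer_penalty,time_boost,error_per_cycle scalars.
#' @param insert_opposite named character vector for states `U`, `S`, `X`.
#' @return An object of class `polymerase_profile`.
#' @examples
#' taq <- polymerase_profile("TAQ")
#' pol5d4 <- polymerase_profile("P5D4")
#' taq$bypass["S"] < pol5d4$bypass["S"]
#' @export
polymerase_profile <- function(name = "CUSTOM", bypass = NULL,
                               homopolymer_penalty = NULL, time_boost = NULL,
                               error_per_cycle = NULL,
                               insert_opposite = c(U = "A", S = "A", X = "A")) {
  presets <- list(
    TAQ = list(bypass = c(U = 0.80, S = 0.05, X = 0),
               homopolymer_penalty = 0.85, time_boost = 0.25,
               error_per_cycle = 5e-5),
    P5D4 = list(bypass = c(U = 0.9995, S = 0.92, X = 0.30),
                homopolymer_penalty = 0.9995, time_boost = 0.20,
                error_per_cycle = 3e-4),
    CUSTOM = list(bypass = c(U = 1, S = 1, X = 1),
                  homopolymer_penalty = 1, time_boost = 0,
                  error_per_cycle = 0)
  )
  name <- toupper(name)
  if (!name %in% names(presets)) stop("unknown polymerase preset: ", name)
  p <- presets[[name]]
  if (!is.null(bypass)) {
    p$bypass[names(bypass)] <- bypass
  }
  if (!is.null(homopolymer_penalty)) p$homopolymer_penalty <- homopolymer_penalty
  if (!is.null(time_boost)) p$time_boost <- time_boost
  if (!is.null(error_per_cycle)) p$error_per_cycle <- error_per_cycle
  if (any(p$bypass < 0 | p$bypass > 1) || !all(c("U", "S", "X") %in% names(p$bypass)))
    stop("bypass must give probabilities in [0, 1] for states U, S, X")
  if (p$homopolymer_penalty <= 0 || p$homopolymer_penalty > 1)
    stop("homopolymer_penalty must lie in (0, 1]")
  if (p$error_per_cycle < 0 || p$error_per_cycle > 1)
    stop("error_per_cycle must lie in [0, 1]")
  if (!all(insert_opposite %in% c("A", "C", "G", "T")))
    stop("insert_opposite must map to DNA bases")
  structure(list(name = name, bypass = p$bypass[c("U", "S", "X")],
                 homopolymer_penalty = p$homopolymer_penalty,
                 time_boost = p$time_boost,
                 error_per_cycle = p$error_per_cycle,
                 insert_opposite = insert_opposite),
            class = "polymerase_profile")
}

#' @export
print.polymerase_profile <- function(x, ...) {
  cat(sprintf("polymerase_profile %s: bypass U=%.3g S=%.3g X=%.3g, hp=%.3g, err/cycle=%.2g\n",
              x$name, x$bypass[["U"]], x$bypass[["S"]], x$bypass[["X"]],
              x$homopolymer_penalty, x$error_per_cycle))
  invisible(x)
}

#' Blend of polymerases acting in one reaction
#'
#' Models a mixed polymerase reaction (e.g. Taq spiked with a lesion-bypass
#' enzyme at 10/1, 5/1 or 1/1). The acting profile is drawn per molecule per
#' copying event with probability proportional to the weights, reflecting a
#' distributive enzyme re-binding between extension events.
#'
#' @param components list of [polymerase_profile] objects.
#' @param weights positive weights, normalized to sum to 1.
#' @return An object of class `polymerase_blend`.
#' @seealso [taq_5d4_blend()] for the standard presets.
#' @export
polymerase_blend <- function(components, weights) {
  if (!length(components)) stop("a blend needs at least one component")
  stopifnot(all(vapply(components, inherits, logical(1), "polymerase_profile")),
            length(weights) == length(components))
  if (any(weights <= 0)) stop("blend weights must be positive")
  structure(list(components = components, weights = weights / sum(weights)),
            class = "polymerase_blend")
}

#' Standard Taq / lesion-bypass enzyme blends
#'
#' @param ratio Taq-to-bypass-enzyme ratio: `"10/1"`, `"5/1"` or `"1/1"`.
#' @return A [polymerase_blend] of the `"TAQ"` and `"P5D4"` presets.
#' @examples
#' taq_5d4_blend("5/1")
#' @export
taq_5d4_blend <- function(ratio = c("10/1", "5/1", "1/1")) {
  ratio <- match.arg(ratio)
  w <- switch(ratio, "10/1" = c(10, 1), "5/1" = c(5, 1), "1/1" = c(1, 1))
  polymerase_blend(list(polymerase_profile("TAQ"), polymerase_profile("P5D4")),
                   weights = w)
}

#' @export
print.polymerase_blend <- function(x, ...) {
  cat("polymerase_blend:",
      paste(sprintf("%s (%.3f)",
                    vapply(x$components, `[[`, character(1), "name"),
                    x$weights), collapse = " + "), "\n")
  invisible(x)
}

# Extension-time factor, normalized to 1 at the standard 0.5 min step.
time_factor <- function(time_min, boost) {
  if (any(time_min <= 0)) stop("time_min must be positive")
  pmax(0.1, 1 + boost * (log1p(time_min) - log1p(0.5)))
}

# Effective per-encounter bypass probability for one obstacle.
effective_bypass <- function(base_bypass, run_index, penalty, tf) {
  b <- pmin(1, pmax(0, base_bypass * penalty^(run_index - 1)))
  1 - (1 - b)^tf
}

# Obstacles (U/S/X) within the extension span, in the order the polymerase
# meets them: primer anneals at the 3' tail, synthesis walks toward the
# 5' end, i.e. positions primer_start-1, ..., 0. run_index counts position
# within a consecutive U/S run (X resets the run).
scan_obstacles <- function(strand) {
  ch <- seq_chars(strand$states)
  span <- strand$primer_start
  if (span == 0L) {
    return(data.frame(pos = integer(0), state = character(0),
                      run_index = integer(0), steps = integer(0)))
  }
  idx <- span:1L  # 1-based positions, walk order
  st <- ch[idx]
  hit <- st %in% c("U", "S", "X")
  if (!any(hit)) {
    return(data.frame(pos = integer(0), state = character(0),
                      run_index = integer(0), steps = integer(0)))
  }
  run_index <- integer(span)
  run <- 0L
  for (k in seq_len(span)) {
    if (st[k] %in% c("U", "S")) run <- run + 1L else run <- 0L
    run_index[k] <- run
  }
  data.frame(pos = idx[hit] - 1L,                 # 0-based template position
             state = st[hit],
             run_index = pmax(1L, run_index[hit]),
             steps = which(hit),                  # nt copied when passing it
             stringsAsFactors = FALSE)
}

# TRUE if the strand's fragments include one interval covering the whole
# molecule (a broken molecule cannot template a full-length product).
is_intact <- function(strand) {
  n <- nchar(strand$states)
  any(vapply(strand$fragments,
             function(f) f[1L] == 0L && f[2L] == n, logical(1)))
}

#' Analytic full-length extension probability
#'
#' Probability that a single molecule is copied to the end of its extension
#' span: the product over all `U`/`S`/`X` obstacles of the effective bypass
#' probability at the given extension time (for a blend, the weight-averaged
#' probability over components). Fragmented molecules have probability 0.
#' This is the closed form whose Monte Carlo counterpart is
#' [extend_primer()], and the per-cycle copying probability used by
#' [run_pcr()].
#'
#' @param strand a [treated_strand].
#' @param pol a [polymerase_profile] or [polymerase_blend].
#' @param time_min extension time in minutes.
#' @return Numeric probability in `[0, 1]`.
#' @export
full_length_prob <- function(strand, pol, time_min = 0.5) {
  if (inherits(pol, "polymerase_blend")) {
    ps <- vapply(pol$components, full_length_prob, numeric(1),
                 strand = strand, time_min = time_min)
    return(sum(pol$weights * ps))
  }
  stopifnot(inherits(pol, "polymerase_profile"))
  if (!is_intact(strand)) return(0)
  obs <- scan_obstacles(strand)
  if (!nrow(obs)) return(1)
  tf <- time_factor(time_min, pol$time_boost)
  eff <- effective_bypass(pol$bypass[obs$state], obs$run_index,
                          pol$homopolymer_penalty, tf)
  prod(eff)
}

#' Simulate primer extension on a treated strand
#'
#' Monte Carlo counterpart of [full_length_prob()]: `n` molecules each walk
#' the template from the primer toward the 5' end; at every `U`/`S`/`X`
#' encounter the walk terminates with probability one minus the effective
#' bypass probability (base bypass, discounted per additional base of a
#' consecutive `U`/`S` run, boosted by extension time). For a blend, the
#' acting profile is drawn per molecule by weight.
#'
#' @param strand a [treated_strand] with a C-free 3' primer site (its
#'   `primer_start` defines the extension span).
#' @param pol a [polymerase_profile] or [polymerase_blend].
#' @param time_min extension time in minutes (> 0).
#' @param n number of molecules to simulate (>= 1).
#' @param seed integer seed.
#' @return An object of class `extension_result` with `product_lengths`
#'   (nt synthesized beyond the primer, one entry per molecule) and
#'   `full_length_fraction`.
#' @examples
#' t3 <- make_benchmark_template("T3", seed = 1)
#' extend_primer(t3, polymerase_profile("P5D4"), time_min = 0.5, n = 1000,
#'               seed = 1)$full_length_fraction
#' @export
extend_primer <- function(strand, pol, time_min = 0.5, n = 1000L, seed = 1L) {
  stopifnot(inherits(strand, "treated_strand"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1")
  if (time_min <= 0) stop("time_min must be positive")
  set.seed(substream_seed(seed, "pcr"))
  span <- strand$primer_start
  obs <- scan_obstacles(strand)
  intact <- is_intact(strand)
  profiles <- if (inherits(pol, "polymerase_blend")) pol$components else list(pol)
  weights <- if (inherits(pol, "polymerase_blend")) pol$weights else 1
  which_prof <- sample.int(length(profiles), n, replace = TRUE, prob = weights)
  lengths <- integer(n)
  if (!intact) {
    # extension from a broken template stops at the first fragment boundary
    frag_end <- 0L
    for (f in strand$fragments) if (f[2L] >= span) frag_end <- max(frag_end, f[1L])
    lengths[] <- max(0L, span - frag_end)
    lengths <- pmin(lengths, span - 1L)  # never full length
  } else if (nrow(obs) == 0L) {
    lengths[] <- span
  } else {
    k <- nrow(obs)
    u <- matrix(stats::runif(n * k), nrow = n)
    for (j in seq_along(profiles)) {
      sel <- which_prof == j
      if (!any(sel)) next
      p <- profiles[[j]]
      tf <- time_factor(time_min, p$time_boost)
      eff <- effective_bypass(p$bypass[obs$state], obs$run_index,
                              p$homopolymer_penalty, tf)
      fail <- u[sel, , drop = FALSE] > rep(eff, each = sum(sel))
      first_fail <- apply(fail, 1L, function(r) if (any(r)) which(r)[1L] else 0L)
      lengths[sel] <- ifelse(first_fail == 0L, span,
                             obs$steps[pmax(first_fail, 1L)] - 1L)
    }
  }
  structure(list(product_lengths = lengths,
                 full_length_fraction = mean(lengths == span),
                 span = span, n = n),
            class = "extension_result")
}

#' @export
print.extension_result <- function(x, ...) {
  cat(sprintf("extension_result: n=%d, span=%d nt, full-length fraction %.3f\n",
              x$n, x$span, x$full_length_fraction))
  invisible(x)
}
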