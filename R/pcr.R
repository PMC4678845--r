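# Binomial draw that stays safe for huge molecule counts: exact rbinom while
# n fits an integer, expectation beyond that (fluctuations are negligible at
# that scale).
sample_binom <- function(n, p) {
  if (n <= 0 || p <= 0) return(0)
  if (p >= 1) return(n)
  if (n < 2^31 - 1) as.numeric(stats::rbinom(1L, as.integer(round(n)), p))
  else round(n * p)
}

# Sequence of the clean copy templated by a treated strand: U and S are both
# read as T (the A-rule insertion opposite either state), bypassed lesions
# read as the profile's insert_opposite base.
clean_copy_seq <- function(states, insert_x = "A") {
  s <- chartr("US", "TT", states)
  gsub("X", insert_x, s, fixed = TRUE)
}

#' Pool of bisulfite-treated molecules
#'
#' Describes the input to a PCR: `n0` molecules of one template, each
#' independently treated under `cond`. Because simulating millions of
#' molecules individually is unnecessary, the pool stores the template and
#' condition plus `n_rep` representative treated strands from which
#' per-cycle copying probabilities are estimated; read generation later
#' draws a fresh conversion pattern per read, which is the exact
#' large-pool limit (each sequenced read descends from a different input
#' molecule with overwhelming probability when `n0` is large).
#'
#' @param template a [methylated_template].
#' @param cond a [treatment_condition].
#' @param n0 number of input molecules.
#' @param seed integer seed.
#' @param n_rep number of representative strands to simulate.
#' @return An object of class `treated_pool`.
#' @examples
#' tpl <- make_benchmark_template("custom", length = 120, n_c = 30,
#'                                n_cpg = 4, cpg_meth = 0.8, seed = 1)
#' treated_pool(tpl, treatment_condition("BS1"), n0 = 1e6, seed = 1)
#' @export
treated_pool <- function(template, cond, n0 = 1e6, seed = 1L, n_rep = 200L) {
  stopifnot(inherits(template, "methylated_template"),
            inherits(cond, "treatment_condition"))
  n_rep <- min(n_rep, max(1, n0))
  reps <- lapply(seq_len(n_rep), function(i)
    apply_bisulfite(template, cond, seed = seed * 1000L + i))
  structure(list(template = template, cond = cond, n0 = n0, reps = reps),
            class = "treated_pool")
}

#' @export
print.treated_pool <- function(x, ...) {
  cat(sprintf("treated_pool: %g molecules of '%s' under %s (%d representatives)\n",
              x$n0, x$template$name, x$cond$name, length(x$reps)))
  invisible(x)
}

# Internal: normalize the pool argument of run_pcr into strata. Each stratum
# is a source of first-generation clean copies with its own copying
# probability and copy sequence.
as_strata <- function(pool) {
  if (is.null(pool)) return(list())
  if (inherits(pool, "treated_pool")) {
    return(list(list(type = "pool", pool = pool, n = pool$n0)))
  }
  if (inherits(pool, "treated_strand")) pool <- list(pool)
  stopifnot(all(vapply(pool, inherits, logical(1), "treated_strand")))
  lapply(pool, function(s) list(type = "strand", strand = s, n = s$count))
}

# Mean full-length probability of a stratum under each blend component.
stratum_p <- function(stratum, profiles, time_min) {
  vapply(profiles, function(p) {
    if (stratum$type == "pool") {
      mean(vapply(stratum$pool$reps, full_length_prob, numeric(1),
                  pol = p, time_min = time_min))
    } else {
      full_length_prob(stratum$strand, p, time_min)
    }
  }, numeric(1))
}

#' Simulate a PCR (or qPCR) amplification
#'
#' Per cycle, every amplifiable molecule is copied with a probability equal
#' to its full-length extension probability under the acting polymerase at
#' that cycle's extension time. Copies of treated strands are clean DNA
#' (uracil and bypassed dhU6S read as T), so they and all their descendants
#' are copied with probability 1; the original treated molecules remain in
#' the reaction and can seed new clean lineages at every cycle. For blends,
#' the acting profile is drawn per molecule per cycle by weight. Molecule
#' counts are drawn stochastically while they fit machine integers and
#' continued analytically beyond that; the reported trajectory is capped at
#' `cap` to mimic the reaction plateau.
#'
#' The threshold cycle `ct` is computed qPCR-style against a fixed
#' molecule-count threshold, with log-linear interpolation between cycles,
#' so exact doubling from `n0` gives `ct = log2(threshold / n0)`.
#'
#' Copies are tracked by generation (number of synthesis events in their
#' ancestry), which is what read generation later uses to accrue per-cycle
#' substitution errors.
#'
#' @param pool a [treated_pool], a [treated_strand], a list of treated
#'   strands, or `NULL` for a zero-input control.
#' @param pol a [polymerase_profile] or [polymerase_blend].
#' @param cycles number of cycles (>= 1).
#' @param first_cycle_extension_min optional longer annealing/extension time
#'   (minutes) for cycle 1 only, the classic rescue manoeuvre for templates
#'   rich in uracil runs or residual sulfonate adducts.
#' @param extension_min extension time for all other cycles (default 0.5,
#'   i.e. a 30 s step).
#' @param seed integer seed.
#' @param ct_threshold molecule count defining Ct.
#' @param cap plateau cap for the reported trajectory.
#' @return An object of class `pcr_run` with `cycles`, `copies_per_cycle`
#'   (capped trajectory), `total` (uncapped analytic totals), `ct` (fractional,
#'   `NA` if the threshold is never reached), and the generation bookkeeping
#'   used by [generate_reads()].
#' @examples
#' tpl <- make_benchmark_template("custom", length = 120, n_c = 30, seed = 1)
#' pool <- treated_pool(tpl, treatment_condition("BS1"), n0 = 1e5, seed = 1)
#' run <- run_pcr(pool, taq_5d4_blend("5/1"), cycles = 20, seed = 1)
#' run$ct
#' @export
run_pcr <- function(pool, pol, cycles, first_cycle_extension_min = NULL,
                    extension_min = 0.5, seed = 1L, ct_threshold = 1e9,
                    cap = 1e12) {
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 1L) stop("cycles must be at least 1")
  if (!is.null(first_cycle_extension_min) && first_cycle_extension_min <= 0)
    stop("first_cycle_extension_min must be positive")
  set.seed(substream_seed(seed, "pcr"))
  strata <- as_strata(pool)
  profiles <- if (inherits(pol, "polymerase_blend")) pol$components else list(pol)
  weights <- if (inherits(pol, "polymerase_blend")) pol$weights else 1
  errs <- vapply(profiles, `[[`, numeric(1), "error_per_cycle")
  e_clean <- sum(weights * errs)
  ns <- length(strata)
  n_treated <- vapply(strata, `[[`, numeric(1), "n")
  gen <- matrix(0, nrow = max(ns, 1L), ncol = cycles)  # clean copies by generation
  e_first <- rep(e_clean, max(ns, 1L))
  t1 <- if (is.null(first_cycle_extension_min)) extension_min else
    first_cycle_extension_min
  # per-stratum, per-component copy probabilities at the two extension times
  p_std <- if (ns) lapply(strata, stratum_p, profiles = profiles,
                          time_min = extension_min) else list()
  p_first <- if (ns) {
    if (t1 == extension_min) p_std
    else lapply(strata, stratum_p, profiles = profiles, time_min = t1)
  } else list()
  for (s in seq_len(ns)) {
    wp <- weights * p_first[[s]]
    if (sum(wp) > 0) e_first[s] <- sum(wp * errs) / sum(wp)
  }
  total <- numeric(cycles)
  for (cy in seq_len(cycles)) {
    p_cy <- if (cy == 1L) p_first else p_std
    # clean copies double deterministically (no obstacles, efficiency 1)
    if (cycles > 1L)
      gen[, 2:cycles] <- gen[, 2:cycles] + gen[, 1:(cycles - 1L)]
    for (s in seq_len(ns)) {
      # acting profile drawn per molecule: successes from each component
      wp <- weights * p_cy[[s]]
      gen[s, 1L] <- gen[s, 1L] + sample_binom(n_treated[s], sum(wp))
    }
    total[cy] <- sum(n_treated) + sum(gen)
  }
  ct <- ct_from_trajectory(c(sum(n_treated), total), ct_threshold)
  structure(list(cycles = cycles,
                 copies_per_cycle = pmin(total, cap),
                 total = total,
                 ct = ct,
                 first_cycle_extension_min = first_cycle_extension_min,
                 extension_min = extension_min,
                 strata = strata,
                 gen_counts = gen,
                 stages = list(list(cycles = cycles, e = e_clean)),
                 e_first = e_first,
                 e_clean = e_clean,
                 pol = pol,
                 ct_threshold = ct_threshold,
                 cap = cap),
            class = "pcr_run")
}

# Fractional threshold cycle from a molecule-count trajectory whose first
# element is the cycle-0 input count.
ct_from_trajectory <- function(counts, threshold) {
  hit <- which(counts >= threshold)
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(0)
  lo <- counts[i - 1L]; hi <- counts[i]
  if (lo <= 0) return(i - 1)
  (i - 2) + (log2(threshold) - log2(lo)) / (log2(hi) - log2(lo))
}

#' @export
print.pcr_run <- function(x, ...) {
  cat(sprintf("pcr_run: %d cycle(s), final copies %.3g, ct %s\n",
              x$cycles, x$total[x$cycles],
              if (is.na(x$ct)) "not reached" else sprintf("%.2f", x$ct)))
  invisible(x)
}

#' Re-amplify a PCR product in a further round
#'
#' Models a nested or indexing PCR: every molecule of the incoming product
#' doubles per cycle under the new polymerase (the product is clean DNA, so
#' copying is not limited by bypass), while per-cycle substitution errors
#' continue to accrue at the new enzyme's rate. The original treated
#' molecules are assumed diluted out of the second-round reaction.
#'
#' @param run a [run_pcr()] result.
#' @param pol polymerase (or blend) of the new round.
#' @param cycles additional cycles.
#' @return The updated `pcr_run`, with the new round appended to its stage
#'   list and trajectory.
#' @export
continue_pcr <- function(run, pol, cycles) {
  stopifnot(inherits(run, "pcr_run"))
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 1L) stop("cycles must be at least 1")
  profiles <- if (inherits(pol, "polymerase_blend")) pol$components else list(pol)
  weights <- if (inherits(pol, "polymerase_blend")) pol$weights else 1
  e <- sum(weights * vapply(profiles, `[[`, numeric(1), "error_per_cycle"))
  last <- run$total[length(run$total)]
  extra <- last * 2^seq_len(cycles)
  run$total <- c(run$total, extra)
  run$copies_per_cycle <- pmin(run$total, run$cap)
  run$cycles <- run$cycles + cycles
  run$stages <- c(run$stages, list(list(cycles = cycles, e = e)))
  run$ct <- ct_from_trajectory(c(sum(vapply(run$strata, `[[`, numeric(1), "n")),
                                 run$total), run$ct_threshold)
  run
}

#' Sample sequencing reads from a PCR product
#'
#' Reads are fixed-length, 5'-anchored slices of the final amplicon pool
#' (the read layout of amplicon deep sequencing): a molecule is drawn from
#' the final clean-copy pool in proportion to abundance, its first
#' `read_len` bases are taken, PCR substitution errors are applied according
#' to the molecule's generation (each of the `g` synthesis events in its
#' ancestry mutates each base with the acting enzyme's per-cycle rate,
#' uniformly over the three alternative bases), and a flat per-base
#' sequencing error is added on top. Quality strings are a constant
#' placeholder (`I`, Q40).
#'
#' For a [treated_pool] input the conversion pattern of each read is drawn
#' fresh from the template's methylation annotation and the treatment
#' condition, the exact behaviour of a large input pool in which every read
#' descends from a distinct treated molecule.
#'
#' @param run a [run_pcr()] (possibly [continue_pcr()]-extended) result.
#' @param n_reads number of reads (>= 1).
#' @param read_len read length in nt; all reads are taken from the amplicon
#'   5' end at exactly this length.
#' @param seq_error flat per-base sequencing substitution probability.
#' @param seed integer seed (the `"reads"` substream).
#' @return A [Biostrings::DNAStringSet] of `n_reads` reads (zero-length if
#'   the run produced no amplifiable copies, with a warning).
#' @examples
#' tpl <- make_benchmark_template("custom", length = 150, n_c = 40,
#'                                n_cpg = 5, cpg_meth = 0.8, seed = 1)
#' pool <- treated_pool(tpl, treatment_condition("BS1"), n0 = 1e5, seed = 1)
#' run <- run_pcr(pool, taq_5d4_blend("5/1"), cycles = 20, seed = 1)
#' generate_reads(run, n_reads = 100, read_len = 120, seq_error = 0.001,
#'                seed = 1)
#' @export
generate_reads <- function(run, n_reads, read_len = 120L, seq_error = 0.001,
                           seed = 1L) {
  stopifnot(inherits(run, "pcr_run"))
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L) stop("n_reads must be at least 1")
  read_len <- as.integer(read_len)
  if (seq_error < 0 || seq_error > 1) stop("seq_error must lie in [0, 1]")
  strata <- run$strata
  amp_len <- vapply(strata, function(s)
    if (s$type == "pool") nchar(s$pool$template$seq) else nchar(s$strand$states),
    numeric(1))
  if (any(amp_len < read_len))
    stop("read_len (", read_len, ") exceeds amplicon length (",
         min(amp_len), ")")
  set.seed(substream_seed(seed, "reads"))
  gen <- run$gen_counts
  if (sum(gen) <= 0) {
    warning("PCR produced no amplifiable copies; returning zero reads")
    return(Biostrings::DNAStringSet())
  }
  # sample (stratum, generation) per read from final abundances
  cells <- which(gen > 0, arr.ind = TRUE)
  w <- gen[cells]
  pick <- sample.int(nrow(cells), n_reads, replace = TRUE, prob = w)
  s_idx <- cells[pick, 1L]
  g1 <- cells[pick, 2L]
  # later rounds: synthesis events per read, Binomial(k, 1/2) per stage
  extra_g <- rep(0L, n_reads)
  log1m_extra <- rep(0, n_reads)
  stages <- run$stages
  if (length(stages) > 1L) {
    for (st in stages[-1L]) {
      j <- stats::rbinom(n_reads, st$cycles, 0.5)
      extra_g <- extra_g + j
      log1m_extra <- log1m_extra + j * log1p(-st$e)
    }
  }
  # per-read per-base PCR mutation probability
  p_mut <- 1 - (1 - run$e_first[s_idx]) *
    (1 - run$e_clean)^(pmax(g1 - 1L, 0L)) * exp(log1m_extra)
  # build the read matrix (read_len x n_reads)
  mat <- matrix("", nrow = read_len, ncol = n_reads)
  for (s in unique(s_idx)) {
    sel <- which(s_idx == s)
    stratum <- strata[[s]]
    if (stratum$type == "strand") {
      prefix <- seq_chars(substr(clean_copy_seq(stratum$strand$states),
                                 1L, read_len))
      mat[, sel] <- prefix
    } else {
      mat[, sel] <- .fresh_converted_reads(stratum$pool, read_len, length(sel))
    }
  }
  mat <- .mutate_bases(mat, p_mut)
  if (seq_error > 0) mat <- .mutate_bases(mat, rep(seq_error, n_reads))
  reads <- Biostrings::DNAStringSet(apply(mat, 2L, paste, collapse = ""))
  names(reads) <- sprintf("read%06d_g%d", seq_len(n_reads), g1 + extra_g)
  reads
}

# Fresh per-read conversion draws for a treated_pool stratum, restricted to
# the read window. Returns a read_len x n character matrix.
.fresh_converted_reads <- function(pool, read_len, n) {
  tpl <- pool$template
  cond <- pool$cond
  prefix <- seq_chars(substr(tpl$seq, 1L, read_len))
  mat <- matrix(prefix, nrow = read_len, ncol = n)
  cpos <- as.integer(names(tpl$meth))  # 0-based
  in_win <- cpos < read_len
  cpos <- cpos[in_win]
  pm <- as.numeric(tpl$meth)[in_win]
  nc <- length(cpos)
  if (nc) {
    meth <- matrix(stats::runif(nc * n) < rep(pm, times = n), nrow = nc)
    conv <- matrix(stats::runif(nc * n) < cond$p_conv, nrow = nc)
    as_t <- (!meth) & conv   # U or S, either reads as T on the copy
    rows <- cpos + 1L
    sub <- mat[rows, , drop = FALSE]
    sub[as_t] <- "T"
    mat[rows, ] <- sub
  }
  if (cond$p_lesion > 0) {
    k <- stats::rbinom(1L, read_len * n, cond$p_lesion)
    if (k > 0) mat[sample.int(read_len * n, k)] <- "A"  # bypassed lesion, A-rule
  }
  mat
}

# Apply per-read substitution probabilities to a base matrix: each base of
# read i mutates with probability p[i], uniformly to one of the other three
# bases.
.mutate_bases <- function(mat, p) {
  n <- ncol(mat); L <- nrow(mat)
  k <- stats::rbinom(n, L, p)
  tot <- sum(k)
  if (tot == 0) return(mat)
  cols <- rep.int(seq_len(n), k)
  rows <- unlist(lapply(k[k > 0], function(ki) sample.int(L, ki)),
                 use.names = FALSE)
  idx <- cbind(rows, cols)
  cur <- mat[idx]
  alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                nrow = 4L, byrow = TRUE,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  mat[idx] <- alt[cbind(match(cur, rownames(alt)),
                        sample.int(3L, tot, replace = TRUE))]
  mat
}
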