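# Independent oracles used across the suite.

# Exhaustive full-matrix glocal DP (free reference prefix/suffix, read
# global, linear gaps) on three-letter collapsed strings. Row-vectorized:
# the left-gap dependency is a running maximum, computed as a cummax on
# gap-shifted scores.
full_dp_score <- function(read, ref_converted, match = 1, mismatch = -2,
                          gap = -3) {
  r <- strsplit(chartr("C", "T", toupper(read)), "")[[1]]
  f <- strsplit(ref_converted, "")[[1]]
  m <- length(r); n <- length(f)
  prev <- rep(0, n + 1)
  for (i in 1:m) {
    sub <- ifelse(r[i] == f, match, mismatch)
    M <- pmax(prev[1:n] + sub, prev[2:(n + 1)] + gap)
    A <- c(i * gap, M) - gap * (0:n)
    prev <- cummax(A) + gap * (0:n)
  }
  as.integer(max(prev))
}

# Random read/reference alignment instance: a substring of the reference
# with substitutions and occasional indels (the read model the aligner is
# built for, scaled down).
random_aln_instance <- function() {
  bases <- c("A", "C", "G", "T")
  n <- sample(20:50, 1)
  m <- sample(5:(n - 2), 1)
  ref <- insilico_convert(paste(sample(bases, n, TRUE), collapse = ""))
  st <- sample(1:(n - m + 1), 1)
  rd <- strsplit(substr(ref$original, st, st + m - 1), "")[[1]]
  nsub <- rbinom(1, m, 0.05)
  if (nsub) rd[sample(m, nsub)] <- sample(bases, nsub, TRUE)
  if (runif(1) < 0.3 && m > 6) rd <- rd[-sample(m, 1)]
  if (runif(1) < 0.3) {
    p <- sample(length(rd), 1)
    rd <- append(rd, sample(bases, 1), p)
  }
  list(read = paste(rd, collapse = ""), ref = ref)
}

# Expected per-base PCR mutation probability of a sampled read, from the
# run's generation bookkeeping (mirrors the generative model's mean field).
expected_pcr_mut <- function(run) {
  gen <- run$gen_counts
  w <- gen / sum(gen)
  g <- matrix(rep(seq_len(ncol(gen)), each = nrow(gen)), nrow = nrow(gen))
  keep <- (1 - run$e_first) * rowSums(w * (1 - run$e_clean)^(g - 1))
  keep <- sum(keep)
  for (st in run$stages[-1]) keep <- keep * (1 - st$e / 2)^st$cycles
  1 - keep
}

# 4x4 substitution kernel: stay with prob 1-p, otherwise uniform over the
# other three bases.
sub_kernel <- function(p) {
  K <- matrix(p / 3, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
  diag(K) <- 1 - p
  K
}

# Analytic expectation of the pileup-level statistics for a treated_pool
# pipeline with no lesions/fragmentation: per-position observed-base
# distributions after conversion, PCR mutation and sequencing error, folded
# through the same exclusion rules as error_rates()/conversion_rate().
expected_pileup_stats <- function(run, read_len, seq_error) {
  pool <- run$strata[[1]]$pool
  tpl <- pool$template
  cond <- pool$cond
  pm <- expected_pcr_mut(run)
  K <- sub_kernel(seq_error) %*% sub_kernel(pm)  # O | true: K[obs, true]
  ch <- strsplit(substr(tpl$seq, 1, read_len), "")[[1]]
  meth <- rep(0, read_len)
  cpos <- as.integer(names(tpl$meth))
  sel <- cpos < read_len
  meth[cpos[sel] + 1] <- as.numeric(tpl$meth)[sel]
  num <- den <- 0           # error numerator/denominator (C-to-T excluded)
  conv_t <- conv_c <- 0     # conversion statistic at non-CpG Cs
  cpg <- data.frame(pos0 = integer(0), p_meth = numeric(0))
  for (i in seq_len(read_len)) {
    b <- ch[i]
    if (b != "C") {
      p_obs <- K[, b]
      num <- num + (1 - p_obs[[b]])
      den <- den + 1
    } else {
      r <- meth[i] + (1 - meth[i]) * (1 - cond$p_conv)  # P(true base C)
      p_obs <- K[, "C"] * r + K[, "T"] * (1 - r)
      num <- num + p_obs[["A"]] + p_obs[["G"]]
      den <- den + 1 - p_obs[["T"]]
      is_cpg <- (i - 1) %in% tpl$cpg_sites
      if (is_cpg) {
        cpg <- rbind(cpg, data.frame(
          pos0 = i - 1,
          p_meth = p_obs[["C"]] / (p_obs[["C"]] + p_obs[["T"]])))
      } else {
        conv_t <- conv_t + p_obs[["T"]]
        conv_c <- conv_c + p_obs[["C"]]
      }
    }
  }
  list(overall_error_pct = 100 * num / den,
       err_frac = num / den,
       counted_per_read = den,
       conversion_pct = 100 * conv_t / (conv_t + conv_c),
       cpg = cpg)
}
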