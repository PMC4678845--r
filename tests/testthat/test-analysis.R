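count_matrix <- function(n) {
  matrix(0, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
}

test_that("in-silico conversion replaces exactly the cytosines", {
  cr <- insilico_convert("ACGTCC")
  expect_identical(cr$converted, "ATGTTT")
  expect_identical(cr$cpg_sites, 1L)
  no_c <- insilico_convert("AGGTTA")
  expect_identical(no_c$converted, no_c$original)
  expect_length(no_c$cpg_sites, 0)
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  cr2 <- insilico_convert(seq)
  o <- strsplit(cr2$original, "")[[1]]
  v <- strsplit(cr2$converted, "")[[1]]
  expect_identical(which(o != v), which(o == "C"))  # set-equality scan
  expect_error(insilico_convert("ACGNT"), "position")
})

test_that("pileup depth bookkeeping is exact for single and overlapping reads", {
  ref <- insilico_convert("AGGTTAAGGTTAAGGT")
  a1 <- align_bisulfite("AGGTTAAG", ref)        # offset 0, length 8
  p1 <- build_pileup(list(a1), ref)
  expect_identical(p1$depth, c(rep(1, 8), rep(0, 8)))
  a2 <- align_bisulfite("TAAGGTTAAGGT", ref)    # offset 4, length 12
  p2 <- build_pileup(list(a1, a2), ref)
  expect_identical(p2$depth, c(rep(1, 4), rep(2, 4), rep(1, 8)))
  bad <- structure(list(offset = 0L, score = 1L, ref_pos = 99L,
                        read_pos = 0L, read = "A", identity = 1, rc = FALSE,
                        ref_name = ref$name), class = "bs_alignment")
  expect_error(build_pileup(list(bad), ref), "out of reference bounds")
})

test_that("error-free simulated reads pile up to the expected converted base", {
  tpl <- make_benchmark_template("custom", length = 100, n_c = 25, seed = 8)
  pool <- treated_pool(tpl, treatment_condition("CUSTOM", p_conv = 1,
                                                p_desulf = 1),
                       n0 = 1e4, seed = 1)
  run <- run_pcr(pool, polymerase_profile("CUSTOM"), cycles = 12, seed = 1)
  reads <- generate_reads(run, n_reads = 300, read_len = 100, seq_error = 0,
                          seed = 2)
  an <- analyze_reads(reads, insilico_convert(tpl), total_cycles = 12)
  pile <- an$pileup
  conv <- strsplit(insilico_convert(tpl)$converted, "")[[1]]
  maj <- c("A", "C", "G", "T")[max.col(as.matrix(pile[, c("A", "C", "G", "T")]))]
  expect_identical(maj, conv)
  expect_equal(an$errors$overall_error_pct, 0)
  expect_equal(an$errors$conversion_pct, 100)
})

test_that("CpG methylation fractions follow the base counts exactly", {
  ref <- insilico_convert("TACGATTACGTT")   # CpGs at 2 and 8
  m <- count_matrix(12)
  m[3, "C"] <- 20                            # all methylated
  m[9, "T"] <- 15                            # all converted
  m[9, "G"] <- 2                             # noise -> "other"
  rep <- cpg_methylation(pileup_from_counts(ref, m), min_depth = 10)
  expect_identical(rep$sites$cpg_index, 1:2)
  expect_equal(rep$sites$fraction, c(1, 0))
  expect_equal(rep$sites$other, c(0, 2))
  expect_false(any(rep$sites$low_depth))
  expect_equal(rep$global, 20 / 35)
  low <- cpg_methylation(pileup_from_counts(ref, m), min_depth = 30)
  expect_true(all(low$sites$low_depth))
})

test_that("simulated per-CpG methylation is recovered at depth", {
  tpl <- make_benchmark_template("custom", length = 80, n_c = 16, n_cpg = 3,
                                 cpg_meth = 0.7, seed = 4)
  pool <- treated_pool(tpl, treatment_condition("CUSTOM", p_conv = 1,
                                                p_desulf = 1),
                       n0 = 1e6, seed = 1)
  run <- run_pcr(pool, polymerase_profile("CUSTOM"), cycles = 15, seed = 1)
  reads <- generate_reads(run, n_reads = 10000, read_len = 80, seq_error = 0,
                          seed = 3)
  an <- analyze_reads(reads, insilico_convert(tpl), total_cycles = 15)
  se <- sqrt(0.7 * 0.3 / 10000)
  for (i in seq_len(nrow(an$methylation$sites)))
    expect_lt(abs(an$methylation$sites$fraction[i] - 0.7), 3 * se)
})

test_that("conversion statistic uses non-CpG cytosines only", {
  ref <- insilico_convert("TACGATCTACTT")   # CpG C at 2; non-CpG Cs at 6, 9
  m <- count_matrix(12)
  m[7, "T"] <- 49; m[7, "C"] <- 1
  m[10, "T"] <- 49; m[10, "C"] <- 1
  m[3, "C"] <- 50                            # methylated CpG, must not count
  expect_equal(conversion_rate(pileup_from_counts(ref, m)), 98)
  m2 <- count_matrix(12)
  m2[7, "T"] <- 10; m2[10, "T"] <- 10; m2[3, "C"] <- 99
  expect_equal(conversion_rate(pileup_from_counts(ref, m2)), 100)
  # no informative observations at eligible positions
  m3 <- count_matrix(12); m3[3, "C"] <- 5
  expect_warning(v <- conversion_rate(pileup_from_counts(ref, m3)),
                 "undefined")
  expect_true(is.na(v))
  ref_noc <- insilico_convert("TAGATTAGATTT")
  expect_error(conversion_rate(pileup_from_counts(ref_noc, count_matrix(12))),
               "no non-CpG cytosine")
})

test_that("error rates follow the exclusion rules with exact arithmetic", {
  # 10 original A/G/T positions, 100 observations each, 4 mismatches total
  ref <- insilico_convert("AGTAGTAGTA")
  m <- count_matrix(10)
  for (i in 1:10) m[i, substr(ref$original, i, i)] <- 100
  m[1, "A"] <- 96; m[1, "G"] <- 4
  er <- error_rates(pileup_from_counts(ref, m), total_cycles = 70)
  expect_equal(er$overall_error_pct, 0.4)
  expect_equal(er$per_cycle_rate, 0.004 / 70)
  expect_equal(signif(er$per_cycle_rate, 1), 6e-5)
  expect_equal(er$per_base_error[["A"]], 100 * 4 / 400)
  expect_equal(er$per_base_error[["G"]], 0)
  expect_equal(er$per_base_error[["T"]], 0)
  # per-cycle x cycles reproduces the cumulative fraction exactly
  expect_identical(er$per_cycle_rate * er$total_cycles,
                   er$overall_error_pct / 100)
  # 1.2% cumulative over 70 cycles
  m2 <- count_matrix(10)
  for (i in 1:10) m2[i, substr(ref$original, i, i)] <- 100
  m2[2, "G"] <- 88; m2[2, "C"] <- 12
  er2 <- error_rates(pileup_from_counts(ref, m2), total_cycles = 70)
  expect_equal(er2$overall_error_pct, 1.2)
  expect_equal(signif(er2$per_cycle_rate, 2), 1.7e-4)
  expect_error(error_rates(pileup_from_counts(ref, m), total_cycles = 0),
               "at least 1")
})

test_that("injected C-to-T events move conversion but never the error rate", {
  ref <- insilico_convert("ACTAGTACTA")     # non-CpG Cs at 1 and 7
  m <- count_matrix(10)
  for (i in 1:10) m[i, substr(ref$original, i, i)] <- 50
  m[2, "T"] <- 40; m[2, "C"] <- 10          # partial conversion
  m[4, "C"] <- 1; m[4, "A"] <- 49           # one genuine error at an A site
  base_er <- error_rates(pileup_from_counts(ref, m), total_cycles = 70)
  base_conv <- conversion_rate(pileup_from_counts(ref, m))
  m2 <- m
  m2[2, "T"] <- m2[2, "T"] + 500            # flood with extra C-to-T events
  m2[8, "T"] <- m2[8, "T"] + 250
  new_er <- error_rates(pileup_from_counts(ref, m2), total_cycles = 70)
  new_conv <- conversion_rate(pileup_from_counts(ref, m2))
  expect_identical(new_er$overall_error_pct, base_er$overall_error_pct)
  expect_identical(new_er$per_base_error, base_er$per_base_error)
  expect_false(isTRUE(all.equal(new_conv, base_conv)))
  expect_gt(new_conv, base_conv)
})

test_that("statistics are invariant to read order and pileup sharding", {
  tpl <- make_benchmark_template("custom", length = 90, n_c = 20, n_cpg = 2,
                                 cpg_meth = 0.5, seed = 10)
  pool <- treated_pool(tpl, treatment_condition("BS1", p_lesion = 0,
                                                p_frag = 0),
                       n0 = 1e4, seed = 1)
  run <- run_pcr(pool, taq_5d4_blend("5/1"), cycles = 15, seed = 1)
  reads <- as.character(generate_reads(run, n_reads = 400, read_len = 90,
                                       seq_error = 0.005, seed = 6))
  ref <- insilico_convert(tpl)
  alns <- lapply(reads, align_bisulfite, ref = ref)
  whole <- build_pileup(alns, ref)
  set.seed(9); perm <- sample(length(alns))
  shuffled <- build_pileup(alns[perm], ref)
  merged <- merge_pileups(build_pileup(alns[1:150], ref),
                          build_pileup(alns[151:400], ref))
  expect_equal(conversion_rate(whole), conversion_rate(shuffled))
  expect_equal(conversion_rate(whole), conversion_rate(merged))
  expect_equal(cpg_methylation(whole)$sites$fraction,
               cpg_methylation(merged)$sites$fraction)
  expect_identical(whole$T, merged$T)
})

test_that("cytosine content arithmetic matches direct counting", {
  expect_equal(c_content(paste0(strrep("C", 20), strrep("A", 140)))$pct, 12.5)
  r <- c_content(paste0(strrep("C", 101), strrep("T", 247)))
  expect_equal(r$count, 101)
  expect_equal(r$pct_display, 29.0)
  expect_equal(r$pct, 100 * 101 / 348)
  expect_equal(c_content(strrep("A", 30))$pct, 0)
  t1 <- make_benchmark_template("T1", seed = 1)
  expect_equal(c_content(t1$seq, window = t1$region)$pct, 40)
  expect_error(c_content("ACGT", window = c(2, 2)), "non-empty")
})

test_that("locus success summaries and blend unions are exact", {
  expect_equal(locus_success_summary(c(rep(TRUE, 15), rep(FALSE, 9)))$percent,
               62.5)
  expect_equal(locus_success_summary(rep(c(TRUE, FALSE), each = 12))$percent,
               50)
  expect_equal(locus_success_summary(rep(FALSE, 24))$percent, 0)
  # two blends amplifying 15 and 17 loci, union 18 of 24
  m <- matrix(FALSE, 24, 2)
  m[1:15, 1] <- TRUE
  m[c(1:14, 16:18), 2] <- TRUE
  expect_equal(sum(m[, 1]), 15); expect_equal(sum(m[, 2]), 17)
  expect_equal(locus_success_summary(m)$percent, 75)
})
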