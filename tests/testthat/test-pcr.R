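test_that("a zero-input reaction yields an absent Ct and an all-zero trajectory", {
  run <- run_pcr(NULL, polymerase_profile("TAQ"), cycles = 10, seed = 1)
  expect_true(is.na(run$ct))
  expect_identical(run$copies_per_cycle, rep(0, 10))
})

test_that("with bypass 1 and zero errors PCR is exact doubling up to the plateau cap", {
  s <- treated_strand(strrep("A", 50), count = 3)
  run <- run_pcr(s, polymerase_profile("CUSTOM"), cycles = 12, seed = 1,
                 cap = 1000)
  expect_identical(run$copies_per_cycle, pmin(1000, 3 * 2^(1:12)))
  expect_identical(run$total, 3 * 2^(1:12))  # analytic continuation beyond cap
})

test_that("Ct spacing between 10-fold dilutions equals log2(10) at efficiency 1", {
  mk <- function(n0) run_pcr(treated_strand(strrep("A", 50), count = n0),
                             polymerase_profile("CUSTOM"), cycles = 35,
                             seed = 1)$ct
  cts <- vapply(c(1e4, 1e5, 1e6), mk, numeric(1))
  expect_equal(cts[2] - cts[3], log2(10), tolerance = 1e-9)
  expect_equal(cts[1] - cts[2], log2(10), tolerance = 1e-9)
  expect_true(all(diff(cts) < 0))  # Ct non-increasing in input copies
})

test_that("Taq cannot amplify a fully sulphonated template; blends can", {
  tpl <- make_benchmark_template("custom", length = 348, n_c = 101,
                                 seed = 5, name = "regD")
  pool <- treated_pool(tpl, treatment_condition("WATER"), n0 = 1e6, seed = 1)
  for (t1 in c(0.5, 5, 10)) {
    rt <- run_pcr(pool, polymerase_profile("TAQ"), cycles = 35,
                  first_cycle_extension_min = t1, seed = 1)
    expect_true(is.na(rt$ct), info = paste("first cycle", t1, "min"))
  }
  for (ratio in c("5/1", "1/1")) {
    rb <- run_pcr(pool, taq_5d4_blend(ratio), cycles = 35,
                  first_cycle_extension_min = 10, seed = 1)
    expect_false(is.na(rb$ct), info = ratio)
  }
})

test_that("extended first-cycle extension rescues Taq on desulphonated templates", {
  tpl <- make_benchmark_template("custom", length = 348, n_c = 101,
                                 seed = 5, name = "regD")
  pool <- treated_pool(tpl, treatment_condition("BS1"), n0 = 1e6, seed = 1)
  std <- run_pcr(pool, polymerase_profile("TAQ"), cycles = 35, seed = 1)
  ext <- run_pcr(pool, polymerase_profile("TAQ"), cycles = 35,
                 first_cycle_extension_min = 10, seed = 1)
  blend <- run_pcr(pool, taq_5d4_blend("5/1"), cycles = 35, seed = 1)
  expect_true(is.na(std$ct))
  expect_false(is.na(ext$ct))
  expect_false(is.na(blend$ct))
  expect_lt(blend$ct, ext$ct)  # blends remain superior
})

test_that("Taq efficiency falls monotonically as template uracil content rises", {
  taq <- polymerase_profile("TAQ")
  base <- c(sample(c("A", "T"), 188, replace = TRUE), strsplit("GATTAGGTGAAG", "")[[1]])
  t_pos <- which(base == "T" & seq_along(base) <= 188)
  p <- vapply(seq(0, 0.95, by = 0.19), function(f) {
    ch <- base
    k <- floor(f * length(t_pos))
    if (k > 0) ch[t_pos[seq_len(k)]] <- "U"
    full_length_prob(treated_strand(paste(ch, collapse = ""),
                                    primer_start = 188L), taq, 0.5)
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("error-free reads reproduce the converted reference prefix exactly", {
  tpl <- make_benchmark_template("custom", length = 150, n_c = 40, seed = 3)
  pool <- treated_pool(tpl, treatment_condition("CUSTOM", p_conv = 1,
                                                p_desulf = 1),
                       n0 = 1e4, seed = 1)
  pol <- polymerase_profile("CUSTOM")  # bypass 1, zero error
  run <- run_pcr(pool, pol, cycles = 15, seed = 1)
  reads <- generate_reads(run, n_reads = 50, read_len = 120, seq_error = 0,
                          seed = 1)
  conv_prefix <- substr(chartr("C", "T", tpl$seq), 1, 120)
  expect_true(all(as.character(reads) == conv_prefix))
  expect_true(all(Biostrings::width(reads) == 120))
})

test_that("sequencing errors recover their nominal rate", {
  s <- treated_strand(paste0(strrep("A", 138), "GATTAGGTGAAG"), count = 100)
  run <- run_pcr(s, polymerase_profile("CUSTOM"), cycles = 10, seed = 1)
  reads <- generate_reads(run, n_reads = 1000, read_len = 120,
                          seq_error = 0.01, seed = 4)
  ref <- substr(clean <- strrep("A", 120), 1, 120)
  mm <- vapply(as.character(reads), function(r)
    sum(strsplit(r, "")[[1]] != "A"), numeric(1))
  frac <- sum(mm) / (1000 * 120)
  se <- sqrt(0.01 * 0.99 / (1000 * 120))
  expect_lt(abs(frac - 0.01), 3 * se)
})

test_that("reads longer than the amplicon are rejected; empty pools warn", {
  s <- treated_strand(strrep("A", 60), count = 10)
  run <- run_pcr(s, polymerase_profile("CUSTOM"), cycles = 5, seed = 1)
  expect_error(generate_reads(run, n_reads = 10, read_len = 100, seed = 1),
               "exceeds amplicon length")
  empty <- run_pcr(treated_strand(strrep("S", 50), count = 10,
                                  primer_start = 50L),
                   polymerase_profile("TAQ", bypass = c(S = 0)),
                   cycles = 10, seed = 1)
  expect_warning(r0 <- generate_reads(empty, n_reads = 10, read_len = 40,
                                      seed = 1), "no amplifiable copies")
  expect_length(r0, 0)
})
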