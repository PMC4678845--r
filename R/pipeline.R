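#' Configuration of an end-to-end simulation + analysis run
#'
#' Collects every knob of the pipeline in one validated object. The cycle
#' schedule mirrors a typical nested amplicon library build -- a first PCR
#' from the treated material, a nested re-amplification, and an
#' indexing/adaptor PCR -- and `total_cycles` is always the sum of the three
#' parts (default 20 + 30 + 20 = 70), which is the denominator of the
#' per-cycle error rate.
#'
#' @param seed master seed; all stage substreams derive from it (see
#'   [substream_seed()]).
#' @param condition a [treatment_condition] or preset name.
#' @param pol a [polymerase_profile]/[polymerase_blend], a profile preset
#'   name, or a blend ratio (`"10/1"`, `"5/1"`, `"1/1"`).
#' @param template a [methylated_template]; by default a 350 nt amplicon
#'   with 10 CpG sites is generated.
#' @param template_length,template_n_c,template_n_cpg,cpg_meth parameters of
#'   the default template.
#' @param n_input input molecule count of the first PCR.
#' @param cycles_first,cycles_nested,cycles_index the cycle schedule.
#' @param first_cycle_extension_min optional extended first-cycle
#'   annealing/extension (minutes).
#' @param n_reads,read_len,seq_error read-generation settings.
#' @param outdir output directory for [run_end_to_end()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, condition = "BS1", pol = "5/1",
                       template = NULL, template_length = 350L,
                       template_n_c = 90L, template_n_cpg = 10L,
                       cpg_meth = 0.8, n_input = 1e6,
                       cycles_first = 20L, cycles_nested = 30L,
                       cycles_index = 20L,
                       first_cycle_extension_min = NULL,
                       n_reads = 10000L, read_len = 120L, seq_error = 0.001,
                       outdir = tempfile("bsamplicon_run_")) {
  if (is.character(condition)) condition <- treatment_condition(condition)
  if (is.character(pol)) {
    pol <- if (pol %in% c("10/1", "5/1", "1/1")) taq_5d4_blend(pol)
    else polymerase_profile(pol)
  }
  if (is.null(template))
    template <- make_benchmark_template("custom", length = template_length,
                                        n_c = template_n_c,
                                        n_cpg = template_n_cpg,
                                        cpg_meth = cpg_meth, seed = seed,
                                        name = "amplicon1")
  cfg <- list(seed = as.integer(seed), condition = condition, pol = pol,
              template = template, n_input = n_input,
              cycles_first = as.integer(cycles_first),
              cycles_nested = as.integer(cycles_nested),
              cycles_index = as.integer(cycles_index),
              first_cycle_extension_min = first_cycle_extension_min,
              n_reads = as.integer(n_reads), read_len = as.integer(read_len),
              seq_error = seq_error, outdir = outdir)
  cfg$total_cycles <- cfg$cycles_first + cfg$cycles_nested + cfg$cycles_index
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "run_config: seed %d, condition %s, template '%s' (%d nt), %d+%d+%d cycles, %d reads\n",
    x$seed, x$condition$name, x$template$name, nchar(x$template$seq),
    x$cycles_first, x$cycles_nested, x$cycles_index, x$n_reads))
  invisible(x)
}

#' Run the whole pipeline: treatment, PCR, reads, analysis
#'
#' Executes the simulation and analysis end to end and writes every
#' artifact under `config$outdir`: the template FASTA + methylation TSV, a
#' representative treated strand (seven-letter FASTA + fragment TSV), the
#' reads FASTQ, the methylation/error TSVs and JSON summary, and a
#' provenance record echoing the configuration and the derived substream
#' seeds. Identical configurations produce byte-identical report files.
#'
#' @param config a [run_config()].
#' @param seeds optional named overrides for individual substream seeds
#'   (e.g. `list(reads = 99L)`) -- changing one stage's stream leaves the
#'   upstream artifacts untouched.
#' @return An object of class `pipeline_result`: `analysis`
#'   ([analyze_reads()] result), `run` (the [run_pcr()] object), `reads`,
#'   `files` (paths written).
#' @examples
#' \donttest{
#' cfg <- run_config(seed = 1, n_input = 1e4, n_reads = 200,
#'                   template_length = 150, template_n_c = 35,
#'                   template_n_cpg = 4)
#' res <- run_end_to_end(cfg)
#' res$analysis$errors$conversion_pct
#' }
#' @export
run_end_to_end <- function(config, seeds = list()) {
  stopifnot(inherits(config, "run_config"))
  sd <- function(stream) {
    if (!is.null(seeds[[stream]])) seeds[[stream]]
    else config$seed
  }
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tpl <- config$template
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  files <- character(0)
  # --- treatment ---------------------------------------------------------
  pool <- stage("treatment",
                treated_pool(tpl, config$condition, n0 = config$n_input,
                             seed = sd("treatment")))
  stage("treatment", {
    write_templates(list(tpl), file.path(outdir, "templates.fa"),
                    file.path(outdir, "templates_meth.tsv"))
    write_treated(pool$reps[[1L]], file.path(outdir, "treated_rep.fa"),
                  file.path(outdir, "treated_rep_fragments.tsv"))
  })
  files <- c(files, file.path(outdir, c("templates.fa", "templates_meth.tsv",
                                        "treated_rep.fa",
                                        "treated_rep_fragments.tsv")))
  # --- PCR (first round + nested + indexing) -----------------------------
  run <- stage("pcr", {
    r <- run_pcr(pool, config$pol, cycles = config$cycles_first,
                 first_cycle_extension_min = config$first_cycle_extension_min,
                 seed = sd("pcr"))
    r <- continue_pcr(r, polymerase_profile("TAQ"), config$cycles_nested)
    continue_pcr(r, polymerase_profile("TAQ"), config$cycles_index)
  })
  jsonlite::write_json(
    list(cycles = run$cycles,
         ct = if (is.na(run$ct)) NULL else run$ct,
         trajectory = run$copies_per_cycle),
    file.path(outdir, "pcr_run.json"), auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE)
  files <- c(files, file.path(outdir, "pcr_run.json"))
  # --- reads -------------------------------------------------------------
  reads <- stage("reads", {
    if (sum(run$gen_counts) <= 0) Biostrings::DNAStringSet()
    else generate_reads(run, n_reads = config$n_reads,
                        read_len = config$read_len,
                        seq_error = config$seq_error, seed = sd("reads"))
  })
  write_fastq(reads, file.path(outdir, "reads.fq"))
  files <- c(files, file.path(outdir, "reads.fq"))
  # --- analysis ----------------------------------------------------------
  analysis <- stage("analysis",
                    analyze_reads(reads, insilico_convert(tpl),
                                  total_cycles = config$total_cycles))
  files <- c(files, write_reports(analysis, outdir, prefix = tpl$name))
  # --- provenance --------------------------------------------------------
  prov <- list(
    package = "bsamplicon",
    version = as.character(utils::packageVersion("bsamplicon")),
    master_seed = config$seed,
    substream_seeds = list(
      treatment = substream_seed(sd("treatment"), "treatment"),
      pcr = substream_seed(sd("pcr"), "pcr"),
      reads = substream_seed(sd("reads"), "reads")),
    condition = unclass(config$condition),
    cycles = c(first = config$cycles_first, nested = config$cycles_nested,
               indexing = config$cycles_index),
    n_input = config$n_input, n_reads = config$n_reads,
    read_len = config$read_len, seq_error = config$seq_error)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(outdir, "provenance.json"))
  structure(list(analysis = analysis, run = run, reads = reads,
                 files = files, outdir = outdir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result in", x$outdir, "\n")
  print(x$analysis)
  invisible(x)
}
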