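#' Read and write amplicon templates
#'
#' Templates travel as a plain FASTA file plus a sidecar TSV of methylation
#' annotations (`template`, `pos` 0-based, `meth` probability). Cytosines
#' absent from the sidecar default to unmethylated, matching the assumption
#' behind the conversion statistic.
#'
#' @param templates list of [methylated_template] objects.
#' @param fasta,meth_tsv file paths.
#' @return `write_templates` invisibly returns the paths; `read_templates`
#'   returns a named list of templates.
#' @export
write_templates <- function(templates, fasta, meth_tsv = NULL) {
  if (inherits(templates, "methylated_template")) templates <- list(templates)
  seqs <- Biostrings::DNAStringSet(vapply(templates, `[[`, character(1), "seq"))
  names(seqs) <- vapply(templates, `[[`, character(1), "name")
  Biostrings::writeXStringSet(seqs, fasta)
  if (!is.null(meth_tsv)) {
    rows <- do.call(rbind, lapply(templates, function(t)
      data.frame(template = t$name,
                 pos = as.integer(names(t$meth)),
                 meth = as.numeric(t$meth))))
    utils::write.table(rows, meth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(fasta, meth_tsv))
}

#' @rdname write_templates
#' @export
read_templates <- function(fasta, meth_tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ann <- if (!is.null(meth_tsv))
    utils::read.table(meth_tsv, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE) else NULL
  out <- lapply(seq_along(seqs), function(i) {
    nm <- names(seqs)[i]
    meth <- NULL
    if (!is.null(ann)) {
      rows <- ann[ann$template == nm, , drop = FALSE]
      if (nrow(rows)) meth <- setNames(rows$meth, rows$pos)
    }
    methylated_template(as.character(seqs[[i]]), name = nm, meth = meth)
  })
  names(out) <- names(seqs)
  out
}

#' Read and write treated strands
#'
#' A treated strand is serialized as FASTA over the seven-letter
#' `ACGTUSX` alphabet plus a BED-like TSV of surviving fragments
#' (`source`, `start`, `end`; 0-based half-open).
#'
#' @param strand a [treated_strand].
#' @param fasta,fragments_tsv file paths.
#' @export
write_treated <- function(strand, fasta, fragments_tsv = NULL) {
  stopifnot(inherits(strand, "treated_strand"))
  x <- Biostrings::BStringSet(strand$states)
  names(x) <- strand$source
  Biostrings::writeXStringSet(x, fasta)
  if (!is.null(fragments_tsv)) {
    f <- do.call(rbind, strand$fragments)
    utils::write.table(data.frame(source = strand$source,
                                  start = f[, 1L], end = f[, 2L]),
                       fragments_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(fasta, fragments_tsv))
}

#' @rdname write_treated
#' @export
read_treated <- function(fasta, fragments_tsv = NULL) {
  x <- Biostrings::readBStringSet(fasta)
  frags <- NULL
  if (!is.null(fragments_tsv)) {
    f <- utils::read.table(fragments_tsv, sep = "\t", header = TRUE)
    frags <- Map(c, f$start, f$end)
  }
  treated_strand(as.character(x[[1L]]), source = names(x)[1L],
                 fragments = frags)
}

#' Write reads as FASTQ
#'
#' Standard 4-line FASTQ records with constant placeholder qualities
#' (`I` = Phred+33 Q40, matching the simulator's flat error model).
#'
#' @param reads a `DNAStringSet` (e.g. from [generate_reads()]).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  if (!length(reads)) {
    file.create(path)
    return(invisible(path))
  }
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0) return(Biostrings::DNAStringSet())
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write analysis reports to TSV
#'
#' @param analysis a [analyze_reads()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, defaulting to the amplicon name.
#' @return Invisibly, the paths written: `<prefix>_methylation.tsv`
#'   (amplicon, cpg_index, pos0, meth_count, unmeth_count, other, fraction,
#'   low_depth), `<prefix>_errors.tsv` and `<prefix>_summary.json`.
#' @export
write_reports <- function(analysis, dir, prefix = NULL) {
  stopifnot(inherits(analysis, "bs_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  amp <- analysis$methylation$amplicon
  if (is.null(prefix)) prefix <- amp
  meth_path <- file.path(dir, paste0(prefix, "_methylation.tsv"))
  err_path <- file.path(dir, paste0(prefix, "_errors.tsv"))
  json_path <- file.path(dir, paste0(prefix, "_summary.json"))
  m <- analysis$methylation$sites
  m <- cbind(amplicon = amp, m)
  utils::write.table(m, meth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  e <- analysis$errors
  edf <- if (is.null(e)) {
    data.frame(amplicon = amp, conversion_pct = NA, overall_error_pct = NA,
               errA = NA, errG = NA, errT = NA, per_cycle_rate = NA,
               total_cycles = NA)
  } else {
    data.frame(amplicon = amp,
               conversion_pct = e$conversion_pct,
               overall_error_pct = e$overall_error_pct,
               errA = e$per_base_error[["A"]],
               errG = e$per_base_error[["G"]],
               errT = e$per_base_error[["T"]],
               per_cycle_rate = e$per_cycle_rate,
               total_cycles = e$total_cycles)
  }
  utils::write.table(edf, err_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(amplicon = amp,
                  n_reads = analysis$n_reads,
                  n_aligned = analysis$n_aligned,
                  n_filtered = analysis$n_filtered,
                  global_methylation = analysis$methylation$global,
                  conversion_pct = if (is.null(e)) NA else e$conversion_pct,
                  overall_error_pct = if (is.null(e)) NA else e$overall_error_pct)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(meth_path, err_path, json_path))
}
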