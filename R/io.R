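# Plain-text serialisation: BED6 for fragment sets, TSV for bin tables,
# YAML for sample specs, JSON for metrics reports.

#' Write a fragment-mode sample as BED6
#'
#' Columns: chrom, start, end, name, score, strand.  The name carries the
#' ground-truth origin label with a `":dup"` suffix for duplicates; the
#' score is the mapping quality; the strand is always `"+"`.  Fragment ends
#' are rounded to integer bp on export (insert lengths are continuous in
#' memory), so a re-imported set can differ at window boundaries by less
#' than half a base.
#'
#' @param sample A fragment-mode [fragment_set].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(sample, path) {
  if (!inherits(sample, "fragment_set") || sample$mode != "fragment")
    stop("'sample' must be a fragment-mode fragment_set", call. = FALSE)
  fr <- sample$fragments
  bed <- data.frame(
    chrom = as.character(fr$chrom),
    start = as.integer(fr$start),
    end = as.integer(fr$start + round(fr$length)),
    name = paste0(fr$origin, ifelse(fr$duplicate, ":dup", "")),
    score = fr$mapq,
    strand = "+"
  )
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED6 fragment file back into a fragment set
#'
#' @param path BED file written by [write_fragments_bed()].
#' @param genome The genome model the fragments live on.
#' @param model The length model to attach (for count-mode style operations).
#' @param sample_id Identifier for the resulting set.
#' @return A fragment-mode `fragment_set` (lengths integer bp).
#' @export
read_fragments_bed <- function(path, genome, model = length_model(),
                               sample_id = basename(path)) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  dup <- grepl(":dup$", bed$name)
  origin <- sub(":dup$", "", bed$name)
  frags <- data.frame(
    chrom = factor(bed$chrom, levels = names(genome$chrom_lengths)),
    start = as.numeric(bed$start),
    length = as.numeric(bed$end - bed$start),
    origin = origin, mapq = as.integer(bed$score), duplicate = dup
  )
  structure(list(
    sample_id = sample_id, mode = "fragment", counts = NULL,
    fragments = frags, genome = genome, model = model, spec = NULL,
    provenance = "imported", selection = NULL, n_total = nrow(frags),
    gc_beta = NA_real_
  ), class = "fragment_set")
}

#' Write / read a bin table as TSV
#'
#' @param table A `bin_table`.
#' @param path File path.
#' @return `path` invisibly (write) or a `bin_table` (read).
#' @export
write_bin_table <- function(table, path) {
  if (!inherits(table, "bin_table")) stop("'table' must be a bin_table", call. = FALSE)
  out <- as.data.frame(table)
  out$chrom <- as.character(out$chrom)
  attr(out, "autosomes") <- NULL
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_bin_table
#' @param autosomes Autosome names to attach on read.
#' @export
read_bin_table <- function(path, autosomes = paste0("chr", 1:22)) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  attr(df, "autosomes") <- autosomes
  class(df) <- c("bin_table", "data.frame")
  df
}

#' Write / read a sample spec as YAML
#'
#' @param spec A [sample_spec()].
#' @param path File path.
#' @return `path` invisibly (write) or a `sample_spec` (read).
#' @export
write_sample_spec <- function(spec, path) {
  if (!inherits(spec, "sample_spec")) stop("'spec' must be a sample_spec", call. = FALSE)
  lst <- unclass(spec)
  if (!is.null(lst$maternal_cnv)) lst$maternal_cnv <- as.list(lst$maternal_cnv)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sample_spec
#' @export
read_sample_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  cnv <- if (!is.null(lst$maternal_cnv)) as.data.frame(lst$maternal_cnv) else NULL
  sample_spec(ff = lst$ff, fetal_sex = lst$fetal_sex,
              aneuploidy = lst$aneuploidy, mosaicism = lst$mosaicism,
              maternal_cnv = cnv, n_fragments = lst$n_fragments,
              seed = lst$seed, sample_id = lst$sample_id)
}

#' Write a metrics report as JSON (summary) plus a per-sample TSV
#'
#' @param report A `metrics_report`.
#' @param path JSON output path; the per-sample table goes to the same path
#'   with a `.tsv` extension.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  if (!inherits(report, "metrics_report")) stop("'report' must be a metrics_report", call. = FALSE)
  jsonlite::write_json(
    list(experiment = report$experiment, config = report$config,
         summary = report$summary),
    path, auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE
  )
  if (is.data.frame(report$per_sample))
    data.table::fwrite(report$per_sample, sub("\\.json$", ".tsv", path), sep = "\t")
  invisible(path)
}
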