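#' Plain-text readers and writers for pipeline inputs
#'
#' All pipeline I/O is plain text: growth records as CSV (`age_days`,
#' `weight_kg`), counts as TSV (`gene_id` + one column per library),
#' samples sheets as CSV (`library_id`, `stage`, `replicate`), annotations
#' and intervals as BED-like TSV (0-based half-open), Ct tables as CSV.
#'
#' @param path File path.
#' @return A tibble (readers) or the path, invisibly (writers).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_growth_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  validate_growth_data(d)
}

#' @rdname pipeline_io
#' @param data Data frame to write.
#' @export
write_growth_csv <- function(data, path) {
  utils::write.csv(data[, c("age_days", "weight_kg")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_counts_tsv <- function(path) {
  d <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
  as_gene_matrix(d)  # validation only
  d
}

#' @rdname pipeline_io
#' @export
write_counts_tsv <- function(data, path) {
  utils::write.table(data, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_samples_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("library_id", "stage") %in% names(d)))
  d
}

#' @rdname pipeline_io
#' @export
write_samples_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @details `read_annotation_bed()` expects columns chrom, start, end, name
#'   and a 5th column with the exonic length in bp; `read_intervals_bed()`
#'   reads chrom, start, end and an optional name column (gene id or QTL
#'   trait) and a 5th id/stage column.
#' @export
read_annotation_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE)
  stopifnot(ncol(d) >= 5)
  tibble::tibble(gene_id = as.character(d[[4]]), chromosome = d[[1]],
                 start = d[[2]], end = d[[3]], exonic_length_bp = d[[5]])
}

#' @rdname pipeline_io
#' @param annotation Annotation tibble (`gene_id`, `chromosome`, `start`,
#'   `end`, `exonic_length_bp`).
#' @export
write_annotation_bed <- function(annotation, path) {
  utils::write.table(
    annotation[, c("chromosome", "start", "end", "gene_id",
                   "exonic_length_bp")],
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_intervals_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE)
  stopifnot(ncol(d) >= 3)
  out <- tibble::tibble(chromosome = d[[1]], start = d[[2]], end = d[[3]])
  if (ncol(d) >= 4) out$name <- as.character(d[[4]])
  if (ncol(d) >= 5) out$extra <- as.character(d[[5]])
  out
}

#' @rdname pipeline_io
#' @param intervals Tibble with `chromosome`, `start`, `end` and optional
#'   further columns, written in order.
#' @export
write_intervals_bed <- function(intervals, path) {
  cols <- c("chromosome", "start", "end",
            setdiff(names(intervals), c("chromosome", "start", "end")))
  utils::write.table(intervals[, cols], path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE, na = ".")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ct_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("condition", "gene_id", "ct") %in% names(d)))
  d
}

#' @rdname pipeline_io
#' @export
write_ct_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a complete synthetic input bundle
#'
#' Materialises one synthetic dataset per pipeline input: growth records,
#' counts with samples sheet and annotation, gene/QTL interval catalogues,
#' a DEG truth table and a Ct table. Regenerating with the same configs
#' yields byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param growth,counts,qtl,ct Config objects from [growth_sim_config()],
#'   [count_sim_config()], [qtl_sim_config()], [ct_sim_config()].
#' @return Named character vector of written file paths, invisibly.
#' @export
write_simulation_bundle <- function(dir,
                                    growth = growth_sim_config(),
                                    counts = count_sim_config(),
                                    qtl = qtl_sim_config(),
                                    ct = ct_sim_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  sim <- simulate_counts(counts)
  db <- simulate_qtl_db(qtl)
  write_growth_csv(simulate_growth(growth), p("growth.csv"))
  write_counts_tsv(sim$counts, p("counts.tsv"))
  write_samples_csv(sim$samples, p("samples.csv"))
  write_annotation_bed(sim$annotation, p("annotation.bed"))
  utils::write.table(sim$truth, p("deg_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_intervals_bed(db$genes[, c("chromosome", "start", "end", "gene_id",
                                   "stage_specific")], p("genes.bed"))
  write_intervals_bed(db$qtls[, c("chromosome", "start", "end", "trait",
                                  "qtl_id")], p("qtl.bed"))
  write_ct_csv(simulate_ct_table(ct), p("ct.csv"))
  files <- c(growth = p("growth.csv"), counts = p("counts.tsv"),
             samples = p("samples.csv"), annotation = p("annotation.bed"),
             deg_truth = p("deg_truth.tsv"), genes = p("genes.bed"),
             qtl = p("qtl.bed"), ct = p("ct.csv"))
  invisible(files)
}
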