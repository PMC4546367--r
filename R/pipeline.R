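#' Pipeline configuration
#'
#' Collects input paths, analysis thresholds and the seed for a full
#' [run_pipeline()] execution. Every input is optional: stages whose inputs
#' are absent are skipped and recorded as such in the report. Thresholds
#' default to the conjunctive DEG rule (p <= 0.05, |log2FC| >= 1), the
#' EASE significance cutoff 0.05 and the 2 Mb QTL length filter.
#'
#' @param growth_csv,counts_tsv,samples_csv,annotation_bed Input paths.
#' @param gene_sets_gmt,genes_bed,qtl_bed,ct_csv More input paths.
#' @param qpcr_target,qpcr_references qPCR gene ids for the ddCt stage.
#' @param mito_genes,nuclear_gene Gene ids for the mtDNA copy stage.
#' @param p_cutoff,lfc_cutoff,ease_cutoff,qtl_max_len_bp Thresholds.
#' @param seed Integer seed used for every stochastic step.
#' @param outdir Output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(growth_csv = NULL, counts_tsv = NULL,
                            samples_csv = NULL, annotation_bed = NULL,
                            gene_sets_gmt = NULL, genes_bed = NULL,
                            qtl_bed = NULL, ct_csv = NULL,
                            qpcr_target = NULL,
                            qpcr_references = c("ACTB", "TBP", "TOP2B"),
                            mito_genes = c("ATP6", "COX1", "ND1"),
                            nuclear_gene = "GCG",
                            p_cutoff = 0.05, lfc_cutoff = 1,
                            ease_cutoff = 0.05, qtl_max_len_bp = 2e6,
                            seed = 1L, outdir = "inflectr-output") {
  stopifnot(p_cutoff > 0, lfc_cutoff > 0, ease_cutoff > 0, qtl_max_len_bp > 0)
  paths <- list(growth_csv = growth_csv, counts_tsv = counts_tsv,
                samples_csv = samples_csv, annotation_bed = annotation_bed,
                gene_sets_gmt = gene_sets_gmt, genes_bed = genes_bed,
                qtl_bed = qtl_bed, ct_csv = ct_csv)
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]])) {
      stop("input file for `", nm, "` does not exist: ", paths[[nm]],
           call. = FALSE)
    }
  }
  structure(c(paths, list(
    qpcr_target = qpcr_target, qpcr_references = qpcr_references,
    mito_genes = mito_genes, nuclear_gene = nuclear_gene,
    p_cutoff = p_cutoff, lfc_cutoff = lfc_cutoff,
    ease_cutoff = ease_cutoff, qtl_max_len_bp = qtl_max_len_bp,
    seed = as.integer(seed), outdir = outdir
  )), class = "pipeline_config")
}

#' Run the full growth-inflection DGE pipeline
#'
#' Executes, for whichever inputs the config provides: growth-model fitting
#' and ranking; RPKM quantification with expressed-transcript summaries and
#' replicate correlations; DEG calling for every stage pair; gene-set
#' enrichment of each contrast's DEGs; QTL-overlap classification with
#' chi-square enrichment; and qPCR ddCt / mtDNA copy-number quantification.
#' Writes one TSV per result table, plus `report.json` carrying every
#' threshold, the seed, a config hash and per-stage summaries, and
#' `manifest.tsv` listing the files written. The same config and seed
#' reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The report, invisibly (a named list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  written <- character(0)
  note <- function(path) written <<- c(written, path)

  report <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    thresholds = list(p_cutoff = config$p_cutoff,
                      lfc_cutoff = config$lfc_cutoff,
                      ease_cutoff = config$ease_cutoff,
                      qtl_max_len_bp = config$qtl_max_len_bp),
    stages = list()
  )

  # growth
  if (!is.null(config$growth_csv)) {
    obs <- read_growth_csv(config$growth_csv)
    cmp <- compare_models(obs)
    utils::write.table(dplyr::select(cmp, -"message"), out("growth_models.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    note(out("growth_models.tsv"))
    best <- cmp[cmp$ok, , drop = FALSE][1, ]
    report$stages$growth <- list(
      n_obs = nrow(obs), best_model = best$model, r2 = best$r2,
      t_star_days = best$t_star_days, w_star_kg = best$w_star_kg,
      g_max_g_day = best$g_max_g_day
    )
  }

  counts <- samples <- annotation <- rpkm <- NULL
  if (!is.null(config$counts_tsv)) {
    if (is.null(config$samples_csv) || is.null(config$annotation_bed)) {
      stop("counts_tsv requires samples_csv and annotation_bed", call. = FALSE)
    }
    counts <- read_counts_tsv(config$counts_tsv)
    samples <- read_samples_csv(config$samples_csv)
    annotation <- read_annotation_bed(config$annotation_bed)

    rpkm <- compute_rpkm(counts, annotation)
    write_counts_tsv(rpkm, out("rpkm.tsv"))
    note(out("rpkm.tsv"))

    expressed <- expressed_transcripts(counts, samples)
    corr <- replicate_correlation(rpkm, samples)
    utils::write.table(corr, out("replicate_correlation.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note(out("replicate_correlation.tsv"))
    report$stages$quantify <- list(
      n_genes = nrow(counts), n_libraries = ncol(counts) - 1L,
      expressed = stats::setNames(as.list(expressed$counts$n_expressed),
                                  expressed$counts$stage),
      min_within_stage_r = suppressWarnings(
        min(corr$r[corr$within_stage %in% TRUE], na.rm = TRUE))
    )
  }

  # DEG calling for every stage pair
  if (!is.null(counts)) {
    stages <- unique(samples$stage)
    pairs <- utils::combn(stages, 2L, simplify = FALSE)
    deg_summary <- list()
    deg_tables <- list()
    for (pr in pairs) {
      ga <- samples$library_id[samples$stage == pr[1]]
      gb <- samples$library_id[samples$stage == pr[2]]
      degs <- call_degs(counts, annotation, ga, gb,
                        p_cutoff = config$p_cutoff,
                        lfc_cutoff = config$lfc_cutoff)
      nm <- paste0(pr[1], "_vs_", pr[2])
      f <- out(paste0("deg_", nm, ".tsv"))
      utils::write.table(degs, f, sep = "\t", row.names = FALSE, quote = FALSE)
      note(f)
      deg_tables[[nm]] <- degs
      deg_summary[[nm]] <- list(tested = nrow(degs), deg = sum(degs$is_deg))
    }
    report$stages$deg <- deg_summary

    # gene-set enrichment of each contrast's DEGs against all counted genes
    if (!is.null(config$gene_sets_gmt)) {
      sets <- read_gmt(config$gene_sets_gmt)
      background <- counts$gene_id
      enr_summary <- list()
      for (nm in names(deg_tables)) {
        deg_ids <- deg_tables[[nm]]$gene_id[deg_tables[[nm]]$is_deg]
        if (length(deg_ids) == 0) {
          enr_summary[[nm]] <- list(significant_terms = 0L)
          next
        }
        enr <- enrich(deg_ids, sets, background, cutoff = config$ease_cutoff)
        f <- out(paste0("enrichment_", nm, ".tsv"))
        utils::write.table(enr, f, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        note(f)
        enr_summary[[nm]] <- list(significant_terms = sum(enr$significant))
      }
      report$stages$enrich <- enr_summary
    }
  }

  # QTL overlap
  if (!is.null(config$genes_bed) && !is.null(config$qtl_bed)) {
    gb <- read_intervals_bed(config$genes_bed)
    genes <- tibble::tibble(gene_id = gb$name, chromosome = gb$chromosome,
                            start = gb$start, end = gb$end,
                            stage_specific = if ("extra" %in% names(gb))
                              ifelse(gb$extra == ".", NA_character_, gb$extra)
                            else NA_character_)
    qb <- read_intervals_bed(config$qtl_bed)
    qtls <- tibble::tibble(qtl_id = if ("extra" %in% names(qb)) qb$extra
                             else sprintf("QTL%04d", seq_len(nrow(qb))),
                           chromosome = qb$chromosome, start = qb$start,
                           end = qb$end,
                           trait = if ("name" %in% names(qb)) qb$name
                             else NA_character_)
    cls <- classify_specific_genes(genes, qtls,
                                   max_qtl_bp = config$qtl_max_len_bp)
    in_qtl <- cls$calls |>
      dplyr::filter(.data$qualifies) |>
      dplyr::distinct(.data$gene_id)
    all_in <- genes$gene_id %in% in_qtl$gene_id
    spec <- !is.na(genes$stage_specific)
    per_chrom <- cls$summary
    chi <- chi_square_enrichment(
      per_chrom$specific_in_qtl,
      per_chrom$specific_genes - per_chrom$specific_in_qtl,
      vapply(per_chrom$chromosome, function(ch)
        sum(all_in & genes$chromosome == ch), integer(1)),
      vapply(per_chrom$chromosome, function(ch)
        sum(!all_in & genes$chromosome == ch), integer(1)),
      chromosome = per_chrom$chromosome
    )
    utils::write.table(cls$calls, out("qtl_calls.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note(out("qtl_calls.tsv"))
    summary_tab <- dplyr::left_join(per_chrom, chi, by = "chromosome")
    utils::write.table(summary_tab, out("qtl_summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note(out("qtl_summary.tsv"))
    report$stages$qtl <- list(
      specific_genes = sum(spec),
      specific_in_qtl = sum(spec & all_in),
      fraction_in_qtl = if (sum(spec) > 0) sum(spec & all_in) / sum(spec)
        else NA_real_
    )
  }

  # qPCR
  if (!is.null(config$ct_csv)) {
    ct <- read_ct_csv(config$ct_csv)
    if (!is.null(config$qpcr_target)) {
      dd <- ddct_fold(ct, config$qpcr_target, config$qpcr_references)
      utils::write.table(dd, out("qpcr_ddct.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      note(out("qpcr_ddct.tsv"))
      report$stages$qpcr_ddct <- stats::setNames(as.list(dd$fold_change),
                                                 dd$condition)
    }
    if ("sample_id" %in% names(ct) &&
        any(config$mito_genes %in% ct$gene_id) &&
        config$nuclear_gene %in% ct$gene_id) {
      mt <- mtdna_copy(ct, config$mito_genes, config$nuclear_gene)
      utils::write.table(mt, out("qpcr_mtdna.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      note(out("qpcr_mtdna.tsv"))
      report$stages$qpcr_mtdna <- list(mean_copy_number = mean(mt$copy_number))
    }
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  note(out("report.json"))
  utils::write.table(tibble::tibble(file = basename(written)),
                     out("manifest.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(report)
}
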