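#' Overlap in bp between two genomic intervals
#'
#' Intervals are 0-based half-open; intervals on different chromosomes
#' overlap by 0.
#'
#' @param chrom_a,start_a,end_a First interval (vectorised).
#' @param chrom_b,start_b,end_b Second interval.
#' @return Non-negative overlap in bp: `max(0, min(end) - max(start))`.
#' @examples
#' overlap_bp("chr1", 10000, 20000, "chr1", 15000, 25000)  # 5000
#' @export
overlap_bp <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  stopifnot(all(end_a > start_a), all(end_b > start_b))
  ov <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  ov[chrom_a != chrom_b] <- 0
  ov
}

#' QTL-gene qualification rule
#'
#' A gene qualifies as a QTL gene for a given QTL region when the region is
#' narrower than 2 Mb and the overlap covers at least half the length of
#' the gene or at least half the length of the QTL region ("at least half"
#' is inclusive). A region of 2 Mb or more can never yield a QTL gene: the
#' length filter is applied to the QTL before the overlap is evaluated.
#'
#' @param gene_start,gene_end Gene interval (bp, 0-based half-open).
#' @param qtl_start,qtl_end QTL interval on the same chromosome.
#' @param max_qtl_bp QTL length filter; default 2e6.
#' @return A one-row tibble `overlap_bp`, `qualifies`.
#' @export
qualifies_as_qtl_gene <- function(gene_start, gene_end, qtl_start, qtl_end,
                                  max_qtl_bp = 2e6) {
  ov <- overlap_bp("x", gene_start, gene_end, "x", qtl_start, qtl_end)
  gene_len <- gene_end - gene_start
  qtl_len <- qtl_end - qtl_start
  tibble::tibble(
    overlap_bp = ov,
    qualifies = qtl_len < max_qtl_bp &
      (ov >= gene_len / 2 | ov >= qtl_len / 2)
  )
}

#' Classify stage-specific genes against a QTL catalogue
#'
#' Pairs every gene with every overlapping QTL region (interval search via
#' IRanges), applies the [qualifies_as_qtl_gene()] rule, and summarises per
#' chromosome: total genes, stage-specific genes, stage-specific genes
#' qualifying as QTL genes (counted once per chromosome however many
#' regions they hit), and the merged length of qualifying QTL regions in
#' Mb (overlapping regions merged before summation).
#'
#' @param genes Tibble `gene_id`, `chromosome`, `start`, `end`, optionally
#'   `stage_specific` (stage label or NA).
#' @param qtls Tibble `qtl_id`, `chromosome`, `start`, `end`, optionally
#'   `trait`.
#' @param max_qtl_bp QTL length filter; default 2e6.
#' @return A list:
#'   * `calls`: tibble of all gene-QTL overlap pairs with `overlap_bp` and
#'     `qualifies`;
#'   * `summary`: per-chromosome tibble `chromosome`, `gene_number`,
#'     `specific_genes`, `specific_in_qtl`, `qtl_length_mb`. A chromosome
#'     present in `genes` but absent from `qtls` is retained (with a
#'     warning) with zero QTL columns.
#' @export
classify_specific_genes <- function(genes, qtls, max_qtl_bp = 2e6) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(genes)),
            all(c("chromosome", "start", "end") %in% names(qtls)))
  if (!"qtl_id" %in% names(qtls)) {
    qtls$qtl_id <- sprintf("QTL%04d", seq_len(nrow(qtls)))
  }
  if (!"stage_specific" %in% names(genes)) {
    genes$stage_specific <- NA_character_
  }
  stopifnot(all(genes$end > genes$start), all(qtls$end > qtls$start))

  orphan <- setdiff(genes$chromosome, qtls$chromosome)
  if (length(orphan) > 0) {
    warning("chromosome(s) with genes but no QTL: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }

  calls <- purrr::map(intersect(genes$chromosome, qtls$chromosome),
    function(chr) {
      g <- genes[genes$chromosome == chr, , drop = FALSE]
      q <- qtls[qtls$chromosome == chr, , drop = FALSE]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(g$start + 1, g$end),
        IRanges::IRanges(q$start + 1, q$end)
      )
      gi <- S4Vectors::queryHits(hits)
      qi <- S4Vectors::subjectHits(hits)
      if (length(gi) == 0) return(NULL)
      qual <- qualifies_as_qtl_gene(g$start[gi], g$end[gi],
                                    q$start[qi], q$end[qi], max_qtl_bp)
      tibble::tibble(
        gene_id = g$gene_id[gi], qtl_id = q$qtl_id[qi], chromosome = chr,
        stage_specific = g$stage_specific[gi],
        overlap_bp = qual$overlap_bp, qualifies = qual$qualifies
      )
    })
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls) == 0) {
    calls <- tibble::tibble(gene_id = character(), qtl_id = character(),
                            chromosome = character(),
                            stage_specific = character(),
                            overlap_bp = numeric(), qualifies = logical())
  }
  calls <- dplyr::arrange(calls, .data$gene_id, .data$qtl_id)

  qual_qtl <- qtls[qtls$end - qtls$start < max_qtl_bp, , drop = FALSE]
  summary <- genes |>
    dplyr::group_by(chromosome = .data$chromosome) |>
    dplyr::summarise(
      gene_number = dplyr::n(),
      specific_genes = sum(!is.na(.data$stage_specific)),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      calls |>
        dplyr::filter(.data$qualifies, !is.na(.data$stage_specific)) |>
        dplyr::distinct(.data$chromosome, .data$gene_id) |>
        dplyr::count(.data$chromosome, name = "specific_in_qtl"),
      by = "chromosome"
    ) |>
    dplyr::left_join(merged_qtl_mb(qual_qtl), by = "chromosome") |>
    dplyr::mutate(
      specific_in_qtl = dplyr::coalesce(.data$specific_in_qtl, 0L),
      qtl_length_mb = dplyr::coalesce(.data$qtl_length_mb, 0)
    ) |>
    dplyr::arrange(.data$chromosome)

  list(calls = calls, summary = summary)
}

# merged (union) length of QTL regions per chromosome, in Mb
merged_qtl_mb <- function(qtls) {
  if (nrow(qtls) == 0) {
    return(tibble::tibble(chromosome = character(), qtl_length_mb = numeric()))
  }
  qtls |>
    dplyr::group_by(chromosome = .data$chromosome) |>
    dplyr::group_modify(function(d, key) {
      r <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
      tibble::tibble(qtl_length_mb = sum(IRanges::width(r)) / 1e6)
    }) |>
    dplyr::ungroup()
}

#' Chi-square enrichment of stage-specific genes in QTL regions
#'
#' For each chromosome, tests the 2x2 table (stage-specific genes in / not
#' in QTL regions) against (background genes in / not in QTL regions) with
#' a 1-df chi-square without continuity correction, plus a pooled
#' genome-wide row. When any expected cell falls below 1 the exact
#' hypergeometric (Fisher) p-value is substituted and flagged.
#'
#' @param specific_in,specific_out Stage-specific gene counts inside /
#'   outside QTL regions (vectorised, one per chromosome).
#' @param background_in,background_out Background gene counts inside /
#'   outside QTL regions.
#' @param chromosome Optional labels for the output.
#' @return Tibble `chromosome`, `chi2`, `p_value`, `exact` (TRUE when the
#'   exact fallback was used). A final `overall` row pools all rows.
#' @export
chi_square_enrichment <- function(specific_in, specific_out,
                                  background_in, background_out,
                                  chromosome = NULL) {
  n <- length(specific_in)
  stopifnot(length(specific_out) == n, length(background_in) == n,
            length(background_out) == n)
  if (is.null(chromosome)) chromosome <- as.character(seq_len(n))

  test_one <- function(si, so, bi, bo) {
    tab <- matrix(c(si, so, bi, bo), nrow = 2, byrow = TRUE)
    if (any(tab < 0)) stop("negative cell count", call. = FALSE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0)) {
      return(tibble::tibble(chi2 = NA_real_, p_value = NA_real_,
                            exact = FALSE))
    }
    if (any(expected < 1)) {
      p <- stats::fisher.test(tab)$p.value
      return(tibble::tibble(chi2 = NA_real_, p_value = p, exact = TRUE))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(chi2 = unname(ct$statistic), p_value = ct$p.value,
                   exact = FALSE)
  }

  rows <- purrr::pmap(list(specific_in, specific_out, background_in,
                           background_out), test_one)
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble::tibble(chromosome = chromosome), out)
  pooled <- test_one(sum(specific_in), sum(specific_out),
                     sum(background_in), sum(background_out))
  dplyr::bind_rows(out,
                   dplyr::bind_cols(tibble::tibble(chromosome = "overall"),
                                    pooled))
}
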