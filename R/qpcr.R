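#' Relative expression by the 2^-ddCt method
#'
#' Quantifies a target gene's relative mRNA abundance across conditions
#' with multi-reference normalization. Per condition, replicate Ct values
#' are averaged per gene first; the reference Ct is the arithmetic mean of
#' the reference genes' mean Ct (averaging Ct, a log2 scale, is equivalent
#' to geometric-mean normalization of quantities). Then
#' `dCt = Ct_target - Ct_ref`, `ddCt = dCt - dCt_calibrator`, and
#' `fold_change = 2^-ddCt`; the calibrator condition has fold 1 by
#' construction.
#'
#' @param ct Tidy Ct tibble: `condition`, `gene_id`, `replicate`, `ct`
#'   (cycles; a `sample_id` column is allowed and ignored).
#' @param target Target gene id.
#' @param references Character vector of reference gene ids; each must be
#'   measured in every condition.
#' @param calibrator Calibrator condition; defaults to the first condition
#'   in the table.
#' @return Tibble `condition`, `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @examples
#' ct <- simulate_ct_table(ct_sim_config(ct_noise_sd = 0))
#' ddct_fold(ct, "TXNIP", c("ACTB", "TBP", "TOP2B"), calibrator = "BIP")
#' @export
ddct_fold <- function(ct, target, references, calibrator = NULL) {
  stopifnot(all(c("condition", "gene_id", "ct") %in% names(ct)),
            all(is.finite(ct$ct)), all(ct$ct > 0))
  conditions <- unique(ct$condition)
  if (is.null(calibrator)) calibrator <- conditions[1L]
  stopifnot(calibrator %in% conditions)

  mean_ct <- function(cond, gene) {
    v <- ct$ct[ct$condition == cond & ct$gene_id == gene]
    if (length(v) == 0) {
      stop("gene ", gene, " not measured in condition ", cond, call. = FALSE)
    }
    mean(v)
  }
  dct <- vapply(conditions, function(cond) {
    ref <- mean(vapply(references, function(g) mean_ct(cond, g), numeric(1)))
    mean_ct(cond, target) - ref
  }, numeric(1))
  ddct <- dct - dct[[calibrator]]
  tibble::tibble(condition = conditions, delta_ct = unname(dct),
                 delta_delta_ct = unname(ddct),
                 fold_change = 2^(-unname(ddct)))
}

#' Relative mtDNA copy number by 2^dCt
#'
#' Estimates mitochondrial genome abundance per diploid cell from the Ct
#' difference between a single-copy nuclear gene and each mitochondrial
#' gene within the same sample: `dCt = Ct_nuclear - Ct_mito` (mitochondrial
#' templates are more abundant, so they cross threshold earlier and the
#' difference is positive), `copy_number = 2^dCt`. The point estimate uses
#' replicate-mean Ct; the spread transforms each replicate pair
#' independently and reports mean and SD of the per-replicate copy numbers.
#'
#' @param ct Tidy Ct tibble: `sample_id`, `gene_id`, `replicate`, `ct`.
#' @param mito_genes Mitochondrial gene ids (e.g. ATP6, COX1, ND1).
#' @param nuclear_gene Single-copy nuclear gene id (e.g. GCG); must be
#'   measured in every sample.
#' @return Tibble `sample_id`, `mito_gene`, `delta_ct`, `copy_number`,
#'   `copy_mean`, `copy_sd` (mean and SD over replicates).
#' @export
mtdna_copy <- function(ct, mito_genes, nuclear_gene) {
  stopifnot(all(c("sample_id", "gene_id", "ct") %in% names(ct)),
            all(is.finite(ct$ct)), all(ct$ct > 0))
  if (!"replicate" %in% names(ct)) ct$replicate <- 1L
  samples <- unique(ct$sample_id)
  rows <- purrr::map(samples, function(s) {
    d <- ct[ct$sample_id == s, , drop = FALSE]
    nuc <- d[d$gene_id == nuclear_gene, , drop = FALSE]
    if (nrow(nuc) == 0) {
      stop("nuclear gene ", nuclear_gene, " not measured in sample ", s,
           call. = FALSE)
    }
    purrr::map(mito_genes, function(g) {
      mito <- d[d$gene_id == g, , drop = FALSE]
      if (nrow(mito) == 0) return(NULL)
      dct <- mean(nuc$ct) - mean(mito$ct)
      # per-replicate copy numbers (paired by replicate index where present)
      shared <- intersect(nuc$replicate, mito$replicate)
      reps <- if (length(shared) >= 1) {
        2^(nuc$ct[match(shared, nuc$replicate)] -
             mito$ct[match(shared, mito$replicate)])
      } else {
        2^dct
      }
      tibble::tibble(sample_id = s, mito_gene = g, delta_ct = dct,
                     copy_number = 2^dct, copy_mean = mean(reps),
                     copy_sd = stats::sd(reps))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
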