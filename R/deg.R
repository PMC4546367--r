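#' Pooled log2 fold change between two library groups
#'
#' Fold change is computed on mean RPKM per group with a small pseudocount
#' guarding zero expression:
#' `log2fc = log2((mean_RPKM_b + pseudocount) / (mean_RPKM_a + pseudocount))`.
#'
#' @param counts Count tibble (`gene_id` + library columns).
#' @param annotation Annotation with `gene_id`, `exonic_length_bp`.
#' @param group_a,group_b Character vectors of library ids; disjoint,
#'   non-empty.
#' @param pseudocount Added to both group means (RPKM units); default 0.001.
#' @return Tibble `gene_id`, `mean_rpkm_a`, `mean_rpkm_b`, `log2fc`
#'   (group_b over group_a).
#' @export
pooled_log2fc <- function(counts, annotation, group_a, group_b,
                          pseudocount = 0.001) {
  check_groups(counts, group_a, group_b)
  rpkm <- as_gene_matrix(compute_rpkm(counts, annotation), "expression")
  ma <- unname(rowMeans(rpkm[, group_a, drop = FALSE]))
  mb <- unname(rowMeans(rpkm[, group_b, drop = FALSE]))
  tibble::tibble(gene_id = rownames(rpkm), mean_rpkm_a = ma, mean_rpkm_b = mb,
                 log2fc = log2((mb + pseudocount) / (ma + pseudocount)))
}

check_groups <- function(counts, group_a, group_b) {
  libs <- setdiff(names(counts), "gene_id")
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  if (length(intersect(group_a, group_b)) > 0) {
    stop("contrast groups must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), libs)
  if (length(missing) > 0) {
    stop("unknown library id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Conditional exact test for a pooled count contrast
#'
#' Tests whether a gene's pooled tag count differs between two groups,
#' conditioning on the gene's total: under the null the count in group b is
#' Binomial(x_a + x_b, n_b / (n_a + n_b)) with n_a, n_b the pooled library
#' sizes (the classic exact test for digital expression tag counts). The
#' two-sided p-value sums the probabilities of all outcomes no more likely
#' than the observed one.
#'
#' @param x_a,x_b Pooled counts in group a / group b (vectorised).
#' @param n_a,n_b Pooled library sizes (> 0).
#' @return p-values in (0, 1].
#' @examples
#' exact_count_test(0, 20, 1e6, 1e6)  # = 2 * 0.5^20
#' @export
exact_count_test <- function(x_a, x_b, n_a, n_b) {
  stopifnot(n_a > 0, n_b > 0)
  if (any(x_a < 0) || any(x_b < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(c(x_a, x_b) != round(c(x_a, x_b)))) {
    stop("counts must be integers", call. = FALSE)
  }
  p0 <- n_b / (n_a + n_b)
  mapply(function(xa, xb) exact_count_test_one(xa + xb, xb, p0), x_a, x_b)
}

# two-sided outcome-probability rule for one Binomial(n, p0) observation,
# scanning only a central window and adding the (strictly less likely)
# far-tail masses in closed form
exact_count_test_one <- function(n, x_obs, p0) {
  if (n == 0) return(1)
  mu <- n * p0
  sd <- sqrt(n * p0 * (1 - p0))
  lo <- max(0, floor(mu - 12 * sd))
  hi <- min(n, ceiling(mu + 12 * sd))
  lo <- min(lo, x_obs)
  hi <- max(hi, x_obs)
  j <- lo:hi
  d <- stats::dbinom(j, n, p0)
  d_obs <- stats::dbinom(x_obs, n, p0)
  p <- sum(d[d <= d_obs * (1 + 1e-7)]) +
    stats::pbinom(lo - 1, n, p0) +
    stats::pbinom(hi, n, p0, lower.tail = FALSE)
  min(p, 1)
}

#' Call differentially expressed genes for a stage contrast
#'
#' Pools replicate libraries within each group, tests every gene expressed
#' in at least one of the two groups with [exact_count_test()], computes
#' pooled RPKM fold changes, and flags DEGs by the conjunctive rule
#' `p_value <= p_cutoff AND |log2fc| >= lfc_cutoff` (defaults 0.05 and 1).
#' No multiple-testing correction enters the call; a Benjamini-Hochberg
#' column `bh_q` is reported for information.
#'
#' @inheritParams pooled_log2fc
#' @param p_cutoff,lfc_cutoff DEG thresholds.
#' @return Tibble `gene_id`, `count_a`, `count_b`, `mean_rpkm_a`,
#'   `mean_rpkm_b`, `log2fc`, `p_value`, `bh_q`, `is_deg`. Genes with zero
#'   counts in both groups are excluded from testing.
#' @export
call_degs <- function(counts, annotation, group_a, group_b,
                      p_cutoff = 0.05, lfc_cutoff = 1, pseudocount = 0.001) {
  check_groups(counts, group_a, group_b)
  m <- as_gene_matrix(counts)
  xa <- unname(rowSums(m[, group_a, drop = FALSE]))
  xb <- unname(rowSums(m[, group_b, drop = FALSE]))
  na <- sum(m[, group_a, drop = FALSE])
  nb <- sum(m[, group_b, drop = FALSE])

  lfc <- pooled_log2fc(counts, annotation, group_a, group_b, pseudocount)
  keep <- (xa + xb) > 0
  out <- tibble::tibble(
    gene_id = rownames(m)[keep],
    count_a = xa[keep], count_b = xb[keep],
    mean_rpkm_a = lfc$mean_rpkm_a[keep], mean_rpkm_b = lfc$mean_rpkm_b[keep],
    log2fc = lfc$log2fc[keep],
    p_value = exact_count_test(xa[keep], xb[keep], na, nb)
  )
  out$bh_q <- bh_adjust(out$p_value)
  out$is_deg <- out$p_value <= p_cutoff & abs(out$log2fc) >= lfc_cutoff
  out
}

#' Hierarchical clustering of libraries on DEG expression
#'
#' Agglomerative (average-linkage) clustering of libraries with distance
#' `1 - Pearson r` computed on `log10(RPKM + 1)` over the supplied genes —
#' the standard check that biological replicates of each developmental
#' stage group together.
#'
#' @param expr Expression (RPKM) tibble.
#' @param gene_ids Optional subset of genes (e.g. the DEG union); default
#'   all.
#' @return An [stats::hclust] object over libraries.
#' @export
cluster_degs <- function(expr, gene_ids = NULL) {
  m <- as_gene_matrix(expr, "expression")
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, rownames(m))
    if (length(missing) > 0) {
      stop("gene(s) not in expression matrix: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    m <- m[gene_ids, , drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 genes and 2 libraries", call. = FALSE)
  }
  lg <- log10(m + 1)
  sds <- apply(lg, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression profile in library: ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(lg))
  stats::hclust(d, method = "average")
}
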