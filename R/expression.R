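#' @keywords internal
"_PACKAGE"

#' @import rlang
#' @importFrom dplyr .data
NULL

# counts/expression tibbles are gene_id plus one numeric column per library
as_gene_matrix <- function(x, what = "counts") {
  stopifnot(is.data.frame(x), "gene_id" %in% names(x))
  if (anyDuplicated(x$gene_id)) {
    stop("duplicate gene ids in ", what, " table", call. = FALSE)
  }
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  if (anyDuplicated(colnames(m))) {
    stop("duplicate library ids in ", what, " table", call. = FALSE)
  }
  if (!is.numeric(m) || any(m < 0) || anyNA(m)) {
    stop(what, " must be non-negative and complete", call. = FALSE)
  }
  rownames(m) <- x$gene_id
  m
}

gene_matrix_tibble <- function(m) {
  tibble::as_tibble(cbind(tibble::tibble(gene_id = rownames(m)),
                          as.data.frame(m, optional = TRUE)))
}

#' RPKM normalization of a tag-count matrix
#'
#' Converts raw tag counts to Reads Per Kilobase of exon model per Million
#' mapped reads: `RPKM = 1e9 * c / (N * L)`, with `c` the gene's count in a
#' library, `N` the library's total assigned reads and `L` the gene's exonic
#' length in bp. For single-end tag data RPKM and FPKM coincide (one read
#' per fragment), so a single unit is used throughout.
#'
#' When the annotation covers every counted gene, the normalization
#' conserves `sum(RPKM * L) = 1e9` within each library.
#'
#' @param counts Tibble: `gene_id` plus one non-negative integer column per
#'   library.
#' @param annotation Tibble with `gene_id` and `exonic_length_bp` (> 0)
#'   covering every gene in `counts`.
#' @return Tibble of the same shape as `counts` holding RPKM values.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", L1 = 1000L)
#' ann <- tibble::tibble(gene_id = "g1", exonic_length_bp = 1000)
#' compute_rpkm(counts, ann)  # 1000 reads over 1e3 bp in a 1e3-read library
#' @export
compute_rpkm <- function(counts, annotation) {
  m <- as_gene_matrix(counts)
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "exonic_length_bp") %in% names(annotation)))
  missing <- setdiff(rownames(m), annotation$gene_id)
  if (length(missing) > 0) {
    stop("no annotation for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
         call. = FALSE)
  }
  len <- annotation$exonic_length_bp[match(rownames(m), annotation$gene_id)]
  if (any(len <= 0)) stop("exonic lengths must be > 0", call. = FALSE)
  n_lib <- colSums(m)
  if (any(n_lib == 0)) {
    stop("library with zero total reads: ",
         paste(colnames(m)[n_lib == 0], collapse = ", "), call. = FALSE)
  }
  rpkm <- 1e9 * sweep(m / len, 2L, n_lib, "/")
  gene_matrix_tibble(rpkm)
}

#' Expressed-transcript sets per stage and overall
#'
#' A transcript is expressed in a stage if it has a non-zero count in at
#' least one library of that stage, and expressed overall if it is non-zero
#' in at least one library anywhere — a presence-based rule with no
#' abundance floor.
#'
#' @param counts Count tibble (see [compute_rpkm()]).
#' @param samples Tibble mapping `library_id` to `stage`.
#' @return A list:
#'   * `overall`: character vector of expressed gene ids;
#'   * `by_stage`: named list of per-stage expressed gene id vectors;
#'   * `counts`: tibble `stage`, `n_expressed` (plus an `overall` row);
#'   * `partition`: tibble of stage-membership combinations
#'     (one logical column per stage) with gene counts — the Venn partition.
#' @export
expressed_transcripts <- function(counts, samples) {
  m <- as_gene_matrix(counts)
  stopifnot(all(c("library_id", "stage") %in% names(samples)),
            all(colnames(m) %in% samples$library_id))
  stages <- unique(samples$stage)
  by_stage <- lapply(stages, function(s) {
    libs <- samples$library_id[samples$stage == s]
    libs <- intersect(libs, colnames(m))
    rownames(m)[rowSums(m[, libs, drop = FALSE] > 0) > 0]
  })
  names(by_stage) <- stages
  overall <- rownames(m)[rowSums(m > 0) > 0]

  membership <- vapply(by_stage, function(g) rownames(m) %in% g,
                       logical(nrow(m)))
  part <- tibble::as_tibble(as.data.frame(membership))
  part <- dplyr::count(part, dplyr::across(dplyr::everything()),
                       name = "n_genes")
  part <- part[rowSums(as.matrix(part[stages])) > 0, , drop = FALSE]

  list(
    overall = overall,
    by_stage = by_stage,
    counts = dplyr::bind_rows(
      tibble::tibble(stage = stages,
                     n_expressed = unname(lengths(by_stage))),
      tibble::tibble(stage = "overall", n_expressed = length(overall))
    ),
    partition = part
  )
}

#' Ranked abundance shares of one library
#'
#' Sorts a library's genes by count (ties broken by gene id) and reports
#' each gene's share of the library's tags and the cumulative share — the
#' summary behind statements like "the most abundant transcript holds 9.6%
#' of all tags and the top ten about 31%".
#'
#' @param counts Count tibble.
#' @param library Library (column) id.
#' @return Tibble `rank`, `gene_id`, `count`, `share`, `cumulative_share`.
#' @export
abundance_profile <- function(counts, library) {
  m <- as_gene_matrix(counts)
  stopifnot(library %in% colnames(m))
  v <- m[, library]
  total <- sum(v)
  if (total == 0) stop("library ", library, " is empty", call. = FALSE)
  ord <- order(-v, rownames(m))
  v <- unname(v)
  tibble::tibble(
    rank = seq_along(v),
    gene_id = rownames(m)[ord],
    count = v[ord],
    share = v[ord] / total,
    cumulative_share = cumsum(v[ord]) / total
  )
}

# one multivariate hypergeometric draw: k tags without replacement from a
# library with per-gene totals `counts`
rmvhyper_one <- function(counts, k) {
  n_rem <- sum(counts)
  k_rem <- k
  out <- integer(length(counts))
  for (g in seq_along(counts)) {
    if (k_rem == 0) break
    x <- stats::rhyper(1L, counts[g], n_rem - counts[g], k_rem)
    out[g] <- x
    k_rem <- k_rem - x
    n_rem <- n_rem - counts[g]
  }
  out
}

#' Sequencing-saturation curve by subsampling
#'
#' Estimates, for each target depth, the expected number of distinct genes
#' detected (>= 1 tag) when that many tags are drawn from the library
#' without replacement — the curve that flattens as a library approaches
#' saturation. Draws are multivariate hypergeometric since tags are reads
#' from a finite sequenced pool.
#'
#' @param counts Count tibble.
#' @param library Library id.
#' @param depths Numeric vector of subsampling depths, each `<=` the
#'   library total.
#' @param n_draws Monte-Carlo draws per depth.
#' @param seed Integer seed.
#' @return Tibble `depth`, `mean_detected`, `sd_detected`, `n_draws`.
#'   `depth = total` returns the exact detected-gene count with zero sd;
#'   `depth = 0` returns 0.
#' @export
saturation_curve <- function(counts, library, depths, n_draws = 20L,
                             seed = 1L) {
  m <- as_gene_matrix(counts)
  stopifnot(library %in% colnames(m), n_draws >= 1)
  v <- m[, library]
  total <- sum(v)
  if (any(depths < 0) || any(depths > total)) {
    stop("depths must lie in [0, library total = ", total, "]", call. = FALSE)
  }
  withr::with_seed(seed, {
    rows <- purrr::map(as.numeric(depths), function(d) {
      if (d == 0) {
        detected <- rep(0, n_draws)
      } else if (d == total) {
        detected <- rep(sum(v > 0), n_draws)
      } else {
        detected <- vapply(seq_len(n_draws),
                           function(i) sum(rmvhyper_one(v, d) > 0), numeric(1))
      }
      tibble::tibble(depth = d, mean_detected = mean(detected),
                     sd_detected = stats::sd(detected), n_draws = n_draws)
    })
    dplyr::bind_rows(rows)
  })
}

#' Pairwise replicate correlation on log expression
#'
#' Pearson correlation between every pair of libraries on
#' `log10(RPKM + offset)`, restricted to genes expressed (value > 0) in at
#' least one library of the pair. With a samples sheet the pair is labelled
#' within- or between-stage, the check behind "biological replicates of each
#' stage correlate at r > 0.96".
#'
#' @param expr Expression (RPKM) tibble.
#' @param samples Optional tibble `library_id`, `stage`.
#' @param offset Added before log10; default 1.
#' @return Tibble `library_a`, `library_b`, `r`, `n_genes`,
#'   `within_stage` (NA without a samples sheet), `degenerate` (TRUE when a
#'   zero-variance vector makes r undefined).
#' @export
replicate_correlation <- function(expr, samples = NULL, offset = 1) {
  m <- as_gene_matrix(expr, "expression")
  if (ncol(m) < 2L) stop("need at least 2 libraries", call. = FALSE)
  libs <- colnames(m)
  pairs <- utils::combn(libs, 2L)
  lg <- log10(m + offset)
  rows <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    keep <- m[, a] > 0 | m[, b] > 0
    x <- lg[keep, a]; y <- lg[keep, b]
    degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0 || sum(keep) < 2L
    r <- if (degenerate) NA_real_ else stats::cor(x, y)
    within <- NA
    if (!is.null(samples)) {
      st <- samples$stage[match(c(a, b), samples$library_id)]
      within <- st[1L] == st[2L]
    }
    tibble::tibble(library_a = a, library_b = b, r = r,
                   n_genes = sum(keep), within_stage = within,
                   degenerate = degenerate)
  })
  dplyr::bind_rows(rows)
}
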