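#' EASE score: modified Fisher's exact test for over-representation
#'
#' The EASE statistic is the one-tailed Fisher (hypergeometric) p-value of a
#' 2x2 gene-set overlap table after removing one gene from the overlap cell,
#' a deliberately conservative penalty on single-gene overlaps: with 0 or 1
#' hits the score is exactly 1, and for every table the score is at least
#' the classical Fisher p-value.
#'
#' @param list_hits Genes in both the query list and the set.
#' @param list_size Query list size.
#' @param set_size Set size within the background.
#' @param background_size Background universe size.
#' @return One-tailed over-representation p-value in (0, 1].
#' @examples
#' ease_score(10, 100, 100, 10000)
#' ease_score(1, 100, 100, 10000)  # == 1 by construction
#' @export
ease_score <- function(list_hits, list_size, set_size, background_size) {
  stopifnot(list_hits >= 0, list_size > 0, set_size >= 0, background_size > 0)
  if (list_size > background_size || set_size > background_size ||
      list_hits > min(list_size, set_size)) {
    stop("inconsistent 2x2 margins", call. = FALSE)
  }
  if (list_hits <= 1) return(1)
  # decremented overlap: P(X >= list_hits - 1) for
  # X ~ Hypergeometric(set_size, background - set_size, list_size)
  stats::phyper(list_hits - 2, set_size, background_size - set_size,
                list_size, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector; the
#' correction applied to EASE scores across a family of gene sets.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input, capped at 1.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation analysis of a query list
#'
#' Scores every gene set intersecting the query with [ease_score()] against
#' a fixed background, adjusts across sets with [bh_adjust()], and flags
#' records significant at the raw-EASE cutoff (the adjusted value is
#' reported alongside). Results are sorted by `ease_p`, ties by `term_id`.
#'
#' @param query_genes Character vector of gene ids; must be a subset of
#'   `background` (an out-of-background query gene is an error, forcing an
#'   explicit background definition).
#' @param gene_sets Named list of character vectors (term id -> members), or
#'   a tibble with columns `term_id`, `gene_id`.
#' @param background Character vector: the gene universe.
#' @param cutoff Significance cutoff on the raw EASE p; default 0.05.
#' @return Tibble `term_id`, `list_hits`, `list_size`, `set_size`,
#'   `background_size`, `ease_p`, `bh_q`, `significant`; one row per set
#'   with a non-empty query intersection.
#' @export
enrich <- function(query_genes, gene_sets, background, cutoff = 0.05) {
  query_genes <- unique(query_genes)
  background <- unique(background)
  stray <- setdiff(query_genes, background)
  if (length(stray) > 0) {
    stop("query gene(s) absent from background: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  if (is.data.frame(gene_sets)) {
    stopifnot(all(c("term_id", "gene_id") %in% names(gene_sets)))
    gene_sets <- split(gene_sets$gene_id, gene_sets$term_id)
  }
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))

  rows <- purrr::imap(gene_sets, function(members, term) {
    members <- intersect(unique(members), background)
    hits <- length(intersect(members, query_genes))
    if (hits == 0 || length(members) == 0) return(NULL)
    tibble::tibble(
      term_id = term, list_hits = hits, list_size = length(query_genes),
      set_size = length(members), background_size = length(background),
      ease_p = ease_score(hits, length(query_genes), length(members),
                          length(background))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(term_id = character(), list_hits = integer(),
                          list_size = integer(), set_size = integer(),
                          background_size = integer(), ease_p = numeric(),
                          bh_q = numeric(), significant = logical()))
  }
  out$bh_q <- bh_adjust(out$ease_p)
  out$significant <- out$ease_p < cutoff
  out[order(out$ease_p, out$term_id), , drop = FALSE]
}

#' Read / write GMT gene-set files
#'
#' GMT is the tab-separated gene-set exchange format: one set per line as
#' `term_id <tab> description <tab> member genes...`.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector, recycled to the sets.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
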