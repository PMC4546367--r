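# Independent brute-force oracles, derived from first principles so they
# share no code path with the implementations they check.

# Conditional exact test by full enumeration: condition on the gene total n,
# P(split with j tags in group b) = C(n, j) * nb^j * na^(n-j) / (na+nb)^n,
# two-sided p = sum of splits no more likely than the observed one.
oracle_exact_test <- function(x_a, x_b, n_a, n_b) {
  n <- x_a + x_b
  if (n == 0) return(1)
  j <- 0:n
  logp <- lchoose(n, j) + j * log(n_b) + (n - j) * log(n_a) -
    n * log(n_a + n_b)
  p_obs <- logp[x_b + 1L]
  sum(exp(logp[logp <= p_obs + 1e-9]))
}

# EASE score by direct enumeration of the decremented hypergeometric tail:
# with the overlap cell reduced by one, sum the probabilities of drawing
# x in {hits-1, ..., min(list, set)} set members in `list` draws from a
# `background` universe containing `set` members.
oracle_ease <- function(hits, list_size, set_size, background) {
  if (hits <= 1) return(1)
  x <- (hits - 1):min(list_size, set_size)
  sum(exp(lchoose(set_size, x) + lchoose(background - set_size, list_size - x) -
            lchoose(background, list_size)))
}

# Expected distinct genes when d of N tags are drawn without replacement:
# a gene with c tags is missed with probability C(N-c, d)/C(N, d).
oracle_saturation_mean <- function(counts, d) {
  N <- sum(counts)
  miss <- exp(lchoose(N - counts, d) - lchoose(N, d))
  sum((1 - miss)[counts > 0])
}

# Quadratic all-pairs QTL-gene scan applying the qualification rule directly.
oracle_qtl_calls <- function(genes, qtls, max_qtl_bp = 2e6) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(qtls))) {
      if (genes$chromosome[i] != qtls$chromosome[j]) next
      ov <- max(0, min(genes$end[i], qtls$end[j]) -
                  max(genes$start[i], qtls$start[j]))
      if (ov <= 0) next
      glen <- genes$end[i] - genes$start[i]
      qlen <- qtls$end[j] - qtls$start[j]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], qtl_id = qtls$qtl_id[j],
        overlap_bp = ov,
        qualifies = qlen < max_qtl_bp && (ov >= glen / 2 || ov >= qlen / 2)
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), qtl_id = character(),
                      overlap_bp = numeric(), qualifies = logical())
  }
  out[order(out$gene_id, out$qtl_id), , drop = FALSE]
}

# Coarse grid search over (A, B, k) refined by Nelder-Mead; the sanity
# check that the nonlinear least-squares optimum is global.
oracle_grid_fit <- function(obs, model, A_grid, B_grid, k_grid) {
  rss <- function(p) {
    sum((obs$weight_kg -
           growth_curve(model, obs$age_days, p[1], p[2], p[3]))^2)
  }
  best <- NULL
  best_rss <- Inf
  for (A in A_grid) for (B in B_grid) for (k in k_grid) {
    r <- rss(c(A, B, k))
    if (r < best_rss) {
      best <- c(A, B, k)
      best_rss <- r
    }
  }
  ref <- stats::optim(best, rss, control = list(maxit = 2000,
                                                reltol = 1e-12))
  list(par = stats::setNames(ref$par, c("A", "B", "k")), rss = ref$value)
}

stage_libs <- function(stage, reps = 3) paste0(stage, "_", seq_len(reps))
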