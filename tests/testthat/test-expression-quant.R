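small_counts <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    L1 = c(1000L, 0L, 9000L),
    L2 = c(500L, 500L, 9000L)
  )
}

small_ann <- function() {
  tibble::tibble(gene_id = c("g1", "g2", "g3"),
                 exonic_length_bp = c(1000, 2000, 500))
}

test_that("RPKM matches the per-cell formula and its trivial cases", {
  rpkm <- compute_rpkm(small_counts(), small_ann())
  # c = 1000, L = 1000 bp, N = 1e4 -> 1e9 * 1000 / (1e4 * 1000) = 1e5;
  # scale to the canonical N = 1e6 example by direct recomputation
  m <- as.matrix(small_counts()[-1])
  L <- small_ann()$exonic_length_bp
  manual <- 1e9 * sweep(m / L, 2, colSums(m), "/")
  expect_equal(as.matrix(rpkm[-1]), manual, ignore_attr = TRUE)
  expect_equal(rpkm$L1[2], 0)  # zero count -> zero RPKM
  one <- compute_rpkm(tibble::tibble(gene_id = "g", lib = 1000L),
                      tibble::tibble(gene_id = "g", exonic_length_bp = 1000))
  # in a single-gene library N = 1000, so RPKM = 1e9/1e3/1e3 = 1000... with
  # N = 1e6 the formula identity gives 1000; check it by the formula itself
  expect_equal(one$lib, 1e9 * 1000 / (1000 * 1000))
  expect_error(compute_rpkm(small_counts(), small_ann()[1:2, ]),
               "no annotation")
})

test_that("random matrices equal an independent per-cell recomputation", {
  set.seed(30)
  g <- 50; l <- 9
  counts <- tibble::as_tibble(cbind(
    tibble::tibble(gene_id = sprintf("g%02d", 1:g)),
    as.data.frame(matrix(rpois(g * l, 40), g, l,
                         dimnames = list(NULL, paste0("L", 1:l))))))
  ann <- tibble::tibble(gene_id = counts$gene_id,
                        exonic_length_bp = sample(500:10000, g))
  rpkm <- as.matrix(compute_rpkm(counts, ann)[-1])
  m <- as.matrix(counts[-1])
  for (j in seq_len(l)) for (i in seq_len(g)) {
    expect_equal(rpkm[i, j],
                 1e9 * m[i, j] / (sum(m[, j]) * ann$exonic_length_bp[i]))
  }
})

test_that("RPKM conserves sum(RPKM * L) = 1e9 and ignores depth scaling", {
  sim <- simulate_counts(count_sim_config(n_genes = 300, library_size = 1e5,
                                          seed = 8))
  rpkm <- as.matrix(compute_rpkm(sim$counts, sim$annotation)[-1])
  L <- sim$annotation$exonic_length_bp
  expect_equal(unname(colSums(rpkm * L)), rep(1e9, ncol(rpkm)),
               tolerance = 1e-9)
  doubled <- sim$counts
  doubled[-1] <- doubled[-1] * 2L
  expect_equal(as.matrix(compute_rpkm(doubled, sim$annotation)[-1]), rpkm,
               ignore_attr = TRUE)
})

test_that("expressed-transcript rule is presence-based per stage", {
  counts <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    BIP_1 = c(0L, 5L, 0L, 0L), BIP_2 = c(0L, 0L, 0L, 0L),
    UIP_1 = c(0L, 0L, 3L, 0L), UIP_2 = c(0L, 0L, 1L, 0L)
  )
  samples <- tibble::tibble(library_id = names(counts)[-1],
                            stage = c("BIP", "BIP", "UIP", "UIP"))
  ex <- expressed_transcripts(counts, samples)
  expect_setequal(ex$overall, c("b", "c"))
  expect_identical(ex$by_stage$BIP, "b")
  expect_setequal(ex$by_stage$UIP, "c")
  expect_identical(sort(union(ex$by_stage$BIP, ex$by_stage$UIP)),
                   sort(ex$overall))
  expect_equal(ex$counts$n_expressed[ex$counts$stage == "overall"], 2)
  expect_equal(sum(ex$partition$n_genes), 2)
})

test_that("planted all-zero genes are excluded from the expressed set", {
  sim <- simulate_counts(count_sim_config(n_genes = 2000, library_size = 1e6,
                                          seed = 21))
  counts <- sim$counts
  zero_idx <- 1:500
  counts[zero_idx, -1] <- 0L
  ex <- expressed_transcripts(counts, sim$samples)
  expressed_possible <- counts$gene_id[-zero_idx]
  detected <- counts$gene_id[rowSums(as.matrix(counts[-1])) > 0]
  expect_setequal(ex$overall, detected)
  expect_equal(length(ex$overall), 1500)
  expect_true(all(!counts$gene_id[zero_idx] %in% ex$overall))
  expect_setequal(ex$overall,
                  Reduce(union, ex$by_stage))
  expect_true(all(detected %in% expressed_possible))
})

test_that("abundance profile sorts, normalises and breaks ties by gene id", {
  counts <- tibble::tibble(gene_id = c("z", "a", "m"),
                           L1 = c(964L, 964L, 8072L))
  prof <- abundance_profile(counts, "L1")
  expect_identical(prof$gene_id, c("m", "a", "z"))
  expect_equal(prof$share[2], 964 / 10000)
  expect_equal(prof$cumulative_share[3], 1)
  ten <- tibble::tibble(gene_id = letters[1:10], L1 = rep(7L, 10))
  expect_equal(abundance_profile(ten, "L1")$cumulative_share[10], 1)
  expect_error(abundance_profile(tibble::tibble(gene_id = "a", L1 = 0L), "L1"),
               "empty")
})

test_that("saturation curve matches the hypergeometric expectation", {
  counts <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                           L1 = c(30L, 20L, 15L, 10L, 8L, 7L, 5L, 3L, 1L, 1L))
  sat <- saturation_curve(counts, "L1", depths = c(0, 20, 100),
                          n_draws = 5000, seed = 2)
  expect_equal(sat$mean_detected[1], 0)
  expect_equal(sat$mean_detected[3], 10)  # full depth detects all genes
  expected <- oracle_saturation_mean(counts$L1, 20)
  se <- sat$sd_detected[2] / sqrt(5000)
  expect_lt(abs(sat$mean_detected[2] - expected), 3 * se)
  # monotone in depth
  sat2 <- saturation_curve(counts, "L1", depths = c(10, 30, 60, 100),
                           n_draws = 300, seed = 3)
  expect_true(all(diff(sat2$mean_detected) > -2 * max(sat2$sd_detected) /
                    sqrt(300)))
  expect_error(saturation_curve(counts, "L1", depths = 1000), "depths")
})

test_that("replicate correlation separates stages on synthetic designs", {
  ident <- tibble::tibble(gene_id = paste0("g", 1:20),
                          A = as.integer(1:20), B = as.integer(1:20))
  rc <- replicate_correlation(ident)
  expect_equal(rc$r, 1)

  x <- c(2, 9, 4, 8, 5); y <- c(3, 7, 6, 9, 4)
  two <- tibble::tibble(gene_id = paste0("g", 1:5), A = x, B = y)
  lx <- log10(x + 1); ly <- log10(y + 1)
  hand <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(replicate_correlation(two)$r, hand)

  sim <- simulate_counts(count_sim_config(n_genes = 500, de_fraction = 0.3,
                                          lfc_magnitude = 3, dispersion = 0.02,
                                          library_size = 2e5, seed = 13))
  rpkm <- compute_rpkm(sim$counts, sim$annotation)
  rc <- replicate_correlation(rpkm, sim$samples)
  expect_gt(min(rc$r[rc$within_stage]), max(rc$r[!rc$within_stage]))

  const <- tibble::tibble(gene_id = paste0("g", 1:5),
                          A = rep(2, 5), B = c(1, 2, 3, 4, 5))
  expect_true(replicate_correlation(const)$degenerate)
})
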