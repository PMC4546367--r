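test_that("interval overlap follows max(0, min(end) - max(start))", {
  expect_equal(overlap_bp("chr1", 10000, 20000, "chr1", 15000, 25000), 5000)
  expect_equal(overlap_bp("chr1", 0, 100, "chr1", 200, 300), 0)
  expect_equal(overlap_bp("chr1", 0, 100, "chr2", 0, 100), 0)
  # nested gene overlaps by its own length
  expect_equal(overlap_bp("chr1", 5000, 6000, "chr1", 0, 1e6), 1000)
})

test_that("QTL-gene rule: half-length disjunction, inclusive, 2 Mb filter", {
  # overlap exactly half the gene length qualifies (inclusive boundary)
  q <- qualifies_as_qtl_gene(10000, 20000, 15000, 25000)
  expect_equal(q$overlap_bp, 5000)
  expect_true(q$qualifies)
  # half of the QTL length qualifies even when the gene is much longer
  q2 <- qualifies_as_qtl_gene(0, 100000, 99000, 101000)
  expect_true(q2$qualifies)
  # a QTL of 2 Mb or more never yields a QTL gene, even fully containing it
  q3 <- qualifies_as_qtl_gene(1e6, 1.01e6, 0, 2.5e6)
  expect_false(q3$qualifies)
  expect_false(qualifies_as_qtl_gene(0, 1000, 0, 2e6)$qualifies)
  expect_true(qualifies_as_qtl_gene(0, 1000, 0, 2e6 - 1)$qualifies)
  # zero overlap never qualifies
  expect_false(qualifies_as_qtl_gene(0, 1000, 5000, 6000)$qualifies)
  # the half-of-either disjunction is symmetric in the two intervals' roles
  expect_equal(qualifies_as_qtl_gene(15000, 25000, 10000, 20000)$qualifies,
               qualifies_as_qtl_gene(10000, 20000, 15000, 25000)$qualifies)
})

test_that("classifier equals the quadratic all-pairs oracle", {
  db <- simulate_qtl_db(qtl_sim_config(n_genes = 400, n_qtl = 60, seed = 23))
  cls <- classify_specific_genes(db$genes, db$qtls)
  oracle <- oracle_qtl_calls(db$genes, db$qtls)
  expect_equal(nrow(cls$calls), nrow(oracle))
  expect_identical(cls$calls$gene_id, oracle$gene_id)
  expect_identical(cls$calls$qtl_id, oracle$qtl_id)
  expect_equal(cls$calls$overlap_bp, oracle$overlap_bp)
  expect_identical(cls$calls$qualifies, oracle$qualifies)
})

test_that("all QTL regions at 2 Mb or longer yield zero QTL genes", {
  db <- simulate_qtl_db(qtl_sim_config(n_genes = 200, n_qtl = 30,
                                       qtl_length_bp = c(2e6, 4e6), seed = 5))
  cls <- classify_specific_genes(db$genes, db$qtls)
  expect_false(any(cls$calls$qualifies))
  expect_true(all(cls$summary$specific_in_qtl == 0))
  expect_true(all(cls$summary$qtl_length_mb == 0))
})

test_that("per-chromosome summary counts genes once and merges QTL lengths", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(100000, 500000, 0), end = c(150000, 520000, 40000),
    stage_specific = c("UIP", NA, "AIP"))
  qtls <- tibble::tibble(
    qtl_id = c("q1", "q2", "q3"),
    chromosome = c("chr1", "chr1", "chr1"),
    start = c(0, 100000, 140000), end = c(200000, 300000, 1540000),
    trait = "adg")
  expect_warning(cls <- classify_specific_genes(genes, qtls), "chr2")
  # g1 hits q1, q2 and q3 but counts once on chr1
  s1 <- cls$summary[cls$summary$chromosome == "chr1", ]
  expect_equal(s1$specific_in_qtl, 1)
  expect_equal(s1$gene_number, 2)
  # merged QTL span: [0, 300000) u [140000, 1540000) = 1.54 Mb
  expect_equal(s1$qtl_length_mb, 1.54)
  s2 <- cls$summary[cls$summary$chromosome == "chr2", ]
  expect_equal(s2$specific_in_qtl, 0)
  expect_equal(s2$qtl_length_mb, 0)
})

test_that("chi-square enrichment matches the textbook statistic", {
  # hand computation for (20/80 vs 100/900): chi2 = sum (O-E)^2/E
  tab <- matrix(c(20, 80, 100, 900), 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2_hand <- sum((tab - expected)^2 / expected)
  res <- chi_square_enrichment(20, 80, 100, 900)
  expect_equal(res$chi2[1], chi2_hand, tolerance = 1e-12)
  expect_equal(res$p_value[1],
               stats::pchisq(chi2_hand, 1, lower.tail = FALSE))
  # equal proportions give chi2 = 0, p = 1
  null <- chi_square_enrichment(10, 90, 100, 900)
  expect_equal(null$chi2[1], 0, tolerance = 1e-12)
  expect_equal(null$p_value[1], 1)
  # small expected cells switch to the exact hypergeometric p
  small <- chi_square_enrichment(2, 3, 1, 200)
  expect_true(small$exact[1])
  tab_s <- matrix(c(2, 3, 1, 200), 2, byrow = TRUE)
  expect_equal(small$p_value[1], stats::fisher.test(tab_s)$p.value)
  # pooled row
  two <- chi_square_enrichment(c(20, 10), c(80, 90), c(100, 100),
                               c(900, 900), chromosome = c("c1", "c2"))
  expect_identical(two$chromosome[3], "overall")
  expect_equal(two$chi2[3], chi_square_enrichment(30, 170, 200, 1800)$chi2[1])
})

test_that("null gene placement keeps chromosome-level false positives rare", {
  frac <- vapply(1:50, function(s) {
    db <- simulate_qtl_db(qtl_sim_config(n_genes = 300, n_qtl = 30,
                                         planted_enrichment = 1, seed = s))
    cls <- classify_specific_genes(db$genes, db$qtls)
    in_qtl <- unique(cls$calls$gene_id[cls$calls$qualifies])
    all_in <- db$genes$gene_id %in% in_qtl
    spec <- !is.na(db$genes$stage_specific)
    per <- cls$summary
    chi <- chi_square_enrichment(
      per$specific_in_qtl, per$specific_genes - per$specific_in_qtl,
      vapply(per$chromosome, function(ch)
        sum(all_in & db$genes$chromosome == ch), integer(1)),
      vapply(per$chromosome, function(ch)
        sum(!all_in & db$genes$chromosome == ch), integer(1)),
      chromosome = per$chromosome)
    chi <- chi[chi$chromosome != "overall", ]
    mean(chi$p_value < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(frac), 0.08)
})

test_that("planted enrichment elevates stage-specific genes inside QTL", {
  null_rate <- enr_rate <- numeric(5)
  for (s in 1:5) {
    db0 <- simulate_qtl_db(qtl_sim_config(planted_enrichment = 1, seed = s))
    db4 <- simulate_qtl_db(qtl_sim_config(planted_enrichment = 4, seed = s))
    rate <- function(db) {
      cls <- classify_specific_genes(db$genes, db$qtls)
      sum(cls$summary$specific_in_qtl) / sum(cls$summary$specific_genes)
    }
    null_rate[s] <- rate(db0)
    enr_rate[s] <- rate(db4)
  }
  expect_gt(mean(enr_rate), mean(null_rate) * 2)
})
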