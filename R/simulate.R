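#' Synthetic growth records
#'
#' Configuration and generator for weight-by-age records with the structure
#' of a longitudinal mean-weight study: a known sigmoid truth plus additive
#' Gaussian measurement noise. The defaults reproduce the study conditions
#' of a slow-growing indigenous pig population followed from birth to 250
#' days at 20 time points, with the Von Bertalanffy truth back-solved from
#' an inflection at 193.40 days, 62.61 kg and a maximum daily gain of
#' 455.43 g/day (A = 211.309 kg, B = 0.85151, k = 0.0048494 /day).
#'
#' @param model One of [growth_models()].
#' @param A,B,k Truth parameters; defaults as above.
#' @param timepoints Ages in days; non-empty, non-negative, strictly
#'   increasing.
#' @param noise_sd Gaussian noise standard deviation in kg (`>= 0`);
#'   default 1 kg, the scale of between-batch mean-weight error.
#' @param seed Integer seed; generation is fully reproducible.
#' @return `growth_sim_config()` returns a validated config list;
#'   `simulate_growth()` returns a tibble with columns `age_days`,
#'   `weight_kg`.
#' @examples
#' head(simulate_growth(growth_sim_config(noise_sd = 0)))
#' @export
growth_sim_config <- function(model = "von_bertalanffy",
                              A = NULL, B = NULL, k = NULL,
                              timepoints = seq(0, 250, length.out = 20),
                              noise_sd = 1, seed = 1L) {
  model <- match_growth_model(model)
  if (is.null(A) || is.null(B) || is.null(k)) {
    truth <- params_from_inflection("von_bertalanffy", 193.40, 62.61, 0.45543)
    if (model != "von_bertalanffy") {
      stop("A, B and k must be given explicitly for model '", model, "'",
           call. = FALSE)
    }
    if (is.null(A)) A <- truth[["A"]]
    if (is.null(B)) B <- truth[["B"]]
    if (is.null(k)) k <- truth[["k"]]
  }
  stopifnot(A > 0, B > 0, k > 0, noise_sd >= 0,
            length(timepoints) > 0, all(timepoints >= 0),
            all(diff(timepoints) > 0))
  structure(list(model = model, A = A, B = B, k = k,
                 timepoints = as.numeric(timepoints),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "growth_sim_config")
}

#' @rdname growth_sim_config
#' @param cfg A `growth_sim_config`.
#' @export
simulate_growth <- function(cfg = growth_sim_config()) {
  stopifnot(inherits(cfg, "growth_sim_config"))
  truth <- growth_curve(cfg$model, cfg$timepoints, cfg$A, cfg$B, cfg$k)
  withr::with_seed(cfg$seed, {
    w <- truth + stats::rnorm(length(truth), 0, cfg$noise_sd)
    # a draw pushing a mean weight non-positive is resampled (capped)
    for (attempt in seq_len(100L)) {
      bad <- w <= 0
      if (!any(bad)) break
      w[bad] <- truth[bad] + stats::rnorm(sum(bad), 0, cfg$noise_sd)
    }
    if (any(w <= 0)) {
      stop("could not draw positive weights after 100 attempts; ",
           "noise_sd is too large for the curve", call. = FALSE)
    }
    tibble::tibble(age_days = cfg$timepoints, weight_kg = w)
  })
}

#' Synthetic digital gene expression (tag-count) matrices
#'
#' Emulates a multi-stage DGE tag-profiling design: counts with
#' negative-binomial overdispersion around stage-specific expected
#' abundances (gamma-distributed per-gene intensities under a multinomial
#' allocation of the library's tags, so each library lands on its target
#' depth), a bounded Pareto (power-law) baseline so a handful of
#' transcripts dominates the library — mirroring muscle libraries where the
#' single most abundant transcript holds roughly a tenth of all tags — and
#' a configurable
#' fraction of genes with planted step changes of known log2 magnitude
#' between adjacent stages, recorded in a truth table.
#'
#' @param n_genes Number of genes.
#' @param gene_length_bp Range (min, max) of exonic lengths drawn uniformly.
#' @param n_stages Number of developmental stages (3 = BIP/UIP/AIP labels).
#' @param reps_per_stage Biological replicates per stage.
#' @param library_size Target sequencing depth (tags) per library.
#' @param dispersion Negative-binomial dispersion (`>= 0`; 0 = Poisson).
#' @param de_fraction Fraction of genes with a planted expression step
#'   between one pair of adjacent stages.
#' @param lfc_magnitude Planted |log2 fold change|.
#' @param abundance_skew Pareto tail exponent for baseline abundances
#'   (smaller = more concentrated).
#' @param seed Integer seed.
#' @return `count_sim_config()` returns a validated config.
#'   `simulate_counts()` returns a list with:
#'   * `counts`: tibble, `gene_id` plus one integer column per library;
#'   * `samples`: tibble `library_id`, `stage`, `replicate`;
#'   * `annotation`: tibble `gene_id`, `chromosome`, `start`, `end`,
#'     `exonic_length_bp` (0-based half-open, single synthetic chromosome);
#'   * `truth`: tibble of planted DEGs — `gene_id`, `stage_from`,
#'     `stage_to`, `log2fc` (signed, stage_to over stage_from).
#' @examples
#' sim <- simulate_counts(count_sim_config(n_genes = 100, library_size = 1e5))
#' sim$counts
#' @export
count_sim_config <- function(n_genes = 2000L,
                             gene_length_bp = c(500L, 10000L),
                             n_stages = 3L, reps_per_stage = 3L,
                             library_size = 1e6, dispersion = 0.1,
                             de_fraction = 0.1, lfc_magnitude = 2,
                             abundance_skew = 0.8, seed = 1L) {
  stopifnot(n_genes >= 2, length(gene_length_bp) == 2L,
            gene_length_bp[1] > 0, diff(gene_length_bp) >= 0,
            n_stages >= 2, reps_per_stage >= 1, library_size > 0,
            de_fraction >= 0, de_fraction <= 1,
            lfc_magnitude >= 0, abundance_skew > 0)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_bp = as.numeric(gene_length_bp),
                 n_stages = as.integer(n_stages),
                 reps_per_stage = as.integer(reps_per_stage),
                 library_size = library_size, dispersion = dispersion,
                 de_fraction = de_fraction, lfc_magnitude = lfc_magnitude,
                 abundance_skew = abundance_skew, seed = as.integer(seed)),
            class = "count_sim_config")
}

stage_names <- function(n_stages) {
  if (n_stages == 3L) c("BIP", "UIP", "AIP") else paste0("S", seq_len(n_stages))
}

# bounded Pareto quantile on [lo, hi] with tail exponent alpha
rpareto_bounded <- function(n, alpha, lo = 1, hi = 5000) {
  u <- stats::runif(n)
  (lo^-alpha - u * (lo^-alpha - hi^-alpha))^(-1 / alpha)
}

# water-filling cap on abundance shares: no entry above `cap`, mass
# redistributed proportionally over the uncapped rest
cap_shares <- function(s, cap, iters = 20L) {
  for (i in seq_len(iters)) {
    over <- s > cap
    if (!any(over)) break
    excess <- sum(s[over] - cap)
    s[over] <- cap
    s[!over] <- s[!over] * (1 + excess / sum(s[!over]))
  }
  s
}

#' @rdname count_sim_config
#' @param cfg A `count_sim_config`.
#' @export
simulate_counts <- function(cfg = count_sim_config()) {
  stopifnot(inherits(cfg, "count_sim_config"))
  withr::with_seed(cfg$seed, {
    g <- cfg$n_genes
    stages <- stage_names(cfg$n_stages)
    gene_id <- sprintf("G%05d", seq_len(g))
    len <- round(stats::runif(g, cfg$gene_length_bp[1], cfg$gene_length_bp[2]))

    base <- rpareto_bounded(g, cfg$abundance_skew)
    # cap any single transcript at ~10% of the library: matches the
    # concentration seen in deep muscle DGE libraries (top transcript just
    # under a tenth of all tags) and keeps library sums near their target
    base <- cap_shares(base / sum(base), 0.10)
    mu <- matrix(base, nrow = g, ncol = cfg$n_stages)

    n_de <- round(cfg$de_fraction * g)
    truth <- tibble::tibble(gene_id = character(), stage_from = character(),
                            stage_to = character(), log2fc = numeric())
    if (n_de > 0) {
      de_idx <- sample.int(g, n_de)
      step_at <- sample.int(cfg$n_stages - 1L, n_de, replace = TRUE)
      sign <- sample(c(-1, 1), n_de, replace = TRUE)
      for (j in seq_len(n_de)) {
        later <- (step_at[j] + 1L):cfg$n_stages
        mu[de_idx[j], later] <- mu[de_idx[j], later] *
          2^(sign[j] * cfg$lfc_magnitude)
      }
      truth <- tibble::tibble(
        gene_id = gene_id[de_idx],
        stage_from = stages[step_at],
        stage_to = stages[step_at + 1L],
        log2fc = sign * cfg$lfc_magnitude,
        # expected per-library count before the step was planted
        base_mean = base[de_idx] / sum(base) * cfg$library_size
      )
      truth <- dplyr::arrange(truth, .data$gene_id)
    }

    samples <- tidyr::expand_grid(stage = stages,
                                  replicate = seq_len(cfg$reps_per_stage))
    samples <- dplyr::mutate(samples,
      library_id = paste0(.data$stage, "_", .data$replicate),
      .before = 1L)

    # gamma-multinomial sampling: per-gene Gamma intensities carry the
    # negative-binomial mixing variance (var = dispersion * mean^2 on the
    # intensity scale), the multinomial layer fixes each library's total at
    # the target depth; at dispersion 0 this collapses to plain multinomial
    # (Poisson-like) sampling
    counts <- matrix(0L, nrow = g, ncol = nrow(samples),
                     dimnames = list(gene_id, samples$library_id))
    depth <- round(cfg$library_size)
    for (i in seq_len(nrow(samples))) {
      s <- match(samples$stage[i], stages)
      share <- mu[, s] / sum(mu[, s])
      lam <- if (cfg$dispersion == 0) share else
        stats::rgamma(g, shape = 1 / cfg$dispersion,
                      scale = cfg$dispersion * share)
      counts[, i] <- stats::rmultinom(1L, depth, lam)[, 1L]
    }

    start <- cumsum(c(0, len[-g] + 1000))  # synthetic chromosome, 1 kb gaps
    list(
      counts = tibble::as_tibble(cbind(tibble::tibble(gene_id = gene_id),
                                       as.data.frame(counts))),
      samples = samples,
      annotation = tibble::tibble(gene_id = gene_id, chromosome = "chrS",
                                  start = start, end = start + len,
                                  exonic_length_bp = len),
      truth = truth
    )
  })
}

#' Synthetic gene and QTL interval catalogues
#'
#' Emulates a genome-wide QTL catalogue against a gene annotation: genes
#' placed uniformly over a multi-chromosome genome, QTL regions with lengths
#' straddling the 2 Mb filter used for QTL-gene calling, and a set of
#' stage-specific genes that can be placed inside sub-2-Mb QTL regions at a
#' configurable enrichment multiple (1 = no enrichment, the null).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param n_genes Total genes.
#' @param n_qtl Total QTL regions.
#' @param qtl_length_bp Range (min, max) of QTL lengths, drawn uniformly;
#'   the default straddles 2 Mb so some regions fail the filter.
#' @param specific_fraction Fraction of genes labelled stage-specific.
#' @param planted_enrichment Multiplier on the background probability that a
#'   stage-specific gene falls inside a qualifying (< 2 Mb) QTL region.
#' @param seed Integer seed.
#' @return `qtl_sim_config()` returns a validated config.
#'   `simulate_qtl_db()` returns a list of tibbles: `genes` (`gene_id`,
#'   `chromosome`, `start`, `end`, `stage_specific` — stage label or `NA`)
#'   and `qtls` (`qtl_id`, `chromosome`, `start`, `end`, `trait`), all
#'   0-based half-open.
#' @export
qtl_sim_config <- function(n_chromosomes = 5L, chrom_length_bp = 5e7,
                           n_genes = 500L, n_qtl = 40L,
                           qtl_length_bp = c(2e5, 3e6),
                           specific_fraction = 0.25,
                           planted_enrichment = 1, seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length_bp > 0, n_genes >= 1,
            n_qtl >= 1, length(qtl_length_bp) == 2L,
            qtl_length_bp[1] > 0, diff(qtl_length_bp) >= 0,
            qtl_length_bp[2] <= chrom_length_bp,
            specific_fraction >= 0, specific_fraction <= 1,
            planted_enrichment > 0)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = chrom_length_bp,
                 n_genes = as.integer(n_genes), n_qtl = as.integer(n_qtl),
                 qtl_length_bp = as.numeric(qtl_length_bp),
                 specific_fraction = specific_fraction,
                 planted_enrichment = planted_enrichment,
                 seed = as.integer(seed)),
            class = "qtl_sim_config")
}

#' @rdname qtl_sim_config
#' @param cfg A `qtl_sim_config`.
#' @export
simulate_qtl_db <- function(cfg = qtl_sim_config()) {
  stopifnot(inherits(cfg, "qtl_sim_config"))
  withr::with_seed(cfg$seed, {
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    traits <- c("average daily gain", "body weight", "drip loss",
                "intramuscular fat", "backfat thickness")

    qlen <- round(stats::runif(cfg$n_qtl, cfg$qtl_length_bp[1],
                               cfg$qtl_length_bp[2]))
    qchrom <- sample(chroms, cfg$n_qtl, replace = TRUE)
    qstart <- floor(stats::runif(cfg$n_qtl) * (cfg$chrom_length_bp - qlen))
    qtls <- tibble::tibble(
      qtl_id = sprintf("QTL%04d", seq_len(cfg$n_qtl)),
      chromosome = qchrom, start = qstart, end = qstart + qlen,
      trait = sample(traits, cfg$n_qtl, replace = TRUE)
    )

    glen <- round(stats::runif(cfg$n_genes, 1000, 100000))
    gchrom <- sample(chroms, cfg$n_genes, replace = TRUE)
    gstart <- floor(stats::runif(cfg$n_genes) * (cfg$chrom_length_bp - glen))

    n_spec <- round(cfg$specific_fraction * cfg$n_genes)
    specific <- rep(NA_character_, cfg$n_genes)
    if (n_spec > 0) {
      specific[sample.int(cfg$n_genes, n_spec)] <-
        sample(stage_names(3L), n_spec, replace = TRUE)
    }

    # planted enrichment: stage-specific genes dropped into qualifying QTL
    # regions with probability planted_enrichment * genome coverage of those
    # regions, so enrichment 1 matches uniform placement in expectation
    qual <- qtls[qtls$end - qtls$start < 2e6, , drop = FALSE]
    if (cfg$planted_enrichment != 1 && nrow(qual) > 0 && n_spec > 0) {
      coverage <- sum(qual$end - qual$start) /
        (cfg$n_chromosomes * cfg$chrom_length_bp)
      p_in <- min(1, cfg$planted_enrichment * coverage)
      for (i in which(!is.na(specific))) {
        if (stats::runif(1) < p_in) {
          q <- qual[sample.int(nrow(qual), 1L), ]
          room <- (q$end - q$start) - glen[i]
          if (room <= 0) next  # gene longer than the region: infeasible pack
          gchrom[i] <- q$chromosome
          gstart[i] <- q$start + floor(stats::runif(1) * room)
        }
      }
    }

    genes <- tibble::tibble(
      gene_id = sprintf("G%05d", seq_len(cfg$n_genes)),
      chromosome = gchrom, start = gstart, end = gstart + glen,
      stage_specific = specific
    )
    list(genes = genes, qtls = qtls)
  })
}

#' Synthetic qPCR cycle-threshold tables
#'
#' Emulates tidy Ct records for both relative mRNA quantification (a target
#' gene against a panel of reference genes across conditions) and mtDNA
#' copy-number measurement (mitochondrial genes against a single-copy
#' nuclear gene). Ct values are constructed as `baseline - log2(quantity) +
#' noise`, so the downstream 2^-ddCt and 2^dCt estimators invert the
#' construction exactly at zero noise.
#'
#' @param target Target gene id for ddCt quantification.
#' @param references Reference (housekeeping) gene ids.
#' @param mito_genes Mitochondrial gene ids.
#' @param nuclear_gene Single-copy nuclear gene id.
#' @param conditions Condition labels; the first is the calibrator.
#' @param true_fold_changes Named (by condition) true target fold changes
#'   relative to the calibrator.
#' @param true_copy_number True mtDNA copies per diploid cell.
#' @param ct_noise_sd Gaussian Ct noise in cycles.
#' @param triplicates Technical replicates per reaction.
#' @param seed Integer seed.
#' @return `ct_sim_config()` returns a validated config.
#'   `simulate_ct_table()` returns a tibble with columns `sample_id`,
#'   `condition`, `gene_id`, `replicate`, `ct`.
#' @export
ct_sim_config <- function(target = "TXNIP",
                          references = c("ACTB", "TBP", "TOP2B"),
                          mito_genes = c("ATP6", "COX1", "ND1"),
                          nuclear_gene = "GCG",
                          conditions = c("BIP", "UIP", "AIP"),
                          true_fold_changes = c(BIP = 1, UIP = 2, AIP = 1.5),
                          true_copy_number = 1024,
                          ct_noise_sd = 0.1, triplicates = 3L, seed = 1L) {
  stopifnot(length(conditions) >= 1, ct_noise_sd >= 0, triplicates >= 1,
            true_copy_number > 0, all(true_fold_changes > 0),
            length(references) >= 1, length(mito_genes) >= 1)
  if (!all(conditions %in% names(true_fold_changes))) {
    stop("true_fold_changes must name every condition", call. = FALSE)
  }
  structure(list(target = target, references = references,
                 mito_genes = mito_genes, nuclear_gene = nuclear_gene,
                 conditions = conditions,
                 true_fold_changes = true_fold_changes,
                 true_copy_number = true_copy_number,
                 ct_noise_sd = ct_noise_sd,
                 triplicates = as.integer(triplicates),
                 seed = as.integer(seed)),
            class = "ct_sim_config")
}

#' @rdname ct_sim_config
#' @param cfg A `ct_sim_config`.
#' @export
simulate_ct_table <- function(cfg = ct_sim_config()) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  withr::with_seed(cfg$seed, {
    rows <- list()
    base_target <- 24
    base_ref <- 20
    base_nuclear <- 25
    for (cond in cfg$conditions) {
      sample_id <- paste0(cond, "_pool")
      fold <- cfg$true_fold_changes[[cond]]
      for (rep in seq_len(cfg$triplicates)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = sample_id, condition = cond,
          gene_id = c(cfg$target, cfg$references, cfg$mito_genes,
                      cfg$nuclear_gene),
          replicate = rep,
          ct = c(base_target - log2(fold),
                 rep(base_ref, length(cfg$references)),
                 rep(base_nuclear - log2(cfg$true_copy_number),
                     length(cfg$mito_genes)),
                 base_nuclear) +
            stats::rnorm(length(cfg$target) + length(cfg$references) +
                           length(cfg$mito_genes) + 1L, 0, cfg$ct_noise_sd)
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    if (any(out$ct <= 0)) {
      stop("generated Ct values left the plausible range; lower ct_noise_sd",
           call. = FALSE)
    }
    out
  })
}
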