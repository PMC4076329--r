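# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Variant definitions for the FTO intron-1 core SNPs
#'
#' The eight lead SNPs used throughout: identifiers, build-37 positions on
#' chromosome 16, alleles, and the effect (BMI-increasing / disease-risk)
#' allele, which at every site is the allele carried by the risk haplotype
#' H1. rs7206790 sits outside the block on ancestral recombination evidence
#' and is flagged accordingly.
#'
#' @return A tibble with the [geno_matrix()] variant columns plus
#'   `recombinant` (logical).
#' @export
fto_core_variants <- function() {
  tibble(
    snp_id = c("rs7206790", "rs1421085", "rs3751812", "rs9939609",
               "rs9941349", "rs56137030", "rs17817964", "rs12149832"),
    chrom = "16",
    pos = c(53797908L, 53800954L, 53818460L, 53820527L,
            53825488L, 53828066L, 53828541L, 53842908L),
    allele_a = c("C", "T", "G", "T", "C", "G", "C", "G"),
    allele_b = c("G", "C", "T", "A", "T", "A", "T", "A"),
    effect_allele = c("G", "C", "T", "A", "T", "A", "T", "A"),
    recombinant = c(TRUE, rep(FALSE, 7))
  )
}

#' Reference haplotypes at the FTO locus
#'
#' The four principal haplotypes (H1-H4) over the eight core SNPs, with the
#' ancestral haplotype H2, optional recombinant / recurrent-mutation
#' sub-haplotypes, and per-population frequency estimates for 1000 Genomes
#' ancestry groups (AFR, EUR, ASN) and the three Asian study populations.
#' Frequencies printed as "Low" in the source estimates (< 0.004) are
#' encoded as 0.002. At the recombinant site rs7206790 each haplotype
#' stores its majority allele; allele comparisons skip recombinant sites
#' unless asked otherwise (see [hap_diff()]).
#'
#' @param include_sub Include the sub-haplotypes (H1-2, H1-3, H2-1, H2-2,
#'   H3-1, H3-3, H3-4) in addition to H1-H4.
#' @return An object of class `hap_table`: list with `snp_list` (variant
#'   tibble incl. `recombinant`), `alleles` (haplotype x SNP character
#'   matrix), `ancestral` (label of the ancestral haplotype) and `freqs`
#'   (long tibble population / haplotype / freq).
#' @export
default_haplotypes <- function(include_sub = FALSE) {
  v <- fto_core_variants()
  al <- rbind(
    H1     = c("G", "C", "T", "A", "T", "A", "T", "A"),
    `H1-2` = c("G", "C", "T", "A", "T", "G", "T", "A"),
    `H1-3` = c("G", "C", "T", "A", "T", "A", "T", "G"),
    `H2-1` = c("G", "T", "G", "A", "C", "A", "C", "G"),
    H2     = c("G", "T", "G", "A", "C", "G", "C", "G"),
    `H2-2` = c("C", "T", "G", "A", "T", "G", "C", "G"),
    H3     = c("C", "T", "G", "T", "C", "G", "C", "G"),
    `H3-1` = c("G", "C", "G", "T", "C", "G", "C", "G"),
    `H3-3` = c("C", "T", "G", "T", "C", "G", "C", "A"),
    `H3-4` = c("C", "T", "G", "T", "C", "G", "T", "G"),
    H4     = c("C", "T", "G", "T", "T", "G", "C", "G")
  )
  colnames(al) <- v$snp_id
  low <- 0.002
  fr <- tibble(
    haplotype = rownames(al),
    AFR       = c(0.05, 0,     0,    0.01, 0.45, 0.03, 0.38, low,  0,    0,    0.07),
    EUR       = c(0.41, 0.003, 0.01, 0,    0,    0,    0.53, 0.02, 0.02, 0,    0.01),
    ASN       = c(0.15, 0,     low,  0,    0,    0,    0.77, 0,    0.01, 0.02, 0.03),
    Japanese  = c(0.18, 0,     0.01, 0,    low,  0,    0.73, low,  0.01, 0.03, 0.03),
    Vietnamese= c(0.18, 0,     0.01, 0,    low,  low,  0.74, low,  0.01, 0.01, 0.05),
    SriLankan = c(0.32, low,   low,  0,    low,  0,    0.54, 0.02, 0.04, 0,    0.07)
  )
  if (!include_sub) {
    keep <- c("H1", "H2", "H3", "H4")
    al <- al[keep, , drop = FALSE]
    fr <- fr[fr$haplotype %in% keep, ]
  }
  freqs <- tidyr::pivot_longer(fr, -"haplotype", names_to = "population",
                               values_to = "freq")
  structure(list(snp_list = v, alleles = al, ancestral = "H2", freqs = freqs),
            class = "hap_table")
}

#' @export
print.hap_table <- function(x, ...) {
  cat(sprintf("<hap_table> %d haplotypes over %d SNPs (ancestral: %s)\n",
              nrow(x$alleles), ncol(x$alleles), x$ancestral))
  print(x$alleles)
  invisible(x)
}

#' SNPs at which two haplotypes differ
#'
#' @param ht A `hap_table` (see [default_haplotypes()]).
#' @param a,b Haplotype labels.
#' @param skip_recombinant Drop sites flagged as recombinant before
#'   comparing (default). Differences at such sites reflect crossover, not
#'   substitution, so they are not mutation events.
#' @return Character vector of differing SNP ids.
#' @export
hap_diff <- function(ht, a, b, skip_recombinant = TRUE) {
  stopifnot(a %in% rownames(ht$alleles), b %in% rownames(ht$alleles))
  use <- if (skip_recombinant) !ht$snp_list$recombinant else
    rep(TRUE, nrow(ht$snp_list))
  ids <- ht$snp_list$snp_id[use]
  ids[ht$alleles[a, ids] != ht$alleles[b, ids]]
}

#' Population configuration for the synthetic generator
#'
#' @param name Population label.
#' @param n_samples Number of diploid individuals (>= 2).
#' @param hap_freqs Named numeric vector of haplotype frequencies; labels
#'   must exist in `haplotypes`. Normalised to sum to one.
#' @param haplotypes A `hap_table`; defaults to [default_haplotypes()].
#' @param filler_snps Filler (proxy) SNPs to plant per core SNP.
#' @param filler_r2 Target r-squared of each filler to its core SNP,
#'   in `[0, 1]`.
#' @param panel Panel label recorded in the phenotype table.
#' @param seed Integer seed making the panel reproducible.
#' @return A `population_config` list.
#' @export
population_config <- function(name, n_samples, hap_freqs,
                              haplotypes = default_haplotypes(),
                              filler_snps = 0, filler_r2 = 0.8,
                              panel = name, seed = 1L) {
  if (n_samples < 2) abort("n_samples must be >= 2", class = "finemapld_config_error")
  if (filler_r2 < 0 || filler_r2 > 1) {
    abort("filler_r2 must lie in [0, 1]", class = "finemapld_config_error")
  }
  unknown <- setdiff(names(hap_freqs), rownames(haplotypes$alleles))
  if (length(unknown) > 0) {
    abort(paste0("hap_freqs names not in haplotype table: ",
                 paste(unknown, collapse = ", ")),
          class = "finemapld_config_error")
  }
  if (any(hap_freqs < 0) || sum(hap_freqs) <= 0) {
    abort("hap_freqs must be non-negative with positive sum",
          class = "finemapld_config_error")
  }
  hap_freqs <- hap_freqs / sum(hap_freqs)
  structure(list(name = name, n_samples = as.integer(n_samples),
                 hap_freqs = hap_freqs, haplotypes = haplotypes,
                 filler_snps = as.integer(filler_snps),
                 filler_r2 = filler_r2, panel = panel,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Haplotype frequencies of a reference population, ready for the generator
#'
#' Pulls one population column out of a `hap_table` and drops
#' zero-frequency haplotypes.
#'
#' @param haplotypes A `hap_table`.
#' @param population Population label present in `haplotypes$freqs`.
#' @return Named numeric vector (not yet normalised).
#' @export
hap_freqs_for <- function(haplotypes, population) {
  fr <- dplyr::filter(haplotypes$freqs, .data$population == !!population,
                      .data$freq > 0)
  if (nrow(fr) == 0) abort(paste0("unknown population: ", population),
                           class = "finemapld_key_error")
  setNames(fr$freq, fr$haplotype)
}

#' Phenotype-effect configuration for the synthetic generator
#'
#' Effects are planted on copies of the causal haplotype (default H1, the
#' risk haplotype): a linear shift per copy on the quantitative trait (in
#' units of the residual standard deviation, i.e. z-score units when
#' `noise_sd = 1`) and a log odds ratio per copy on disease liability.
#' Defaults are calibrated to the combined Asian estimates for the H1
#' haplotype: beta 0.064 z-units, OR 1.221.
#'
#' @param bmi_beta_per_h1 Trait shift per causal-haplotype copy.
#' @param t2d_logor_per_h1 Log odds ratio per copy.
#' @param baseline_prevalence Disease probability at zero copies.
#' @param noise_sd Residual standard deviation of the trait (> 0).
#' @param age_range Uniform sampling range for age, years.
#' @param sex_ratio Proportion of sex code 2.
#' @param causal_haplotype Label carrying the planted effect.
#' @return An `effect_config` list.
#' @export
effect_config <- function(bmi_beta_per_h1 = 0.064,
                          t2d_logor_per_h1 = log(1.221),
                          baseline_prevalence = 0.3,
                          noise_sd = 1,
                          age_range = c(35, 74),
                          sex_ratio = 0.5,
                          causal_haplotype = "H1") {
  if (noise_sd < 0) abort("noise_sd must be >= 0", class = "finemapld_config_error")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1) {
    abort("baseline_prevalence must lie in (0, 1)", class = "finemapld_config_error")
  }
  structure(list(bmi_beta_per_h1 = bmi_beta_per_h1,
                 t2d_logor_per_h1 = t2d_logor_per_h1,
                 baseline_prevalence = baseline_prevalence,
                 noise_sd = noise_sd, age_range = age_range,
                 sex_ratio = sex_ratio, causal_haplotype = causal_haplotype),
            class = "effect_config")
}

#' Simulate a genotype panel with planted haplotype structure and effects
#'
#' Draws two haplotypes per individual i.i.d. from the configured
#' frequencies; core-SNP genotypes follow from the diplotype. Each filler
#' SNP copies its core SNP's allele on every haplotype with a switch
#' probability `eps = (1 - sqrt(filler_r2)) / 2`, so that the expected
#' haplotype correlation is `sqrt(filler_r2)` and the expected r-squared is
#' `filler_r2` at matched frequency. The quantitative trait is an age/sex
#' baseline plus the planted per-copy effect plus Gaussian noise; disease
#' status is Bernoulli with logit equal to the baseline-prevalence
#' intercept plus the planted log odds ratio times copies.
#'
#' @param pop_cfg A [population_config()].
#' @param eff_cfg An [effect_config()].
#' @param seed Overrides `pop_cfg$seed` when given.
#' @return A list of class `sim_panel`: `geno` ([geno_matrix()]), `pheno`
#'   (tibble: sample_id, sex, age, bmi, t2d, population, panel), `truth`
#'   (list: `diplotypes` tibble, `clusters` tibble snp_id -> core cluster
#'   SNP, `causal_haplotype`).
#' @export
simulate_panel <- function(pop_cfg, eff_cfg = effect_config(), seed = NULL) {
  stopifnot(inherits(pop_cfg, "population_config"),
            inherits(eff_cfg, "effect_config"))
  seed <- seed %||% pop_cfg$seed
  with_seed(seed, {
    n <- pop_cfg$n_samples
    ht <- pop_cfg$haplotypes
    labs <- names(pop_cfg$hap_freqs)
    hap1 <- sample(labs, n, replace = TRUE, prob = pop_cfg$hap_freqs)
    hap2 <- sample(labs, n, replace = TRUE, prob = pop_cfg$hap_freqs)

    core <- ht$snp_list
    carry <- ht$alleles[, core$snp_id, drop = FALSE] ==
      matrix(core$effect_allele, nrow(ht$alleles), nrow(core), byrow = TRUE)
    storage.mode(carry) <- "integer"
    h1c <- carry[hap1, , drop = FALSE]
    h2c <- carry[hap2, , drop = FALSE]

    variants <- core[, c("snp_id", "chrom", "pos", "allele_a", "allele_b",
                         "effect_allele")]
    calls <- h1c + h2c
    cluster_of <- setNames(core$snp_id, core$snp_id)

    if (pop_cfg$filler_snps > 0) {
      eps <- (1 - sqrt(pop_cfg$filler_r2)) / 2
      fv <- list(); fc <- list()
      for (k in seq_len(nrow(core))) {
        for (j in seq_len(pop_cfg$filler_snps)) {
          flip1 <- rbinom(n, 1, eps)
          flip2 <- rbinom(n, 1, eps)
          g <- abs(h1c[, k] - flip1) + abs(h2c[, k] - flip2)
          id <- sprintf("%s_f%d", core$snp_id[k], j)
          fv[[id]] <- tibble(snp_id = id, chrom = core$chrom[k],
                             pos = core$pos[k] + j,
                             allele_a = core$allele_a[k],
                             allele_b = core$allele_b[k],
                             effect_allele = core$effect_allele[k])
          fc[[id]] <- g
          cluster_of[id] <- core$snp_id[k]
        }
      }
      variants <- bind_rows(variants, bind_rows(fv))
      calls <- cbind(calls, do.call(cbind, fc))
    }

    sample_id <- sprintf("%s_%05d", pop_cfg$name, seq_len(n))
    gm <- geno_matrix(variants, sample_id, calls)

    h1_copies <- (hap1 == eff_cfg$causal_haplotype) +
      (hap2 == eff_cfg$causal_haplotype)
    age <- runif(n, eff_cfg$age_range[1], eff_cfg$age_range[2])
    sex <- 1L + rbinom(n, 1, eff_cfg$sex_ratio)
    bmi <- 23 + 0.01 * (age - mean(eff_cfg$age_range)) - 0.2 * (sex == 2L) +
      eff_cfg$bmi_beta_per_h1 * h1_copies +
      rnorm(n, 0, eff_cfg$noise_sd)
    lin <- qlogis(eff_cfg$baseline_prevalence) +
      eff_cfg$t2d_logor_per_h1 * h1_copies
    t2d <- ifelse(rbinom(n, 1, plogis(lin)) == 1L, "case", "control")

    pheno <- tibble(sample_id = sample_id, sex = sex, age = age, bmi = bmi,
                    t2d = t2d, population = pop_cfg$name,
                    panel = pop_cfg$panel)
    truth <- list(
      diplotypes = tibble(sample_id = sample_id, hap1 = hap1, hap2 = hap2,
                          h1_copies = h1_copies),
      clusters = tibble(snp_id = names(cluster_of),
                        cluster = unname(cluster_of)),
      causal_haplotype = eff_cfg$causal_haplotype
    )
    structure(list(geno = gm, pheno = pheno, truth = truth),
              class = "sim_panel")
  })
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> %s: %d samples, %d variants (causal haplotype %s)\n",
              x$pheno$population[1], length(x$geno$samples),
              nrow(x$geno$variants), x$truth$causal_haplotype))
  invisible(x)
}

#' Simulate a panel of independent planted LD clusters
#'
#' Companion generator for the partitioning and filtering stages: each
#' cluster is an independent core SNP (haplotype-level allele Bernoulli
#' at `maf`) surrounded by filler proxies created by per-haplotype allele
#' switching at `eps = (1 - sqrt(within_r2)) / 2`, so within-cluster
#' r-squared is about `within_r2` while between-cluster r-squared is 0 in
#' expectation. A quantitative-trait effect is planted on the causal
#' cluster's core SNP; disease status uses the same linear predictor on
#' the logit scale. `private_fillers` adds population-private proxies of
#' the causal core (named with the population label), emulating
#' population-specific tagging SNPs that cross-population intersection
#' should remove.
#'
#' @param n_samples Individuals.
#' @param n_clusters Independent clusters.
#' @param fillers_per_cluster Proxies per cluster core.
#' @param maf Core-SNP allele frequency.
#' @param within_r2 Target r-squared of fillers to their core.
#' @param causal_cluster Which cluster carries the effect (index).
#' @param beta Trait shift per causal-core allele copy (z units).
#' @param logor Log odds ratio per copy for disease status.
#' @param noise_sd Trait residual SD.
#' @param prevalence Baseline disease probability.
#' @param population Population label (also used in private-filler names).
#' @param private_fillers Population-private proxies of the causal core.
#' @param seed RNG seed.
#' @return A `sim_panel` (see [simulate_panel()]); `truth$clusters` maps
#'   every SNP to its cluster core, `truth$causal_snp` names the causal
#'   core SNP.
#' @export
simulate_cluster_panel <- function(n_samples, n_clusters = 3,
                                   fillers_per_cluster = 3, maf = 0.3,
                                   within_r2 = 0.95, causal_cluster = 1,
                                   beta = 0.15, logor = log(1.4),
                                   noise_sd = 1, prevalence = 0.3,
                                   population = "POP",
                                   private_fillers = 0, seed = 1L) {
  if (n_samples < 2) abort("n_samples must be >= 2", class = "finemapld_config_error")
  with_seed(seed, {
    n <- as.integer(n_samples)
    eps <- (1 - sqrt(within_r2)) / 2
    variants <- list(); calls <- list(); cluster_of <- character()
    core_ids <- sprintf("idx%d", seq_len(n_clusters))
    causal_id <- core_ids[causal_cluster]
    g_causal <- NULL
    for (c in seq_len(n_clusters)) {
      h1 <- rbinom(n, 1, maf); h2 <- rbinom(n, 1, maf)
      id <- core_ids[c]
      variants[[id]] <- tibble(snp_id = id, chrom = "16",
                               pos = 1000000L * c,
                               allele_a = "T", allele_b = "C",
                               effect_allele = "C")
      calls[[id]] <- h1 + h2
      cluster_of[id] <- id
      if (c == causal_cluster) g_causal <- h1 + h2
      n_fill <- fillers_per_cluster +
        if (c == causal_cluster) private_fillers else 0
      for (j in seq_len(n_fill)) {
        f1 <- abs(h1 - rbinom(n, 1, eps))
        f2 <- abs(h2 - rbinom(n, 1, eps))
        fid <- if (j <= fillers_per_cluster) sprintf("%s_f%d", id, j) else
          sprintf("%s_%s_p%d", id, population, j - fillers_per_cluster)
        variants[[fid]] <- tibble(snp_id = fid, chrom = "16",
                                  pos = 1000000L * c + j,
                                  allele_a = "T", allele_b = "C",
                                  effect_allele = "C")
        calls[[fid]] <- f1 + f2
        cluster_of[fid] <- id
      }
    }
    sample_id <- sprintf("%s_%05d", population, seq_len(n))
    gm <- geno_matrix(bind_rows(variants), sample_id,
                      do.call(cbind, calls))
    age <- runif(n, 35, 74)
    sex <- 1L + rbinom(n, 1, 0.5)
    bmi <- 23 + 0.01 * (age - 54.5) - 0.2 * (sex == 2L) +
      beta * g_causal + rnorm(n, 0, noise_sd)
    t2d <- ifelse(rbinom(n, 1, plogis(qlogis(prevalence) +
                                        logor * g_causal)) == 1L,
                  "case", "control")
    pheno <- tibble(sample_id = sample_id, sex = sex, age = age, bmi = bmi,
                    t2d = t2d, population = population, panel = population)
    truth <- list(clusters = tibble(snp_id = names(cluster_of),
                                    cluster = unname(cluster_of)),
                  causal_snp = causal_id)
    structure(list(geno = gm, pheno = pheno, truth = truth),
              class = "sim_panel")
  })
}
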