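ht <- default_haplotypes()

test_that("inverse normal transform produces Blom scores with symmetric tails", {
  out <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(out[2], 0)
  expect_equal(out[1], qnorm((1 - 3 / 8) / 3.25))
  expect_equal(out[1], -out[3])

  # rank invariance under a monotone transform
  withr::with_seed(11, {
    x <- rnorm(100)
    expect_equal(inverse_normal_transform(exp(x)),
                 inverse_normal_transform(x))
    # groups transformed independently; concatenation is per-group output
    g <- rep(1:2, each = 50)
    joint <- inverse_normal_transform(x, g)
    expect_equal(joint[g == 1], inverse_normal_transform(x[g == 1]))
    expect_equal(joint[g == 2], inverse_normal_transform(x[g == 2]))
    # near-zero mean within each group
    expect_lt(abs(mean(joint[g == 1])), 1e-8 * 50)
  })

  # missing stays missing; undersized group errors
  expect_true(is.na(inverse_normal_transform(c(1, NA, 3, 4))[2]))
  expect_error(inverse_normal_transform(c(1, 2, 3), c(1, 1, 2)),
               class = "finemapld_transform_error")
})

test_that("ties receive average ranks in the transform", {
  out <- inverse_normal_transform(c(5, 5, 9))
  expect_equal(out[1], out[2])
  expect_equal(out[1], qnorm((1.5 - 3 / 8) / 3.25))
})

test_that("linear association is exact in the noiseless limit and equivariant under allele flips", {
  pc <- population_config("ASN", 500, hap_freqs_for(ht, "ASN"), seed = 12)
  sim <- simulate_panel(pc, effect_config(bmi_beta_per_h1 = 0.07,
                                          noise_sd = 0))
  a <- suppressWarnings(   # lm flags the essentially perfect fit
    linear_assoc(sim$geno, sim$pheno, "rs1421085",
                 covariates = c("age", "sex"), int = FALSE))
  expect_equal(a$beta, 0.07, tolerance = 1e-10)

  # flipping the effect allele negates beta and preserves p
  sim_n <- simulate_panel(pc, effect_config(bmi_beta_per_h1 = 0.07))
  a1 <- linear_assoc(sim_n$geno, sim_n$pheno, "rs1421085")
  a2 <- linear_assoc(flip_effect_allele(sim_n$geno, "rs1421085"),
                     sim_n$pheno, "rs1421085")
  expect_equal(a2$beta, -a1$beta, tolerance = 1e-10)
  expect_equal(a2$p, a1$p, tolerance = 1e-10)
  expect_equal(a2$eaf, 1 - a1$eaf, tolerance = 1e-10)
})

test_that("planted BMI effect is recovered within 2 standard errors", {
  pc <- population_config("ASN", 10000, hap_freqs_for(ht, "ASN"), seed = 13)
  sim <- simulate_panel(pc, effect_config(bmi_beta_per_h1 = 0.07))
  a <- linear_assoc(sim$geno, sim$pheno, "rs1421085")
  expect_lt(abs(a$beta - 0.07), 2 * a$se)
})

test_that("association p-values are uniform under the permutation null", {
  pc <- population_config("ASN", 400, hap_freqs_for(ht, "ASN"), seed = 14)
  sim <- simulate_panel(pc, effect_config(bmi_beta_per_h1 = 0))
  ps <- withr::with_seed(15, vapply(1:200, function(i) {
    ph <- sim$pheno
    ph$bmi <- sample(ph$bmi)
    linear_assoc(sim$geno, ph, "rs1421085")$p
  }, numeric(1)))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("planted disease log-OR is recovered and the null stays at zero", {
  pc <- population_config("ASN", 20000, hap_freqs_for(ht, "ASN"), seed = 16)
  sim <- simulate_panel(pc)   # default log(1.221) per H1 copy
  l <- logistic_assoc(sim$geno, sim$pheno, "rs1421085")
  expect_lt(abs(l$beta - log(1.221)), 2 * l$se)

  sim0 <- simulate_panel(pc, effect_config(t2d_logor_per_h1 = 0), seed = 17)
  l0 <- logistic_assoc(sim0$geno, sim0$pheno, "rs1421085")
  expect_lt(abs(l0$beta), 2 * l0$se)
})

test_that("additive logistic fit equals the closed-form allelic OR under HWE strata", {
  # cases at allele freq 0.3, controls at 0.2, both in exact HWE
  expand <- function(counts, status) {
    tibble::tibble(g = rep(0:2, counts), y = status)
  }
  df <- dplyr::bind_rows(expand(c(490, 420, 90), 1),
                         expand(c(640, 320, 40), 0))
  n <- nrow(df)
  gm <- make_gm(cbind(rsT = df$g))
  ph <- tibble::tibble(sample_id = gm$samples, sex = 1L,
                       age = 50, bmi = NA_real_,
                       t2d = ifelse(df$y == 1, "case", "control"),
                       population = "X", panel = "X")
  fit <- logistic_assoc(gm, ph, "rsT", covariates = character(0))
  allelic_or <- (0.3 / 0.7) / (0.2 / 0.8)
  expect_equal(fit$beta, log(allelic_or), tolerance = 1e-8)
})

test_that("complete separation raises a fit error with a diagnostic", {
  g <- c(rep(0, 30), rep(2, 30))
  gm <- make_gm(cbind(rsS = g))
  ph <- tibble::tibble(sample_id = gm$samples, sex = 1L, age = 50,
                       bmi = NA_real_,
                       t2d = ifelse(g == 2, "case", "control"),
                       population = "X", panel = "X")
  expect_error(logistic_assoc(gm, ph, "rsS", covariates = character(0)),
               class = "finemapld_fit_error")
})

test_that("the direction-consistency rule gates significance", {
  res <- tibble::tibble(snp_id = c("a", "b", "c"),
                        effect_allele = c("T", "T", "T"),
                        other_allele = c("C", "C", "C"),
                        beta = c(0.1, 0.1, 0.05),
                        p = c(0.003, 0.003, 0.412))
  out <- direction_significance(res, c(a = "T", b = "C", c = "T"))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  # negative effect on the non-reference allele is direction-consistent
  res2 <- tibble::tibble(snp_id = "d", effect_allele = "T",
                         other_allele = "C", beta = -0.1, p = 0.001)
  expect_true(direction_significance(res2, c(d = "C"))$significant)
})

test_that("self-conditioning and perfect proxies are flagged indistinguishable", {
  chain <- chain_panel(500, r2_steps = 1, seed = 18)
  self <- pairwise_conditional(chain$geno, chain$pheno, "causal", "causal",
                               "bmi")
  expect_true(self$indistinguishable)
  dup <- pairwise_conditional(chain$geno, chain$pheno, "causal", "proxy1",
                              "bmi")
  expect_true(dup$indistinguishable)
})

test_that("conditioning on an uncorrelated SNP leaves the marginal effect unchanged", {
  withr::with_seed(19, {
    n <- 400
    g_a <- rbinom(n, 2, 0.4)
    g_b_raw <- rbinom(n, 2, 0.4)
    # force exact in-sample orthogonality by residual permutation search
    g_b <- g_b_raw
    for (i in 1:2000) {
      if (abs(cor(g_a, g_b)) < 1e-3) break
      g_b <- sample(g_b)
    }
    gm <- make_gm(cbind(A = g_a, B = g_b))
    ph <- tibble::tibble(sample_id = gm$samples, sex = 1L + rbinom(n, 1, .5),
                         age = runif(n, 35, 74),
                         bmi = 23 + 0.2 * g_a + rnorm(n),
                         t2d = "control", population = "X", panel = "X")
    marg <- linear_assoc(gm, ph, "A")
    cond <- pairwise_conditional(gm, ph, "A", "B", "bmi")
    expect_lt(abs(cond$beta_a_given_b - marg$beta), 5e-3)
    expect_lt(abs(log(cond$p_a_given_b) - log(marg$p)), 0.3)
  })
})

test_that("two truly independent causal SNPs both stay significant conditionally", {
  withr::with_seed(20, {
    n <- 8000
    g_a <- rbinom(n, 2, 0.3)
    g_b <- rbinom(n, 2, 0.3)
    gm <- make_gm(cbind(A = g_a, B = g_b))
    ph <- tibble::tibble(sample_id = gm$samples, sex = 1L + rbinom(n, 1, .5),
                         age = runif(n, 35, 74),
                         bmi = 23 + 0.15 * g_a + 0.15 * g_b + rnorm(n),
                         t2d = "control", population = "X", panel = "X")
    cond <- pairwise_conditional(gm, ph, "A", "B", "bmi")
    expect_lt(cond$p_a_given_b, 0.0056)
    expect_lt(cond$p_b_given_a, 0.0056)
  })
})

test_that("the exclusion screen retains the causal SNP of a proxy chain", {
  chain <- chain_panel(20000, r2_steps = c(0.7, 0.85, 0.85, 0.85), seed = 21)
  snps <- chain$geno$variants$snp_id
  cond <- conditional_all_pairs(chain$geno, chain$pheno, snps, "bmi")
  scr <- exclusion_screen(cond)
  expect_equal(scr$alpha_adj, 0.05 / 5)
  expect_equal(scr$retained, "causal")
  expect_setequal(scr$excluded$snp_id, setdiff(snps, "causal"))
  # one-pass semantics exclude only the SNP losing to every other
  scr1 <- exclusion_screen(cond, iterate = FALSE)
  expect_lte(nrow(scr1$excluded), nrow(scr$excluded))
})

test_that("mutually perfect proxies exclude nothing and coverage gaps error", {
  chain <- chain_panel(500, r2_steps = c(1, 1), seed = 22)
  snps <- chain$geno$variants$snp_id
  cond <- conditional_all_pairs(chain$geno, chain$pheno, snps, "bmi")
  expect_true(all(cond$indistinguishable))
  scr <- exclusion_screen(cond)
  expect_equal(nrow(scr$excluded), 0)
  expect_setequal(scr$retained, snps)
  expect_error(exclusion_screen(cond[-1, ]),
               class = "finemapld_input_error")
})

test_that("the Bonferroni-adjusted level for 9 screened SNPs rounds to 0.0056", {
  cond <- tidyr::expand_grid(snp_a = sprintf("rs%d", 1:9),
                             snp_b = sprintf("rs%d", 1:9)) |>
    dplyr::filter(snp_a < snp_b) |>
    dplyr::mutate(indistinguishable = FALSE,
                  beta_a_given_b = 0.1, se_a_given_b = 0.02,
                  p_a_given_b = 1e-4,
                  beta_b_given_a = 0.1, se_b_given_a = 0.02,
                  p_b_given_a = 1e-4, n = 1000L)
  scr <- exclusion_screen(cond)
  expect_equal(round(scr$alpha_adj, 4), 0.0056)
})
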