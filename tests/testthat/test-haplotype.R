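ht <- default_haplotypes()
ht_sub <- default_haplotypes(include_sub = TRUE)

# panel built from known phased haplotypes; returns geno + true hap counts
phased_panel <- function(hap_codes, k, seed = 1) {
  withr::with_seed(seed, {
    n <- length(hap_codes) / 2
    h1 <- hap_codes[seq(1, 2 * n, 2)]
    h2 <- hap_codes[seq(2, 2 * n, 2)]
    bits <- function(h) vapply(seq_len(k), function(j)
      as.integer(bitwAnd(h, 2^(j - 1)) > 0), integer(1))
    calls <- t(vapply(seq_len(n), function(i) bits(h1[i]) + bits(h2[i]),
                      integer(k)))
    make_gm(calls)
  })
}

test_that("phase-unambiguous panels are phased exactly", {
  # pool of two haplotypes differing at one site: no double heterozygotes,
  # so the MLE is plain haplotype counting
  codes <- c(rep(0L, 55), rep(1L, 45))
  withr::with_seed(41, codes <- sample(codes))
  ph <- em_phase(phased_panel(codes, 2), c("snp1", "snp2"))
  truth <- table(factor(codes, levels = c(0, 1))) / length(codes)
  f <- setNames(ph$haplotypes$freq, ph$haplotypes$code)
  expect_equal(unname(f["0"]), unname(truth["0"]), tolerance = 1e-8)
  expect_equal(unname(f["1"]), unname(truth["1"]), tolerance = 1e-8)
})

test_that("two-SNP phasing agrees with the two-locus EM", {
  withr::with_seed(42, {
    codes <- sample(0:3, 400, TRUE, prob = c(0.4, 0.15, 0.15, 0.3))
    gm <- phased_panel(codes, 2)
    ph <- em_phase(gm, c("snp1", "snp2"))
    h2 <- em_hapfreq2(geno_calls(gm, "snp1"), geno_calls(gm, "snp2"))
    f <- setNames(ph$haplotypes$freq, ph$haplotypes$code)
    # code bit1 = snp1 effect allele (A), bit2 = snp2 (B)
    expect_equal(unname(f["3"]), h2$f_AB, tolerance = 1e-7)
    expect_equal(unname(f["1"]), h2$f_Ab, tolerance = 1e-7)
    expect_equal(unname(f["2"]), h2$f_aB, tolerance = 1e-7)
    expect_equal(unname(f["0"]), h2$f_ab, tolerance = 1e-7)
  })
})

test_that("reference-frequency panels are re-estimated within sampling error", {
  pc <- population_config("ASN", 5000, hap_freqs_for(ht, "ASN"), seed = 43)
  sim <- simulate_panel(pc)
  snps <- setdiff(ht$snp_list$snp_id, "rs7206790")
  ph <- label_haplotypes(em_phase(sim$geno, snps), ht)
  f <- setNames(ph$haplotypes$freq, ph$haplotypes$hap)
  for (h in names(pc$hap_freqs)) {
    tr <- pc$hap_freqs[h]
    se3 <- 3 * sqrt(tr * (1 - tr) / (2 * pc$n_samples))
    expect_lt(abs(f[h] - tr), se3)
  }
})

test_that("dosages are conserved and match hand-computed posteriors", {
  withr::with_seed(44, {
    # two-locus pool with all four haplotypes present
    codes <- sample(0:3, 600, TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
    gm <- phased_panel(codes, 2)
    ph <- em_phase(gm, c("snp1", "snp2"))

    # total dosage over all haplotypes is exactly 2 for every sample
    total <- Reduce(`+`, lapply(ph$haplotypes$hap,
                                function(h) haplotype_dosage(ph, h)))
    expect_equal(unname(total), rep(2, length(ph$samples)), tolerance = 1e-12)

    # hand-computed double-heterozygote posterior from the fitted freqs
    f <- setNames(ph$haplotypes$freq, ph$haplotypes$code)
    p_cis <- 2 * f["3"] * f["0"] / (2 * f["3"] * f["0"] + 2 * f["1"] * f["2"])
    dhet <- ph$samples[geno_calls(gm, "snp1")[match(ph$samples, gm$samples)] == 1 &
                         geno_calls(gm, "snp2")[match(ph$samples, gm$samples)] == 1]
    lab_ab <- ph$haplotypes$hap[ph$haplotypes$code == 3]
    d <- haplotype_dosage(ph, lab_ab)
    expect_equal(unname(d[dhet[1]]), unname(p_cis), tolerance = 1e-8)
  })
})

test_that("a sample compatible only with a homozygous diplotype gets dosage 2", {
  pc <- population_config("ASN", 400, hap_freqs_for(ht, "ASN"), seed = 45)
  sim <- simulate_panel(pc)
  snps <- setdiff(ht$snp_list$snp_id, "rs7206790")
  ph <- label_haplotypes(em_phase(sim$geno, snps), ht)
  hom <- sim$truth$diplotypes$sample_id[
    sim$truth$diplotypes$hap1 == "H1" & sim$truth$diplotypes$hap2 == "H1"]
  hom <- intersect(hom, ph$samples)
  d <- haplotype_dosage(ph, "H1")
  expect_true(all(abs(d[hom] - 2) < 1e-9))
  expect_error(haplotype_dosage(ph, "H9"), class = "finemapld_key_error")
})

test_that("haplotype-dosage association recovers the planted H1 effect", {
  pc <- population_config("ASN", 15000, hap_freqs_for(ht, "ASN"), seed = 46)
  sim <- simulate_panel(pc, effect_config(bmi_beta_per_h1 = 0.064))
  snps <- setdiff(ht$snp_list$snp_id, "rs7206790")
  ph <- label_haplotypes(em_phase(sim$geno, snps), ht)
  a <- haplotype_assoc(ph, sim$pheno, "H1", "bmi")
  expect_lt(abs(a$beta - 0.064), 2 * a$se)
})

test_that("dosage regression reduces to the single-SNP model when the target tags one allele", {
  withr::with_seed(47, {
    # only two haplotypes, differing at snp2: dosage(target) == genotype(snp2)
    codes <- sample(c(0L, 2L), 500, TRUE, prob = c(0.7, 0.3))
    gm <- phased_panel(codes, 2)
    ph <- em_phase(gm, c("snp1", "snp2"))
    n <- length(gm$samples)
    pheno <- tibble::tibble(sample_id = gm$samples,
                            sex = 1L + rbinom(n, 1, .5),
                            age = runif(n, 35, 74),
                            bmi = 23 + 0.1 *
                              geno_calls(gm, "snp2")[seq_len(n)] + rnorm(n),
                            t2d = "control", population = "X", panel = "X")
    target <- ph$haplotypes$hap[ph$haplotypes$code == 2]
    a_hap <- haplotype_assoc(ph, pheno, target, "bmi")
    a_snp <- linear_assoc(gm, pheno, "snp2")
    expect_equal(a_hap$beta, a_snp$beta, tolerance = 1e-6)
    expect_equal(a_hap$p, a_snp$p, tolerance = 1e-6)
  })
})

test_that("an absent target haplotype raises a degenerate-variance error", {
  pc <- population_config("SriLankan", 400,
                          c(H1 = 0.3, H3 = 0.6, H4 = 0.1), seed = 48)
  sim <- simulate_panel(pc)
  snps <- setdiff(ht$snp_list$snp_id, "rs7206790")
  ph <- label_haplotypes(em_phase(sim$geno, snps), ht_sub)
  expect_error(haplotype_assoc(ph, sim$pheno, "H3-4", "bmi"),
               class = "finemapld_degenerate_error")
})

test_that("phasing preconditions are enforced", {
  gm <- make_gm(matrix(NA_integer_, 30, 2))
  expect_error(em_phase(gm, c("snp1", "snp2")),
               class = "finemapld_input_error")
  gm2 <- make_gm(matrix(0L, 30, 1))
  expect_error(em_phase(gm2, "snp1"), class = "finemapld_input_error")
})

test_that("the principal-haplotype phylogeny has the expected topology", {
  net <- build_phylogeny(ht)
  e <- net$edges
  expect_equal(e$kind, rep("mutation", 3))
  h2h3 <- e[e$child == "H3", ]
  expect_equal(h2h3$parent, "H2")
  expect_equal(h2h3$detail, "rs9939609")
  h3h4 <- e[e$child == "H4", ]
  expect_equal(h3h4$parent, "H3")
  expect_equal(h3h4$detail, "rs9941349")
  h2h1 <- e[e$child == "H1", ]
  expect_equal(h2h1$parent, "H2")
  expect_equal(h2h1$n_events, 6L)
  expect_setequal(strsplit(h2h1$detail, ",")[[1]],
                  c("rs1421085", "rs3751812", "rs9941349", "rs56137030",
                    "rs17817964", "rs12149832"))
})

test_that("a constructed single-crossover haplotype is classified as recombinant", {
  sites <- ht$snp_list$snp_id[!ht$snp_list$recombinant]
  rec <- ht$alleles["H1", ]
  right <- sites[4:7]
  rec[right] <- ht$alleles["H3", right]
  ht2 <- ht
  ht2$alleles <- rbind(ht$alleles, R1 = rec)
  ht2$freqs <- dplyr::bind_rows(ht2$freqs,
                                tibble::tibble(haplotype = "R1",
                                               population = "ASN",
                                               freq = 0.05))
  net <- build_phylogeny(ht2)
  e <- net$edges[net$edges$child == "R1", ]
  expect_equal(e$kind, "recombination")
  expect_equal(e$n_events, 1L)
  # breakpoint interval lies where the parents differ
  expect_match(e$detail, "breakpoint")
  expect_setequal(sort(c(e$parent, e$other_parent)), c("H1", "H3"))
})

test_that("phylogeny events are parsimony-bounded and degenerate inputs handled", {
  net <- build_phylogeny(ht_sub, freq_floor = 0,
                         keep = rownames(ht_sub$alleles))
  star <- sum(vapply(setdiff(net$nodes$label, "H2"), function(h)
    length(hap_diff(ht_sub, h, "H2")), numeric(1)))
  expect_lte(sum(net$edges$n_events), star)

  # only the ancestral haplotype: a single-node network
  ht1 <- ht
  ht1$alleles <- ht$alleles["H2", , drop = FALSE]
  ht1$freqs <- dplyr::filter(ht$freqs, haplotype == "H2")
  net1 <- build_phylogeny(ht1)
  expect_equal(net1$nodes$label, "H2")
  expect_equal(nrow(net1$edges), 0)

  expect_error(build_phylogeny(ht, ancestral = "H99"),
               class = "finemapld_input_error")
})

test_that("mutation-only networks export to Newick", {
  nw <- phylo_newick(build_phylogeny(ht))
  expect_match(nw, "^\\(.*H2;$")
  expect_match(nw, "H4:1")
  tr <- ape::read.tree(text = nw)
  expect_setequal(c(tr$tip.label, tr$node.label),
                  c("H1", "H2", "H3", "H4"))
})
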