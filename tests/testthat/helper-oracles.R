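# Independent oracles and small panel builders used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quick genotype-matrix builder from a samples x SNPs call matrix.
make_gm <- function(calls, ids = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  k <- ncol(calls)
  ids <- ids %||% (colnames(calls) %||% sprintf("snp%d", seq_len(k)))
  v <- tibble::tibble(snp_id = ids, chrom = "16",
                      pos = pos %||% (1000L * seq_len(k)),
                      allele_a = "T", allele_b = "C", effect_allele = "C")
  geno_matrix(v, sprintf("s%04d", seq_len(nrow(calls))), calls)
}

# Canonical form for semantic genotype-matrix comparison: allele order may
# swap across a write/read cycle, but ids, positions, allele sets, effect
# designations and calls must survive.
geno_canonical <- function(gm) {
  v <- gm$variants
  other <- ifelse(v$effect_allele == v$allele_a, v$allele_b, v$allele_a)
  list(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
       effect = v$effect_allele, other = other,
       samples = gm$samples, calls = unname(gm$calls))
}

expect_geno_equal <- function(a, b) {
  expect_equal(geno_canonical(a), geno_canonical(b))
}

# Brute-force two-locus ML oracle, independent of the EM path: coarse
# simplex grid over (f_AB, f_Ab, f_aB) followed by Nelder-Mead refinement
# of the best grid point on a softmax parameterisation.
grid_oracle_loglik <- function(tab, step = 0.02) {
  ll <- function(f) finemapld:::hapfreq2_loglik(f, tab)
  g <- seq(0, 1, by = step)
  grid <- expand.grid(f1 = g, f2 = g, f3 = g)
  grid <- grid[grid$f1 + grid$f2 + grid$f3 <= 1, ]
  vals <- apply(grid, 1, function(x) ll(c(x, 1 - sum(x))))
  best <- as.numeric(grid[which.max(vals), ])
  start <- log(pmax(c(best, 1 - sum(best)), 1e-4))
  opt <- optim(start, function(th) -ll(exp(th) / sum(exp(th))),
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  max(max(vals), -opt$value)
}

# Random two-locus genotype-pair count table with n individuals, both loci
# guaranteed polymorphic.
random_geno_tab <- function(n = 20) {
  repeat {
    p <- runif(9)
    tab <- matrix(as.numeric(rmultinom(1, n, p)), 3, 3)
    ga <- rowSums(tab) %*% c(0, 1, 2) / (2 * n)
    gb <- colSums(tab) %*% c(0, 1, 2) / (2 * n)
    if (ga > 0 && ga < 1 && gb > 0 && gb < 1) return(tab)
  }
}

# Exhaustive-enumeration HWE oracle, coded independently with exact
# combinatorics (small n only).
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n2 + n1              # effect-allele copies
  nb <- 2 * n0 + n1
  nm <- min(na, nb)
  if (nm == 0) return(1)
  prob_of <- function(h) {
    homm <- (nm - h) / 2
    homM <- (max(na, nb) - h) / 2
    exp(lchoose(n, homm) + lchoose(n - homm, h) + h * log(2) +
          lgamma(nm + 1) + lgamma(2 * n - nm + 1) - lgamma(2 * n + 1))
  }
  hs <- seq(nm %% 2, nm, by = 2)
  pr <- vapply(hs, prob_of, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n1, hs)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Markov-chain proxy panel: each SNP is a noisy copy of the previous one,
# so conditioning on the adjacent SNP removes all trait signal of the
# farther one. r2_steps are per-step haplotype r2 targets.
chain_panel <- function(n, r2_steps = c(0.7, 0.95, 0.93, 0.9),
                        maf = 0.3, beta = 0.15, seed = 1) {
  withr::with_seed(seed, {
    flip <- function(h, r2) {
      eps <- (1 - sqrt(r2)) / 2
      abs(h - rbinom(length(h), 1, eps))
    }
    h1 <- rbinom(n, 1, maf); h2 <- rbinom(n, 1, maf)
    haps1 <- list(h1); haps2 <- list(h2)
    for (r in r2_steps) {
      haps1 <- c(haps1, list(flip(haps1[[length(haps1)]], r)))
      haps2 <- c(haps2, list(flip(haps2[[length(haps2)]], r)))
    }
    calls <- mapply(function(a, b) a + b, haps1, haps2)
    colnames(calls) <- c("causal", sprintf("proxy%d", seq_along(r2_steps)))
    gm <- make_gm(calls)
    pheno <- tibble::tibble(
      sample_id = gm$samples, sex = 1L + rbinom(n, 1, 0.5),
      age = runif(n, 35, 74),
      bmi = 23 + beta * (h1 + h2) + rnorm(n),
      t2d = "control", population = "SIM", panel = "SIM")
    list(geno = gm, pheno = pheno)
  })
}
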