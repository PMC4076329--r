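is_polymorphic <- function(g) {
  g <- g[!is.na(g)]
  length(g) > 0 && min(g) != max(g)
}

genopair_counts <- function(g_a, g_b) {
  keep <- !is.na(g_a) & !is.na(g_b)
  tab <- matrix(0, 3, 3)
  if (any(keep)) {
    t0 <- table(factor(g_a[keep], levels = 0:2),
                factor(g_b[keep], levels = 0:2))
    tab <- matrix(as.numeric(t0), 3, 3)
  }
  tab
}

hapfreq2_loglik <- function(f, tab) {
  # f = c(AB, Ab, aB, ab); tab[i+1, j+1] = count with i copies of A, j of B
  P <- matrix(0, 3, 3)
  P[3, 3] <- f[1]^2;           P[3, 2] <- 2 * f[1] * f[2]; P[3, 1] <- f[2]^2
  P[2, 3] <- 2 * f[1] * f[3]
  P[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
  P[2, 1] <- 2 * f[2] * f[4]
  P[1, 3] <- f[3]^2;           P[1, 2] <- 2 * f[3] * f[4]; P[1, 1] <- f[4]^2
  use <- tab > 0
  sum(tab[use] * log(pmax(P[use], 1e-300)))
}

#' Two-locus haplotype frequencies by EM from unphased genotypes
#'
#' Maximum-likelihood estimation of the four two-locus haplotype
#' frequencies from genotype pairs, resolving double-heterozygote phase by
#' expected counts. The "A"/"B" alleles are the effect-allele codings of
#' the two genotype vectors. Starts from linkage equilibrium and iterates
#' until the largest absolute frequency change falls below `tol`.
#'
#' @param g_a,g_b Genotype vectors (0/1/2/NA) of equal length.
#' @param tol Convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @return A list of class `hapfreq2`: `f_AB`, `f_Ab`, `f_aB`, `f_ab`,
#'   `n_used`, `loglik`, `p_A`, `p_B`, `n_iter`.
#' @export
em_hapfreq2 <- function(g_a, g_b, tol = 1e-10, max_iter = 1000L) {
  if (length(g_a) != length(g_b)) {
    abort("genotype vectors must have equal length", class = "finemapld_input_error")
  }
  keep <- !is.na(g_a) & !is.na(g_b)
  if (sum(keep) < 2) {
    abort("need at least 2 complete genotype pairs", class = "finemapld_input_error")
  }
  if (!is_polymorphic(g_a[keep]) || !is_polymorphic(g_b[keep])) {
    abort("monomorphic SNP among complete pairs: LD undefined",
          class = "finemapld_degenerate_error")
  }
  tab <- genopair_counts(g_a, g_b)
  n <- sum(tab)
  pA <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  pB <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  run_em <- function(f) {
    it <- 0L
    repeat {
      it <- it + 1L
      denom <- f[1] * f[4] + f[2] * f[3]
      p_cis <- if (denom > 0) f[1] * f[4] / denom else 0.5
      cAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + p_cis * tab[2, 2]
      cAb <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + (1 - p_cis) * tab[2, 2]
      caB <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3] + (1 - p_cis) * tab[2, 2]
      cab <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1] + p_cis * tab[2, 2]
      f_new <- c(cAB, cAb, caB, cab) / (2 * n)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol || it >= max_iter) break
    }
    list(f = f, loglik = hapfreq2_loglik(f, tab), it = it)
  }
  # multiple deterministic starts guard against local optima: linkage
  # equilibrium plus near-extreme coupling and repulsion configurations
  le <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  d_hi <- min(pA, pB) - pA * pB
  d_lo <- max(0, pA + pB - 1) - pA * pB
  corner <- function(D) le + c(D, -D, -D, D)
  starts <- list(le,
                 0.98 * corner(d_hi) + 0.02 * le,
                 0.98 * corner(d_lo) + 0.02 * le)
  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  f <- best$f
  structure(list(f_AB = f[1], f_Ab = f[2], f_aB = f[3], f_ab = f[4],
                 n_used = as.integer(n),
                 loglik = best$loglik,
                 p_A = f[1] + f[2], p_B = f[1] + f[3], n_iter = best$it),
            class = "hapfreq2")
}

#' LD statistics from two-locus haplotype frequencies
#'
#' Computes the disequilibrium `D = f_AB - p_A p_B`, the squared
#' correlation `r2 = D^2 / (p_A q_A p_B q_B)` and the normalised
#' `D' = |D| / Dmax`, with `Dmax = min(p_A q_B, q_A p_B)` when `D > 0` and
#' `min(p_A p_B, q_A q_B)` otherwise.
#'
#' @param h A `hapfreq2` (from [em_hapfreq2()]) or a numeric vector of the
#'   four haplotype frequencies `(AB, Ab, aB, ab)`.
#' @param snp_a,snp_b Optional SNP labels carried into the result.
#' @return One-row tibble: `snp_a`, `snp_b`, `r2`, `d_prime`, `D`,
#'   `n_used`.
#' @export
ld_stats <- function(h, snp_a = NA_character_, snp_b = NA_character_) {
  if (inherits(h, "hapfreq2")) {
    f <- c(h$f_AB, h$f_Ab, h$f_aB, h$f_ab)
    n_used <- h$n_used
  } else {
    f <- as.numeric(h)
    n_used <- NA_integer_
  }
  stopifnot(length(f) == 4)
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  qA <- 1 - pA; qB <- 1 - pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    abort("degenerate marginals: LD undefined", class = "finemapld_degenerate_error")
  }
  D <- f[1] - pA * pB
  r2 <- D^2 / (pA * qA * pB * qB)
  dmax <- if (D > 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  d_prime <- if (D == 0) 0 else abs(D) / dmax
  tibble(snp_a = snp_a, snp_b = snp_b, r2 = r2, d_prime = d_prime, D = D,
         n_used = n_used)
}

#' Pairwise LD between a SNP pair of a genotype panel
#'
#' @param gm A [geno_matrix()].
#' @param snp_a,snp_b SNP ids in `gm`.
#' @return One-row tibble as in [ld_stats()].
#' @export
ld_pair <- function(gm, snp_a, snp_b) {
  h <- em_hapfreq2(geno_calls(gm, snp_a), geno_calls(gm, snp_b))
  ld_stats(h, snp_a, snp_b)
}

#' All pairwise LD within a SNP list
#'
#' Monomorphic SNPs (for which LD is undefined) are dropped with a
#' warning. Pairs farther apart than `window_bp` are skipped.
#'
#' @param gm A [geno_matrix()].
#' @param snps SNP ids; default all in the panel.
#' @param window_bp Maximum distance between pair members (default `Inf`).
#' @return Tibble of unordered pairs: `snp_a`, `snp_b`, `r2`, `d_prime`,
#'   `D`, `n_used`.
#' @export
ld_pairs <- function(gm, snps = gm$variants$snp_id, window_bp = Inf) {
  poly <- snps[vapply(snps, function(s) is_polymorphic(geno_calls(gm, s)),
                      logical(1))]
  if (length(poly) < length(snps)) {
    warn(paste0("dropping monomorphic SNP(s): ",
                paste(setdiff(snps, poly), collapse = ", ")))
  }
  if (length(poly) < 2) {
    return(tibble(snp_a = character(), snp_b = character(), r2 = numeric(),
                  d_prime = numeric(), D = numeric(), n_used = integer()))
  }
  pos <- setNames(gm$variants$pos, gm$variants$snp_id)[poly]
  cmb <- utils::combn(poly, 2)
  out <- vector("list", ncol(cmb))
  j <- 0L
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1, k]; b <- cmb[2, k]
    if (abs(pos[a] - pos[b]) > window_bp) next
    j <- j + 1L
    out[[j]] <- ld_pair(gm, a, b)
  }
  bind_rows(out[seq_len(j)])
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: enumerates all heterozygote counts compatible
#' with the observed allele counts and sums the probabilities of tables no
#' more probable than the observed one (two-sided, no mid-p correction).
#' Used as the panel QC gate (retain SNPs with p > 0.01).
#'
#' @param g Genotype vector (0/1/2/NA), or a length-3 vector of genotype
#'   counts `c(n0, n1, n2)` when `counts = TRUE`.
#' @param counts Interpret `g` as genotype counts.
#' @return Two-sided exact p-value.
#' @export
hwe_test <- function(g, counts = FALSE) {
  if (counts) {
    nv <- as.numeric(g)
  } else {
    g <- g[!is.na(g)]
    if (length(g) < 1) abort("need at least one genotype",
                             class = "finemapld_input_error")
    nv <- as.numeric(table(factor(g, levels = 0:2)))
  }
  n <- sum(nv)
  n_eff <- 2 * nv[3] + nv[2]        # copies of the effect allele
  n_oth <- 2 * nv[1] + nv[2]
  n_m <- min(n_eff, n_oth)
  if (n_m == 0) return(1)
  hets <- seq(n_m %% 2, n_m, by = 2)
  logp <- vapply(hets, function(h) {
    hom_m <- (n_m - h) / 2
    hom_M <- (max(n_eff, n_oth) - h) / 2
    h * log(2) + lgamma(n + 1) - lgamma(hom_m + 1) - lgamma(h + 1) -
      lgamma(hom_M + 1) + lgamma(n_m + 1) + lgamma(2 * n - n_m + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(nv[2], hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg QC over a panel
#'
#' @param gm A [geno_matrix()].
#' @param p_threshold Retention rule: a SNP passes when its exact HWE p
#'   exceeds this (default 0.01). Failing SNPs are flagged, not dropped.
#' @return Tibble: `snp_id`, `p_hwe`, `pass`.
#' @export
hwe_screen <- function(gm, p_threshold = 0.01) {
  tibble(snp_id = gm$variants$snp_id,
         p_hwe = vapply(gm$variants$snp_id,
                        function(s) hwe_test(geno_calls(gm, s)), numeric(1))) |>
    mutate(pass = .data$p_hwe > p_threshold)
}

#' Proxy set of an index SNP
#'
#' All SNPs whose EM-estimated r-squared with the index reaches the
#' threshold; always contains the index itself. Monomorphic partners are
#' skipped (LD undefined).
#'
#' @param index_snp SNP id present in the panel.
#' @param panel A [geno_matrix()].
#' @param r2_threshold Minimum r-squared (0 admits every polymorphic SNP).
#' @param snps Candidate SNP ids (default: whole panel).
#' @return Character vector of SNP ids.
#' @export
proxy_set <- function(index_snp, panel, r2_threshold,
                      snps = panel$variants$snp_id) {
  g_i <- geno_calls(panel, index_snp)
  if (!is_polymorphic(g_i)) {
    abort(paste0("index SNP is monomorphic: ", index_snp),
          class = "finemapld_degenerate_error")
  }
  others <- setdiff(snps, index_snp)
  hit <- vapply(others, function(s) {
    g <- geno_calls(panel, s)
    if (!is_polymorphic(g)) return(FALSE)
    ld_stats(em_hapfreq2(g_i, g), index_snp, s)$r2 >= r2_threshold
  }, logical(1))
  c(index_snp, others[hit])
}
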