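# Ordered diplotype resolutions compatible with one multilocus genotype.
# Haplotypes are bit-coded: bit j set = effect allele carried at SNP j.
compatible_pairs <- function(g) {
  k <- length(g)
  bits <- 2^(seq_len(k) - 1)
  base <- sum(bits[g == 2L])
  het <- which(g == 1L)
  if (length(het) == 0) return(matrix(base, 2, 1))
  n_h <- length(het)
  combos <- as.matrix(expand.grid(rep(list(0:1), n_h)))
  h1 <- base + combos %*% bits[het]
  h2 <- base + (1 - combos) %*% bits[het]
  rbind(as.numeric(h1), as.numeric(h2))
}

hap_code_label <- function(code, variants) {
  k <- nrow(variants)
  other <- ifelse(variants$effect_allele == variants$allele_a,
                  variants$allele_b, variants$allele_a)
  vapply(code, function(h) {
    carries <- bitwAnd(h, 2^(seq_len(k) - 1)) > 0
    paste(ifelse(carries, variants$effect_allele, other), collapse = "")
  }, character(1))
}

#' Multilocus EM haplotype phasing
#'
#' Estimates haplotype frequencies over a short SNP list (2-12 sites; the
#' diplotype space is expanded exhaustively) from unphased genotypes by
#' EM, retaining per-sample posterior probabilities over ordered
#' haplotype pairs. Starts uniform over haplotypes compatible with the
#' observed genotypes; the log-likelihood is checked to be non-decreasing
#' at every iteration. Haplotypes with converged frequency below `prune`
#' are removed afterwards (unless a sample would lose all compatible
#' diplotypes).
#'
#' @param gm A [geno_matrix()].
#' @param snp_list SNP ids to phase over (order defines the haplotype
#'   strings).
#' @param tol Convergence tolerance on the max absolute frequency change.
#' @param max_iter Iteration cap.
#' @param prune Post-convergence frequency floor.
#' @param min_samples Minimum complete samples required (default 20).
#' @return Object of class `hap_phase`: `variants` (tibble), `haplotypes`
#'   (tibble `hap` allele-string label, `code`, `freq`), `posterior`
#'   (tibble `sample_id`, `hap1`, `hap2`, `prob` over ordered pairs),
#'   `samples` (complete samples used), `loglik`, `n_iter`.
#' @export
em_phase <- function(gm, snp_list, tol = 1e-8, max_iter = 5000L,
                     prune = 1e-4, min_samples = 20L) {
  k <- length(snp_list)
  if (k < 2 || k > 12) abort("snp_list must have 2..12 SNPs",
                             class = "finemapld_input_error")
  G <- gm$calls[, snp_list, drop = FALSE]
  complete <- which(rowSums(is.na(G)) == 0)
  if (length(complete) == 0) abort("all samples have incomplete genotypes",
                                   class = "finemapld_input_error")
  if (length(complete) < min_samples) {
    abort(sprintf("only %d complete samples (< %d)", length(complete),
                  min_samples), class = "finemapld_input_error")
  }
  G <- G[complete, , drop = FALSE]
  samples <- gm$samples[complete]
  pat_key <- apply(G, 1, paste, collapse = "")
  upat <- !duplicated(pat_key)
  patterns <- G[upat, , drop = FALSE]
  pat_n <- as.numeric(table(pat_key)[pat_key[upat]])
  pairs <- lapply(seq_len(nrow(patterns)), function(i)
    compatible_pairs(patterns[i, ]))

  universe <- sort(unique(unlist(pairs)))
  f <- setNames(rep(1 / length(universe), length(universe)),
                as.character(universe))
  n_tot <- sum(pat_n)
  loglik_prev <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    counts <- setNames(numeric(length(f)), names(f))
    loglik <- 0
    for (i in seq_along(pairs)) {
      pp <- pairs[[i]]
      w <- f[as.character(pp[1, ])] * f[as.character(pp[2, ])]
      s <- sum(w)
      loglik <- loglik + pat_n[i] * log(max(s, 1e-300))
      post <- w / s
      add1 <- tapply(pat_n[i] * post, pp[1, ], sum)
      add2 <- tapply(pat_n[i] * post, pp[2, ], sum)
      counts[names(add1)] <- counts[names(add1)] + add1
      counts[names(add2)] <- counts[names(add2)] + add2
    }
    if (loglik < loglik_prev - 1e-9 * max(1, abs(loglik_prev))) {
      abort("EM log-likelihood decreased: numerical failure",
            class = "finemapld_numeric_error")
    }
    loglik_prev <- loglik
    f_new <- counts / (2 * n_tot)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || it >= max_iter) break
  }

  # prune rare haplotypes, protecting patterns that would lose all pairs
  keep <- f >= prune
  for (i in seq_along(pairs)) {
    pp <- pairs[[i]]
    ok <- keep[as.character(pp[1, ])] & keep[as.character(pp[2, ])]
    if (!any(ok)) {
      w <- f[as.character(pp[1, ])] * f[as.character(pp[2, ])]
      best <- which.max(w)
      keep[as.character(pp[, best])] <- TRUE
    }
  }
  f <- f[keep]
  f <- f / sum(f)

  variants <- gm$variants[match(snp_list, gm$variants$snp_id), ]
  labels <- setNames(hap_code_label(as.numeric(names(f)), variants), names(f))

  post_rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pp <- pairs[[i]]
    ok <- as.character(pp[1, ]) %in% names(f) &
      as.character(pp[2, ]) %in% names(f)
    pp <- pp[, ok, drop = FALSE]
    w <- f[as.character(pp[1, ])] * f[as.character(pp[2, ])]
    post_rows[[i]] <- tibble(pattern = i,
                             hap1 = labels[as.character(pp[1, ])],
                             hap2 = labels[as.character(pp[2, ])],
                             prob = w / sum(w))
  }
  pat_of_sample <- match(pat_key, pat_key[upat])
  posterior <- purrr::map_dfr(seq_along(samples), function(s) {
    pr <- post_rows[[pat_of_sample[s]]]
    tibble(sample_id = samples[s], hap1 = pr$hap1, hap2 = pr$hap2,
           prob = pr$prob)
  })

  structure(list(
    variants = variants,
    haplotypes = tibble(hap = unname(labels), code = as.numeric(names(f)),
                        freq = unname(f)) |> arrange(desc(.data$freq)),
    posterior = posterior, samples = samples,
    loglik = loglik_prev, n_iter = it
  ), class = "hap_phase")
}

#' @export
print.hap_phase <- function(x, ...) {
  cat(sprintf("<hap_phase> %d haplotypes over %d SNPs, %d samples, loglik %.2f\n",
              nrow(x$haplotypes), nrow(x$variants), length(x$samples),
              x$loglik))
  print(x$haplotypes)
  invisible(x)
}

#' Relabel phased haplotypes by matching a reference haplotype table
#'
#' Allele-string labels that match a reference haplotype (over the phased
#' SNPs) are replaced by the reference label (e.g. `H1`); unmatched
#' haplotypes keep their allele string.
#'
#' @param phase A [em_phase()] result.
#' @param ht A `hap_table` ([default_haplotypes()]).
#' @return The relabelled `hap_phase`.
#' @export
label_haplotypes <- function(phase, ht) {
  if (!all(phase$variants$snp_id %in% colnames(ht$alleles))) {
    abort("reference table lacks some phased SNPs",
          class = "finemapld_input_error")
  }
  ref <- apply(ht$alleles[, phase$variants$snp_id, drop = FALSE], 1,
               paste, collapse = "")
  map <- setNames(names(ref), ref)
  relab <- function(x) ifelse(x %in% names(map), map[x], x)
  phase$haplotypes$hap <- unname(relab(phase$haplotypes$hap))
  phase$posterior$hap1 <- unname(relab(phase$posterior$hap1))
  phase$posterior$hap2 <- unname(relab(phase$posterior$hap2))
  phase
}

#' Posterior haplotype dosage
#'
#' Expected number of copies of the target haplotype carried by each
#' sample, from the phasing posterior: `sum over ordered pairs
#' P(pair | sample) x copies of target in the pair`. Dosages over all
#' haplotypes sum to 2 for every sample.
#'
#' @param phase A [em_phase()] result (possibly relabelled).
#' @param target Haplotype label present in `phase$haplotypes$hap`.
#' @return Named numeric vector (by sample id) of dosages in `[0, 2]`.
#' @export
haplotype_dosage <- function(phase, target) {
  if (!target %in% phase$haplotypes$hap) {
    abort(paste0("unknown haplotype label: ", target),
          class = "finemapld_key_error")
  }
  d <- phase$posterior |>
    mutate(copies = (.data$hap1 == target) + (.data$hap2 == target)) |>
    group_by(.data$sample_id) |>
    summarise(dosage = sum(.data$prob * .data$copies))
  setNames(d$dosage, d$sample_id)[phase$samples]
}

#' Haplotype-dosage association with a trait
#'
#' Regresses the trait on the posterior dosage of the target haplotype:
#' linear on the inverse-normal transformed quantitative trait (age,
#' age-squared adjusted) or logistic on disease status (sex adjusted).
#' Run per population; combine with [fixed_effect_meta()].
#'
#' @param phase A [em_phase()] result.
#' @param pheno Phenotype tibble covering the phased samples.
#' @param target Haplotype label.
#' @param trait `"bmi"` or `"t2d"`.
#' @return One-row association tibble (`snp_id` holds `hap:<label>`;
#'   `beta` is per haplotype copy, log-OR for disease).
#' @export
haplotype_assoc <- function(phase, pheno, target, trait = c("bmi", "t2d")) {
  trait <- match.arg(trait)
  dos <- tryCatch(haplotype_dosage(phase, target),
                  finemapld_key_error = function(e) {
                    abort(paste0("haplotype ", target,
                                 " absent from this population"),
                          class = "finemapld_degenerate_error")
                  })
  if (var(dos) <= 0) {
    abort(paste0("degenerate dosage variance for haplotype ", target),
          class = "finemapld_degenerate_error")
  }
  idx <- match(phase$samples, pheno$sample_id)
  if (anyNA(idx)) abort("phenotype table lacks phased samples",
                        class = "finemapld_input_error")
  ph <- pheno[idx, ]
  if (trait == "bmi") {
    y <- inverse_normal_transform(ph$bmi, ph$sex)
    df <- tibble(y = y, g = dos, age = ph$age, age2 = ph$age^2)
    df <- df[complete.cases(df), ]
    fit <- lm(y ~ g + age + age2, data = df)
  } else {
    y <- ifelse(ph$t2d == "case", 1, ifelse(ph$t2d == "control", 0, NA))
    df <- tibble(y = y, g = dos, sex = as.numeric(ph$sex))
    df <- df[complete.cases(df), ]
    fit <- suppressWarnings(glm(y ~ g + sex, data = df, family = binomial()))
  }
  cf <- summary(fit)$coefficients
  tibble(snp_id = paste0("hap:", target), trait = trait,
         effect_allele = target, other_allele = "other",
         eaf = mean(dos) / 2,
         beta = cf["g", 1], se = cf["g", 2], p = cf["g", 4],
         n = as.integer(stats::nobs(fit)),
         population = ph$population[1],
         covariates = if (trait == "bmi") "age+age2" else "sex")
}
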