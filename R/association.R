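#' Rank-based inverse normal transformation
#'
#' Blom scores computed separately within each group (in GWAS practice the
#' groups are the sexes): a value with (average, for ties) rank `r` among
#' `n` non-missing values maps to `qnorm((r - 3/8) / (n + 1/4))`. Missing
#' values stay missing.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector, recycled against `values`; default one
#'   group.
#' @return Transformed numeric vector, same length and order.
#' @export
inverse_normal_transform <- function(values, groups = rep(1L, length(values))) {
  if (length(groups) != length(values)) {
    abort("values and groups must have equal length", class = "finemapld_input_error")
  }
  out <- rep(NA_real_, length(values))
  for (g in unique(groups[!is.na(values)])) {
    i <- which(groups == g & !is.na(values))
    if (length(i) < 2) {
      abort(sprintf("group '%s' has fewer than 2 non-missing values", g),
            class = "finemapld_transform_error")
    }
    r <- rank(values[i], ties.method = "average")
    out[i] <- qnorm((r - 3 / 8) / (length(i) + 1 / 4))
  }
  out
}

# Align phenotype rows to the panel's sample order; complete-case on the
# needed columns is handled downstream.
aligned_pheno <- function(gm, pheno) {
  idx <- match(gm$samples, pheno$sample_id)
  if (anyNA(idx)) {
    abort("phenotype table lacks rows for some panel samples",
          class = "finemapld_input_error")
  }
  pheno[idx, ]
}

assoc_row <- function(fit, term, snp_id, trait, gm, g, pheno_pop, covariates) {
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit))) {
    abort("rank-deficient fit: collinear covariates or genotype",
          class = "finemapld_rank_error")
  }
  v <- gm$variants[gm$variants$snp_id == snp_id, ]
  eaf <- mean(g, na.rm = TRUE) / 2
  tibble(snp_id = snp_id, trait = trait,
         effect_allele = v$effect_allele,
         other_allele = ifelse(v$effect_allele == v$allele_a,
                               v$allele_b, v$allele_a),
         eaf = eaf,
         beta = cf[term, 1], se = cf[term, 2], p = cf[term, 4],
         n = as.integer(stats::nobs(fit)),
         population = pheno_pop,
         covariates = paste(covariates, collapse = "+"))
}

#' Single-SNP linear association with a quantitative trait
#'
#' Ordinary least squares of the (by default inverse-normal transformed,
#' per sex) trait on the additive 0/1/2 effect-allele count, adjusted for
#' age and age-squared.
#'
#' @param gm A [geno_matrix()].
#' @param pheno Phenotype tibble with `sample_id`, `sex`, `age`, and the
#'   trait column.
#' @param snp_id SNP to test.
#' @param covariates Covariate set; `"age2"` expands to age-squared.
#' @param int Apply the per-sex inverse normal transformation to the trait
#'   before fitting (default TRUE).
#' @param trait_col Trait column name (default `"bmi"`).
#' @return One-row association tibble (the summary-stat schema).
#' @export
linear_assoc <- function(gm, pheno, snp_id, covariates = c("age", "age2"),
                         int = TRUE, trait_col = "bmi") {
  ph <- aligned_pheno(gm, pheno)
  g <- as.numeric(geno_calls(gm, snp_id))
  y <- ph[[trait_col]]
  if (int) y <- inverse_normal_transform(y, ph$sex)
  df <- tibble(y = y, g = g, age = ph$age, age2 = ph$age^2,
               sex = as.numeric(ph$sex))
  df <- df[complete.cases(df[c("y", "g", covariates)]), ]
  if (nrow(df) < 10) abort("fewer than 10 complete cases",
                           class = "finemapld_input_error")
  if (!is_polymorphic(df$g)) abort("monomorphic SNP",
                                   class = "finemapld_degenerate_error")
  fml <- stats::reformulate(c("g", covariates), response = "y")
  fit <- lm(fml, data = df)
  assoc_row(fit, "g", snp_id, trait_col, gm, df$g, ph$population[1], covariates)
}

#' Single-SNP logistic association with disease status
#'
#' Additive-model logistic regression of case/control status on the
#' effect-allele count, adjusted for sex. `beta` is the log odds ratio per
#' effect allele.
#'
#' @inheritParams linear_assoc
#' @param status_col Column holding `"case"` / `"control"` (other values
#'   are treated as missing).
#' @export
logistic_assoc <- function(gm, pheno, snp_id, covariates = "sex",
                           status_col = "t2d") {
  ph <- aligned_pheno(gm, pheno)
  g <- as.numeric(geno_calls(gm, snp_id))
  status <- ph[[status_col]]
  y <- ifelse(status == "case", 1, ifelse(status == "control", 0, NA))
  df <- tibble(y = y, g = g, age = ph$age, age2 = ph$age^2,
               sex = as.numeric(ph$sex))
  df <- df[complete.cases(df[c("y", "g", covariates)]), ]
  if (sum(df$y == 1) < 10 || sum(df$y == 0) < 10) {
    abort("need at least 10 cases and 10 controls",
          class = "finemapld_input_error")
  }
  if (!is_polymorphic(df$g)) abort("monomorphic SNP",
                                   class = "finemapld_degenerate_error")
  fml <- stats::reformulate(c("g", covariates), response = "y")
  fit <- withCallingHandlers(
    glm(fml, data = df, family = binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  # separation: the genotype log-OR diverges (perfectly fitted classes)
  cf <- summary(fit)$coefficients
  if (!fit$converged || abs(cf["g", 1]) > 15 || cf["g", 2] > 30) {
    abort(paste0("complete or quasi-complete separation fitting ", snp_id,
                 ": log-OR unbounded"),
          class = "finemapld_fit_error")
  }
  assoc_row(fit, "g", snp_id, "t2d", gm, df$g, ph$population[1], covariates)
}

#' Scan every SNP of a panel for one trait
#'
#' @inheritParams linear_assoc
#' @param trait `"bmi"` (linear on INT-BMI) or `"t2d"` (logistic).
#' @param snps SNPs to test (default all).
#' @return Association tibble, one row per SNP; monomorphic SNPs are
#'   skipped with a warning.
#' @export
assoc_scan <- function(gm, pheno, trait = c("bmi", "t2d"),
                       snps = gm$variants$snp_id) {
  trait <- match.arg(trait)
  rows <- list()
  skipped <- character()
  for (s in snps) {
    res <- tryCatch(
      if (trait == "bmi") linear_assoc(gm, pheno, s)
      else logistic_assoc(gm, pheno, s),
      finemapld_degenerate_error = function(e) NULL)
    if (is.null(res)) skipped <- c(skipped, s) else rows[[s]] <- res
  }
  if (length(skipped) > 0) {
    warn(paste0("skipped monomorphic SNP(s): ", paste(skipped, collapse = ", ")))
  }
  bind_rows(rows)
}

#' Significance with the direction-consistency rule
#'
#' An association counts as significant only when its p-value passes the
#' threshold AND the effect direction implies trait/risk increase on the
#' stated reference risk allele (the allele reported risk-increasing in
#' European-descent populations).
#'
#' @param result Association tibble (needs `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `p`).
#' @param reference_risk_allele Named character vector `snp_id -> allele`,
#'   or a single allele when `result` has one row.
#' @param alpha Significance threshold (default 0.05).
#' @return `result` with a logical `significant` column appended.
#' @export
direction_significance <- function(result, reference_risk_allele,
                                   alpha = 0.05) {
  if (is.null(names(reference_risk_allele))) {
    if (length(reference_risk_allele) == 1) {
      reference_risk_allele <- setNames(rep(reference_risk_allele,
                                            nrow(result)), result$snp_id)
    } else {
      abort("reference_risk_allele must be named by snp_id",
            class = "finemapld_input_error")
    }
  }
  ref <- reference_risk_allele[result$snp_id]
  if (anyNA(ref)) abort("missing reference risk allele for some SNPs",
                        class = "finemapld_input_error")
  ok_allele <- ref == result$effect_allele | ref == result$other_allele
  if (any(!ok_allele)) {
    abort("reference risk allele matches neither allele",
          class = "finemapld_input_error")
  }
  risk_increasing <- unname(ifelse(ref == result$effect_allele,
                                   result$beta > 0, result$beta < 0))
  mutate(result, significant = .data$p < alpha & risk_increasing)
}

#' Pairwise conditional association of two SNPs
#'
#' Fits the trait model with both genotype terms plus the standard
#' covariates and reports each term's conditional effect and p-value. The
#' pair is declared indistinguishable (no fit attempted) when the two SNPs
#' are identical or their r-squared reaches `r2_limit`.
#'
#' @inheritParams linear_assoc
#' @param snp_a,snp_b The SNP pair.
#' @param trait `"bmi"` or `"t2d"`.
#' @param r2_limit Indistinguishability bound (default 0.99).
#' @return One-row tibble: `snp_a`, `snp_b`, `beta_a_given_b`,
#'   `se_a_given_b`, `p_a_given_b`, `beta_b_given_a`, `se_b_given_a`,
#'   `p_b_given_a`, `n`, `indistinguishable`, `population`.
#' @export
pairwise_conditional <- function(gm, pheno, snp_a, snp_b,
                                 trait = c("bmi", "t2d"), r2_limit = 0.99) {
  trait <- match.arg(trait)
  ph <- aligned_pheno(gm, pheno)
  flagged <- function() {
    tibble(snp_a = snp_a, snp_b = snp_b,
           beta_a_given_b = NA_real_, se_a_given_b = NA_real_,
           p_a_given_b = NA_real_,
           beta_b_given_a = NA_real_, se_b_given_a = NA_real_,
           p_b_given_a = NA_real_,
           n = NA_integer_, indistinguishable = TRUE,
           population = ph$population[1])
  }
  if (snp_a == snp_b) return(flagged())
  ga <- as.numeric(geno_calls(gm, snp_a))
  gb <- as.numeric(geno_calls(gm, snp_b))
  r2 <- tryCatch(ld_stats(em_hapfreq2(ga, gb))$r2,
                 finemapld_degenerate_error = function(e) NA_real_)
  if (!is.na(r2) && r2 >= r2_limit) return(flagged())
  if (trait == "bmi") {
    y <- inverse_normal_transform(ph$bmi, ph$sex)
    covariates <- c("age", "age2")
  } else {
    y <- ifelse(ph$t2d == "case", 1, ifelse(ph$t2d == "control", 0, NA))
    covariates <- "sex"
  }
  df <- tibble(y = y, ga = ga, gb = gb, age = ph$age, age2 = ph$age^2,
               sex = as.numeric(ph$sex))
  df <- df[complete.cases(df[c("y", "ga", "gb", covariates)]), ]
  fml <- stats::reformulate(c("ga", "gb", covariates), response = "y")
  fit <- if (trait == "bmi") lm(fml, data = df) else
    suppressWarnings(glm(fml, data = df, family = binomial()))
  if (anyNA(coef(fit))) return(flagged())   # near-collinear pair
  cf <- summary(fit)$coefficients
  tibble(snp_a = snp_a, snp_b = snp_b,
         beta_a_given_b = cf["ga", 1], se_a_given_b = cf["ga", 2],
         p_a_given_b = cf["ga", 4],
         beta_b_given_a = cf["gb", 1], se_b_given_a = cf["gb", 2],
         p_b_given_a = cf["gb", 4],
         n = as.integer(stats::nobs(fit)), indistinguishable = FALSE,
         population = ph$population[1])
}

#' Conditional analysis over all pairs of a SNP set
#'
#' @inheritParams pairwise_conditional
#' @param snps SNP set (>= 2 ids).
#' @return Tibble of one row per unordered pair.
#' @export
conditional_all_pairs <- function(gm, pheno, snps, trait = c("bmi", "t2d")) {
  trait <- match.arg(trait)
  cmb <- utils::combn(snps, 2)
  purrr::map_dfr(seq_len(ncol(cmb)), function(k) {
    pairwise_conditional(gm, pheno, cmb[1, k], cmb[2, k], trait)
  })
}

# A SNP "loses" to a partner when its conditional p exceeds alpha while
# the partner's conditional p passes; indistinguishable pairs yield no loss.
loses_matrix <- function(cond, snps, alpha) {
  L <- matrix(FALSE, length(snps), length(snps),
              dimnames = list(snps, snps))
  for (k in seq_len(nrow(cond))) {
    a <- cond$snp_a[k]; b <- cond$snp_b[k]
    if (isTRUE(cond$indistinguishable[k])) next
    pa <- cond$p_a_given_b[k]; pb <- cond$p_b_given_a[k]
    if (!is.na(pa) && !is.na(pb)) {
      if (pa > alpha && pb <= alpha) L[a, b] <- TRUE
      if (pb > alpha && pa <= alpha) L[b, a] <- TRUE
    }
  }
  L
}

#' Exclusion screen from pairwise conditional results
#'
#' A SNP is excluded when, against every other SNP still in the set, it
#' loses: its conditional p-value exceeds `alpha_adj` while the partner's
#' does not. With `iterate = TRUE` (default) the rule is re-applied to the
#' surviving set (using the same pairwise results) until no further SNP is
#' excluded; a single pass reproduces the one-shot screen.
#'
#' @param cond_results Tibble from [conditional_all_pairs()] covering all
#'   unordered pairs of the SNP set (a meta-combined table is equally
#'   valid).
#' @param alpha_adj Adjusted significance level; default `0.05 / n_snps`
#'   (Bonferroni over the SNPs screened).
#' @param iterate Re-apply the rule until a fixed point.
#' @return Object of class `exclusion_screen`: list with `excluded`
#'   (tibble `snp_id`, `round`), `retained`, `alpha_adj`, `n_snps`.
#' @export
exclusion_screen <- function(cond_results, alpha_adj = NULL, iterate = TRUE) {
  snps <- sort(unique(c(cond_results$snp_a, cond_results$snp_b)))
  need <- utils::combn(snps, 2)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- key(cond_results$snp_a, cond_results$snp_b)
  missing_pairs <- !(key(need[1, ], need[2, ]) %in% have)
  if (any(missing_pairs)) {
    abort(paste0("conditional results missing for pair(s): ",
                 paste(need[1, missing_pairs], need[2, missing_pairs],
                       sep = "-", collapse = ", ")),
          class = "finemapld_input_error")
  }
  n_snps <- length(snps)
  alpha_adj <- alpha_adj %||% (0.05 / n_snps)
  L <- loses_matrix(cond_results, snps, alpha_adj)
  active <- snps
  excluded <- tibble(snp_id = character(), round = integer())
  round <- 0L
  repeat {
    round <- round + 1L
    out <- active[vapply(active, function(s) {
      others <- setdiff(active, s)
      length(others) > 0 && all(L[s, others])
    }, logical(1))]
    if (length(out) == 0) break
    excluded <- bind_rows(excluded, tibble(snp_id = out, round = round))
    active <- setdiff(active, out)
    if (!iterate || length(active) <= 1) break
  }
  structure(list(excluded = excluded, retained = active,
                 alpha_adj = alpha_adj, n_snps = n_snps),
            class = "exclusion_screen")
}

#' @export
print.exclusion_screen <- function(x, ...) {
  cat(sprintf("<exclusion_screen> %d SNPs, alpha_adj = %.4g\n",
              x$n_snps, x$alpha_adj))
  cat("  excluded:", if (nrow(x$excluded) > 0)
    paste(x$excluded$snp_id, collapse = ", ") else "(none)", "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}
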