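#' Inverse-variance fixed-effect meta-analysis
#'
#' Combines per-study estimates with weights `w_i = 1 / se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1 / sqrt(sum(w))`, two-sided p from
#' the normal z. Cochran's Q heterogeneity statistic and its chi-square
#' p-value (df = k - 1) are attached when k >= 2.
#'
#' @param estimates Data frame with columns `beta` and `se` (one row per
#'   study), or a numeric vector of betas with `se` given separately.
#' @param se Standard errors when `estimates` is a plain vector.
#' @return One-row tibble of class `meta_result`: `beta`, `se`, `z`, `p`,
#'   `q_stat`, `q_df`, `p_hetero`, `k`.
#' @export
fixed_effect_meta <- function(estimates, se = NULL) {
  if (is.data.frame(estimates)) {
    b <- estimates$beta; s <- estimates$se
  } else {
    b <- as.numeric(estimates); s <- as.numeric(se)
  }
  keep <- !is.na(b) & !is.na(s)
  b <- b[keep]; s <- s[keep]
  if (length(b) < 1) abort("no estimates to combine",
                           class = "finemapld_input_error")
  if (any(s <= 0)) abort("all se must be > 0", class = "finemapld_value_error")
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se_c <- 1 / sqrt(sum(w))
  z <- beta / se_c
  k <- length(b)
  if (k >= 2) {
    q <- sum(w * (b - beta)^2)
    p_het <- pchisq(q, df = k - 1, lower.tail = FALSE)
  } else {
    q <- NA_real_; p_het <- NA_real_
  }
  out <- tibble(beta = beta, se = se_c, z = z, p = 2 * pnorm(-abs(z)),
                q_stat = q, q_df = k - 1L, p_hetero = p_het, k = k)
  class(out) <- c("meta_result", class(out))
  out
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_i (beta_i - beta_combined)^2` against chi-square with k - 1
#' degrees of freedom.
#'
#' @inheritParams fixed_effect_meta
#' @param meta Optional precomputed [fixed_effect_meta()] result (saves
#'   recombining).
#' @return One-row tibble: `q_stat`, `q_df`, `p_hetero`.
#' @export
cochran_q <- function(estimates, se = NULL, meta = NULL) {
  if (is.data.frame(estimates)) {
    b <- estimates$beta; s <- estimates$se
  } else {
    b <- as.numeric(estimates); s <- as.numeric(se)
  }
  if (length(b) < 2) abort("heterogeneity needs k >= 2 studies",
                           class = "finemapld_input_error")
  if (is.null(meta)) meta <- fixed_effect_meta(b, s)
  w <- 1 / s^2
  q <- sum(w * (b - meta$beta)^2)
  tibble(q_stat = q, q_df = length(b) - 1L,
         p_hetero = pchisq(q, df = length(b) - 1, lower.tail = FALSE))
}

#' Meta-analyse a summary-statistic table by SNP and trait
#'
#' Groups the [read_summary_stats()] schema by `snp_id` and `trait` and
#' combines across populations/panels by inverse-variance fixed effect.
#'
#' @param stats Summary-stat tibble.
#' @return Tibble with one row per (snp_id, trait): combined `beta`, `se`,
#'   `z`, `p`, heterogeneity columns, `k`, total `n`, plus the effect
#'   allele carried through (must be consistent within a group).
#' @export
meta_by_snp <- function(stats) {
  stats |>
    group_by(.data$snp_id, .data$trait) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$effect_allele)) != 1) {
        abort(paste0("inconsistent effect allele within group for ",
                     key$snp_id), class = "finemapld_input_error")
      }
      m <- fixed_effect_meta(d)
      mutate(as_tibble(m), effect_allele = d$effect_allele[1],
             other_allele = d$other_allele[1],
             eaf = sum(d$eaf * d$n) / sum(d$n),
             n = sum(d$n))
    }) |>
    ungroup()
}
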