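#' Construct a genotype matrix
#'
#' The central genotype container: unphased diploid calls for a panel of
#' samples over a set of biallelic variants, coded as counts (0/1/2) of each
#' variant's effect allele. Missing calls are `NA`.
#'
#' @param variants A data frame with one row per variant and columns
#'   `snp_id`, `chrom`, `pos` (1-based), `allele_a`, `allele_b`,
#'   `effect_allele`. The effect allele must equal `allele_a` or `allele_b`.
#' @param samples Character vector of unique sample identifiers.
#' @param calls Integer matrix, `length(samples)` rows by `nrow(variants)`
#'   columns, values in `{0, 1, 2, NA}` counting copies of the effect
#'   allele.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `variants` (tibble), `samples` (character) and `calls` (integer
#'   matrix with sample rownames and snp_id colnames).
#' @export
#' @examples
#' v <- tibble::tibble(snp_id = "rs1", chrom = "16", pos = 100L,
#'                     allele_a = "C", allele_b = "T", effect_allele = "C")
#' gm <- geno_matrix(v, c("s1", "s2"), matrix(c(0L, 2L), ncol = 1))
#' gm
geno_matrix <- function(variants, samples, calls) {
  variants <- as_tibble(variants)
  req <- c("snp_id", "chrom", "pos", "allele_a", "allele_b", "effect_allele")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) {
    abort(paste0("variants is missing column(s): ", paste(miss, collapse = ", ")),
          class = "finemapld_schema_error")
  }
  variants$pos <- as.integer(variants$pos)
  if (anyDuplicated(variants$snp_id)) {
    abort("duplicate snp_id in variants", class = "finemapld_schema_error")
  }
  if (any(variants$pos < 1L, na.rm = TRUE)) {
    abort("variant positions must be >= 1 (1-based)", class = "finemapld_schema_error")
  }
  bad_ea <- variants$effect_allele != variants$allele_a &
    variants$effect_allele != variants$allele_b
  if (any(bad_ea)) {
    abort(paste0("effect_allele not among the two alleles for: ",
                 paste(variants$snp_id[bad_ea], collapse = ", ")),
          class = "finemapld_schema_error")
  }
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    abort("duplicate sample ids", class = "finemapld_schema_error")
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(variants)) {
    abort(sprintf("calls must be %d x %d, got %d x %d",
                  length(samples), nrow(variants), nrow(calls), ncol(calls)),
          class = "finemapld_schema_error")
  }
  ok <- is.na(calls) | (calls >= 0L & calls <= 2L)
  if (!all(ok)) {
    abort("genotype calls must be 0, 1, 2 or NA", class = "finemapld_schema_error")
  }
  dimnames(calls) <- list(samples, variants$snp_id)
  structure(list(variants = variants, samples = samples, calls = calls),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  n_mis <- sum(is.na(x$calls))
  if (n_mis > 0) cat(sprintf("  missing calls: %d\n", n_mis))
  print(head(x$variants, 8))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(length(x$samples), nrow(x$variants))

#' Long-format view of a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `snp_id`, `call`.
#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  tidyr::expand_grid(sample_id = x$samples, snp_id = x$variants$snp_id) |>
    mutate(call = as.integer(t(x$calls))[row_number()])
}

#' Extract effect-allele dosage vector(s) for named SNPs
#'
#' @param gm A [geno_matrix()].
#' @param snp_ids Character vector of SNP ids present in `gm`.
#' @return Integer matrix (samples x requested SNPs), or a vector when a
#'   single id is requested.
#' @export
geno_calls <- function(gm, snp_ids) {
  stopifnot(inherits(gm, "geno_matrix"))
  missing_ids <- setdiff(snp_ids, gm$variants$snp_id)
  if (length(missing_ids) > 0) {
    abort(paste0("unknown snp_id(s): ", paste(missing_ids, collapse = ", ")),
          class = "finemapld_key_error")
  }
  out <- gm$calls[, snp_ids, drop = length(snp_ids) > 1]
  out
}

#' Flip the effect allele of selected variants
#'
#' Recodes calls `g -> 2 - g` (missing stays missing) and swaps the stored
#' effect allele. Association statistics are equivariant under this flip.
#'
#' @param gm A [geno_matrix()].
#' @param snp_ids SNPs to flip; default all.
#' @return A new `geno_matrix`.
#' @export
flip_effect_allele <- function(gm, snp_ids = gm$variants$snp_id) {
  idx <- match(snp_ids, gm$variants$snp_id)
  if (anyNA(idx)) abort("unknown snp_id in flip", class = "finemapld_key_error")
  v <- gm$variants
  other <- ifelse(v$effect_allele[idx] == v$allele_a[idx],
                  v$allele_b[idx], v$allele_a[idx])
  v$effect_allele[idx] <- other
  calls <- gm$calls
  calls[, idx] <- 2L - calls[, idx]
  geno_matrix(v, gm$samples, calls)
}
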