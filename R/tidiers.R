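#' Tidy a fine-mapping run into the meta-analysed association table
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return Tibble of per-SNP combined association results with each SNP's
#'   cluster index attached where assigned.
#' @method tidy finemap_run
#' @export
tidy.finemap_run <- function(x, ...) {
  out <- x$meta
  if (!is.null(x$clusters) && nrow(x$clusters$assignment) > 0) {
    out <- left_join(out,
                     select(x$clusters$assignment, "snp_id",
                            cluster = "index", r2_to_index = "r2"),
                     by = "snp_id")
  }
  out
}

#' One-row summary of a fine-mapping run
#'
#' @inheritParams tidy.finemap_run
#' @return Tibble: populations, SNPs tested, indices found, clusters
#'   retained, conditional exclusions, final candidate count.
#' @method glance finemap_run
#' @export
glance.finemap_run <- function(x, ...) {
  tibble(
    n_populations = length(x$panels),
    n_snps = length(unique(x$stats$snp_id)),
    n_index = length(x$index_snps),
    n_clusters_retained = if (!is.null(x$clusters))
      length(x$clusters$index_snps) else 0L,
    n_excluded_conditional = if (!is.null(x$screen))
      nrow(x$screen$excluded) else 0L,
    n_candidates = if (!is.null(x$candidates))
      length(x$candidates$intersection) else NA_integer_
  )
}

#' @method tidy exclusion_screen
#' @export
tidy.exclusion_screen <- function(x, ...) {
  mutate(x$excluded, alpha_adj = x$alpha_adj)
}

#' @method glance exclusion_screen
#' @export
glance.exclusion_screen <- function(x, ...) {
  tibble(n_snps = x$n_snps, n_excluded = nrow(x$excluded),
         n_retained = length(x$retained), alpha_adj = x$alpha_adj)
}

#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) x$assignment

#' @method tidy hap_phylogeny
#' @export
tidy.hap_phylogeny <- function(x, ...) x$edges

#' @method tidy candidate_set
#' @export
tidy.candidate_set <- function(x, ...) x$venn_counts

#' @method tidy hap_phase
#' @export
tidy.hap_phase <- function(x, ...) x$haplotypes

#' @method glance hap_phase
#' @export
glance.hap_phase <- function(x, ...) {
  tibble(n_haplotypes = nrow(x$haplotypes), n_samples = length(x$samples),
         loglik = x$loglik, n_iter = x$n_iter)
}
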