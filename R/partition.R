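# Symmetric r2 lookup backed by a pair table (snp_a, snp_b, r2).
ld_lookup <- function(ld) {
  key <- paste(pmin(ld$snp_a, ld$snp_b), pmax(ld$snp_a, ld$snp_b))
  r2 <- setNames(ld$r2, key)
  function(a, b) {
    if (a == b) return(1)
    v <- r2[paste(pmin(a, b), pmax(a, b))]
    unname(v)
  }
}

#' Select index SNPs by greedy LD clumping
#'
#' Sorts SNPs passing the significance gate by ascending p-value and
#' accepts a SNP as a new index exactly when its r-squared to every
#' already-accepted index is below `r2_independence`. Ties on p are
#' broken by smaller position, then lexicographic id, so the selection is
#' deterministic.
#'
#' @param results Association tibble with `snp_id`, `p` and (for
#'   tie-breaking) optionally `pos`; a `significant` column from
#'   [direction_significance()] is honoured when present.
#' @param ld Pairwise LD tibble (`snp_a`, `snp_b`, `r2`) covering all
#'   candidate pairs, e.g. from [ld_pairs()].
#' @param p_threshold Significance gate on `p` (default 0.05).
#' @param r2_independence Independence bound between indices
#'   (default 0.9).
#' @param positions Optional named position vector used when `results`
#'   lacks `pos`.
#' @return Ordered character vector of index SNP ids (possibly empty,
#'   with a warning).
#' @export
select_index_snps <- function(results, ld, p_threshold = 0.05,
                              r2_independence = 0.9, positions = NULL) {
  cand <- results[results$p < p_threshold, ]
  if ("significant" %in% names(cand)) cand <- cand[cand$significant, ]
  if (nrow(cand) == 0) {
    warn("no SNP passes the significance gate; empty index list")
    return(character())
  }
  pos <- if ("pos" %in% names(cand)) cand$pos else
    if (!is.null(positions)) unname(positions[cand$snp_id]) else
      rep(0, nrow(cand))
  cand <- cand[order(cand$p, pos, cand$snp_id), ]
  r2 <- ld_lookup(ld)
  idx <- character()
  for (s in cand$snp_id) {
    vals <- vapply(idx, function(i) r2(s, i), numeric(1))
    if (anyNA(vals)) {
      abort(paste0("LD missing for pair ", s, " - ",
                   paste(idx[is.na(vals)], collapse = ", ")),
            class = "finemapld_input_error")
    }
    if (all(vals < r2_independence)) idx <- c(idx, s)
  }
  idx
}

#' Partition significant SNPs into index-SNP LD clusters
#'
#' Each SNP is binned with the index it is in strongest LD with (argmax
#' r-squared); SNPs whose best r-squared falls below `r2_floor` are left
#' unassigned. Argmax ties go to the physically nearer index, then
#' lexicographic. Every index maps to itself.
#'
#' @param significant_snps SNP ids to assign.
#' @param index_snps Index list from [select_index_snps()].
#' @param ld Pairwise LD tibble covering (snp, index) pairs.
#' @param r2_floor Minimum best-r-squared for assignment (default 0).
#' @param positions Named physical positions (for tie-breaks).
#' @return Object of class `cluster_assignment`: `assignment` tibble
#'   (`snp_id`, `index`, `r2`), `index_snps`, `unassigned`.
#' @export
assign_clusters <- function(significant_snps, index_snps, ld, r2_floor = 0,
                            positions = NULL) {
  if (length(index_snps) == 0) abort("index list is empty",
                                     class = "finemapld_input_error")
  r2f <- ld_lookup(ld)
  rows <- list(); unassigned <- character()
  for (s in significant_snps) {
    r2v <- vapply(index_snps, function(i) r2f(s, i), numeric(1))
    if (anyNA(r2v)) {
      abort(paste0("LD missing for pair ", s, " - ",
                   paste(index_snps[is.na(r2v)], collapse = ", ")),
            class = "finemapld_input_error")
    }
    best <- max(r2v)
    if (best < r2_floor) {
      unassigned <- c(unassigned, s)
      next
    }
    tied <- index_snps[r2v == best]
    if (length(tied) > 1 && !is.null(positions)) {
      dist <- abs(positions[tied] - positions[s])
      tied <- tied[order(dist, tied)]
    } else {
      tied <- sort(tied)
    }
    rows[[s]] <- tibble(snp_id = s, index = tied[1], r2 = best)
  }
  structure(list(assignment = bind_rows(rows), index_snps = index_snps,
                 unassigned = unassigned, dropped = NULL),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d SNPs in %d clusters",
              nrow(x$assignment), length(x$index_snps)))
  if (length(x$unassigned) > 0)
    cat(sprintf(" (%d unassigned)", length(x$unassigned)))
  cat("\n")
  print(dplyr::count(x$assignment, .data$index))
  if (!is.null(x$dropped) && nrow(x$dropped) > 0) {
    cat("dropped clusters:\n"); print(x$dropped)
  }
  invisible(x)
}

#' Drop LD clusters on association/conditional evidence
#'
#' Removes named indices and their whole bins from downstream filtering,
#' recording the reason (e.g. non-significant marginal association, or
#' losing the conditional exclusion screen).
#'
#' @param assignment A [assign_clusters()] result.
#' @param evidence Named character vector `index -> reason`, or a tibble
#'   with columns `index`, `reason`.
#' @return The reduced `cluster_assignment` with a `dropped` record.
#' @export
drop_clusters <- function(assignment, evidence) {
  if (is.data.frame(evidence)) {
    evidence <- setNames(evidence$reason, evidence$index)
  }
  if (length(evidence) == 0) return(assignment)
  unknown <- setdiff(names(evidence), assignment$index_snps)
  if (length(unknown) > 0) {
    abort(paste0("unknown index: ", paste(unknown, collapse = ", ")),
          class = "finemapld_key_error")
  }
  out <- assignment
  out$index_snps <- setdiff(out$index_snps, names(evidence))
  out$assignment <- out$assignment[!out$assignment$index %in% names(evidence), ]
  drop_rec <- tibble(index = names(evidence), reason = unname(evidence))
  out$dropped <- bind_rows(assignment$dropped, drop_rec)
  out
}

#' Trans-ethnic proxy-set filtering
#'
#' For each ancestry group, takes the union over retained index SNPs of
#' that index's proxy set (r-squared at or above the group's threshold in
#' the group's panel), then intersects across groups. The intersection is
#' the fine-mapped candidate list; membership-pattern (Venn) counts over
#' the union are reported. Indices monomorphic in a panel are skipped for
#' that group with a warning; indices absent from a panel are an error.
#'
#' @param retained_indices Index SNPs surviving the cluster screens.
#' @param panels Named list of [geno_matrix()] per ancestry group.
#' @param thresholds Single r-squared or named per-group vector
#'   (convention: 0.9 for array/HapMap-density panels, 0.95 for
#'   sequencing-density panels).
#' @return Object of class `candidate_set`: `per_group_sets` (named list),
#'   `intersection`, `venn_counts` (tibble `pattern`, `count`),
#'   `thresholds`.
#' @export
transethnic_filter <- function(retained_indices, panels, thresholds = 0.9) {
  groups <- names(panels)
  if (is.null(groups) || any(!nzchar(groups))) {
    abort("panels must be a named list", class = "finemapld_input_error")
  }
  if (is.null(names(thresholds))) {
    thresholds <- setNames(rep(thresholds, length(groups)), groups)
  }
  per_group <- lapply(groups, function(g) {
    gm <- panels[[g]]
    absent <- setdiff(retained_indices, gm$variants$snp_id)
    if (length(absent) > 0) {
      abort(paste0("index SNP(s) absent from panel ", g, ": ",
                   paste(absent, collapse = ", ")),
            class = "finemapld_input_error")
    }
    sets <- lapply(retained_indices, function(i) {
      tryCatch(proxy_set(i, gm, thresholds[[g]]),
               finemapld_degenerate_error = function(e) {
                 warn(paste0("index ", i, " monomorphic in panel ", g,
                             "; skipped for that group"))
                 character()
               })
    })
    unique(unlist(sets))
  })
  names(per_group) <- groups
  intersection <- Reduce(intersect, per_group)
  all_snps <- sort(unique(unlist(per_group)))
  pattern <- unname(vapply(all_snps, function(s) {
    paste(sort(groups[vapply(per_group, function(x) s %in% x, logical(1))]),
          collapse = "&")
  }, character(1)))
  venn <- tibble(pattern = pattern) |>
    dplyr::count(.data$pattern, name = "count") |>
    arrange(desc(.data$count))
  structure(list(per_group_sets = per_group, intersection = intersection,
                 venn_counts = venn, thresholds = thresholds),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d candidate SNP(s) in the %d-group intersection\n",
              length(x$intersection), length(x$per_group_sets)))
  for (g in names(x$per_group_sets)) {
    cat(sprintf("  %s (r2 >= %.2f): %d SNPs\n", g, x$thresholds[[g]],
                length(x$per_group_sets[[g]])))
  }
  print(x$venn_counts)
  invisible(x)
}
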