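# Hamming distance between two haplotype allele vectors over given sites.
hap_hamming <- function(al, a, b, sites) sum(al[a, sites] != al[b, sites])

#' Ancestral-rooted haplotype network with recombination classification
#'
#' Builds a phylogeny of haplotypes rooted at the ancestral haplotype by
#' greedy minimum-mutation attachment: the unplaced haplotype with the
#' smallest Hamming distance to any placed node is attached by a mutation
#' edge listing the differing SNPs (ties broken toward the
#' higher-frequency parent, then the parent closer to the root, then
#' label). Afterwards, any haplotype expressible as a single crossover of
#' two other placed haplotypes with strictly fewer implied events than its
#' mutation edge is re-labelled as a recombination edge with the
#' breakpoint interval. Sites flagged recombinant in the haplotype table
#' (ancestral crossover, e.g. rs7206790 at FTO) are excluded from event
#' counting.
#'
#' @param ht A `hap_table` ([default_haplotypes()]).
#' @param ancestral Root haplotype label; default the table's ancestral.
#' @param freq_floor Haplotypes whose maximum frequency over populations
#'   is below this are excluded (default 0.004, the conventional "Low"
#'   cut); pass labels in `keep` to retain putative recombinants anyway.
#' @param keep Labels always retained.
#' @param skip_recombinant Exclude recombinant-flagged sites (default).
#' @return Object of class `hap_phylogeny`: `nodes` (tibble `label`,
#'   `freq`, `depth`), `root`, `edges` (tibble `parent`, `child`, `kind`
#'   in mutation/recombination, `detail`, `n_events`, `other_parent`).
#' @export
build_phylogeny <- function(ht, ancestral = ht$ancestral, freq_floor = 0.004,
                            keep = character(), skip_recombinant = TRUE) {
  if (!ancestral %in% rownames(ht$alleles)) {
    abort(paste0("ancestral haplotype missing: ", ancestral),
          class = "finemapld_input_error")
  }
  fr <- ht$freqs |>
    group_by(.data$haplotype) |>
    summarise(fmax = max(.data$freq), fmean = mean(.data$freq))
  freq_of <- setNames(fr$fmean, fr$haplotype)
  fmax <- setNames(fr$fmax, fr$haplotype)
  labs <- rownames(ht$alleles)
  labs <- labs[fmax[labs] >= freq_floor | labs %in% c(keep, ancestral)]
  use_sites <- if (skip_recombinant) !ht$snp_list$recombinant else
    rep(TRUE, nrow(ht$snp_list))
  sites <- ht$snp_list$snp_id[use_sites]
  sites <- sites[order(ht$snp_list$pos[match(sites, ht$snp_list$snp_id)])]
  al <- ht$alleles

  placed <- ancestral
  depth <- setNames(0L, ancestral)
  unplaced <- setdiff(labs, ancestral)
  edges <- list()
  while (length(unplaced) > 0) {
    cand <- purrr::map_dfr(unplaced, function(h) {
      d <- vapply(placed, function(p) hap_hamming(al, h, p, sites),
                  numeric(1))
      tibble(child = h, dmin = min(d),
             parents = list(placed[d == min(d)]))
    })
    cand <- cand |>
      arrange(.data$dmin, desc(freq_of[.data$child]), .data$child)
    child <- cand$child[1]
    ps <- cand$parents[[1]]
    ord <- order(-freq_of[ps], depth[ps], ps)
    parent <- ps[ord[1]]
    diffs <- sites[al[child, sites] != al[parent, sites]]
    edges[[child]] <- tibble(parent = parent, child = child,
                             kind = "mutation",
                             detail = paste(diffs, collapse = ","),
                             n_events = length(diffs),
                             other_parent = NA_character_)
    depth[child] <- depth[parent] + 1L
    placed <- c(placed, child)
    unplaced <- setdiff(unplaced, child)
  }
  edges <- bind_rows(edges)

  # single-crossover re-labelling where strictly fewer events are implied
  k <- length(sites)
  if (nrow(edges) > 0 && k >= 2 && length(placed) >= 3) {
    for (i in seq_len(nrow(edges))) {
      if (edges$n_events[i] <= 1) next
      child <- edges$child[i]
      others <- setdiff(placed, child)
      best <- NULL
      for (p1 in others) for (p2 in setdiff(others, p1)) {
        cuts <- integer()
        for (cut in 1:(k - 1)) {
          rec <- c(al[p1, sites[1:cut]], al[p2, sites[(cut + 1):k]])
          if (all(rec == al[child, sites])) cuts <- c(cuts, cut)
        }
        if (length(cuts) > 0) {
          score <- freq_of[p1] + freq_of[p2]
          if (is.null(best) || score > best$score) {
            best <- list(p1 = p1, p2 = p2, cuts = cuts, score = score)
          }
        }
      }
      if (!is.null(best)) {
        edges$parent[i] <- best$p1
        edges$other_parent[i] <- best$p2
        edges$kind[i] <- "recombination"
        edges$detail[i] <- sprintf("breakpoint in (%s, %s)",
                                   sites[min(best$cuts)],
                                   sites[max(best$cuts) + 1])
        edges$n_events[i] <- 1L
      }
    }
  }

  structure(list(
    nodes = tibble(label = placed, freq = unname(freq_of[placed]),
                   depth = unname(depth[placed])),
    root = ancestral, edges = edges, sites = sites
  ), class = "hap_phylogeny")
}

#' @export
print.hap_phylogeny <- function(x, ...) {
  cat(sprintf("<hap_phylogeny> %d haplotypes rooted at %s\n",
              nrow(x$nodes), x$root))
  if (!is.null(x$edges) && nrow(x$edges) > 0) {
    for (i in seq_len(nrow(x$edges))) {
      e <- x$edges[i, ]
      arrow <- if (e$kind == "mutation") "->" else "~>"
      extra <- if (e$kind == "recombination")
        paste0(" [x ", e$other_parent, "]") else ""
      cat(sprintf("  %s %s %s%s (%s)\n", e$parent, arrow, e$child, extra,
                  e$detail))
    }
  }
  invisible(x)
}

#' Newick export of a mutation-only haplotype tree
#'
#' Branch lengths are substitution counts. Errors if the network contains
#' recombination edges (not representable as a tree).
#'
#' @param net A [build_phylogeny()] result.
#' @return Newick string.
#' @export
phylo_newick <- function(net) {
  if (any(net$edges$kind == "recombination")) {
    abort("network contains recombination edges; no tree export",
          class = "finemapld_input_error")
  }
  kids <- split(net$edges, net$edges$parent)
  rec <- function(node, len) {
    ch <- kids[[node]]
    inner <- if (is.null(ch)) "" else
      paste0("(", paste(purrr::map2_chr(ch$child, ch$n_events, rec),
                        collapse = ","), ")")
    paste0(inner, node, if (!is.na(len)) paste0(":", len) else "")
  }
  paste0(rec(net$root, NA), ";")
}
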