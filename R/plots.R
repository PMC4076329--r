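#' Plot an LD-cluster assignment
#'
#' Best r-squared of each assigned SNP to its index, coloured by cluster.
#'
#' @param object A [assign_clusters()] result.
#' @param positions Optional named position vector for the x axis; when
#'   absent SNPs are spread in assignment order.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_assignment
#' @export
autoplot.cluster_assignment <- function(object, positions = NULL, ...) {
  df <- object$assignment
  df$x <- if (!is.null(positions)) unname(positions[df$snp_id]) else
    seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$r2,
                                   colour = .data$index)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = if (is.null(positions)) "SNP" else "position (bp)",
                  y = expression(r^2 ~ "to index"),
                  colour = "LD cluster") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot cross-population candidate overlap
#'
#' Bar chart of the Venn membership-pattern counts from
#' [transethnic_filter()].
#'
#' @param object A `candidate_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot candidate_set
#' @export
autoplot.candidate_set <- function(object, ...) {
  df <- object$venn_counts
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pattern,
                                                      -.data$count),
                                   y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "group membership", y = "SNPs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a haplotype phylogeny network
#'
#' Nodes laid out by depth from the ancestral root; mutation edges solid
#' (labelled with substitution counts), recombination edges dashed from
#' both parents.
#'
#' @param object A [build_phylogeny()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hap_phylogeny
#' @export
autoplot.hap_phylogeny <- function(object, ...) {
  nodes <- object$nodes
  nodes <- nodes |>
    group_by(.data$depth) |>
    mutate(y = row_number() - (n() + 1) / 2) |>
    ungroup()
  xy <- setNames(asplit(as.matrix(nodes[c("depth", "y")]), 1), nodes$label)
  seg <- purrr::map_dfr(seq_len(nrow(object$edges)), function(i) {
    e <- object$edges[i, ]
    out <- tibble(x = xy[[e$parent]][1], y = xy[[e$parent]][2],
                  xend = xy[[e$child]][1], yend = xy[[e$child]][2],
                  kind = e$kind, label = as.character(e$n_events))
    if (!is.na(e$other_parent)) {
      out <- bind_rows(out,
                       tibble(x = xy[[e$other_parent]][1],
                              y = xy[[e$other_parent]][2],
                              xend = xy[[e$child]][1],
                              yend = xy[[e$child]][2],
                              kind = e$kind, label = ""))
    }
    out
  })
  p <- ggplot2::ggplot()
  if (nrow(seg) > 0) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$kind),
      colour = "grey40") +
      ggplot2::geom_text(data = seg[seg$label != "", ],
                         ggplot2::aes(x = (.data$x + .data$xend) / 2,
                                      y = (.data$y + .data$yend) / 2,
                                      label = .data$label),
                         size = 3, vjust = -0.5)
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$depth, y = .data$y,
                                     size = .data$freq),
                        colour = "steelblue") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$depth, y = .data$y,
                                    label = .data$label),
                       vjust = -1.2) +
    ggplot2::scale_linetype_manual(values = c(mutation = "solid",
                                              recombination = "dashed")) +
    ggplot2::labs(x = "events from ancestral root", y = NULL,
                  size = "frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
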