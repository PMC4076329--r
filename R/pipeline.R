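stage_seed <- function(seed, stage, i = 0L) {
  # counter-based expansion: adding a stage never perturbs earlier stages
  (as.integer(seed) + 1009L * as.integer(stage) + 97L * as.integer(i)) %% 2147483647L
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "finemapld_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or YAML path",
                              class = "finemapld_config_error")
  defaults <- list(
    seed = 1L,
    traits = "bmi",
    index_trait = "bmi",
    thresholds = list(),
    target_haplotypes = c("H1", "H3", "H4"),
    run_haplotypes = NULL,
    ld_population = NULL,
    proxy_r2 = 0.9,
    out_dir = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  thr_defaults <- list(p_threshold = 0.05, r2_independence = 0.9,
                       r2_floor = 0, alpha_adj = NULL, window_bp = 500000)
  cfg$thresholds <- utils::modifyList(thr_defaults, cfg$thresholds)
  with(cfg$thresholds, {
    stopifnot(p_threshold > 0, p_threshold <= 1,
              r2_independence >= 0, r2_independence <= 1,
              r2_floor >= 0, r2_floor <= 1)
  })
  if (is.null(cfg$populations) || length(cfg$populations) == 0) {
    abort("config needs at least one population entry",
          class = "finemapld_config_error")
  }
  # fail fast on any missing input path, before any stage runs
  for (p in cfg$populations) {
    for (path in c(p$geno_path, p$pheno_path)) {
      if (!is.null(path) && !file.exists(path)) {
        abort(paste0("input path does not exist: ", path),
              class = "finemapld_config_error")
      }
    }
  }
  cfg
}

load_population <- function(p, seed) {
  name <- p$name %||% p$population %||% "POP"
  if (!is.null(p$geno_path)) {
    gm <- read_genotypes(p$geno_path, p$format %||% "vcf")
    pheno <- utils::read.delim(p$pheno_path, stringsAsFactors = FALSE) |>
      as_tibble()
    return(list(geno = gm, pheno = pheno, truth = NULL, name = name,
                generator = "file"))
  }
  if (!is.null(p$n_clusters)) {
    sim <- simulate_cluster_panel(
      n_samples = p$n_samples, n_clusters = p$n_clusters,
      fillers_per_cluster = p$fillers_per_cluster %||% 3,
      maf = p$maf %||% 0.3, within_r2 = p$within_r2 %||% 0.95,
      causal_cluster = p$causal_cluster %||% 1,
      beta = p$beta %||% 0.15, logor = p$logor %||% log(1.4),
      private_fillers = p$private_fillers %||% 0,
      population = name, seed = seed)
    return(c(sim, list(name = name, generator = "clusters")))
  }
  ht <- default_haplotypes(include_sub = isTRUE(p$include_sub))
  hf <- if (!is.null(p$hap_freqs)) unlist(p$hap_freqs) else
    hap_freqs_for(ht, p$freq_population %||% name)
  pc <- population_config(name, p$n_samples, hf, haplotypes = ht,
                          filler_snps = p$filler_snps %||% 0,
                          filler_r2 = p$filler_r2 %||% 0.8,
                          seed = seed)
  ec_args <- p$effects %||% list()
  ec <- do.call(effect_config, ec_args)
  sim <- simulate_panel(pc, ec)
  c(sim, list(name = name, generator = "fto"))
}

#' Run the fine-mapping pipeline end to end
#'
#' Executes, in order: panel simulation or loading per population;
#' Hardy-Weinberg QC; per-population single-SNP association and
#' cross-population fixed-effect meta-analysis; index-SNP selection and
#' LD-cluster partitioning; pairwise conditional screening of indices
#' (per population, meta-combined) with the direction-consistency
#' marginal gate; EM haplotype phasing and haplotype-dosage association
#' (haplotype-architecture panels only); trans-ethnic proxy-set
#' intersection of the retained clusters. Identical config and seed give
#' an identical report.
#'
#' @param config A list or YAML file path. Required: `populations` (list
#'   of per-population entries; each either simulation parameters or
#'   `geno_path`/`pheno_path`). Optional: `seed`, `traits`,
#'   `index_trait`, `thresholds` (`p_threshold`, `r2_independence`,
#'   `r2_floor`, `alpha_adj`, `window_bp`), `proxy_r2` (scalar or named
#'   per population), `target_haplotypes`, `ld_population`, `out_dir`.
#' @param out_dir Overrides `config$out_dir`; when set, every stage's
#'   table is written there as TSV plus a machine-readable `report.json`.
#' @return Object of class `finemap_run`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  thr <- cfg$thresholds
  log_lines <- sprintf(
    "thresholds: p<%g, r2_independence=%g, r2_floor=%g, proxy_r2=%s, seed=%d",
    thr$p_threshold, thr$r2_independence, thr$r2_floor,
    paste(unlist(cfg$proxy_r2), collapse = "/"), cfg$seed)

  # stage 1: panels
  panels <- purrr::map(seq_along(cfg$populations), function(i) {
    load_population(cfg$populations[[i]], stage_seed(cfg$seed, 1L, i))
  })
  names(panels) <- purrr::map_chr(panels, "name")

  # stage 2: HWE QC (flagging, not dropping)
  hwe <- purrr::imap_dfr(panels, function(pan, nm) {
    mutate(hwe_screen(pan$geno), population = nm)
  })

  # stage 3: association + meta
  stats <- purrr::map_dfr(panels, function(pan) {
    purrr::map_dfr(cfg$traits, function(tr) {
      suppressWarnings(assoc_scan(pan$geno, pan$pheno, tr))
    })
  })
  meta <- meta_by_snp(stats)

  # stage 4: LD panel
  ld_pop <- cfg$ld_population %||% names(panels)[1]
  ld <- suppressWarnings(
    ld_pairs(panels[[ld_pop]]$geno, window_bp = thr$window_bp))

  # stage 5: index selection and partitioning
  # index candidates must be present in every panel (they are conditioned
  # on and proxied in each population)
  shared <- Reduce(intersect, purrr::map(panels, ~ .x$geno$variants$snp_id))
  m_idx <- meta[meta$trait == cfg$index_trait & meta$snp_id %in% shared, ]
  ref_alleles <- setNames(m_idx$effect_allele, m_idx$snp_id)
  m_idx <- direction_significance(m_idx, ref_alleles, thr$p_threshold)
  positions <- setNames(panels[[ld_pop]]$geno$variants$pos,
                        panels[[ld_pop]]$geno$variants$snp_id)
  index_snps <- select_index_snps(m_idx, ld,
                                  p_threshold = thr$p_threshold,
                                  r2_independence = thr$r2_independence,
                                  positions = positions)
  clusters <- NULL; screen <- NULL; cond <- NULL
  if (length(index_snps) > 0) {
    sig <- m_idx$snp_id[m_idx$significant]
    clusters <- assign_clusters(sig, index_snps, ld,
                                r2_floor = thr$r2_floor,
                                positions = positions)

    # stage 6: conditional screen + marginal direction gate
    drop <- character()
    not_sig <- setdiff(index_snps, sig)
    for (s in not_sig) {
      drop[s] <- sprintf("marginal association fails direction-significance (p=%.3g)",
                         m_idx$p[m_idx$snp_id == s])
    }
    surviving <- setdiff(index_snps, names(drop))
    if (length(surviving) >= 2) {
      cond <- purrr::map_dfr(panels, function(pan) {
        conditional_all_pairs(pan$geno, pan$pheno, surviving,
                              trait = cfg$index_trait)
      })
      cond_comb <- cond |>
        group_by(.data$snp_a, .data$snp_b) |>
        summarise(
          indistinguishable = any(.data$indistinguishable),
          beta_a_given_b = fixed_effect_meta(.data$beta_a_given_b,
                                             .data$se_a_given_b)$beta,
          p_a_given_b = fixed_effect_meta(.data$beta_a_given_b,
                                          .data$se_a_given_b)$p,
          beta_b_given_a = fixed_effect_meta(.data$beta_b_given_a,
                                             .data$se_b_given_a)$beta,
          p_b_given_a = fixed_effect_meta(.data$beta_b_given_a,
                                          .data$se_b_given_a)$p,
          .groups = "drop")
      screen <- exclusion_screen(cond_comb, alpha_adj = thr$alpha_adj)
      for (s in screen$excluded$snp_id) {
        drop[s] <- "loses pairwise conditional screen"
      }
    }
    if (length(drop) > 0) clusters <- drop_clusters(clusters, drop)
  }

  # stage 7: haplotype analysis (haplotype-architecture panels only)
  run_hap <- cfg$run_haplotypes %||%
    all(purrr::map_chr(panels, "generator") == "fto")
  hap_effects <- NULL
  if (isTRUE(run_hap)) {
    ht <- default_haplotypes(include_sub = TRUE)
    hap_snps <- setdiff(intersect(ht$snp_list$snp_id,
                                  panels[[1]]$geno$variants$snp_id),
                        ht$snp_list$snp_id[ht$snp_list$recombinant])
    per_pop <- purrr::map_dfr(panels, function(pan) {
      phase <- label_haplotypes(em_phase(pan$geno, hap_snps), ht)
      purrr::map_dfr(cfg$target_haplotypes, function(h) {
        purrr::map_dfr(cfg$traits, function(tr) {
          tryCatch(haplotype_assoc(phase, pan$pheno, h, tr),
                   error = function(e) {
                     warn(sprintf("haplotype %s dropped for %s (%s)",
                                  h, pan$name, conditionMessage(e)))
                     NULL
                   })
        })
      })
    })
    hap_effects <- if (nrow(per_pop) > 0) meta_by_snp(per_pop) else NULL
  }

  # stage 8: trans-ethnic filtering
  candidates <- NULL
  retained <- if (!is.null(clusters)) clusters$index_snps else character()
  if (length(retained) > 0) {
    candidates <- transethnic_filter(retained,
                                     purrr::map(panels, "geno"),
                                     thresholds = unlist(cfg$proxy_r2))
  }

  run <- structure(list(
    config = cfg, panels = panels, hwe = hwe, stats = stats, meta = meta,
    ld = ld, index_snps = index_snps, clusters = clusters,
    conditional = cond, screen = screen, hap_effects = hap_effects,
    candidates = candidates, log = log_lines
  ), class = "finemap_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0) {
      utils::write.table(as.data.frame(df), file.path(out_dir, name),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_summary_stats(run$stats, file.path(out_dir, "summary_stats.tsv"))
  tsv(run$meta, "meta.tsv")
  tsv(run$hwe, "hwe.tsv")
  tsv(run$ld, "ld.tsv")
  if (!is.null(run$clusters)) tsv(run$clusters$assignment, "clusters.tsv")
  tsv(run$conditional, "conditional.tsv")
  if (!is.null(run$hap_effects)) tsv(run$hap_effects, "haplotype_effects.tsv")
  if (!is.null(run$candidates)) {
    tsv(run$candidates$venn_counts, "venn.tsv")
    writeLines(run$candidates$intersection,
               file.path(out_dir, "candidates.txt"))
  }
  jsonlite::write_json(report_list(run), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

report_list <- function(run) {
  list(
    seed = run$config$seed,
    log = run$log,
    n_populations = length(run$panels),
    index_snps = run$index_snps,
    clusters_retained = if (!is.null(run$clusters))
      run$clusters$index_snps else character(),
    clusters_dropped = if (!is.null(run$clusters) &&
                           !is.null(run$clusters$dropped))
      run$clusters$dropped else NULL,
    excluded_by_conditional = if (!is.null(run$screen))
      run$screen$excluded$snp_id else character(),
    alpha_adj = if (!is.null(run$screen)) run$screen$alpha_adj else NULL,
    haplotype_effects = if (!is.null(run$hap_effects))
      run$hap_effects[c("snp_id", "trait", "beta", "se", "p")] else NULL,
    candidates = if (!is.null(run$candidates))
      sort(run$candidates$intersection) else character(),
    venn = if (!is.null(run$candidates)) run$candidates$venn_counts else NULL
  )
}

#' @export
print.finemap_run <- function(x, ...) {
  cat("<finemap_run>\n")
  cat(" ", x$log, "\n")
  cat(sprintf("  populations: %s\n", paste(names(x$panels), collapse = ", ")))
  cat(sprintf("  index SNPs: %s\n", paste(x$index_snps, collapse = ", ")))
  if (!is.null(x$clusters)) {
    cat(sprintf("  clusters retained: %s\n",
                paste(x$clusters$index_snps, collapse = ", ")))
  }
  if (!is.null(x$candidates)) {
    cat(sprintf("  candidate SNPs: %d\n", length(x$candidates$intersection)))
  }
  invisible(x)
}
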