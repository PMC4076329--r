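pkg_version <- function() as.character(utils::packageVersion("finemapld"))

#' Read a genotype panel from VCF or PLINK-style text
#'
#' Both dialects are plain text. VCF parsing is restricted to the GT field
#' of biallelic records (multi-allelic records are rejected, not split);
#' PLINK-style input is the whitespace-delimited `.ped`/`.map` pair.
#'
#' @param path For `vcf`, the `.vcf` file. For `plink_text`, either the
#'   `.ped` file or the common basename of the `.ped`/`.map` pair.
#' @param format `"vcf"` or `"plink_text"`.
#' @param effect_alleles Optional named character vector (`snp_id` ->
#'   allele) designating the effect allele. Defaults: the VCF ALT allele;
#'   for PLINK text (which carries no ref/alt designation) the minor
#'   allele, ties broken to the alphabetically later allele.
#' @return A [geno_matrix()]. Missing genotypes are preserved as `NA`.
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text"),
                           effect_alleles = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    gm <- read_vcf_gt(path)
  } else {
    gm <- read_plink_text(path)
  }
  if (!is.null(effect_alleles)) {
    ids <- intersect(names(effect_alleles), gm$variants$snp_id)
    flip <- ids[effect_alleles[ids] != gm$variants$effect_allele[match(ids, gm$variants$snp_id)]]
    if (length(flip) > 0) gm <- flip_effect_allele(gm, flip)
    chk <- match(ids, gm$variants$snp_id)
    bad <- effect_alleles[ids] != gm$variants$effect_allele[chk]
    if (any(bad)) {
      abort(paste0("requested effect allele not observed at: ",
                   paste(ids[bad], collapse = ", ")),
            class = "finemapld_format_error")
    }
  }
  gm
}

read_vcf_gt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "finemapld_io_error")
  lines <- readLines(path)
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) != 1) {
    abort("VCF parse error: expected exactly one #CHROM header line",
          class = "finemapld_parse_error")
  }
  hdr <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) {
    abort("VCF parse error: no sample columns", class = "finemapld_parse_error")
  }
  samples <- hdr[-(1:9)]
  body_idx <- seq_along(lines) > hdr_idx & nzchar(lines)
  rows <- which(body_idx)
  n_var <- length(rows)
  vr <- vector("list", n_var)
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = n_var)
  for (k in seq_len(n_var)) {
    ln <- rows[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr)) {
      abort(sprintf("VCF parse error at line %d: %d fields, expected %d",
                    ln, length(f), length(hdr)),
            class = "finemapld_parse_error")
    }
    alt <- f[5]
    if (grepl(",", alt, fixed = TRUE)) {
      abort(sprintf("VCF format error at line %d: multi-allelic record (%s) rejected",
                    ln, f[3]), class = "finemapld_format_error")
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) {
      abort(sprintf("VCF parse error at line %d: bad POS '%s'", ln, f[2]),
            class = "finemapld_parse_error")
    }
    gt_i <- match("GT", strsplit(f[9], ":", fixed = TRUE)[[1]])
    if (is.na(gt_i)) {
      abort(sprintf("VCF format error at line %d: no GT in FORMAT", ln),
            class = "finemapld_format_error")
    }
    for (s in seq_along(samples)) {
      gt <- strsplit(f[9 + s], ":", fixed = TRUE)[[1]][gt_i]
      al <- strsplit(gt, "[/|]")[[1]]
      if (length(al) != 2) {
        abort(sprintf("VCF format error at line %d, sample %s: non-diploid call '%s'",
                      ln, samples[s], gt), class = "finemapld_format_error")
      }
      if (any(al == ".")) next  # stays NA
      ai <- suppressWarnings(as.integer(al))
      if (anyNA(ai) || any(ai > 1L)) {
        abort(sprintf("VCF parse error at line %d: bad genotype '%s'", ln, gt),
              class = "finemapld_parse_error")
      }
      calls[s, k] <- sum(ai)
    }
    vr[[k]] <- tibble(snp_id = f[3], chrom = f[1], pos = pos,
                      allele_a = f[4], allele_b = alt, effect_allele = alt)
  }
  variants <- if (n_var > 0) bind_rows(vr) else
    tibble(snp_id = character(), chrom = character(), pos = integer(),
           allele_a = character(), allele_b = character(),
           effect_allele = character())
  geno_matrix(variants, samples, calls)
}

plink_paths <- function(path) {
  base <- sub("\\.ped$", "", path)
  list(ped = paste0(base, ".ped"), map = paste0(base, ".map"))
}

read_plink_text <- function(path) {
  p <- plink_paths(path)
  if (!file.exists(p$ped) || !file.exists(p$map)) {
    abort(paste0("missing .ped/.map pair for: ", path),
          class = "finemapld_io_error")
  }
  map_lines <- grep("^#", readLines(p$map), value = TRUE, invert = TRUE)
  map_lines <- map_lines[nzchar(map_lines)]
  mp <- strsplit(trimws(map_lines), "\\s+")
  if (length(mp) > 0 && any(lengths(mp) != 4)) {
    abort(sprintf("map parse error at line %d: expected 4 fields",
                  which(lengths(mp) != 4)[1]), class = "finemapld_parse_error")
  }
  n_var <- length(mp)
  ped_lines <- grep("^#", readLines(p$ped), value = TRUE, invert = TRUE)
  ped_lines <- ped_lines[nzchar(ped_lines)]
  n_samp <- length(ped_lines)
  samples <- character(n_samp)
  a1 <- matrix("0", n_samp, n_var)
  a2 <- matrix("0", n_samp, n_var)
  for (i in seq_len(n_samp)) {
    f <- strsplit(trimws(ped_lines[i]), "\\s+")[[1]]
    if (length(f) != 6 + 2 * n_var) {
      abort(sprintf("ped parse error at line %d: %d fields, expected %d",
                    i, length(f), 6 + 2 * n_var),
            class = "finemapld_parse_error")
    }
    samples[i] <- f[2]
    if (n_var > 0) {
      g <- f[-(1:6)]
      a1[i, ] <- g[seq(1, 2 * n_var, by = 2)]
      a2[i, ] <- g[seq(2, 2 * n_var, by = 2)]
    }
  }
  vr <- vector("list", n_var)
  calls <- matrix(NA_integer_, n_samp, n_var)
  for (k in seq_len(n_var)) {
    als <- c(a1[, k], a2[, k])
    obs <- sort(unique(als[als != "0"]))
    if (length(obs) > 2) {
      abort(sprintf("plink format error: >2 alleles at %s", mp[[k]][2]),
            class = "finemapld_format_error")
    }
    if (length(obs) == 0) obs <- c("0", "0")
    if (length(obs) == 1) obs <- c(obs, obs)
    # effect allele: minor; ties to the alphabetically later allele
    cnt <- c(sum(als == obs[1]), sum(als == obs[2]))
    eff <- if (cnt[2] < cnt[1]) obs[2] else if (cnt[1] < cnt[2]) obs[1] else
      sort(obs, decreasing = TRUE)[1]
    mis <- a1[, k] == "0" | a2[, k] == "0"
    calls[!mis, k] <- (a1[!mis, k] == eff) + (a2[!mis, k] == eff)
    other <- setdiff(obs, eff)
    if (length(other) == 0) other <- eff
    vr[[k]] <- tibble(snp_id = mp[[k]][2], chrom = mp[[k]][1],
                      pos = as.integer(mp[[k]][4]),
                      allele_a = other[1], allele_b = eff, effect_allele = eff)
  }
  variants <- if (n_var > 0) bind_rows(vr) else
    tibble(snp_id = character(), chrom = character(), pos = integer(),
           allele_a = character(), allele_b = character(),
           effect_allele = character())
  geno_matrix(variants, samples, calls)
}

#' Write a genotype panel to VCF or PLINK-style text
#'
#' The VCF writer places the effect allele in ALT (so a default re-read
#' recovers the same coding); the PLINK writer emits allele letters, which
#' carry no effect-allele designation (pass `effect_alleles` on re-read).
#'
#' @param gm A [geno_matrix()].
#' @param path Output path (`.vcf`, or `.ped` / basename for PLINK).
#' @param format `"vcf"` or `"plink_text"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  stopifnot(inherits(gm, "geno_matrix"))
  bad <- grepl("[\\s,]", c(gm$variants$allele_a, gm$variants$allele_b))
  if (any(bad)) {
    abort("unencodable allele string (whitespace or comma)",
          class = "finemapld_format_error")
  }
  if (format == "vcf") write_vcf_gt(gm, path) else write_plink_text(gm, path)
  invisible(path)
}

write_vcf_gt <- function(gm, path) {
  v <- gm$variants
  ref <- ifelse(v$effect_allele == v$allele_b, v$allele_a, v$allele_b)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=finemapld-", pkg_version()),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  for (k in seq_len(nrow(v))) {
    g <- gm$calls[, k]
    gt <- ifelse(is.na(g), "./.", code[g + 1L])
    writeLines(paste(c(v$chrom[k], v$pos[k], v$snp_id[k], ref[k],
                       v$effect_allele[k], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
}

write_plink_text <- function(gm, path) {
  p <- plink_paths(path)
  v <- gm$variants
  other <- ifelse(v$effect_allele == v$allele_b, v$allele_a, v$allele_b)
  map <- sprintf("%s\t%s\t0\t%d", v$chrom, v$snp_id, v$pos)
  writeLines(c(paste0("# finemapld-", pkg_version()), map), p$map)
  n_var <- nrow(v)
  rows <- character(length(gm$samples))
  for (i in seq_along(gm$samples)) {
    g <- gm$calls[i, ]
    al <- character(2 * n_var)
    if (n_var > 0) {
      a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, v$effect_allele, other))
      a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, v$effect_allele, other))
      al[seq(1, 2 * n_var, 2)] <- a1
      al[seq(2, 2 * n_var, 2)] <- a2
    }
    rows[i] <- paste(c(gm$samples[i], gm$samples[i], "0", "0", "0", "-9", al),
                     collapse = " ")
  }
  writeLines(c(paste0("# finemapld-", pkg_version()), rows), p$ped)
}

#' Read per-SNP summary statistics
#'
#' Tab-separated with header columns `snp_id`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `p`, `n`, `population`, `trait`.
#' `beta` is on the analysis scale: z-score units for inverse-normal
#' transformed BMI, log odds ratio for disease status. Leading `#` comment
#' lines are skipped.
#'
#' @param path TSV file.
#' @return A tibble, one row per association result.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "finemapld_io_error")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  req <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta", "se",
           "p", "n", "population", "trait")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    abort(paste0("summary-stat schema error, missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "finemapld_schema_error")
  }
  out <- as_tibble(df[req])
  for (col in c("eaf", "beta", "se", "p")) out[[col]] <- as.numeric(out[[col]])
  out$n <- as.integer(out$n)
  if (any(out$se <= 0, na.rm = TRUE)) {
    abort("summary-stat value error: se must be > 0",
          class = "finemapld_value_error")
  }
  out
}

#' Write summary statistics in the package TSV schema
#'
#' @param stats A data frame with the [read_summary_stats()] columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  cols <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta", "se",
            "p", "n", "population", "trait")
  df <- as.data.frame(stats)[, cols]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# finemapld-", pkg_version()), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
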