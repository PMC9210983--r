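#' SNP filtering policy
#'
#' The filter rules applied by [read_vcf], in this fixed order: restrict to
#' biallelic SNPs, remove SNPs within `min_indel_distance` bp of any indel
#' record, set genotypes with low depth or genotype quality missing, then drop
#' sites whose missing rate exceeds `max_missing_rate`.
#'
#' @param biallelic_only keep only biallelic SNPs.
#' @param min_indel_distance minimum distance (bp) from a SNP to the nearest
#'   base of any indel's reference span.
#' @param genotype_min_depth genotypes with `DP` below this become missing.
#' @param genotype_min_gq genotypes with `GQ` below this become missing.
#' @param max_missing_rate per-site missing-genotype fraction above which the
#'   site is discarded.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(biallelic_only = TRUE, min_indel_distance = 5,
                          genotype_min_depth = 5, genotype_min_gq = 10,
                          max_missing_rate = 0.1) {
  stopifnot(min_indel_distance >= 0, max_missing_rate >= 0,
            max_missing_rate <= 1)
  structure(list(biallelic_only = biallelic_only,
                 min_indel_distance = min_indel_distance,
                 genotype_min_depth = genotype_min_depth,
                 genotype_min_gq = genotype_min_gq,
                 max_missing_rate = max_missing_rate),
            class = "filter_policy")
}

#' A policy that filters nothing (round-trip testing, pre-filtered input)
#' @return A [filter_policy] with every rule disabled.
#' @export
permissive_policy <- function() {
  filter_policy(biallelic_only = TRUE, min_indel_distance = 0,
                genotype_min_depth = 0, genotype_min_gq = 0,
                max_missing_rate = 1)
}

#' Read a two-column sample-to-population map
#'
#' @param path TSV with columns sample and population; populations must be
#'   `pop1`, `pop2` or `outgroup`.
#' @return data.frame with columns `sample` and `pop`.
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("sample", "pop"),
                   colClasses = "character")
  if (!all(pm$pop %in% c("pop1", "pop2", "outgroup")))
    stop("population labels must be 'pop1', 'pop2' or 'outgroup'")
  pm
}

# dosage matrix (samples x sites) from vcfR GT strings
.gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "." | is.na(gt) | a2 == ""] <- NA
  matrix(as.integer(d), nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Read and filter a multi-sample VCF
#'
#' Parses a VCF of SNP/indel records, applies the filter policy rules in their
#' fixed order (biallelic SNPs, indel distance, DP/GQ genotype masking, site
#' missing rate), and returns one [genotype_matrix] per chromosome plus a
#' report counting removals per rule. Dosage counts the alternate allele;
#' sites are unpolarized until [polarize] is applied against an outgroup.
#'
#' @param path VCF file (plain or gzipped).
#' @param popmap data.frame (`sample`, `pop`) or path to one; every mapped
#'   sample must exist in the VCF, unmapped VCF samples are dropped.
#' @param policy a [filter_policy].
#' @return list with `matrices` (named by chromosome) and `report`.
#' @export
read_vcf <- function(path, popmap, policy = filter_policy()) {
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_input <- nrow(fix)
  report <- list(n_input = n_input, n_not_biallelic_snp = 0,
                 n_near_indel = 0, n_genotypes_masked = 0,
                 n_high_missing = 0, n_retained = 0, dp_rule = "applied",
                 gq_rule = "applied")
  if (n_input == 0) {
    return(list(matrices = list(), report = report))
  }
  fix$POS <- as.integer(fix$POS)
  alt_split <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  max_alt_len <- vapply(alt_split, function(a) if (length(a)) max(nchar(a)) else 0L, 0L)
  n_alt <- lengths(alt_split)
  is_indel <- nchar(fix$REF) > 1 | max_alt_len > 1
  is_bi_snp <- !is_indel & n_alt == 1 & nchar(fix$REF) == 1 &
    fix$ALT %in% c("A", "C", "G", "T")

  keep <- if (policy$biallelic_only) is_bi_snp else !is_indel
  report$n_not_biallelic_snp <- sum(!keep)

  # distance from each SNP to the nearest base of any indel reference span
  if (policy$min_indel_distance > 0 && any(is_indel)) {
    near <- rep(FALSE, n_input)
    ind <- which(is_indel)
    for (chrom in unique(fix$CHROM[ind])) {
      ii <- ind[fix$CHROM[ind] == chrom]
      ss <- which(keep & fix$CHROM == chrom)
      if (!length(ss)) next
      starts <- fix$POS[ii]
      ends <- fix$POS[ii] + nchar(fix$REF[ii]) - 1L
      for (s in ss) {
        d <- pmax(starts - fix$POS[s], fix$POS[s] - ends, 0)
        if (min(d) < policy$min_indel_distance) near[s] <- TRUE
      }
    }
    report$n_near_indel <- sum(near)
    keep <- keep & !near
  }

  vcf_samples <- colnames(v@gt)[-1]
  missing_samples <- setdiff(popmap$sample, vcf_samples)
  if (length(missing_samples))
    stop("samples in popmap absent from VCF: ",
         paste(missing_samples, collapse = ", "))

  gt <- vcfR::extract.gt(v, "GT")          # variants x samples
  dose <- t(.gt_to_dosage(gt))[popmap$sample, , drop = FALSE]

  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (policy$genotype_min_depth > 0 && "DP" %in% fmt) {
    dp <- t(suppressWarnings(
      vcfR::extract.gt(v, "DP", as.numeric = TRUE)))[popmap$sample, , drop = FALSE]
    mask <- !is.na(dose) & (is.na(dp) | dp < policy$genotype_min_depth)
    report$n_genotypes_masked <- report$n_genotypes_masked + sum(mask[, keep])
    dose[mask] <- NA
  } else if (policy$genotype_min_depth > 0) report$dp_rule <- "skipped (no DP field)"
  if (policy$genotype_min_gq > 0 && "GQ" %in% fmt) {
    gq <- t(suppressWarnings(
      vcfR::extract.gt(v, "GQ", as.numeric = TRUE)))[popmap$sample, , drop = FALSE]
    mask <- !is.na(dose) & (is.na(gq) | gq < policy$genotype_min_gq)
    report$n_genotypes_masked <- report$n_genotypes_masked + sum(mask[, keep])
    dose[mask] <- NA
  } else if (policy$genotype_min_gq > 0) report$gq_rule <- "skipped (no GQ field)"

  miss_rate <- colMeans(is.na(dose))
  high_miss <- keep & miss_rate > policy$max_missing_rate
  report$n_high_missing <- sum(high_miss)
  keep <- keep & !high_miss
  report$n_retained <- sum(keep)

  matrices <- list()
  for (chrom in unique(fix$CHROM[keep])) {
    cols <- which(keep & fix$CHROM == chrom)
    cols <- cols[order(fix$POS[cols])]
    matrices[[chrom]] <- genotype_matrix(
      dose[, cols, drop = FALSE], popmap$sample, popmap$pop, chrom = chrom,
      pos = fix$POS[cols], polarized = rep(FALSE, length(cols)))
  }
  list(matrices = matrices, report = report)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Derived/alternate dosage becomes GT (`0/0`, `0/1`, `1/1`, `./.`); REF/ALT
#' are placeholder alleles A/T. Allows synthetic data to exercise the VCF
#' entry path end to end.
#'
#' @param g a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", g$chrom, max(g$pos)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$sample_ids), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (s in seq_along(g$pos)) {
    gt <- gt_codes[g$geno[, s] + 1L]
    gt[is.na(gt)] <- "./."
    writeLines(paste(c(g$chrom, g$pos[s], ".", "A", "T", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write the window statistics table as TSV
#' @param stats a `window_stats` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(stats, path) .write_tsv(stats, path)

#' Write outlier calls as TSV
#' @param calls an `outlier_calls` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outlier_calls <- function(calls, path) .write_tsv(calls, path)

#' Write window spans or outlier calls as BED
#'
#' Converts the package's 1-based inclusive spans to BED's 0-based half-open
#' convention; for outlier calls the class goes in the name column and the
#' smaller of the two q-values in the score column.
#'
#' @param x a `window_stats` or `outlier_calls` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  bed <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end)
  if (!is.null(x$class)) {
    bed$name <- x$class
    bed$score <- pmin(x$q_high, x$q_low)
  }
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = "NA")
  invisible(path)
}

#' Serialize a 2D-SFS as plain text
#' @param sfs an `sfs2d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(sfs, path) {
  mask_idx <- which(sfs$mask, arr.ind = TRUE) - 1L
  hdr <- sprintf("# sfs2d k1=%d k2=%d polarized=%s probabilities=%s mask=%s",
                 sfs$k1, sfs$k2, sfs$polarized, sfs$probabilities,
                 paste(sprintf("%d:%d", mask_idx[, 1], mask_idx[, 2]),
                       collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(sfs$counts, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a 2D-SFS written by [write_sfs]
#' @param path input path.
#' @return An `sfs2d`.
#' @export
read_sfs <- function(path) {
  hdr <- readLines(path, n = 1)
  get <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", hdr)
  k1 <- as.integer(get("k1"))
  k2 <- as.integer(get("k2"))
  counts <- as.matrix(read.table(path, skip = 1, sep = "\t"))
  out <- .new_sfs2d(unname(counts), k1, k2,
                    polarized = as.logical(get("polarized")),
                    probabilities = as.logical(get("probabilities")))
  mask <- matrix(FALSE, k1 + 1, k2 + 1)
  for (cell in strsplit(get("mask"), ",", fixed = TRUE)[[1]]) {
    ij <- as.integer(strsplit(cell, ":", fixed = TRUE)[[1]])
    mask[ij[1] + 1, ij[2] + 1] <- TRUE
  }
  out$mask <- mask
  out
}

#' Assemble a pipeline run configuration
#'
#' @param mode `"simulate"` (synthetic data) or `"vcf"` (real data).
#' @param outdir output directory.
#' @param seed master seed; all stage randomness derives from it.
#' @param model generating/null [demographic_model] (default
#'   [default_im_model]).
#' @param n_windows number of simulated windows (simulate mode).
#' @param window_bp window width.
#' @param n1,n2,n_out diploid sample sizes (simulate mode).
#' @param rho_range recombination-rate range per bp.
#' @param layer a [read_layer].
#' @param null_reps null-distribution replicates.
#' @param q FDR threshold per tail.
#' @param vcf,popmap input paths (vcf mode).
#' @param chrom_length chromosome length (vcf mode; default from data).
#' @param compare_stats window statistics to contrast across classes.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "vcf"), outdir, seed = 1,
                       model = default_im_model(), n_windows = 200,
                       window_bp = 10000, n1 = 20, n2 = 19, n_out = 0,
                       rho_range = c(0.001, 0.005), layer = read_layer(),
                       null_reps = 2000, q = 0.01, vcf = NULL, popmap = NULL,
                       chrom_length = NULL,
                       compare_stats = c("theta_pi_pop1", "tajima_d_pop1",
                                         "prop_fixed", "prop_shared", "dxy")) {
  mode <- match.arg(mode)
  if (mode == "vcf" && (is.null(vcf) || is.null(popmap)))
    stop("vcf mode requires 'vcf' and 'popmap' paths")
  # empirical P-values are bounded below at 1/(null_reps+1); warn when no
  # window could survive BH at level q
  if (1 / (null_reps + 1) >= q)
    warning("null_reps too small for any discovery at q = ", q)
  structure(list(mode = mode, outdir = outdir, seed = as.integer(seed),
                 model = model, n_windows = n_windows, window_bp = window_bp,
                 n1 = n1, n2 = n2, n_out = n_out, rho_range = rho_range,
                 layer = layer, null_reps = null_reps, q = q, vcf = vcf,
                 popmap = popmap, chrom_length = chrom_length,
                 compare_stats = compare_stats),
            class = "run_config")
}

#' Run the full divergence-scan pipeline
#'
#' Chains data entry (simulation or VCF), window statistics, null building,
#' outlier classification and the class contrasts, writing each stage's table
#' under `outdir`. Stages whose output file already exists are skipped, so a
#' partially deleted output directory resumes from the missing stage onward;
#' the manifest is written last as the completion marker.
#'
#' @param config a [run_config].
#' @return Invisible list of output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    stats = file.path(config$outdir, "window_stats.tsv"),
    null = file.path(config$outdir, "null_fst.tsv"),
    calls = file.path(config$outdir, "outlier_calls.tsv"),
    calls_bed = file.path(config$outdir, "outlier_calls.bed"),
    compare = file.path(config$outdir, "region_contrasts.tsv"),
    manifest = file.path(config$outdir, "manifest.json"))

  # stage seeds derive deterministically from the master seed
  seeds <- config$seed + c(stats = 101L, null = 202L)

  if (!file.exists(paths$stats)) {
    if (config$mode == "simulate") {
      sim <- simulate_genome(config$model, n_windows = config$n_windows,
                             window_bp = config$window_bp,
                             rho_range = config$rho_range,
                             layer = config$layer, n1 = config$n1,
                             n2 = config$n2, n_out = config$n_out,
                             seed = seeds[["stats"]])
      stats <- window_stats_genome(sim$windows, window_bp = config$window_bp,
                                   rho = sim$truth$rho)
    } else {
      res <- read_vcf(config$vcf, config$popmap)
      stats <- do.call(rbind, lapply(res$matrices, function(g) {
        window_stats(g, window_bp = config$window_bp,
                     chrom_length = config$chrom_length)
      }))
    }
    write_window_stats(stats, paths$stats)
  }
  stats <- read.table(paths$stats, header = TRUE, sep = "\t")

  if (!file.exists(paths$null)) {
    null <- build_null(config$model, n1 = config$n1, n2 = config$n2,
                       window_bp = config$window_bp,
                       rho_range = config$rho_range, layer = config$layer,
                       n_reps = config$null_reps, seed = seeds[["null"]])
    .write_tsv(data.frame(fst = null$fst_samples), paths$null)
  }
  null <- structure(list(fst_samples = read.table(paths$null, header = TRUE,
                                                  sep = "\t")$fst,
                         model = config$model, n_reps = config$null_reps),
                    class = "null_distribution")

  if (!file.exists(paths$calls)) {
    calls <- classify_windows(stats, null, q = config$q)
    write_outlier_calls(calls, paths$calls)
    write_bed(calls, paths$calls_bed)
  }
  calls <- read.table(paths$calls, header = TRUE, sep = "\t")

  if (!file.exists(paths$compare)) {
    contrasts <- do.call(rbind, lapply(
      intersect(config$compare_stats, names(stats)),
      function(s) compare_regions(stats, calls, s)))
    .write_tsv(contrasts, paths$compare)
  }

  manifest <- list(
    mode = config$mode, seed = config$seed, window_bp = config$window_bp,
    n_windows = config$n_windows, null_reps = config$null_reps, q = config$q,
    package_version = as.character(utils::packageVersion("divscan")),
    outputs = lapply(paths[c("stats", "null", "calls")], function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    inputs = if (config$mode == "vcf")
      list(vcf = list(path = config$vcf,
                      md5 = unname(tools::md5sum(config$vcf)))) else NULL)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
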