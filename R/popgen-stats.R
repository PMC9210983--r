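#' Partition a chromosome into non-overlapping windows
#'
#' @param chrom_length chromosome length in bp.
#' @param window window width in bp (default 10 kbp).
#' @return A data.frame with 1-based inclusive `start` and `end`; the spans are
#'   contiguous, cover `[1, chrom_length]`, and only the last may be shorter.
#' @export
iter_windows <- function(chrom_length, window = 10000) {
  if (!is.numeric(chrom_length) || chrom_length < 1) stop("chrom_length must be >= 1")
  if (!is.numeric(window) || window < 1) stop("window must be >= 1")
  start <- seq(1, chrom_length, by = window)
  data.frame(start = as.integer(start),
             end = as.integer(pmin(start + window - 1, chrom_length)))
}

# Counted-site bookkeeping shared by the per-population estimators. Returns
# per-site observed allele copies (n) and derived counts (d) for sites in the
# span, plus whether the span holds any SNP records at all.
.pop_sites <- function(g, pop, span) {
  keep <- .span_sites(g, span)
  m <- g$geno[g$pop == pop, keep, drop = FALSE]
  c(.site_counts(m), list(any_sites = ncol(m) > 0, polarized = g$polarized[keep]))
}

.span_denominator <- function(g, span, denominator) {
  if (!is.null(denominator)) {
    if (denominator <= 0) stop("denominator must be positive")
    return(denominator)
  }
  if (!is.null(span)) span[2] - span[1] + 1 else max(g$pos)
}

#' Per-site nucleotide diversity (theta-pi)
#'
#' Mean pairwise difference per site: `sum(2*p*(1-p)*n/(n-1))` over counted
#' sites divided by `denominator`, with `n` the observed allele copies at the
#' site. Sites with fewer than two observed copies are not counted; a span
#' without SNP records is monomorphic and returns 0, while a span whose sites
#' are all uncountable returns `NA`.
#'
#' @param g a [genotype_matrix].
#' @param pop population label.
#' @param span optional `c(start, end)` window (1-based inclusive).
#' @param denominator number of callable base pairs (default: span width).
#' @return Per-site diversity, or `NA` when undefined.
#' @export
nucleotide_diversity <- function(g, pop = "pop1", span = NULL,
                                 denominator = NULL) {
  denom <- .span_denominator(g, span, denominator)
  s <- .pop_sites(g, pop, span)
  if (!s$any_sites) return(0)
  ok <- s$n >= 2
  if (!any(ok)) return(NA_real_)
  p <- s$d[ok] / s$n[ok]
  sum(2 * p * (1 - p) * s$n[ok] / (s$n[ok] - 1)) / denom
}

#' Per-site Watterson's theta
#'
#' `S / a_n / denominator` where `S` is the number of segregating sites in the
#' population and `a_n` the harmonic number for the window-modal number of
#' observed allele copies.
#'
#' @inheritParams nucleotide_diversity
#' @return Per-site Watterson estimate, or `NA` when undefined.
#' @export
watterson_theta <- function(g, pop = "pop1", span = NULL, denominator = NULL) {
  denom <- .span_denominator(g, span, denominator)
  s <- .pop_sites(g, pop, span)
  if (!s$any_sites) return(0)
  ok <- s$n >= 2
  if (!any(ok)) return(NA_real_)
  n_modal <- .modal_n(s$n[ok])
  S <- sum(s$d[ok] > 0 & s$d[ok] < s$n[ok])
  S / sum(1 / seq_len(n_modal - 1)) / denom
}

.modal_n <- function(n) {
  tab <- table(n)
  as.numeric(names(tab)[which.max(tab)])
}

#' Tajima's D
#'
#' Normalized difference between the pairwise and Watterson estimates of theta
#' (count scale, not per site), using the standard constants computed from the
#' window-modal number of observed allele copies.
#'
#' @inheritParams nucleotide_diversity
#' @return `D`, 0 when both numerator and variance vanish (e.g. `n = 2`), `NA`
#'   when there are no segregating sites.
#' @export
tajimas_d <- function(g, pop = "pop1", span = NULL) {
  s <- .pop_sites(g, pop, span)
  ok <- s$n >= 2
  if (!any(ok)) return(NA_real_)
  n <- .modal_n(s$n[ok])
  d <- s$d[ok]
  seg <- d > 0 & d < s$n[ok]
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  p <- d[seg] / s$n[ok][seg]
  pi_count <- sum(2 * p * (1 - p) * s$n[ok][seg] / (s$n[ok][seg] - 1))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  num <- pi_count - S / a1
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(if (abs(num) < 1e-12) 0 else NA_real_)
  num / sqrt(v)
}

#' Fay and Wu's H (unnormalized)
#'
#' `H = theta_pi - theta_H` on the count scale, where `theta_H` weights
#' high-frequency derived alleles: `sum(2 * i^2 / (n * (n - 1)))` over derived
#' counts `i`. Only polarized sites enter; a span with SNPs but no polarized
#' sites is undefined rather than silently folded.
#'
#' @inheritParams nucleotide_diversity
#' @return `H`, or `NA` when the span cannot be polarized.
#' @export
faywu_h <- function(g, pop = "pop1", span = NULL) {
  s <- .pop_sites(g, pop, span)
  if (!s$any_sites) return(0)
  ok <- s$n >= 2 & s$polarized
  if (!any(ok)) return(NA_real_)
  n <- s$n[ok]
  i <- s$d[ok]
  seg <- i > 0 & i < n
  if (!any(seg)) return(0)
  n <- n[seg]; i <- i[seg]
  pi_count <- sum(2 * i * (n - i) / (n * (n - 1)))
  th_h <- sum(2 * i^2 / (n * (n - 1)))
  pi_count - th_h
}

#' Expected heterozygosity
#'
#' Mean over sites of `2 * p * (1 - p)` from observed allele frequencies.
#'
#' @inheritParams nucleotide_diversity
#' @return `H_E`, 0 for a span without SNP records, `NA` when every site is
#'   entirely missing in the population.
#' @export
expected_heterozygosity <- function(g, pop = "pop1", span = NULL) {
  s <- .pop_sites(g, pop, span)
  if (!s$any_sites) return(0)
  ok <- s$n >= 1
  if (!any(ok)) return(NA_real_)
  p <- s$d[ok] / s$n[ok]
  mean(2 * p * (1 - p))
}

#' Weir-Cockerham FST for the two focal populations
#'
#' Per-site variance components on allele-copy counts (mean squares between and
#' within populations), combined across the window as a ratio of sums.
#' Monomorphic sites are skipped; the estimator may be negative and is reported
#' as computed.
#'
#' @inheritParams nucleotide_diversity
#' @return The window FST estimate, or `NA` when no usable sites exist.
#' @export
wc_fst <- function(g, span = NULL) {
  s1 <- .pop_sites(g, "pop1", span)
  s2 <- .pop_sites(g, "pop2", span)
  comp <- .wc_components(s1$n, s1$d, s2$n, s2$d)
  if (comp$den <= 0) return(NA_real_)
  comp$num / comp$den
}

# Sums of the per-site WC variance components a and a+b over usable sites.
.wc_components <- function(n1, d1, n2, d2) {
  ok <- n1 >= 2 & n2 >= 2
  n1 <- n1[ok]; d1 <- d1[ok]; n2 <- n2[ok]; d2 <- d2[ok]
  p1 <- d1 / n1
  p2 <- d2 / n2
  pbar <- (d1 + d2) / (n1 + n2)
  poly <- pbar > 0 & pbar < 1
  if (!any(poly)) return(list(num = 0, den = 0))
  n1 <- n1[poly]; n2 <- n2[poly]; p1 <- p1[poly]; p2 <- p2[poly]
  pbar <- pbar[poly]
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  a <- (msp - msg) / nc
  list(num = sum(a), den = sum(a + msg))
}

#' Absolute divergence dxy
#'
#' `sum(pA * (1 - pB) + pB * (1 - pA))` over sites with at least one observed
#' copy in each population, divided by `denominator`.
#'
#' @param g a [genotype_matrix].
#' @param popA,popB population labels.
#' @param span optional `c(start, end)` window.
#' @param denominator number of callable base pairs (default: span width).
#' @return Per-site dxy.
#' @export
dxy <- function(g, popA = "pop1", popB = "pop2", span = NULL,
                denominator = NULL) {
  denom <- .span_denominator(g, span, denominator)
  sA <- .pop_sites(g, popA, span)
  sB <- .pop_sites(g, popB, span)
  if (!sA$any_sites) return(0)
  ok <- sA$n >= 1 & sB$n >= 1
  if (!any(ok)) return(NA_real_)
  pA <- sA$d[ok] / sA$n[ok]
  pB <- sB$d[ok] / sB$n[ok]
  sum(pA * (1 - pB) + pB * (1 - pA)) / denom
}

#' Relative node depth
#'
#' Ratio of the focal-pair divergence to the divergence from an outgroup,
#' controlling for local mutation-rate variation.
#'
#' @param dxy_focal per-site dxy between the focal populations.
#' @param dxy_outgroup per-site dxy between a focal population and the
#'   outgroup.
#' @return `dxy_focal / dxy_outgroup`, `NA` when the outgroup divergence is
#'   zero or undefined.
#' @export
rnd <- function(dxy_focal, dxy_outgroup) {
  out <- dxy_focal / dxy_outgroup
  out[is.na(dxy_outgroup) | dxy_outgroup <= 0] <- NA_real_
  out
}

#' Classify polymorphic sites into fixed / shared / private
#'
#' Every biallelic site segregating in the union of the two focal populations
#' is assigned to exactly one class: `fixed` (alternative alleles fixed in the
#' two populations), `shared` (segregating in both), `private1` / `private2`
#' (segregating in exactly one). Sites monomorphic in the union are excluded.
#'
#' @inheritParams wc_fst
#' @return Named numeric vector of the four proportions (summing to 1), all
#'   `NA` when no site segregates in the union.
#' @export
classify_polymorphisms <- function(g, span = NULL) {
  s1 <- .pop_sites(g, "pop1", span)
  s2 <- .pop_sites(g, "pop2", span)
  ok <- s1$n >= 1 & s2$n >= 1
  n1 <- s1$n[ok]; d1 <- s1$d[ok]; n2 <- s2$n[ok]; d2 <- s2$d[ok]
  du <- d1 + d2
  nu_ <- n1 + n2
  seg <- du > 0 & du < nu_
  if (!any(seg)) {
    return(c(prop_fixed = NA_real_, prop_shared = NA_real_,
             prop_private1 = NA_real_, prop_private2 = NA_real_))
  }
  poly1 <- d1 > 0 & d1 < n1
  poly2 <- d2 > 0 & d2 < n2
  fixed <- seg & !poly1 & !poly2 & ((d1 > 0) != (d2 > 0))
  shared <- seg & poly1 & poly2
  private1 <- seg & poly1 & !poly2
  private2 <- seg & !poly1 & poly2
  tot <- sum(seg)
  c(prop_fixed = sum(fixed) / tot, prop_shared = sum(shared) / tot,
    prop_private1 = sum(private1) / tot, prop_private2 = sum(private2) / tot)
}

# dosage (or haplotype) matrix for LD computations: individuals x segregating
# sites within the span, together with the retained site positions
.ld_matrix <- function(g, pop, span, phased) {
  keep <- .span_sites(g, span)
  if (phased) {
    hap <- attr(g, "haplotypes")
    if (is.null(hap)) stop("phased LD requires haplotype data (simulated windows)")
    rows <- rep(which(g$pop == pop), each = 2) * 2 - c(1, 0)
    m <- hap[rows, keep, drop = FALSE]
  } else {
    m <- g$geno[g$pop == pop, keep, drop = FALSE]
  }
  v <- apply(m, 2, function(x) stats::var(x, na.rm = TRUE))
  usable <- !is.na(v) & v > 0
  list(m = m[, usable, drop = FALSE], pos = g$pos[keep][usable])
}

#' Mean pairwise r-squared within a window
#'
#' Squared correlation of genotype dosages (or haplotypes when `phased`) over
#' all pairs of segregating sites; pairs whose correlation is undefined after
#' missing-data removal are skipped.
#'
#' @inheritParams nucleotide_diversity
#' @param phased use haplotypes rather than dosages (simulated data only).
#' @return Mean r-squared, `NA` with fewer than two usable sites.
#' @export
ld_r2 <- function(g, pop = "pop1", span = NULL, phased = FALSE) {
  m <- .ld_matrix(g, pop, span, phased)$m
  if (ncol(m) < 2) return(NA_real_)
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  r2 <- r[upper.tri(r)]^2
  if (all(is.na(r2))) return(NA_real_)
  mean(r2, na.rm = TRUE)
}

#' Linkage-disequilibrium decay curve
#'
#' Mean r-squared over site pairs binned by physical distance.
#'
#' @inheritParams ld_r2
#' @param max_dist maximum pair separation in bp.
#' @param bin bin width in bp.
#' @return data.frame with bin midpoints, mean r-squared (`NA` for empty bins)
#'   and pair counts.
#' @export
ld_decay <- function(g, pop = "pop1", max_dist = 10000, bin = 500,
                     span = NULL, phased = FALSE) {
  lm_ <- .ld_matrix(g, pop, span, phased)
  m <- lm_$m
  pos <- lm_$pos
  brk <- seq(0, max_dist, by = bin)
  if (brk[length(brk)] < max_dist) brk <- c(brk, max_dist)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  out <- data.frame(mid = mids, r2 = NA_real_, n_pairs = 0L)
  if (ncol(m) < 2) return(out)
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  dist <- abs(pos[idx[, 2]] - pos[idx[, 1]])
  r2 <- r[upper.tri(r)]^2
  ok <- !is.na(r2) & dist <= max_dist & dist > 0
  bin_id <- cut(dist[ok], breaks = brk, labels = FALSE, include.lowest = TRUE)
  agg_mean <- tapply(r2[ok], bin_id, mean)
  agg_n <- tapply(r2[ok], bin_id, length)
  ii <- as.integer(names(agg_mean))
  out$r2[ii] <- as.numeric(agg_mean)
  out$n_pairs[ii] <- as.integer(agg_n)
  out
}
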