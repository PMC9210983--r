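#' Compute the full per-window statistics table
#'
#' Applies every per-window statistic of the divergence scan to non-overlapping
#' windows: within-population diversity (theta-pi, Watterson's theta, Tajima's
#' D, Fay and Wu's H, expected heterozygosity, mean r-squared), cross-population
#' differentiation (Weir-Cockerham FST, dxy, relative node depth when an
#' outgroup is present), and the fixed/shared/private partition of segregating
#' sites. Per-site statistics use the number of callable base pairs in the span
#' as denominator (the span width by default); undefined values are `NA`.
#'
#' @param g a [genotype_matrix].
#' @param window_bp window width in bp.
#' @param chrom_length chromosome length (default: largest position present).
#' @param rho optional population-scaled recombination rate per bp (scalar or
#'   one value per window); when supplied, `rho / theta_pi` ratios are added.
#' @return A data.frame with one row per window (class `window_stats`).
#' @export
window_stats <- function(g, window_bp = 10000, chrom_length = NULL,
                         rho = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(chrom_length)) chrom_length <- max(g$pos)
  win <- iter_windows(chrom_length, window_bp)
  nw <- nrow(win)
  if (!is.null(rho) && length(rho) == 1) rho <- rep(rho, nw)
  has_out <- any(g$pop == "outgroup")

  rows <- vector("list", nw)
  for (i in seq_len(nw)) {
    span <- c(win$start[i], win$end[i])
    denom <- span[2] - span[1] + 1
    s1 <- .pop_sites(g, "pop1", span)
    s2 <- .pop_sites(g, "pop2", span)
    du <- s1$d + s2$d
    nu_ <- s1$n + s2$n
    n_seg <- sum(nu_ > 0 & du > 0 & du < nu_)
    props <- classify_polymorphisms(g, span)
    dxy12 <- dxy(g, "pop1", "pop2", span)
    rnd_v <- if (has_out) rnd(dxy12, dxy(g, "pop1", "outgroup", span)) else NA_real_
    pi1 <- nucleotide_diversity(g, "pop1", span)
    pi2 <- nucleotide_diversity(g, "pop2", span)
    rows[[i]] <- data.frame(
      chrom = g$chrom, start = span[1], end = span[2],
      n_callable = denom, n_seg = n_seg,
      theta_pi_pop1 = pi1, theta_pi_pop2 = pi2,
      theta_w_pop1 = watterson_theta(g, "pop1", span),
      theta_w_pop2 = watterson_theta(g, "pop2", span),
      tajima_d_pop1 = tajimas_d(g, "pop1", span),
      tajima_d_pop2 = tajimas_d(g, "pop2", span),
      faywu_h_pop1 = faywu_h(g, "pop1", span),
      faywu_h_pop2 = faywu_h(g, "pop2", span),
      he_pop1 = expected_heterozygosity(g, "pop1", span),
      he_pop2 = expected_heterozygosity(g, "pop2", span),
      r2_pop1 = ld_r2(g, "pop1", span),
      r2_pop2 = ld_r2(g, "pop2", span),
      fst = wc_fst(g, span), dxy = dxy12, rnd = rnd_v,
      prop_fixed = props[["prop_fixed"]],
      prop_shared = props[["prop_shared"]],
      prop_private1 = props[["prop_private1"]],
      prop_private2 = props[["prop_private2"]],
      rho_over_theta_pop1 = if (is.null(rho)) NA_real_ else rho[i] / pi1,
      rho_over_theta_pop2 = if (is.null(rho)) NA_real_ else rho[i] / pi2)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Window statistics for a list of simulated windows
#'
#' Convenience driver for [simulate_genome] output: each simulated window is a
#' full window of its own chromosome, so the table has one row per simulated
#' window.
#'
#' @param windows list of [genotype_matrix] objects (one window each).
#' @param window_bp window width in bp.
#' @param rho optional per-window recombination rates (e.g. the truth table's).
#' @return A `window_stats` data.frame.
#' @export
window_stats_genome <- function(windows, window_bp = 10000, rho = NULL) {
  rows <- lapply(seq_along(windows), function(i) {
    window_stats(windows[[i]], window_bp = window_bp, chrom_length = window_bp,
                 rho = if (is.null(rho)) NULL else rho[i])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_stats", "data.frame")
  out
}
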