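#' Build a simulated null distribution of window FST
#'
#' Simulates windows under the accepted demographic model (recombination rate
#' drawn per replicate from `rho_range`), passes each through the sequencing
#' read layer, and records the Weir-Cockerham window FST. Replicates with
#' undefined FST (no usable sites) are discarded and counted.
#'
#' @param model a [demographic_model] (the accepted null model).
#' @param n1,n2 diploid sample sizes matching the observed data.
#' @param window_bp window length in bp.
#' @param rho_range range of the population-scaled recombination rate per bp.
#' @param layer a [read_layer] emulating the sequencing regime.
#' @param n_reps number of null replicates (>= 100).
#' @param seed integer seed.
#' @return An object of class `null_distribution`: sorted `fst_samples` plus
#'   the generating metadata.
#' @export
build_null <- function(model, n1 = 20, n2 = 19, window_bp = 10000,
                       rho_range = c(0.001, 0.005), layer = read_layer(),
                       n_reps = 5000, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"), n_reps >= 100)
  if (rho_range[1] > rho_range[2]) stop("rho_range must be increasing")
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_genome(model, n_windows = n_reps, window_bp = window_bp,
                         rho_range = rho_range, layer = layer, n1 = n1,
                         n2 = n2, n_out = 0)
  fst <- vapply(sim$windows, wc_fst, 0)
  n_undefined <- sum(is.na(fst))
  structure(list(fst_samples = sort(fst[!is.na(fst)]),
                 n_reps = n_reps, n_undefined = n_undefined, model = model,
                 rho_range = rho_range, layer = layer, window_bp = window_bp,
                 n1 = n1, n2 = n2, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  q <- quantile(x$fst_samples, c(0.025, 0.5, 0.975))
  cat("null_distribution:", length(x$fst_samples), "FST replicates",
      sprintf("(median %.4f, 95%% band %.4f-%.4f;", q[2], q[1], q[3]),
      x$n_undefined, "undefined discarded)\n")
  invisible(x)
}

#' Add-one empirical P-value against a simulated null
#'
#' `p = (r + 1) / (n + 1)` where `r` counts null samples at least as extreme
#' as the observation (ties count as extreme); never exactly zero, so FDR
#' adjustment downstream is well defined.
#'
#' @param fst_obs observed statistic (vectorized).
#' @param null a `null_distribution` (or numeric vector of null samples).
#' @param tail `"high"` (null >= obs extreme) or `"low"` (null <= obs).
#' @return Empirical P-values in `(0, 1]`; `NA` observations give `NA`.
#' @export
empirical_pvalue <- function(fst_obs, null, tail = c("high", "low")) {
  tail <- match.arg(tail)
  samples <- if (inherits(null, "null_distribution")) null$fst_samples
             else sort(null)
  n <- length(samples)
  if (!n) stop("null distribution is empty")
  # sorted null: count via binary search on either tail
  r <- if (tail == "high") n - findInterval(fst_obs, samples, left.open = TRUE)
       else findInterval(fst_obs, samples)
  out <- (r + 1) / (n + 1)
  out[is.na(fst_obs)] <- NA_real_
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted P-values (via [stats::p.adjust]) and rejection flags at
#' level `q`.
#'
#' @param pvalues raw P-values in `(0, 1]`.
#' @param q FDR threshold.
#' @return data.frame with `p`, `q_value` and logical `reject`.
#' @export
bh_fdr <- function(pvalues, q = 0.01) {
  if (!length(pvalues)) {
    return(data.frame(p = numeric(0), q_value = numeric(0),
                      reject = logical(0)))
  }
  adj <- p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, q_value = adj, reject = !is.na(adj) & adj < q)
}

#' Classify windows against the simulated null
#'
#' Each window receives upper- and lower-tail empirical P-values against the
#' null FST distribution; Benjamini-Hochberg correction is applied separately
#' per tail, and windows are labelled `high`, `low` or `background`. Windows
#' with undefined FST are kept with `NA` P-values and class `background`.
#'
#' @param stats a `window_stats` data.frame (see [window_stats]).
#' @param null a `null_distribution`.
#' @param q FDR threshold per tail.
#' @return data.frame of class `outlier_calls`: window id, observed FST, both
#'   tails' P- and q-values, and the class label.
#' @export
classify_windows <- function(stats, null, q = 0.01) {
  stopifnot(inherits(null, "null_distribution"), q > 0, q < 0.5)
  if (!nrow(stats)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), fst_obs = numeric(0),
                      p_high = numeric(0), p_low = numeric(0),
                      q_high = numeric(0), q_low = numeric(0),
                      class = character(0))
    class(out) <- c("outlier_calls", "data.frame")
    return(out)
  }
  p_high <- empirical_pvalue(stats$fst, null, "high")
  p_low <- empirical_pvalue(stats$fst, null, "low")
  ok <- !is.na(p_high)
  q_high <- q_low <- rep(NA_real_, nrow(stats))
  q_high[ok] <- p.adjust(p_high[ok], method = "BH")
  q_low[ok] <- p.adjust(p_low[ok], method = "BH")
  cls <- rep("background", nrow(stats))
  hi <- ok & q_high < q
  lo <- ok & q_low < q
  if (any(hi & lo)) stop("window significant in both tails; q too permissive")
  cls[hi] <- "high"
  cls[lo] <- "low"
  out <- data.frame(chrom = stats$chrom, start = stats$start, end = stats$end,
                    fst_obs = stats$fst, p_high = p_high, p_low = p_low,
                    q_high = q_high, q_low = q_low, class = cls)
  class(out) <- c("outlier_calls", "data.frame")
  out
}

#' Contrast a statistic across window classes
#'
#' Summaries (mean and SD) of one window statistic per outlier class, plus
#' two-sided Mann-Whitney (Wilcoxon rank-sum) P-values for high-vs-background
#' and low-vs-background contrasts (exact for small untied samples, normal
#' approximation with tie correction otherwise, as [stats::wilcox.test]
#' provides).
#'
#' @param stats a `window_stats` data.frame.
#' @param calls matching `outlier_calls` (same window order).
#' @param statistic column name of the statistic to contrast.
#' @return data.frame with one row per class (high, low, background): n, mean,
#'   sd, and the rank-test P-value against background (`NA` for background
#'   itself or classes with fewer than two windows).
#' @export
compare_regions <- function(stats, calls, statistic) {
  stopifnot(statistic %in% names(stats), nrow(stats) == nrow(calls))
  x <- stats[[statistic]]
  cls <- calls$class
  out <- do.call(rbind, lapply(c("high", "low", "background"), function(cl) {
    v <- x[cls == cl & !is.na(x)]
    data.frame(statistic = statistic, class = cl, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               p_vs_background = NA_real_)
  }))
  bg <- x[cls == "background" & !is.na(x)]
  for (cl in c("high", "low")) {
    v <- x[cls == cl & !is.na(x)]
    if (length(v) >= 2 && length(bg) >= 2) {
      p <- suppressWarnings(wilcox.test(v, bg, exact = NULL)$p.value)
      if (is.nan(p)) p <- 1   # complete ties: no evidence of a difference
      out$p_vs_background[out$class == cl] <- p
    }
  }
  out
}
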