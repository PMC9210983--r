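#' Build a joint 2D site frequency spectrum from genotypes
#'
#' Counts sites by derived-allele copies in the two focal populations. Sites
#' with missing genotypes are projected down to a fixed number of observed
#' copies per population by hypergeometric projection (expected, possibly
#' fractional, contributions), or dropped. The monomorphic corners are masked
#' from likelihood use.
#'
#' @param g a [genotype_matrix] (polarized sites are used when `polarized`).
#' @param project target allele-copy counts `c(k1, k2)`; defaults to the full
#'   sample sizes. Sites observed at fewer copies than the target are dropped.
#' @param on_missing `"project"` (default) or `"drop"`.
#' @param polarized build the derived-allele spectrum (default); `FALSE` folds
#'   each cell onto its minor-allele image.
#' @return An object of class `sfs2d` with `counts`, logical `mask` (`TRUE` =
#'   excluded from likelihoods), target copy numbers and the polarization flag.
#' @export
sfs_from_genotypes <- function(g, project = NULL,
                               on_missing = c("project", "drop"),
                               polarized = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  on_missing <- match.arg(on_missing)
  if (!length(g$pos)) stop("empty genotype matrix")
  k1 <- if (is.null(project)) 2L * sum(g$pop == "pop1") else as.integer(project[1])
  k2 <- if (is.null(project)) 2L * sum(g$pop == "pop2") else as.integer(project[2])
  s1 <- .pop_sites(g, "pop1", NULL)
  s2 <- .pop_sites(g, "pop2", NULL)
  use <- if (polarized) g$polarized else rep(TRUE, length(g$pos))

  counts <- matrix(0, k1 + 1, k2 + 1)
  for (s in which(use)) {
    m1 <- s1$n[s]; d1 <- s1$d[s]
    m2 <- s2$n[s]; d2 <- s2$d[s]
    if (m1 == k1 && m2 == k2) {
      counts[d1 + 1, d2 + 1] <- counts[d1 + 1, d2 + 1] + 1
    } else if (on_missing == "project" && m1 >= k1 && m2 >= k2) {
      w1 <- dhyper(0:k1, d1, m1 - d1, k1)
      w2 <- dhyper(0:k2, d2, m2 - d2, k2)
      counts <- counts + outer(w1, w2)
    }
    # sites observed at fewer copies than the projection target are dropped
  }
  if (!polarized) counts <- .fold_sfs(counts, k1, k2)
  .new_sfs2d(counts, k1, k2, polarized)
}

# fold a joint spectrum onto its minor-allele image: cell (i, j) is combined
# with (k1-i, k2-j) and the mass kept on the half with the smaller total count
.fold_sfs <- function(counts, k1, k2) {
  rot <- counts[(k1 + 1):1, (k2 + 1):1, drop = FALSE]
  tot <- counts + rot
  ij <- outer(0:k1, rep(1, k2 + 1)) + outer(rep(1, k1 + 1), 0:k2)
  half <- (k1 + k2) / 2
  keep <- ij < half
  center <- ij == half
  out <- matrix(0, k1 + 1, k2 + 1)
  out[keep] <- tot[keep]
  # self-conjugate centre line: each pair must be counted once
  if (any(center)) {
    idx <- which(center, arr.ind = TRUE)
    seen <- matrix(FALSE, k1 + 1, k2 + 1)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      ci <- k1 + 2 - i; cj <- k2 + 2 - j
      if (seen[i, j]) next
      if (i == ci && j == cj) out[i, j] <- counts[i, j]
      else out[i, j] <- tot[i, j]
      seen[ci, cj] <- TRUE
    }
  }
  out
}

.new_sfs2d <- function(counts, k1, k2, polarized, probabilities = FALSE) {
  dimnames(counts) <- list(0:k1, 0:k2)
  mask <- matrix(FALSE, k1 + 1, k2 + 1)
  mask[1, 1] <- TRUE
  mask[k1 + 1, k2 + 1] <- TRUE
  structure(list(counts = counts, mask = mask, k1 = k1, k2 = k2,
                 polarized = polarized, probabilities = probabilities),
            class = "sfs2d")
}

#' @export
print.sfs2d <- function(x, ...) {
  cat("sfs2d: (", x$k1 + 1, "x", x$k2 + 1, ")",
      if (x$probabilities) "probabilities" else "counts",
      "|", if (x$polarized) "polarized" else "folded",
      "| unmasked total:", sum(x$counts[!x$mask]), "\n")
  invisible(x)
}

#' Monte-Carlo expected 2D-SFS under a demographic model
#'
#' Estimates the probability of each unmasked spectrum entry, conditional on
#' segregation, from coalescent simulations under the model. Rather than
#' placing mutations, each replicate genealogy contributes its expected branch
#' length per joint frequency class (the Rao-Blackwellized estimator), which
#' removes all mutational noise from the estimate. Zero cells are floored at
#' `1 / (10 * n_reps)` before renormalization so that observed counts never
#' meet a zero probability.
#'
#' @param model a [demographic_model].
#' @param n1,n2 diploid sample sizes of the two focal populations.
#' @param n_reps number of replicate genealogies.
#' @param seed optional integer seed (reuse the same seed across parameter
#'   evaluations for common-random-numbers fitting).
#' @return An `sfs2d` of probabilities summing to 1 over unmasked cells.
#' @export
expected_sfs <- function(model, n1, n2, n_reps = 2000, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  dem <- .compile_demography(model)
  res <- cpp_simulate(as.integer(c(2 * n1, 2 * n2, 0)), 1, 0, 0, dem$times,
                      dem$nu, dem$beta, dem$mig, dem$merges,
                      as.integer(n_reps), 2L)
  out <- .new_sfs2d(res$sfs, 2L * n1, 2L * n2, polarized = TRUE,
                    probabilities = TRUE)
  un <- !out$mask
  S <- res$sfs
  tot <- res$tot_sum
  if (tot <= 0) stop("no segregating branch length simulated; increase n_reps")
  # second-order bias correction of log(S_cell / S_total): the log of a
  # Monte-Carlo mean is biased by -Var/(2*mean^2); correcting per cell keeps
  # composite likelihoods comparable across parameter values
  v_cell <- pmax(res$sfs_sq - S^2 / n_reps, 0)
  v_tot <- max(res$tot_sumsq - tot^2 / n_reps, 0)
  corr <- matrix(0, nrow(S), ncol(S))
  pos <- S > 0
  corr[pos] <- pmin(v_cell[pos] / (2 * S[pos]^2), 1) - v_tot / (2 * tot^2)
  p <- S / tot * exp(corr)
  p[un & p == 0] <- 1 / (10 * n_reps)
  p[un] <- p[un] / sum(p[un])
  p[!un] <- 0
  out$counts <- p
  out
}

#' Simulate an observed joint 2D-SFS under a demographic model
#'
#' Tallies derived-allele counts over the segregating sites of `n_reps`
#' simulated windows: the count-scale counterpart of [expected_sfs], used to
#' generate observed spectra for parameter-recovery experiments.
#'
#' @inheritParams expected_sfs
#' @param rho population-scaled recombination rate per bp within windows.
#' @return An `sfs2d` of counts.
#' @export
simulate_sfs <- function(model, n1, n2, n_reps = 100, L = 10000, rho = 0,
                         seed = NULL) {
  stopifnot(inherits(model, "demographic_model"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- .cpp_sim(model, n1, n2, n_out = 0, L = L, rho = rho,
                  n_reps = n_reps, mode = 1)
  .new_sfs2d(res$sfs, 2L * n1, 2L * n2, polarized = TRUE)
}

#' Composite log-likelihood of an observed SFS
#'
#' `sum(m_ij * ln p_ij)` over unmasked entries: the multinomial composite
#' likelihood of SFS counts against model probabilities.
#'
#' @param obs `sfs2d` of counts.
#' @param expected `sfs2d` of probabilities (see [expected_sfs]).
#' @return The composite log-likelihood (natural log).
#' @export
composite_loglik <- function(obs, expected) {
  stopifnot(inherits(obs, "sfs2d"), inherits(expected, "sfs2d"))
  if (!all(dim(obs$counts) == dim(expected$counts)))
    stop("observed and expected spectra have different shapes")
  if (!identical(obs$mask, expected$mask))
    stop("observed and expected spectra have different masks")
  un <- !obs$mask
  m <- obs$counts[un]
  p <- expected$counts[un]
  if (any(m > 0 & p <= 0)) stop("observed mass on zero-probability cell")
  sum(ifelse(m > 0, m * log(p), 0))
}

#' Akaike information criterion
#'
#' @param loglik maximized log-likelihood (natural log).
#' @param k number of free parameters.
#' @return `2k - 2*loglik`.
#' @export
aic <- function(loglik, k) {
  stopifnot(k >= 0)
  2 * k - 2 * loglik
}

#' Akaike weights
#'
#' Normalized relative model support `exp(-delta/2) / sum(exp(-delta/2))`,
#' computed stably by subtracting the minimum AIC first. Invariant to adding a
#' constant to all AICs, so AIC differences (deltas) may be supplied directly.
#'
#' @param aics numeric vector of AIC values (or deltas).
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (!length(aics)) stop("at least one model required")
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Members of the isolation-with-migration model family
#'
#' Returns a fit specification for one class of the IM family: free parameters
#' with bounds, fixed parameters, and a builder mapping a parameter vector to a
#' [demographic_model]. The ancestral size is a fixed parameter: with a
#' segregation-conditioned composite SFS likelihood the absolute scale is not
#' identifiable, so `N_anc` anchors the scale (typically set from genome-wide
#' Watterson theta) and sizes/times are estimated relative to that anchor.
#'
#' @param class one of `"no_migration"`, `"asym_migration"`,
#'   `"asym_migration_growth"`, `"bottleneck_pop1"`, `"bottleneck_pop2"`.
#' @param N_anc fixed ancestral effective size (individuals).
#' @param mu per-site per-generation mutation rate.
#' @param gen_years years per generation.
#' @param size_bounds,time_bounds,mig_bounds,growth_bounds free-parameter
#'   bounds (sizes in individuals, times in generations, migration as forward
#'   per-generation probability, growth per generation).
#' @param fix named list of parameters to hold fixed at the given values
#'   (removed from the free set; a spec with every parameter fixed evaluates
#'   the likelihood at that point without searching).
#' @return An object of class `im_model_spec`.
#' @export
im_model_spec <- function(class = c("no_migration", "asym_migration",
                                    "asym_migration_growth",
                                    "bottleneck_pop1", "bottleneck_pop2"),
                          N_anc, mu = 3.75e-8, gen_years = 15,
                          size_bounds = c(N_anc / 20, N_anc * 5),
                          time_bounds = c(N_anc / 100, N_anc * 4),
                          mig_bounds = c(0, 1e-5),
                          growth_bounds = c(0, 1e-4), fix = list()) {
  class <- match.arg(class)
  free <- list(N1 = size_bounds, N2 = size_bounds, T_div = time_bounds)
  logs <- c(N1 = TRUE, N2 = TRUE, T_div = TRUE)
  if (class %in% c("asym_migration", "asym_migration_growth")) {
    # migration stays on the linear scale so the no-migration boundary is a
    # reachable point of the class
    free$m12 <- mig_bounds; free$m21 <- mig_bounds
    logs <- c(logs, m12 = FALSE, m21 = FALSE)
  }
  if (class == "asym_migration_growth") {
    free$growth1 <- growth_bounds; free$growth2 <- growth_bounds
    logs <- c(logs, growth1 = FALSE, growth2 = FALSE)
  }
  if (class %in% c("bottleneck_pop1", "bottleneck_pop2")) {
    free$N_b <- c(N_anc / 200, N_anc)
    logs <- c(logs, N_b = TRUE)
  }
  model_id <- match(class, c("no_migration", "asym_migration",
                             "asym_migration_growth", "bottleneck_pop1",
                             "bottleneck_pop2"))
  if (length(fix)) {
    unknown <- setdiff(names(fix), names(free))
    if (length(unknown)) stop("cannot fix unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    free <- free[setdiff(names(free), names(fix))]
    logs <- logs[setdiff(names(logs), names(fix))]
  }
  build <- function(par) {
    par <- utils::modifyList(as.list(fix), as.list(par))
    args <- list(model_id = model_id, N_anc = N_anc, mu = mu,
                 gen_years = gen_years, N1 = par[["N1"]], N2 = par[["N2"]],
                 T_div = par[["T_div"]])
    if (!is.null(par[["m12"]])) { args$m12 <- par[["m12"]]; args$m21 <- par[["m21"]] }
    if (!is.null(par[["growth1"]])) {
      args$growth1 <- par[["growth1"]]; args$growth2 <- par[["growth2"]]
    }
    if (!is.null(par[["N_b"]])) {
      # the bottleneck occupies the central half of the divergence interval
      bn <- c(par[["N_b"]], 0.25 * par[["T_div"]], 0.75 * par[["T_div"]])
      if (class == "bottleneck_pop1") args$bottleneck1 <- bn else args$bottleneck2 <- bn
    }
    do.call(demographic_model, args)
  }
  structure(list(class = class, model_id = model_id, N_anc = N_anc, mu = mu,
                 gen_years = gen_years, free = free, logs = logs, fix = fix,
                 build = build),
            class = "im_model_spec")
}

#' Fit a demographic model to an observed 2D-SFS
#'
#' Multi-start conditional (coordinate-cycling) maximization of the composite
#' likelihood. Each run starts from log-uniform draws within the bounds and
#' cycles bounded one-dimensional Brent searches over the free parameters; the
#' Monte-Carlo expected spectrum reuses one seed across all evaluations
#' (common random numbers) so the objective is a deterministic surface within
#' a fit.
#'
#' @param obs observed `sfs2d` counts.
#' @param spec an [im_model_spec].
#' @param n_runs independent optimization starts.
#' @param cycles conditional maximization rounds per run.
#' @param n_reps replicate genealogies per likelihood evaluation.
#' @param seed integer seed controlling starts and the common-random-number
#'   stream.
#' @param tol stop a run when a full cycle improves the log-likelihood by less
#'   than this.
#' @param init optional named parameter vector used as the first run's start
#'   (warm start); remaining runs start from random draws.
#' @return An object of class `model_fit`: best model, parameter vector,
#'   log-likelihood, `k`, AIC, convergence flag, and fitting metadata.
#' @export
fit_model <- function(obs, spec, n_runs = 50, cycles = 40, n_reps = 2000,
                      seed = NULL, tol = 0.01, init = NULL) {
  stopifnot(inherits(obs, "sfs2d"), inherits(spec, "im_model_spec"))
  if (obs$k1 %% 2 || obs$k2 %% 2) stop("allele-copy counts must be even (diploids)")
  n1 <- obs$k1 / 2
  n2 <- obs$k2 / 2
  if (is.null(seed)) seed <- 1L
  set.seed(seed)
  crn_seed <- sample.int(.Machine$integer.max, 1)
  pn <- names(spec$free)
  k <- length(pn)
  lo <- vapply(spec$free, `[`, 0, 1)
  hi <- vapply(spec$free, `[`, 0, 2)
  logs <- spec$logs[pn]
  to_x <- function(p) ifelse(logs, log(p), p)
  from_x <- function(x) ifelse(logs, exp(x), x)
  starts <- matrix(runif(n_runs * k), n_runs, k)
  xlo <- to_x(lo); xhi <- to_x(hi)
  if (!is.null(init) && k > 0) {
    iv <- unlist(init)[pn]
    iv[is.na(iv)] <- lo[is.na(iv)]   # parameters absent from init start low
    xi <- to_x(pmin(pmax(iv, lo), hi))
    starts[1, ] <- (xi - xlo) / (xhi - xlo)
  }

  eval_ll <- function(x) {
    par <- as.list(setNames(from_x(x), pn))
    model <- spec$build(par)
    exp_sfs <- expected_sfs(model, n1, n2, n_reps = n_reps, seed = crn_seed)
    composite_loglik(obs, exp_sfs)
  }

  if (k == 0) {
    ll <- eval_ll(numeric(0))
    par <- numeric(0)
    best <- list(x = par, ll = ll)
    converged <- TRUE
  } else {
    best <- NULL
    converged <- FALSE
    # joint size/time parameters form a weakly identified scaling ridge when
    # N_anc is fixed; a per-cycle line search along that ray (scaling them
    # together) lets the conditional cycles traverse it
    ray <- which(logs & pn %in% c("N1", "N2", "T_div", "N_b"))
    for (r in seq_len(n_runs)) {
      x <- xlo + starts[r, ] * (xhi - xlo)
      ll0 <- eval_ll(x)
      ll <- ll0
      for (cy in seq_len(cycles)) {
        ll_before <- ll
        for (j in seq_len(k)) {
          f1 <- function(v) { xx <- x; xx[j] <- v; -eval_ll(xx) }
          op <- optimize(f1, interval = c(xlo[j], xhi[j]),
                         tol = max(1e-4, (xhi[j] - xlo[j]) * 1e-3))
          if (-op$objective > ll) { x[j] <- op$minimum; ll <- -op$objective }
          # Brent never samples the interval endpoints; boundary optima
          # (e.g. migration exactly zero) must be checked explicitly
          for (v in c(xlo[j], xhi[j])) {
            lv <- -f1(v)
            if (lv > ll) { x[j] <- v; ll <- lv }
          }
        }
        if (length(ray) >= 2) {
          fr <- function(s) { xx <- x; xx[ray] <- xx[ray] + s; -eval_ll(xx) }
          smin <- max(xlo[ray] - x[ray])
          smax <- min(xhi[ray] - x[ray])
          if (smax > smin) {
            op <- optimize(fr, interval = c(smin, smax),
                           tol = max(1e-4, (smax - smin) * 1e-3))
            if (-op$objective > ll) {
              x[ray] <- x[ray] + op$minimum
              ll <- -op$objective
            }
          }
        }
        if (ll - ll_before < tol) break
      }
      if (ll > ll0 + 1e-9) converged <- TRUE
      if (is.null(best) || ll > best$ll) best <- list(x = x, ll = ll)
    }
  }

  par <- setNames(from_x(best$x), pn)
  structure(list(model = spec$build(as.list(par)), par = par,
                 loglik = best$ll, k = k, aic = aic(best$ll, k),
                 n_runs = n_runs, cycles = cycles, n_reps = n_reps,
                 seed = seed, crn_seed = crn_seed, converged = converged,
                 spec = spec, obs = obs, n1 = n1, n2 = n2),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit:", x$spec$class, "| loglik =", format(x$loglik),
      "| AIC =", format(x$aic), if (!x$converged) "(non-convergence flagged)",
      "\n")
  if (length(x$par)) print(x$par)
  invisible(x)
}

#' Fit a set of nested model classes with warm-started convergence
#'
#' Fits each specification in turn, warm-starting every fit from the best
#' previous fit's shared parameters, then makes one backward pass refitting
#' earlier (nested) classes from the later best points. With the common
#' random-number likelihood surface this drives nested classes to the same
#' region of parameter space, so AIC differences reflect the extra parameters
#' rather than unequal optimizer convergence.
#'
#' @param obs observed `sfs2d` counts.
#' @param specs list of [im_model_spec] objects (typically from simplest to
#'   richest).
#' @param ... passed to [fit_model] (`n_runs`, `cycles`, `n_reps`, `tol`).
#' @param seed integer seed shared by all fits (common random numbers).
#' @param refine_reps when non-`NULL`, every model's maximized log-likelihood
#'   is re-estimated at this (larger) number of replicate genealogies with one
#'   shared seed; each spec is evaluated both at its own optimum and at every
#'   other fit's optimum projected into its parameter space (a feasible point,
#'   so a valid profile lower bound), keeping the best. This removes the
#'   low-precision surface tilt from the AIC comparison.
#' @return list with `fits` (one `model_fit` per spec) and `comparison` (the
#'   [compare_model_fits] table).
#' @export
fit_nested_models <- function(obs, specs, ..., seed = NULL,
                              refine_reps = 50000) {
  if (inherits(specs, "im_model_spec")) specs <- list(specs)
  fits <- vector("list", length(specs))
  best_par <- NULL
  for (i in seq_along(specs)) {
    fits[[i]] <- fit_model(obs, specs[[i]], ..., seed = seed, init = best_par)
    if (is.null(best_par) || fits[[i]]$loglik > -Inf) best_par <- fits[[i]]$par
  }
  if (length(specs) > 1) {
    # backward pass: let classes that lag far behind the best fit catch up
    # from the richer optimum (skipped when already aligned)
    lls <- vapply(fits, `[[`, 0, "loglik")
    best_all <- fits[[which.max(lls)]]$par
    for (i in seq_along(specs)) {
      if (lls[i] >= max(lls) - 1) next
      refit <- fit_model(obs, specs[[i]], ..., seed = seed, init = best_all)
      if (refit$loglik > fits[[i]]$loglik) fits[[i]] <- refit
    }
  }
  if (!is.null(refine_reps)) {
    if (is.null(seed)) seed <- 1L
    n1 <- obs$k1 / 2
    n2 <- obs$k2 / 2
    ref_seed <- seed + 997L
    for (i in seq_along(specs)) {
      spec <- specs[[i]]
      pn <- names(spec$free)
      cand <- unique(lapply(fits, function(f) {
        v <- f$par[intersect(names(f$par), pn)]
        full <- vapply(spec$free, `[`, 0, 1)      # absent parameters at lo
        full[names(v)] <- v
        full
      }))
      ll <- vapply(cand, function(p) {
        composite_loglik(obs, expected_sfs(spec$build(as.list(p)), n1, n2,
                                           n_reps = refine_reps,
                                           seed = ref_seed))
      }, 0)
      j <- which.max(ll)
      fits[[i]]$par <- cand[[j]]
      fits[[i]]$model <- spec$build(as.list(cand[[j]]))
      fits[[i]]$loglik <- ll[j]
      fits[[i]]$aic <- aic(ll[j], fits[[i]]$k)
    }
  }
  list(fits = fits, comparison = compare_model_fits(fits))
}

#' Compare fitted models by AIC and Akaike weight
#'
#' @param fits list of `model_fit` objects.
#' @return data.frame with log-likelihood, AIC, delta (AIC minus the minimum)
#'   and Akaike weight per model.
#' @export
compare_model_fits <- function(fits) {
  ll <- vapply(fits, `[[`, 0, "loglik")
  kk <- vapply(fits, `[[`, 0, "k")
  aics <- vapply(fits, `[[`, 0, "aic")
  data.frame(
    model = vapply(fits, function(f) f$spec$class, ""),
    loglik = ll, k = kk, aic = aics, delta = aics - min(aics),
    weight = akaike_weights(aics))
}

#' Parametric bootstrap confidence intervals for a fitted model
#'
#' Simulates bootstrap SFS data sets from the fitted model (multinomial draws
#' of the observed number of segregating sites from a high-precision expected
#' spectrum), refits each, and reports 2.5/97.5 percentile intervals of the
#' refitted parameters. Bootstrap replicates whose refit fails to improve on
#' its starts are excluded and counted.
#'
#' @param fit a `model_fit`.
#' @param n_boot number of bootstrap data sets.
#' @param runs_per_boot optimization starts per refit.
#' @param cycles conditional rounds per refit.
#' @param n_reps simulated windows per likelihood evaluation during refits.
#' @param seed integer seed.
#' @return data.frame of per-parameter point estimate, lower and upper bounds,
#'   with the number of excluded replicates as attribute `n_failed`.
#' @export
parametric_bootstrap <- function(fit, n_boot = 100, runs_per_boot = 50,
                                 cycles = 40, n_reps = NULL, seed = NULL) {
  stopifnot(inherits(fit, "model_fit"), n_boot >= 1)
  if (!fit$converged) stop("best fit did not converge; bootstrap not meaningful")
  if (is.null(n_reps)) n_reps <- fit$n_reps
  if (is.null(seed)) seed <- fit$seed + 1L
  set.seed(seed)
  gen_seed <- sample.int(.Machine$integer.max, 1)
  p_gen <- expected_sfs(fit$model, fit$n1, fit$n2,
                        n_reps = max(2 * fit$n_reps, 2000), seed = gen_seed)
  un <- !p_gen$mask
  n_sites <- round(sum(fit$obs$counts[un]))
  cell_p <- p_gen$counts[un]
  boot_seeds <- sample.int(.Machine$integer.max, n_boot)
  est <- matrix(NA_real_, n_boot, length(fit$par),
                dimnames = list(NULL, names(fit$par)))
  n_failed <- 0
  for (b in seq_len(n_boot)) {
    set.seed(boot_seeds[b])
    draw <- as.vector(stats::rmultinom(1, n_sites, cell_p))
    boot_obs <- fit$obs
    boot_obs$counts[un] <- draw
    refit <- fit_model(boot_obs, fit$spec, n_runs = runs_per_boot,
                       cycles = cycles, n_reps = n_reps,
                       seed = boot_seeds[b])
    if (!refit$converged && length(fit$par)) { n_failed <- n_failed + 1; next }
    est[b, ] <- refit$par
  }
  ok <- stats::complete.cases(est)
  ci <- apply(est[ok, , drop = FALSE], 2, quantile, probs = c(0.025, 0.5, 0.975))
  out <- data.frame(parameter = names(fit$par), estimate = unname(fit$par),
                    lower = ci[1, ], median_refit = ci[2, ], upper = ci[3, ],
                    row.names = NULL)
  attr(out, "n_failed") <- n_failed
  out
}

#' Convert generations to years
#' @param generations time in generations.
#' @param gen_years years per generation.
#' @return Time in years.
#' @export
generations_to_years <- function(generations, gen_years = 15) {
  stopifnot(gen_years > 0)
  generations * gen_years
}

#' Convert years to millions of years (two decimals)
#' @param years time in years.
#' @return Time in Ma, rounded to two decimals.
#' @export
years_to_ma <- function(years) round(years / 1e6, 2)

#' Scale fitted parameters to natural units
#'
#' Converts parameter estimates to individuals and years. Estimates expressed
#' in units of a reference size `N_ref` (sizes as multiples of `N_ref`, times
#' in units of `N_ref` generations) are multiplied out; time parameters
#' (names starting with `T`) additionally gain years and Ma columns using the
#' generation time.
#'
#' @param fit a `model_fit`, or a named numeric vector of parameters.
#' @param mu per-site per-generation mutation rate (recorded for reference).
#' @param gen_years years per generation.
#' @param N_ref reference size the estimates are scaled by (1 = already in
#'   natural units).
#' @return data.frame with scaled values; time rows carry `years` and `ma`.
#' @export
scale_parameters <- function(fit, mu = 3.75e-8, gen_years = 15, N_ref = 1) {
  par <- if (inherits(fit, "model_fit")) fit$par else fit
  stopifnot(mu > 0, gen_years > 0, N_ref > 0)
  nm <- names(par)
  scaled <- unname(par) * N_ref
  is_time <- startsWith(nm, "T")
  is_rate <- startsWith(nm, "m") | startsWith(nm, "growth")
  scaled[is_rate] <- unname(par)[is_rate]   # rates are not size-scaled
  years <- ifelse(is_time, generations_to_years(scaled, gen_years), NA_real_)
  data.frame(parameter = nm, value = unname(par), natural = scaled,
             years = years, ma = ifelse(is_time, years_to_ma(years), NA_real_))
}
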