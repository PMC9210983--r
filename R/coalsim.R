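#' Specify a two-population isolation-with-migration demographic model
#'
#' Parameters are in natural units: effective sizes in diploid individuals,
#' times in generations, migration as forward-in-time per-generation
#' probabilities (source to sink), growth as forward per-generation exponential
#' rates. Internally the simulator rescales everything to coalescent units of
#' `2 * N_anc` generations.
#'
#' @param model_id integer tag identifying the family member (1-18).
#' @param N_anc,N1,N2 ancestral and current effective sizes (individuals);
#'   `N1` is the first focal population, `N2` the second.
#' @param growth1,growth2 forward per-generation exponential growth rates of
#'   the two focal populations since the split (0 = constant size).
#' @param bottleneck1,bottleneck2 optional numeric `c(N_b, T_start, T_end)`
#'   per population: size `N_b` between `T_start` and `T_end` generations ago;
#'   the interval must lie within `(0, T_div)`.
#' @param m12 forward per-generation probability of migration from population 1
#'   into population 2; `m21` the reverse.
#' @param m21 see `m12`.
#' @param T_div split time in generations.
#' @param mu per-site per-generation mutation rate.
#' @param gen_years years per generation.
#' @param N_out effective size of the outgroup lineage.
#' @param T_out split time of the outgroup in generations (default ten times
#'   `T_div`).
#'
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(model_id = 1L, N_anc, N1, N2, growth1 = 0,
                              growth2 = 0, bottleneck1 = NULL,
                              bottleneck2 = NULL, m12 = 0, m21 = 0, T_div,
                              mu = 3.75e-8, gen_years = 15, N_out = N_anc,
                              T_out = 10 * T_div) {
  stopifnot(N_anc > 0, N1 > 0, N2 > 0, N_out > 0, T_div >= 0, mu > 0,
            gen_years > 0, m12 >= 0, m12 < 1, m21 >= 0, m21 < 1)
  for (b in list(bottleneck1, bottleneck2)) {
    if (!is.null(b)) {
      if (length(b) != 3 || b[1] <= 0) stop("bottleneck must be c(N_b, T_start, T_end)")
      if (b[2] <= 0 || b[3] <= b[2] || b[3] >= T_div)
        stop("bottleneck interval must lie within (0, T_div)")
    }
  }
  if (T_out <= T_div && T_div > 0)
    stop("outgroup split T_out must predate T_div")
  structure(list(model_id = as.integer(model_id), N_anc = N_anc, N1 = N1,
                 N2 = N2, growth1 = growth1, growth2 = growth2,
                 bottleneck1 = bottleneck1, bottleneck2 = bottleneck2,
                 m12 = m12, m21 = m21, T_div = T_div, mu = mu,
                 gen_years = gen_years, N_out = N_out, T_out = T_out),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic_model (id ", x$model_id, ")\n", sep = "")
  cat(sprintf("  N_anc=%g N1=%g N2=%g N_out=%g\n", x$N_anc, x$N1, x$N2, x$N_out))
  cat(sprintf("  T_div=%g gens (%.2f Ma) T_out=%g gens\n", x$T_div,
              x$T_div * x$gen_years / 1e6, x$T_out))
  cat(sprintf("  m12=%g m21=%g growth=(%g, %g)\n", x$m12, x$m21, x$growth1, x$growth2))
  if (!is.null(x$bottleneck1)) cat("  bottleneck pop1:", x$bottleneck1, "\n")
  if (!is.null(x$bottleneck2)) cat("  bottleneck pop2:", x$bottleneck2, "\n")
  invisible(x)
}

#' Calibrated default model for the aspen sister-species system
#'
#' An isolation-with-migration model emulating the divergence of two sister
#' aspen species: split 53,491 generations ago (0.80 Ma at 15 years per
#' generation), mutation rate 3.75e-8, low asymmetric migration, and effective
#' sizes chosen so that per-site diversity (about 0.009) and the predicted
#' window FST (about 0.3) match the scale reported for this system.
#'
#' @return A [demographic_model].
#' @export
default_im_model <- function() {
  demographic_model(model_id = 4L, N_anc = 60000, N1 = 59300, N2 = 63300,
                    m12 = 3.97e-7, m21 = 9.19e-7, T_div = 53491,
                    mu = 3.75e-8, gen_years = 15)
}

# Compile a demographic model to the epoch tables the C++ engine consumes.
# Populations: 0 = pop1, 1 = pop2 (merges into 0 at T_div), 2 = outgroup
# (merges into 0 at T_out). Time unit: 2 * N_anc generations.
.compile_demography <- function(model) {
  Nref <- model$N_anc
  unit <- 2 * Nref
  t_div <- max(model$T_div / unit, 1e-12)
  t_out <- max(model$T_out / unit, t_div * (1 + 1e-9))

  cuts <- c(0, t_div, t_out)
  for (b in list(model$bottleneck1, model$bottleneck2))
    if (!is.null(b)) cuts <- c(cuts, b[2] / unit, b[3] / unit)
  times <- sort(unique(cuts))
  times <- times[c(TRUE, diff(times) > 1e-15)]
  E <- length(times)

  nu <- matrix(1, E, 3)
  beta <- matrix(0, E, 3)
  mig <- array(0, dim = c(3, 3, E))
  beta1 <- unit * model$growth1
  beta2 <- unit * model$growth2
  # backward migration: a lineage sampled in the sink jumps to the source at
  # rate (forward probability) * N_source / N_sink, scaled to 2*N_ref units
  M10 <- unit * model$m12 * model$N1 / model$N2  # lineage in pop2 -> pop1
  M01 <- unit * model$m21 * model$N2 / model$N1  # lineage in pop1 -> pop2

  in_bn <- function(b, t) !is.null(b) && t >= b[2] / unit - 1e-15 &&
    t < b[3] / unit - 1e-15
  for (e in seq_len(E)) {
    t0 <- times[e]
    if (t0 < t_div) {
      if (in_bn(model$bottleneck1, t0)) {
        nu[e, 1] <- model$bottleneck1[1] / Nref
      } else {
        nu[e, 1] <- model$N1 / Nref * exp(-beta1 * t0)
        beta[e, 1] <- beta1
      }
      if (in_bn(model$bottleneck2, t0)) {
        nu[e, 2] <- model$bottleneck2[1] / Nref
      } else {
        nu[e, 2] <- model$N2 / Nref * exp(-beta2 * t0)
        beta[e, 2] <- beta2
      }
      mig[1, 2, e] <- M01
      mig[2, 1, e] <- M10
    }
    nu[e, 3] <- model$N_out / Nref
  }

  merges <- NULL
  e_div <- which(abs(times - t_div) < 1e-15) - 1L   # 0-based epoch index
  e_out <- which(abs(times - t_out) < 1e-15) - 1L
  merges <- rbind(c(e_div, 1L, 0L), c(e_out, 2L, 0L))
  storage.mode(merges) <- "integer"

  list(times = times, nu = nu, beta = beta, mig = as.numeric(mig),
       merges = merges, unit = unit)
}

# One low-level batch call into the C++ engine. rho may be scalar or one value
# per replicate. mode 0 returns haplotypes per replicate, mode 1 accumulates a
# joint 2D SFS over replicates.
.cpp_sim <- function(model, n1, n2, n_out, L, rho, n_reps, mode) {
  dem <- .compile_demography(model)
  theta_bp <- 4 * model$N_anc * model$mu
  res <- cpp_simulate(as.integer(c(2 * n1, 2 * n2, 2 * n_out)), as.numeric(L),
                      as.numeric(rho), theta_bp, dem$times, dem$nu, dem$beta,
                      dem$mig, dem$merges, as.integer(n_reps),
                      as.integer(mode))
  res$unit <- dem$unit
  res
}

# Map continuous mutation coordinates on [0, L) to unique integer positions in
# 1..L; collisions are shifted to the nearest free integer to preserve local
# linkage. Returns the integer positions and the ordering permutation.
.discretize_positions <- function(x, L) {
  p <- as.integer(floor(x)) + 1L
  p[p > L] <- as.integer(L)
  if (length(p) > L) stop("more segregating sites than integer positions")
  if (anyDuplicated(p)) {
    occ <- logical(L)
    for (i in seq_along(p)) {
      if (!occ[p[i]]) { occ[p[i]] <- TRUE; next }
      off <- 1L
      repeat {
        lo <- p[i] - off; hi <- p[i] + off
        if (lo >= 1L && !occ[lo]) { p[i] <- lo; occ[lo] <- TRUE; break }
        if (hi <= L && !occ[hi]) { p[i] <- hi; occ[hi] <- TRUE; break }
        off <- off + 1L
      }
    }
  }
  ord <- order(p)
  list(pos = p[ord], ord = ord)
}

#' Simulate one window under an isolation-with-migration model
#'
#' Runs the structured coalescent with recombination for a window of `L` base
#' pairs and places infinite-sites mutations on the genealogy. Haplotypes are
#' returned for `2*(n1+n2+n_out)` lineages (two per diploid, grouped pop1,
#' pop2, outgroup); the derived allele is coded 1.
#'
#' @param model a [demographic_model].
#' @param n1,n2,n_out diploid sample sizes (outgroup may be 0).
#' @param L window length in base pairs.
#' @param rho population-scaled recombination rate per base pair
#'   (`4 * N_anc * c`).
#' @param seed optional integer seed; a fixed seed gives a bitwise-identical
#'   window.
#'
#' @return An object of class `sim_window` with elements `haplotypes` (binary
#'   matrix, lineages x sites), `positions` (1-based integer coordinates),
#'   `tmrca` (generations), and `truth` (model, rho, sizes, seed).
#' @export
simulate_window <- function(model, n1 = 20, n2 = 19, n_out = 0, L = 10000,
                            rho = 0, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"), n1 >= 1, n2 >= 0, n_out >= 0,
            L >= 1, rho >= 0)
  if (n_out > 0 && model$T_out <= model$T_div)
    stop("outgroup split must predate the focal split")
  if (!is.null(seed)) set.seed(seed)
  res <- .cpp_sim(model, n1, n2, n_out, L, rho, n_reps = 1, mode = 0)
  rep1 <- res$reps[[1]]
  d <- .discretize_positions(rep1$positions, L)
  structure(
    list(haplotypes = rep1$haplotypes[, d$ord, drop = FALSE],
         positions = d$pos, L = as.integer(L), n1 = n1, n2 = n2, n_out = n_out,
         tmrca = rep1$tmrca * res$unit,
         truth = list(model = model, rho = rho, seed = seed)),
    class = "sim_window")
}

#' @export
print.sim_window <- function(x, ...) {
  cat("sim_window:", ncol(x$haplotypes), "segregating sites,",
      nrow(x$haplotypes), "lineages over", x$L, "bp\n")
  invisible(x)
}

.sim_pop_labels <- function(n1, n2, n_out) {
  c(rep("pop1", n1), rep("pop2", n2), rep("outgroup", n_out))
}

#' Convert a simulated window to perfect genotypes
#'
#' Pairs consecutive haplotypes into diploid dosages with no sequencing error
#' or missingness. The haplotypes are kept as an attribute so phased linkage
#' statistics remain available.
#'
#' @param w a `sim_window`.
#' @return A [genotype_matrix] with all sites polarized.
#' @export
as_genotype_matrix <- function(w) {
  stopifnot(inherits(w, "sim_window"))
  n_ind <- (w$n1 + w$n2 + w$n_out)
  hap <- w$haplotypes
  G <- hap[seq(1, 2 * n_ind, 2), , drop = FALSE] +
    hap[seq(2, 2 * n_ind, 2), , drop = FALSE]
  pop <- .sim_pop_labels(w$n1, w$n2, w$n_out)
  ids <- paste0(pop, "_", stats::ave(seq_along(pop), pop, FUN = seq_along))
  g <- genotype_matrix(G, ids, pop, chrom = "sim", pos = w$positions)
  attr(g, "haplotypes") <- hap
  g
}

#' Describe a sequencing read layer
#'
#' @param mean_depth expected reads per site per individual.
#' @param error_rate per-base error probability.
#' @param depth_model `"poisson"` (depth drawn per individual per site) or
#'   `"fixed"` (constant depth, mainly for closed-form checks).
#' @param missing_rule depth below which a genotype is recorded as missing.
#' @return An object of class `read_layer`.
#' @export
read_layer <- function(mean_depth = 20, error_rate = 0.005,
                       depth_model = c("poisson", "fixed"), missing_rule = 5) {
  depth_model <- match.arg(depth_model)
  stopifnot(mean_depth >= 0, error_rate >= 0, error_rate < 1, missing_rule >= 0)
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 depth_model = depth_model, missing_rule = missing_rule),
            class = "read_layer")
}

# genotype log-likelihood with 0*log(0) treated as 0
.geno_ll <- function(k, d, p) {
  t1 <- k * log(p)
  t1[k == 0] <- 0
  t2 <- (d - k) * log1p(-p)
  t2[d - k == 0] <- 0
  t1 + t2
}

#' Pass simulated genotypes through a sequencing read layer
#'
#' Per individual and site, a read depth is drawn, read bases are sampled from
#' the true diploid genotype with per-base error, and the genotype is re-called
#' by maximum likelihood over the three diploid genotypes (uniform prior).
#' Genotypes with depth below `missing_rule` are set missing. Likelihood ties
#' are broken in favour of the heterozygote, then the smaller dosage.
#'
#' @param w a `sim_window`.
#' @param layer a [read_layer].
#' @param seed optional integer seed.
#' @return A [genotype_matrix] of called dosages.
#' @export
apply_read_layer <- function(w, layer = read_layer(), seed = NULL) {
  stopifnot(inherits(w, "sim_window"), inherits(layer, "read_layer"))
  if (!is.null(seed)) set.seed(seed)
  n_ind <- w$n1 + w$n2 + w$n_out
  hap <- w$haplotypes
  S <- ncol(hap)
  G <- hap[seq(1, 2 * n_ind, 2), , drop = FALSE] +
    hap[seq(2, 2 * n_ind, 2), , drop = FALSE]
  n <- length(G)
  d <- if (layer$depth_model == "poisson") rpois(n, layer$mean_depth)
       else rep(round(layer$mean_depth), n)
  eps <- layer$error_rate
  p_true <- c(eps, 0.5, 1 - eps)[as.vector(G) + 1L]
  k <- rbinom(n, d, p_true)

  ll0 <- .geno_ll(k, d, eps)
  ll1 <- .geno_ll(k, d, 0.5)
  ll2 <- .geno_ll(k, d, 1 - eps)
  best <- pmax(ll0, ll1, ll2)
  call <- ifelse(ll1 >= best, 1L, ifelse(ll0 >= best, 0L, 2L))
  call[d < layer$missing_rule] <- NA_integer_
  Gm <- matrix(call, nrow = n_ind, ncol = S)

  pop <- .sim_pop_labels(w$n1, w$n2, w$n_out)
  ids <- paste0(pop, "_", stats::ave(seq_along(pop), pop, FUN = seq_along))
  genotype_matrix(Gm, ids, pop, chrom = "sim", pos = w$positions)
}

#' Simulate a set of independent windows ("synthetic genome")
#'
#' Windows are simulated independently under `model`, each with a
#' recombination rate drawn uniformly from `rho_range`; an optional read layer
#' produces called genotypes with error and missingness. A truth table records
#' the generating parameters per window.
#'
#' @param model a [demographic_model].
#' @param n_windows number of windows.
#' @param window_bp window length in base pairs.
#' @param rho_range length-2 range (per bp) from which each window's
#'   population-scaled recombination rate is drawn.
#' @param layer optional [read_layer]; `NULL` returns perfect genotypes.
#' @param n1,n2,n_out diploid sample sizes.
#' @param seed integer seed; all randomness flows from it.
#' @return A list with `windows` (list of [genotype_matrix]) and `truth`
#'   (data.frame: window, rho, n_seg).
#' @export
simulate_genome <- function(model, n_windows, window_bp = 10000,
                            rho_range = c(0.001, 0.005), layer = NULL,
                            n1 = 20, n2 = 19, n_out = 0, seed = NULL) {
  stopifnot(n_windows >= 1, length(rho_range) == 2)
  if (rho_range[1] > rho_range[2]) stop("rho_range must be increasing")
  if (!is.null(seed)) set.seed(seed)
  rho <- runif(n_windows, rho_range[1], rho_range[2])
  res <- .cpp_sim(model, n1, n2, n_out, window_bp, rho, n_reps = n_windows,
                  mode = 0)
  pop <- .sim_pop_labels(n1, n2, n_out)
  ids <- paste0(pop, "_", stats::ave(seq_along(pop), pop, FUN = seq_along))
  windows <- vector("list", n_windows)
  for (i in seq_len(n_windows)) {
    rep_i <- res$reps[[i]]
    dd <- .discretize_positions(rep_i$positions, window_bp)
    w <- structure(
      list(haplotypes = rep_i$haplotypes[, dd$ord, drop = FALSE],
           positions = dd$pos, L = as.integer(window_bp), n1 = n1, n2 = n2,
           n_out = n_out, tmrca = rep_i$tmrca * res$unit,
           truth = list(model = model, rho = rho[i], seed = seed)),
      class = "sim_window")
    windows[[i]] <- if (is.null(layer)) as_genotype_matrix(w)
                    else apply_read_layer(w, layer)
    windows[[i]]$chrom <- sprintf("sim_w%05d", i)
  }
  truth <- data.frame(window = seq_len(n_windows), rho = rho,
                      n_seg = res$n_seg)
  list(windows = windows, truth = truth)
}

#' Emulate linked-selection diversity loss in a model
#'
#' Returns a model variant emulating the footprint of selection at linked
#' sites in a window: the chosen population's post-split size is multiplied by
#' `reduction` over an episode that ends `recovery * T_div` generations ago
#' (the population has since recovered to its current size). The
#' crash-and-recovery shape reproduces the full hitchhiking signature - loss
#' of diversity, star-like genealogies (negative Tajima's D), elevated
#' differentiation and fixed differences. With `recovery = 0` the reduction
#' instead applies to the whole post-split period (a constant-size variant
#' that lowers diversity and raises FST but leaves Tajima's D near its
#' equilibrium value).
#'
#' @param model a [demographic_model].
#' @param reduction size multiplier in `(0, 1]`; 1 returns the model
#'   unchanged.
#' @param pop `"pop1"`, `"pop2"` or `"both"`.
#' @param recovery fraction of `T_div` elapsed since the swept population
#'   recovered (0 = no recovery, constant reduced size).
#' @param episode_end fraction of `T_div`, looking backwards, at which the
#'   reduced-size episode ends (ignored when `recovery = 0`).
#' @return A [demographic_model].
#' @export
sweep_emulation <- function(model, reduction, pop = c("pop1", "pop2", "both"),
                            recovery = 0.05, episode_end = 0.6) {
  pop <- match.arg(pop)
  if (!is.numeric(reduction) || reduction <= 0 || reduction > 1)
    stop("reduction must lie in (0, 1]")
  if (reduction == 1) return(model)
  if (recovery <= 0) {
    if (pop %in% c("pop1", "both")) model$N1 <- model$N1 * reduction
    if (pop %in% c("pop2", "both")) model$N2 <- model$N2 * reduction
    return(model)
  }
  if (recovery >= episode_end || episode_end >= 1)
    stop("need 0 < recovery < episode_end < 1")
  if (pop %in% c("pop1", "both"))
    model$bottleneck1 <- c(model$N1 * reduction, recovery * model$T_div,
                           episode_end * model$T_div)
  if (pop %in% c("pop2", "both"))
    model$bottleneck2 <- c(model$N2 * reduction, recovery * model$T_div,
                           episode_end * model$T_div)
  model
}
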