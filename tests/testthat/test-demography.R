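# 2D-SFS construction, composite likelihood, AIC machinery, unit scaling,
# and the fitting scaffolding (heavier recovery experiments live in the
# acceptance suite).

test_that("SFS tallies genotypes into the correct cells", {
  # 2 diploids per population: a site fixed derived in pop1 and absent in
  # pop2 lands at (2n1, 0)
  g <- as_gm(matrix(2L, 2, 1), matrix(0L, 2, 1))
  s <- sfs_from_genotypes(g)
  expect_equal(s$counts[5, 1], 1)
  expect_equal(sum(s$counts), 1)

  # monomorphic ancestral site increments the masked (0, 0) corner
  g0 <- as_gm(matrix(0L, 2, 2), matrix(0L, 2, 2))
  s0 <- sfs_from_genotypes(g0)
  expect_equal(s0$counts[1, 1], 2)
  expect_true(s0$mask[1, 1])
  expect_true(s0$mask[5, 5])

  # 5-site toy matrix against a hand tally
  m1 <- cbind(c(1L, 0L), c(2L, 2L), c(0L, 0L), c(1L, 1L), c(2L, 1L))
  m2 <- cbind(c(0L, 0L), c(1L, 0L), c(2L, 2L), c(0L, 1L), c(2L, 2L))
  s5 <- sfs_from_genotypes(as_gm(m1, m2))
  expect_equal(s5$counts[2, 1], 1)  # (1,0)
  expect_equal(s5$counts[5, 2], 1)  # (4,1)
  expect_equal(s5$counts[1, 5], 1)  # (0,4)
  expect_equal(s5$counts[3, 2], 1)  # (2,1)
  expect_equal(s5$counts[4, 5], 1)  # (3,4)
  expect_equal(sum(s5$counts), 5)
})

test_that("missing data is dropped at full size or projected down", {
  m1 <- cbind(c(1L, NA), c(1L, 1L))
  m2 <- cbind(c(1L, 0L), c(0L, 0L))
  g <- as_gm(m1, m2)
  # full-size target: the site with a missing genotype is dropped
  s <- sfs_from_genotypes(g)
  expect_equal(sum(s$counts), 1)
  # projecting to 2 copies per population keeps it, with hypergeometric
  # weights for the complete site too
  sp <- sfs_from_genotypes(g, project = c(2, 2))
  expect_equal(sum(sp$counts), 2, tolerance = 1e-12)
  # hand check: site 1 keeps pop1 at (1 of 2) and projects pop2 (1 of 4) to
  # P(0) = P(1) = 1/2; site 2 projects pop1 (2 of 4) to (1/6, 4/6, 1/6) with
  # pop2 fixed ancestral
  expect_equal(sp$counts[2, 1], 0.5 + 4 / 6, tolerance = 1e-12)
  expect_equal(sp$counts[2, 2], 0.5, tolerance = 1e-12)
  expect_equal(sp$counts[1, 1], 1 / 6, tolerance = 1e-12)
  expect_equal(sp$counts[3, 1], 1 / 6, tolerance = 1e-12)
  sd_ <- sfs_from_genotypes(g, on_missing = "drop")
  expect_equal(sum(sd_$counts), 1)
  expect_error(sfs_from_genotypes(as_gm(matrix(integer(0), 2, 0))))
})

test_that("the folded spectrum combines minor-allele images", {
  # 1 diploid per pop (k = 2 each): derived-count cells (2,1) and (0,1) are
  # minor-allele images of each other and must merge on the minor side
  m1 <- cbind(c(2L), c(0L), c(1L))
  m2 <- cbind(c(1L), c(1L), c(1L))
  g <- as_gm(m1, m2, polarized = FALSE)
  f <- sfs_from_genotypes(g, polarized = FALSE)
  expect_equal(sum(f$counts), 3)
  expect_equal(f$counts[1, 2], 2)   # (0,1): own count + folded (2,1)
  expect_equal(f$counts[3, 2], 0)
  # the self-conjugate centre cell (1,1) keeps its own count once
  expect_equal(f$counts[2, 2], 1)
})

test_that("SFS round-trips through the plain-text format", {
  g <- as_gm(rand_dose(3, 8, miss = 0), rand_dose(3, 8, miss = 0))
  s <- sfs_from_genotypes(g)
  path <- tempfile(fileext = ".sfs")
  write_sfs(s, path)
  s2 <- read_sfs(path)
  expect_equal(s2$counts, s$counts, ignore_attr = TRUE)
  expect_equal(s2$mask, s$mask)
  expect_equal(s2$k1, s$k1)
})

test_that("composite log-likelihood matches hand arithmetic and the MLE property", {
  obs <- divscan:::.new_sfs2d(matrix(c(0, 3, 1, 0), 2, 2), 1, 1, TRUE)
  ex <- divscan:::.new_sfs2d(matrix(c(0, 0.75, 0.25, 0), 2, 2), 1, 1, TRUE,
                             probabilities = TRUE)
  expect_equal(composite_loglik(obs, ex), 3 * log(0.75) + log(0.25),
               tolerance = 1e-12)

  # observed proportions maximize the multinomial likelihood: random
  # perturbations never do better
  set.seed(9)
  counts <- matrix(c(0, 40, 25, 0, 10, 3, 7, 9, 6), 3, 3)
  obs3 <- divscan:::.new_sfs2d(counts, 2, 2, TRUE)
  un <- !obs3$mask
  p_hat <- counts / sum(counts[un])
  ex_hat <- divscan:::.new_sfs2d(p_hat, 2, 2, TRUE, probabilities = TRUE)
  ll_hat <- composite_loglik(obs3, ex_hat)
  for (i in 1:20) {
    q <- p_hat
    q[un] <- q[un] * exp(rnorm(sum(un), 0, 0.2))
    q[un] <- q[un] / sum(q[un])
    expect_lte(composite_loglik(obs3, divscan:::.new_sfs2d(q, 2, 2, TRUE,
                                                           TRUE)), ll_hat)
  }

  # all observed mass in masked cells contributes nothing
  masked_only <- divscan:::.new_sfs2d(matrix(c(5, 0, 0, 5), 2, 2), 1, 1, TRUE)
  expect_equal(composite_loglik(masked_only, ex), 0)
})

test_that("AIC and Akaike weights follow their definitions", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-2.249, 1), 2 + 2 * 2.249)
  expect_gt(aic(-10, 3), aic(-10, 2))
  expect_error(aic(0, -1))

  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(sum(akaike_weights(c(3, 9, 1, 7))), 1)
  # invariance to adding a constant
  expect_equal(akaike_weights(c(3, 9, 1, 7)),
               akaike_weights(c(3, 9, 1, 7) + 1e6))
})

test_that("the expected spectrum is exchangeable for a label-only split", {
  m0 <- demographic_model(N_anc = 20000, N1 = 20000, N2 = 20000, T_div = 0,
                          mu = 3.75e-8)
  e <- expected_sfs(m0, n1 = 3, n2 = 3, n_reps = 4000, seed = 11)
  p <- e$counts
  expect_lt(max(abs(p - t(p))), 0.01)
  expect_equal(sum(p[!e$mask]), 1, tolerance = 1e-12)
})

test_that("without migration a deep split concentrates mass on the margins", {
  md <- demographic_model(N_anc = 20000, N1 = 20000, N2 = 20000,
                          T_div = 40 * 20000, mu = 3.75e-8)
  e <- expected_sfs(md, n1 = 3, n2 = 3, n_reps = 2000, seed = 12)
  p <- e$counts
  margin_mass <- sum(p[, 1]) + sum(p[1, ]) + p[7, 7] + p[7, 1] + p[1, 7]
  expect_gt(margin_mass, 0.98)
})

test_that("two-lineage split places every variant as a fixed difference", {
  # one haploid copy per population: every mutation below the species MRCA is
  # carried by exactly one lineage, so the spectrum mass sits at (1,0)/(0,1)
  # in equal parts, and E[S] = theta/2 * (2*t_div + 2) in 2N units
  N <- 20000
  Tdiv <- 60000
  mu <- 2.5e-7
  m <- demographic_model(N_anc = N, N1 = N, N2 = N, T_div = Tdiv, mu = mu)
  dem <- divscan:::.compile_demography(m)
  set.seed(13)
  res <- divscan:::cpp_simulate(c(1L, 1L, 0L), 10000, 0, 4 * N * mu,
                                dem$times, dem$nu, dem$beta, dem$mig,
                                dem$merges, 4000L, 1L)
  sfs <- res$sfs
  expect_equal(sum(sfs) , sfs[2, 1] + sfs[1, 2])
  expect_lt(abs(sfs[2, 1] / sum(sfs) - 0.5), 0.02)
  t_div_scaled <- Tdiv / (2 * N)
  expected_S <- (4 * N * mu * 10000 / 2) * (2 * t_div_scaled + 2)
  expect_lt(abs(mean(res$n_seg) - expected_S) / expected_S, 0.05)
})

test_that("fitting is deterministic and honours fixed parameters", {
  truth <- demographic_model(N_anc = 20000, N1 = 15000, N2 = 25000,
                             T_div = 30000, mu = 3.75e-8)
  obs <- simulate_sfs(truth, 3, 3, n_reps = 300, L = 2000, seed = 14)

  spec <- im_model_spec("no_migration", N_anc = 20000)
  f1 <- fit_model(obs, spec, n_runs = 1, cycles = 1, n_reps = 200, seed = 15)
  f2 <- fit_model(obs, spec, n_runs = 1, cycles = 1, n_reps = 200, seed = 15)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loglik, f2$loglik)

  # zero free parameters: evaluates at the fixed point without searching
  spec0 <- im_model_spec("no_migration", N_anc = 20000,
                         fix = list(N1 = 15000, N2 = 25000, T_div = 30000))
  f0 <- fit_model(obs, spec0, n_runs = 1, cycles = 1, n_reps = 400, seed = 16)
  expect_equal(f0$k, 0)
  expect_equal(f0$aic, -2 * f0$loglik)
  direct <- composite_loglik(obs, expected_sfs(truth, 3, 3, n_reps = 400,
                                               seed = f0$crn_seed))
  expect_equal(f0$loglik, direct)
})

test_that("warm starts seed the first optimization run", {
  truth <- demographic_model(N_anc = 20000, N1 = 15000, N2 = 25000,
                             T_div = 30000, mu = 3.75e-8)
  obs <- simulate_sfs(truth, 3, 3, n_reps = 300, L = 2000, seed = 17)
  spec <- im_model_spec("no_migration", N_anc = 20000)
  f <- fit_model(obs, spec, n_runs = 1, cycles = 0, n_reps = 200, seed = 18,
                 init = c(N1 = 15000, N2 = 25000, T_div = 30000))
  # zero cycles: the fit reports the warm-start point itself
  expect_equal(unname(f$par), c(15000, 25000, 30000), tolerance = 1e-8)
})

test_that("bootstrap intervals bracket the refit median and handle n_boot = 1", {
  truth <- demographic_model(N_anc = 20000, N1 = 15000, N2 = 25000,
                             T_div = 30000, mu = 3.75e-8)
  obs <- simulate_sfs(truth, 3, 3, n_reps = 400, L = 2000, seed = 19)
  spec <- im_model_spec("no_migration", N_anc = 20000,
                        fix = list(N2 = 25000, T_div = 30000))
  fit <- fit_model(obs, spec, n_runs = 1, cycles = 2, n_reps = 300, seed = 20)
  ci <- parametric_bootstrap(fit, n_boot = 4, runs_per_boot = 1, cycles = 1,
                             n_reps = 200, seed = 21)
  expect_true(ci$lower <= ci$median_refit && ci$median_refit <= ci$upper)
  ci1 <- parametric_bootstrap(fit, n_boot = 1, runs_per_boot = 1, cycles = 1,
                              n_reps = 200, seed = 22)
  expect_equal(ci1$lower, ci1$upper)
  expect_equal(ci1$lower, ci1$median_refit)
})

test_that("unit scaling converts generations to years and Ma", {
  expect_equal(generations_to_years(53491, 15), 802365)
  expect_equal(years_to_ma(802365), 0.80)
  sc <- scale_parameters(c(N1 = 1.5, T_div = 2.67455), gen_years = 15,
                         N_ref = 20000)
  expect_equal(sc$natural[sc$parameter == "N1"], 30000)
  expect_equal(sc$years[sc$parameter == "T_div"], 2.67455 * 20000 * 15)
  # identity scaling leaves natural-unit estimates untouched
  sc1 <- scale_parameters(c(N1 = 30000, T_div = 53491))
  expect_equal(sc1$natural, c(30000, 53491))
  expect_equal(sc1$ma[2], 0.80)
})
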