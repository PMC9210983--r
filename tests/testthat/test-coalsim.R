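# Simulator checks against closed-form coalescent expectations and an
# independent small-state-space oracle for the island model.

neutral_model <- function(N = 60000) {
  demographic_model(N_anc = N, N1 = N, N2 = N, T_div = 1e7, mu = 3.75e-8)
}

test_that("a fixed seed reproduces windows and genotypes bitwise", {
  m <- default_im_model()
  w1 <- simulate_window(m, n1 = 4, n2 = 4, n_out = 1, L = 5000, rho = 0.002,
                        seed = 77)
  w2 <- simulate_window(m, n1 = 4, n2 = 4, n_out = 1, L = 5000, rho = 0.002,
                        seed = 77)
  expect_identical(w1$haplotypes, w2$haplotypes)
  expect_identical(w1$positions, w2$positions)

  g1 <- apply_read_layer(w1, read_layer(), seed = 5)
  g2 <- apply_read_layer(w2, read_layer(), seed = 5)
  expect_identical(g1$geno, g2$geno)

  s1 <- simulate_genome(m, 3, n1 = 3, n2 = 3, seed = 123)
  s2 <- simulate_genome(m, 3, n1 = 3, n2 = 3, seed = 123)
  expect_identical(lapply(s1$windows, `[[`, "geno"),
                   lapply(s2$windows, `[[`, "geno"))
  expect_equal(s1$truth$rho, s2$truth$rho)
})

test_that("pairwise TMRCA has mean 2N generations", {
  N <- 60000
  set.seed(101)
  res <- divscan:::.cpp_sim(neutral_model(N), n1 = 1, n2 = 0, n_out = 0,
                            L = 100, rho = 0, n_reps = 5000, mode = 1)
  mean_tmrca <- mean(res$tmrca) * 2 * N
  expect_lt(abs(mean_tmrca - 2 * N) / (2 * N), 0.05)
})

test_that("segregating sites match Watterson's expectation", {
  # theta_window = 10 with n = 10 haploid copies: E[S] = 10 * a_9 = 28.29
  N <- 60000
  L <- 10 / (4 * N * 3.75e-8)
  set.seed(102)
  res <- divscan:::.cpp_sim(neutral_model(N), n1 = 5, n2 = 0, n_out = 0,
                            L = L, rho = 0, n_reps = 5000, mode = 1)
  expected <- 10 * sum(1 / (1:9))
  expect_lt(abs(mean(res$n_seg) - expected) / expected, 0.03)
})

test_that("island-model FST matches the two-lineage structured-coalescent oracle", {
  # symmetric two-island model, no split; oracle = linear solve of the
  # two-lineage state space (S = same deme, D = different demes) for expected
  # coalescence times, in units of 2N generations with per-lineage backward
  # migration rate M
  N <- 10000
  m_rate <- 1 / (4 * N)           # 4Nm = 1
  M <- 2 * N * m_rate             # scaled per-lineage rate
  # t_S = (1 + 2M t_D) / (1 + 2M); t_D = 1/(2M) + t_S
  A <- matrix(c(1 + 2 * M, -2 * M, -1, 1), 2, 2, byrow = TRUE)
  tt <- solve(A, c(1, 1 / (2 * M)))
  fst_expect <- 1 - tt[1] / tt[2]

  mi <- demographic_model(N_anc = N, N1 = N, N2 = N, m12 = m_rate,
                          m21 = m_rate, T_div = 4e9, mu = 2.5e-6, T_out = 8e9)
  set.seed(103)
  res <- divscan:::.cpp_sim(mi, n1 = 8, n2 = 8, n_out = 0, L = 1000, rho = 0,
                            n_reps = 3000, mode = 1)
  k1 <- 16; k2 <- 16
  idx <- expand.grid(i = 0:k1, j = 0:k2)
  cnt <- as.vector(res$sfs)
  piw <- sum(cnt * (idx$i * (k1 - idx$i) / choose(k1, 2) / 2 +
                    idx$j * (k2 - idx$j) / choose(k2, 2) / 2))
  pib <- sum(cnt * (idx$i * (k2 - idx$j) + idx$j * (k1 - idx$i)) / (k1 * k2))
  fst_sim <- 1 - piw / pib
  expect_lt(abs(fst_sim - fst_expect), 0.03)
})

test_that("dxy matches 4*N_anc*mu + 2*mu*T_div under a clean split", {
  m <- demographic_model(N_anc = 50000, N1 = 30000, N2 = 40000, T_div = 60000,
                         mu = 3.75e-8)
  sim <- simulate_genome(m, 600, rho_range = c(0, 0), n1 = 5, n2 = 5,
                         seed = 104)
  dx <- vapply(sim$windows, function(g) dxy(g, span = c(1, 10000)), 0)
  expected <- 4 * 50000 * 3.75e-8 + 2 * 3.75e-8 * 60000
  expect_lt(abs(mean(dx) - expected) / expected, 0.05)
})

test_that("a label-only split shows no differentiation", {
  m0 <- demographic_model(N_anc = 50000, N1 = 50000, N2 = 50000, T_div = 0,
                          mu = 3.75e-8)
  sim <- simulate_genome(m0, 300, rho_range = c(0, 0), n1 = 5, n2 = 5,
                         seed = 105)
  f <- vapply(sim$windows, function(g) wc_fst(g, c(1, 10000)), 0)
  expect_lt(abs(mean(f, na.rm = TRUE)), 0.01)
})

test_that("deep splits drive polymorphism to fixed differences", {
  N <- 50000
  mk <- function(T_mult) {
    demographic_model(N_anc = N, N1 = N, N2 = N, T_div = T_mult * N,
                      mu = 3.75e-8)
  }
  prop_fixed_at <- function(model, seed) {
    sim <- simulate_genome(model, 150, rho_range = c(0, 0), n1 = 1, n2 = 1,
                           seed = seed)
    pf <- t(vapply(sim$windows, function(g) classify_polymorphisms(g, c(1, 10000)),
                   numeric(4)))
    colMeans(pf, na.rm = TRUE)
  }
  deep <- prop_fixed_at(mk(100), 106)
  mid <- prop_fixed_at(mk(20), 107)
  shallow <- prop_fixed_at(mk(2), 108)
  expect_gt(deep[["prop_fixed"]], 0.9)
  expect_lt(deep[["prop_shared"]], 0.01)
  expect_gt(deep[["prop_fixed"]], mid[["prop_fixed"]])
  expect_gt(mid[["prop_fixed"]], shallow[["prop_fixed"]])
})

test_that("window FST increases with divergence time", {
  mk <- function(T_div) demographic_model(N_anc = 50000, N1 = 50000,
                                          N2 = 50000, T_div = T_div,
                                          mu = 3.75e-8)
  f_small <- vapply(simulate_genome(mk(10000), 150, rho_range = c(0, 0),
                                    n1 = 5, n2 = 5, seed = 109)$windows,
                    function(g) wc_fst(g, c(1, 10000)), 0)
  f_large <- vapply(simulate_genome(mk(120000), 150, rho_range = c(0, 0),
                                    n1 = 5, n2 = 5, seed = 110)$windows,
                    function(g) wc_fst(g, c(1, 10000)), 0)
  wt <- wilcox.test(f_large, f_small, alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
})

test_that("recombination produces decaying linkage with distance", {
  m <- neutral_model()
  set.seed(111)
  curves <- NULL
  for (i in 1:30) {
    w <- simulate_window(m, n1 = 8, n2 = 0, L = 10000, rho = 0.005)
    g <- as_genotype_matrix(w)
    d <- ld_decay(g, "pop1", max_dist = 10000, bin = 1000, phased = TRUE)
    curves <- rbind(curves, d$r2)
  }
  mean_curve <- colMeans(curves, na.rm = TRUE)
  mids <- seq(500, 9500, by = 1000)
  expect_lt(cor(mids, mean_curve, method = "spearman"), 0)
})

test_that("degenerate rho range is honoured and bad ranges rejected", {
  m <- default_im_model()
  sim <- simulate_genome(m, 3, rho_range = c(0.002, 0.002), n1 = 2, n2 = 2,
                         seed = 112)
  expect_equal(sim$truth$rho, rep(0.002, 3))
  expect_error(simulate_genome(m, 3, rho_range = c(0.005, 0.001), seed = 1))
})

test_that("sweep emulation shrinks the chosen population", {
  m <- default_im_model()
  expect_identical(sweep_emulation(m, 1, "pop1"), m)
  # constant-size variant
  ms <- sweep_emulation(m, 0.05, "pop1", recovery = 0)
  expect_equal(ms$N1, m$N1 * 0.05)
  expect_equal(ms$N2, m$N2)
  mb <- sweep_emulation(m, 0.1, "both", recovery = 0)
  expect_equal(mb$N2, m$N2 * 0.1)
  # crash-and-recovery default: a bottleneck episode inside (0, T_div)
  mr <- sweep_emulation(m, 0.05, "pop1")
  expect_equal(mr$N1, m$N1)
  expect_equal(mr$bottleneck1[1], m$N1 * 0.05)
  expect_true(mr$bottleneck1[2] > 0 && mr$bottleneck1[3] < m$T_div)
  expect_error(sweep_emulation(m, 0))
  expect_error(sweep_emulation(m, -1))
  expect_error(sweep_emulation(m, 0.5, recovery = 0.9, episode_end = 0.5))
})

test_that("model validation rejects impossible parameter combinations", {
  expect_error(demographic_model(N_anc = 0, N1 = 1, N2 = 1, T_div = 1))
  expect_error(demographic_model(N_anc = 100, N1 = 100, N2 = 100, T_div = 100,
                                 bottleneck1 = c(10, 50, 200)))
  expect_error(demographic_model(N_anc = 100, N1 = 100, N2 = 100, T_div = 100,
                                 m12 = 1.5))
  expect_error(demographic_model(N_anc = 100, N1 = 100, N2 = 100, T_div = 100,
                                 T_out = 50))
})
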