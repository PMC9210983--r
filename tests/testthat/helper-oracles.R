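# Independent brute-force oracles for the per-window statistics. These code
# each estimator from its definition (explicit loops over allele copies and
# sample pairs), deliberately avoiding the vectorized frequency algebra of the
# package implementations.

# expand a dosage vector into the multiset of observed allele copies
copies_at_site <- function(dose) {
  out <- integer(0)
  for (d in dose) {
    if (is.na(d)) next
    out <- c(out, switch(d + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L)))
  }
  out
}

# mean pairwise difference summed over sites (count scale)
oracle_pi_count <- function(m) {
  total <- 0
  for (s in seq_len(ncol(m))) {
    x <- copies_at_site(m[, s])
    n <- length(x)
    if (n < 2) next
    diffs <- 0
    for (i in seq_len(n - 1))
      for (j in (i + 1):n) diffs <- diffs + abs(x[i] - x[j])
    total <- total + diffs / choose(n, 2)
  }
  total
}

oracle_theta_w_count <- function(m) {
  ns <- integer(0)
  S <- 0
  for (s in seq_len(ncol(m))) {
    x <- copies_at_site(m[, s])
    if (length(x) < 2) next
    ns <- c(ns, length(x))
    if (length(unique(x)) > 1) S <- S + 1
  }
  if (!length(ns)) return(NA_real_)
  tab <- table(ns)
  n <- as.integer(names(tab)[which.max(tab)])
  S / sum(1 / seq_len(n - 1))
}

oracle_tajima_d <- function(m) {
  ns <- integer(0)
  S <- 0
  pi_count <- 0
  for (s in seq_len(ncol(m))) {
    x <- copies_at_site(m[, s])
    n <- length(x)
    if (n < 2) next
    ns <- c(ns, n)
    if (length(unique(x)) > 1) {
      S <- S + 1
      diffs <- 0
      for (i in seq_len(n - 1))
        for (j in (i + 1):n) diffs <- diffs + abs(x[i] - x[j])
      pi_count <- pi_count + diffs / choose(n, 2)
    }
  }
  if (S == 0 || !length(ns)) return(NA_real_)
  tab <- table(ns)
  n <- as.integer(names(tab)[which.max(tab)])
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  num <- pi_count - S / a1
  if (v <= 0) return(if (abs(num) < 1e-12) 0 else NA_real_)
  num / sqrt(v)
}

oracle_he <- function(m) {
  vals <- numeric(0)
  for (s in seq_len(ncol(m))) {
    x <- copies_at_site(m[, s])
    if (!length(x)) next
    p <- mean(x)
    vals <- c(vals, 2 * p * (1 - p))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# mean cross-population pairwise difference summed over sites (count scale)
oracle_dxy_count <- function(mA, mB) {
  total <- 0
  any_ok <- FALSE
  for (s in seq_len(ncol(mA))) {
    x <- copies_at_site(mA[, s])
    y <- copies_at_site(mB[, s])
    if (!length(x) || !length(y)) next
    any_ok <- TRUE
    diffs <- 0
    for (a in x) for (b in y) diffs <- diffs + abs(a - b)
    total <- total + diffs / (length(x) * length(y))
  }
  if (!any_ok) return(NA_real_)
  total
}

# Weir-Cockerham theta from literal per-site mean squares on allele copies,
# combined as a ratio of sums
oracle_wc_fst <- function(m1, m2) {
  num <- 0
  den <- 0
  for (s in seq_len(ncol(m1))) {
    x <- copies_at_site(m1[, s])
    y <- copies_at_site(m2[, s])
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) next
    all_c <- c(x, y)
    if (length(unique(all_c)) < 2) next
    gmean <- mean(all_c)
    ssb <- n1 * (mean(x) - gmean)^2 + n2 * (mean(y) - gmean)^2
    ssw <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
    msp <- ssb / 1
    msg <- ssw / (n1 + n2 - 2)
    nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
    a <- (msp - msg) / nc
    num <- num + a
    den <- den + a + msg
  }
  if (den <= 0) return(NA_real_)
  num / den
}

# random dosage matrix with missing entries
rand_dose <- function(n_samples, n_sites, miss = 0.1) {
  m <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)),
              n_samples, n_sites)
  m[runif(length(m)) < miss] <- NA
  m
}

# wrap two dosage matrices as a genotype_matrix with pop1/pop2 labels
as_gm <- function(m1, m2 = NULL, polarized = TRUE) {
  geno <- if (is.null(m2)) m1 else rbind(m1, m2)
  pop <- c(rep("pop1", nrow(m1)), if (!is.null(m2)) rep("pop2", nrow(m2)))
  genotype_matrix(geno, paste0("s", seq_len(nrow(geno))), pop,
                  pos = seq_len(ncol(geno)),
                  polarized = rep(polarized, ncol(geno)))
}

# fabricate a sim_window object from explicit haplotypes (rows = lineages)
fake_window <- function(hap, n1, n2 = 0, n_out = 0, L = ncol(hap)) {
  structure(list(haplotypes = hap, positions = seq_len(ncol(hap)),
                 L = as.integer(L), n1 = n1, n2 = n2, n_out = n_out,
                 tmrca = NA_real_, truth = list(model = NULL, rho = 0,
                                                seed = NULL)),
            class = "sim_window")
}
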