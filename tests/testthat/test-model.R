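test_that("design covariates match their closed forms", {
  s <- tiny_sim(seed = 4, n_cows = 30)
  rec <- s$spectra$records
  rec$dim[1] <- 365L; rec$dim[2] <- 1L
  ds <- spectra_dataset(rec, s$spectra$transmittance, s$spectra$grid)
  des <- build_design(ds, s$geno, ds$grid[1])
  expect_equal(unname(des$X[1, "DIM"]), 1.0)
  expect_equal(unname(des$X[1, "wilmink"]), exp(-0.05))
  expect_equal(unname(des$X[2, "DIM"]), 1 / 365)
  expect_equal(unname(des$X[2, "wilmink"]), exp(-0.05 / 365))
  # conventional per-day Wilmink switch
  desd <- build_design(ds, s$geno, ds$grid[1], wilmink = "per_day")
  expect_equal(unname(desd$X[1, "wilmink"]), exp(-0.05 * 365))
  # dosage columns are mean-centred
  expect_lt(max(abs(colMeans(des$G))), 1e-8)
  expect_error(build_design(ds, s$geno, 9999), "not in dataset grid")
})

test_that("dosage centring subtracts the column mean", {
  g <- genotype_data(matrix(c(0, 1, 2, 1), 4, 1),
                     data.frame(snp_id = "s1", chrom = 1, bp = 100))
  expect_identical(as.numeric(center_dosages(g)), c(-1, 0, 1, 0))
  # missing dosages are mean-imputed before centring
  g2 <- genotype_data(matrix(c(0, 2, NA, 2, 2, 0, NA, 0), 4, 2),
                      data.frame(snp_id = c("s1", "s2"), chrom = 1,
                                 bp = c(100, 200)))
  cc <- center_dosages(g2)
  expect_equal(colMeans(cc), c(s1 = 0, s2 = 0))
  expect_equal(cc[3, 1], 0)  # imputed to the mean, centred to zero
})

test_that("chain bookkeeping: saved draws = floor((iters - burnin)/thin)", {
  s <- tiny_sim(seed = 4, n_cows = 30)
  des <- build_design(s$spectra, s$geno, s$spectra$grid[1])
  for (cfg in list(c(203, 100, 10), c(200, 100, 7), c(55, 5, 1))) {
    fit <- fit_mcmc(des, mcmc_config(cfg[1], cfg[2], cfg[3], seed = 1),
                    store_effects = FALSE)
    expect_identical(nrow(fit$var), as.integer((cfg[1] - cfg[2]) %/% cfg[3]))
  }
  expect_error(mcmc_config(100, 100, 1))
})

test_that("posterior draws respect positivity and h2 bounds", {
  s <- tiny_sim(seed = 14, n_cows = 60)
  des <- build_design(s$spectra, s$geno, s$spectra$grid[2])
  fit <- fit_mcmc(des, mcmc_config(600, 200, 2, seed = 2))
  expect_true(all(fit$var >= 0))
  h <- heritability(fit)
  expect_true(all(h$h2_draws >= 0 & h$h2_draws <= 1))
  expect_identical(length(h$h2_draws), nrow(fit$var))
  # identical seed reproduces the chain exactly
  fit2 <- fit_mcmc(des, mcmc_config(600, 200, 2, seed = 2))
  expect_identical(fit$snp, fit2$snp)
  expect_identical(fit$var, fit2$var)
})

test_that("heritability arithmetic on constructed draws", {
  # single draw, components (1,1,1,1): cow_a values with across-cow
  # variance exactly 1
  v <- matrix(c(1, 1, 1, 1), 1,
              dimnames = list(NULL, c("sigma2_Herd", "sigma2_PE",
                                      "sigma2_E", "sigma2_a")))
  s1 <- fake_samples(snp = matrix(0, 1, 2),
                     cow_a = matrix(c(-1, 0, 1), 1), var = v)
  expect_equal(heritability(s1)$mean, 0.25)
  # zero additive variance in every draw
  s0 <- fake_samples(snp = matrix(0, 3, 2), cow_a = matrix(0, 3, 4),
                     var = v[rep(1, 3), ])
  expect_identical(heritability(s0)$mean, 0)
})

test_that("heritability gate keeps wavenumbers at or above threshold", {
  mk <- function(w, m) structure(list(wavenumber = w, mean = m),
                                 class = "heritability_estimate")
  ests <- list(mk(1000, 0.04), mk(1100, 0.05), mk(1200, 0.20))
  expect_identical(gate_heritable(ests), c(1100, 1200))
  # 17 inputs of which 2 fall below the gate leave 15
  h2s <- c(0.04, 0.03, seq(0.06, 0.34, length.out = 15))
  ests17 <- Map(mk, 1000 + seq_along(h2s), h2s)
  expect_identical(length(gate_heritable(ests17)), 15L)
  expect_identical(gate_heritable(list()), numeric(0))
})

test_that("record order does not change posterior conclusions", {
  s <- tiny_sim(seed = 25, n_cows = 80)
  des <- build_design(s$spectra, s$geno, s$spectra$grid[3])
  perm <- sample(nrow(s$spectra$records))
  ds2 <- spectra_dataset(s$spectra$records[perm, ],
                         s$spectra$transmittance[perm, ], s$spectra$grid)
  des2 <- build_design(ds2, s$geno, s$spectra$grid[3])
  cfg <- mcmc_config(1200, 400, 4, seed = 6)
  f1 <- fit_mcmc(des, cfg, store_effects = FALSE)
  f2 <- fit_mcmc(des2, cfg, store_effects = FALSE)
  # float summation order differs, so equality is statistical, not bitwise
  h1 <- heritability(f1); h2 <- heritability(f2)
  expect_lt(abs(h1$mean - h2$mean),
            3 * sqrt(mcse(h1$h2_draws)^2 + mcse(h2$h2_draws)^2) + 0.02)
  for (j in seq_len(ncol(f1$fixed))) {
    tol <- 3 * sqrt(mcse(f1$fixed[, j])^2 + mcse(f2$fixed[, j])^2) + 0.02
    expect_lt(abs(mean(f1$fixed[, j]) - mean(f2$fixed[, j])), tol)
  }
})

test_that("with additive variance off, fixed effects match a REML oracle", {
  s <- tiny_sim(seed = 33, n_cows = 100)
  des <- build_design(s$spectra, s$geno, s$spectra$grid[1])
  df <- data.frame(y = des$y, herd = factor(des$herd),
                   cow = factor(des$cow), des$X[, -1])
  lme <- lme4::lmer(y ~ DIM + wilmink + parity2 + seasonwinter +
                      (1 | herd) + (1 | cow), data = df, REML = TRUE)
  vcs <- as.data.frame(lme4::VarCorr(lme))
  get_vc <- function(g) vcs$vcov[vcs$grp == g]
  fit <- fit_mcmc(des, mcmc_config(4000, 1000, 3, seed = 3),
                  fix_variances = c(sigma2_Herd = get_vc("herd"),
                                    sigma2_PE = get_vc("cow"),
                                    sigma2_E = get_vc("Residual"),
                                    sigma2_a = 1e-9),
                  store_effects = FALSE)
  bhat <- colMeans(fit$fixed)
  oracle <- lme4::fixef(lme)
  # intercept / DIM / wilmink ride a near-collinear ridge, so compare the
  # identifiable quantities: the contrasts and the fixed-effect predictor
  expect_lt(abs(bhat["parity2"] - oracle["parity2"]), 0.05)
  expect_lt(abs(bhat["seasonwinter"] - oracle["seasonwinter"]), 0.05)
  ord <- c("(Intercept)", "DIM", "wilmink", "parity2", "seasonwinter")
  pred_gibbs <- des$X %*% bhat
  pred_reml <- des$X %*% unname(oracle[ord])
  expect_lt(max(abs(pred_gibbs - pred_reml)), 0.05)
})

test_that("null data keeps posterior heritability below the gate", {
  # response is fixed effects + noise only; a heritable signal must not be
  # invented. Scaled down from the spec's 20 replicates to 10.
  pass <- 0L
  for (r in 1:10) {
    cfg <- sim_config(n_cows = 250, n_herds = 12,
                      records_per_cow_range = c(2, 3),
                      n_chromosomes = 1, snps_per_chromosome = 60,
                      variance_components = c(sigma2_A = 0, sigma2_Herd = 0,
                                              sigma2_PE = 0, sigma2_E = 1),
                      seed = 100 + r)
    g <- simulate_genotypes(cfg)
    ds <- simulate_spectra(cfg, g)$spectra
    des <- build_design(ds, g, ds$grid[1])
    fit <- fit_mcmc(des, mcmc_config(1500, 500, 5, seed = r),
                    store_effects = FALSE)
    if (heritability(fit)$mean < 0.05) pass <- pass + 1L
  }
  expect_gte(pass, 9L)
})

test_that("doubling chain length leaves posterior means stationary", {
  s <- tiny_sim(seed = 44, n_cows = 60)
  des <- build_design(s$spectra, s$geno, s$spectra$grid[2])
  f1 <- fit_mcmc(des, mcmc_config(1500, 500, 2, seed = 5),
                 store_effects = FALSE)
  f2 <- fit_mcmc(des, mcmc_config(3000, 500, 2, seed = 5),
                 store_effects = FALSE)
  h1 <- heritability(f1); h2 <- heritability(f2)
  tol <- 3 * sqrt(mcse(h1$h2_draws)^2 + mcse(h2$h2_draws)^2) + 0.01
  expect_lt(abs(h1$mean - h2$mean), tol)
})

test_that("degenerate designs fail loudly", {
  s <- tiny_sim(seed = 4, n_cows = 30)
  ds <- s$spectra
  ds$transmittance[, 1] <- 5
  des <- build_design(ds, s$geno, ds$grid[1])
  expect_error(fit_mcmc(des, mcmc_config(100, 10, 1, seed = 1)),
               "zero-variance")
  rec <- s$spectra$records
  rec$parity <- 1L
  ds2 <- spectra_dataset(rec, s$spectra$transmittance, s$spectra$grid)
  expect_warning(build_design(ds2, s$geno, ds2$grid[1]), "parity")
})
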