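test_that("conjugate limits: intercept-only model matches closed forms", {
  set.seed(1)
  n <- 400
  ped <- founder_ped(n)
  y <- rnorm(n, 10, 2)
  m <- stage1_model(founder_pheno(y), ped, "my")
  fit <- fit_animal_model(m, gibbs_config(4000, 500, seed = 2,
                                          keep = "(Intercept)",
                                          fixed_sigma_u = 1e-8,
                                          fixed_sigma_e = 4))
  ch <- fit$chain$samples[, "(Intercept)"]
  # flat prior, known variance: posterior = N(ybar, sigma2/n)
  expect_lt(abs(mean(ch) - mean(y)), 3 * mcse_batch(ch))
  expect_lt(abs(sd(ch) - 2 / sqrt(n)), 0.015)
  # with an intercept in the design the residuals average to zero
  expect_lt(abs(mean(fit$residuals)), 3 * mcse_batch(ch))
})

small_design <- function(n = 350, seed = 31) {
  set.seed(seed)
  ped <- random_pedigree(n + 100, seed = seed + 1)
  ids <- ped$id[(nrow(ped) - n + 1):nrow(ped)]
  u <- simulate_breeding_values(ped, c(my = 20), seed = seed + 2)[, "my"]
  ph <- data.frame(
    cow_id = ids,
    my = 8000 + u[match(ids, ped$id)] + rnorm(n, 0, 100),
    fp = 1, dim_life = 1,
    age_bin = sample(c("25", "26", "27"), n, TRUE),
    year_region = sample(c("y1_r1", "y1_r2", "y2_r1"), n, TRUE),
    herd_year = sample(sprintf("h%d", 1:5), n, TRUE),
    dam_id = "0", stringsAsFactors = FALSE)
  list(ped = ped, ph = ph)
}

test_that("posterior means solve the mixed-model equations at fixed variances", {
  d <- small_design()
  ph <- d$ph
  su2 <- 400; se2 <- 10000
  mod <- stage1_model(ph, d$ped, "my")
  keep <- c("(Intercept)", ph$cow_id[c(1, 50)])
  fit <- fit_animal_model(mod, gibbs_config(6000, 1000, seed = 32,
                                            keep = keep,
                                            fixed_sigma_u = su2,
                                            fixed_sigma_e = se2))
  # direct sparse solve of (W'W + alpha A~) theta = W'y
  n <- length(mod$y); q <- length(mod$ped_id)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = mod$zi, x = 1,
                            dims = c(n, q))
  W <- cbind(mod$X, Z)
  alpha <- se2 / su2
  Atil <- Matrix::bdiag(Matrix::Diagonal(ncol(mod$X), 0), mod$ainv)
  C <- Matrix::crossprod(W) + alpha * Atil
  theta <- as.numeric(Matrix::solve(C, Matrix::crossprod(W, mod$y)))
  for (kk in keep) {
    i <- match(kk, names(fit$theta_mean))
    expect_lt(abs(fit$theta_mean[i] - theta[i]),
              4 * mcse_batch(fit$chain$samples[, kk]))
  }
  dev <- fit$theta_mean - theta
  expect_lt(sqrt(mean((as.numeric(W %*% dev))^2)), 0.05 * sd(mod$y))
})

test_that("zero-noise data yields near-zero residuals", {
  set.seed(3)
  ped <- random_pedigree(120, seed = 4)
  u <- simulate_breeding_values(ped, c(my = 5), seed = 5)[, "my"]
  ids <- ped$id[51:120]
  y <- 100 + u[match(ids, ped$id)]
  ph <- founder_pheno(y, ids)
  mod <- stage1_model(ph, ped, "my")
  fit <- fit_animal_model(mod, gibbs_config(3000, 500, seed = 6,
                                            fixed_sigma_u = 25,
                                            fixed_sigma_e = 1e-4))
  expect_lt(max(abs(fit$residuals)), 0.1)
})

test_that("chains are reproducible and row-order exchangeable", {
  d <- small_design(seed = 71)
  ph <- d$ph
  cfgc <- gibbs_config(3000, 600, seed = 7)
  f1 <- fit_animal_model(stage1_model(ph, d$ped, "my"), cfgc)
  f2 <- fit_animal_model(stage1_model(ph, d$ped, "my"), cfgc)
  expect_identical(f1$chain$samples, f2$chain$samples)
  expect_identical(f1$theta_mean, f2$theta_mean)

  set.seed(77)
  perm <- sample(nrow(ph))
  f3 <- fit_animal_model(stage1_model(ph[perm, ], d$ped, "my"),
                         gibbs_config(3000, 600, seed = 8))
  r13 <- f3$residuals[names(f1$residuals)]
  expect_gt(cor(r13, f1$residuals), 0.99)
  expect_lt(mean(abs(r13 - f1$residuals)), 0.05 * sd(ph$my))
})

test_that("heritability is recovered from simulated data", {
  cfg <- sim_config("smoke", cows_per_gen = 1000, n_founder_females = 700,
                    n_founder_males = 30, n_generations = 3)
  cfg$traits$my$sigma_u <- cfg$traits$my$sigma_e * sqrt(0.3 / 0.7)
  herd <- simulate_herd(cfg, seed = 5)
  flt <- apply_filters(herd$cows, herd$lactations, herd$pedigree)
  ph <- derive_traits(flt$cows)
  fit <- fit_animal_model(stage1_model(ph, herd$pedigree, "my"),
                          gibbs_config(3000, 500, seed = 6))
  h2 <- fit$chain$samples[, "sigma2_u"] /
    (fit$chain$samples[, "sigma2_u"] + fit$chain$samples[, "sigma2_e"])
  expect_lt(abs(mean(h2) - 0.3), 0.08)

  # estimated breeding values rank cows far better than chance: the top
  # decile of EBV overlaps the true top decile well above the 10% baseline
  ebv <- fit$ebv[ph$cow_id]
  sets <- genetic_merit_percentiles(ebv)
  u_true <- herd$truth$u[ph$cow_id, "my"]
  true_top <- ph$cow_id[rank(-u_true, ties.method = "first") <=
                          length(sets$top)]
  expect_gt(mean(sets$top %in% true_top), 0.25)
})

test_that("residuals retain planted maternal signal when noise is small", {
  cfg <- sim_config("smoke", cows_per_gen = 800, n_founder_females = 500,
                    n_founder_males = 20, n_sires = 15)
  cfg$traits$my$sigma_e <- 10
  cfg$traits$my$sigma_u <- 2
  cfg <- plant_effects(cfg, "lact")
  herd <- simulate_herd(cfg, seed = 41)
  flt <- apply_filters(herd$cows, herd$lactations, herd$pedigree)
  ph <- derive_traits(flt$cows)
  fit <- fit_animal_model(stage1_model(ph, herd$pedigree, "my"),
                          gibbs_config(1500, 300, seed = 42))
  tr <- herd$truth$circumstance
  m_true <- c(0, cfg$maternal$my$lact)[
    tr$lact_group[match(ph$cow_id, tr$cow_id)] + 1]
  expect_gt(cor(fit$residuals, m_true), 0.9)
})

test_that("genetic-merit percentile sets are exact and tie-stable", {
  ebv <- setNames(rnorm(100), sprintf("c%03d", 1:100))
  s <- genetic_merit_percentiles(ebv)
  expect_length(s$bottom, 10)
  expect_length(s$top, 10)
  expect_true(max(ebv[s$bottom]) <= min(ebv[setdiff(names(ebv), s$bottom)]))

  tied <- setNames(rep(1, 30), sprintf("t%02d", 1:30))
  s2 <- genetic_merit_percentiles(tied)
  expect_length(s2$bottom, 3)
  expect_length(s2$top, 3)
  expect_equal(s2$bottom, sprintf("t%02d", 1:3))

  expect_error(genetic_merit_percentiles(ebv[1:3], lower = 0.1),
               "degenerate")
})
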