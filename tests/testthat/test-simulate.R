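test_that("generated treatments match target prevalences and phi", {
  cfg <- sim_config(
    n_samples = 5000, n_cpgs = 5,
    treatments = data.frame(name = c("a", "b"), prevalence = c(0.5, 0.5)),
    phi_targets = matrix(c(1, 0.6, 0.6, 1), 2), seed = 3
  )
  tx <- generate_treatments(cfg)
  expect_true(all(abs(colMeans(tx) - 0.5) < 0.03))
  ph <- phi_matrix(tx)$phi[1, 2]
  expect_lt(abs(ph - 0.6), 0.05)

  cfg0 <- sim_config(
    n_samples = 5000, n_cpgs = 5,
    treatments = data.frame(name = c("a", "b"), prevalence = c(0.5, 0.5)),
    seed = 3
  )
  tx0 <- generate_treatments(cfg0)
  expect_lt(abs(phi_matrix(tx0)$phi[1, 2]), 0.05)
})

test_that("latent copula conversion agrees with a Riemann-sum orthant oracle", {
  # for several (phi, prevalence) pairs, the latent rho chosen by the
  # generator must reproduce the target joint cell probability
  for (case in list(c(0.6, 0.5, 0.5), c(0.3, 0.3, 0.6), c(-0.2, 0.4, 0.5))) {
    phi <- case[1]
    p1 <- case[2]
    p2 <- case[3]
    rho <- ewasmed:::phi_to_latent_rho(phi, p1, p2)
    p11_target <- phi * sqrt(p1 * (1 - p1) * p2 * (1 - p2)) + p1 * p2
    p11_oracle <- oracle_orthant(qnorm(1 - p1), qnorm(1 - p2), rho)
    expect_lt(abs(p11_oracle - p11_target), 1e-4)
  }
})

test_that("treatment generation is deterministic and rejects impossible targets", {
  cfg <- sim_config(
    n_samples = 200, n_cpgs = 5,
    treatments = data.frame(name = c("a", "b"), prevalence = c(0.5, 0.5)),
    phi_targets = matrix(c(1, 0.4, 0.4, 1), 2), seed = 11
  )
  expect_identical(generate_treatments(cfg), generate_treatments(cfg))

  bad <- sim_config(
    n_samples = 100, n_cpgs = 5,
    treatments = data.frame(name = c("rare", "common"), prevalence = c(0.05, 0.9)),
    phi_targets = matrix(c(1, 0.9, 0.9, 1), 2), seed = 1
  )
  expect_error(generate_treatments(bad), "rare.*common|not attainable")
})

test_that("methylation is the exact reference mixture in the degenerate case", {
  cfg <- sim_config(
    n_samples = 4, n_cpgs = 6, n_cell_types = 1,
    dirichlet_alpha = 1, noise_sd = 0, seed = 2
  )
  me <- generate_methylation(cfg, generate_treatments(cfg), generate_cell_proportions(cfg))
  expect_lt(max(abs(me$beta - matrix(me$reference[1, ], 6, 4))), 1e-12)
})

test_that("injected M-scale shifts and detection failures have the designed magnitude", {
  cfg <- sim_config(
    n_samples = 200, n_cpgs = 10, n_cell_types = 1, dirichlet_alpha = 1,
    causal_cpgs = list(tx1 = data.frame(cpg = 3L, delta = 1.0)),
    noise_sd = 0, seed = 5
  )
  tx <- generate_treatments(cfg)
  me <- generate_methylation(cfg, tx, generate_cell_proportions(cfg))
  m <- to_m(me$beta)
  diff_m <- mean(m[3, tx[, 1] == 1]) - mean(m[3, tx[, 1] == 0])
  expect_equal(diff_m, 1.0, tolerance = 1e-9)

  cfg2 <- sim_config(
    n_samples = 1000, n_cpgs = 100,
    detection_fail_rate = 0.02, seed = 8
  )
  me2 <- generate_methylation(cfg2, generate_treatments(cfg2), generate_cell_proportions(cfg2))
  expect_lt(abs(mean(me2$detp > 0.01) - 0.02), 0.005)
})

test_that("outcome prevalence follows the inverse-logit of the linear predictor", {
  base <- list(n_samples = 10000, n_cpgs = 3, seed = 4)
  covars <- data.frame(age = rep(30, 10000), sex = rep(0, 10000))
  cfg0 <- sim_config(
    n_samples = 10000, n_cpgs = 3, seed = 4,
    outcome_models = list(chc1 = list(intercept = 0))
  )
  tx <- generate_treatments(cfg0)
  mr <- matrix(0, 3, 10000)
  out0 <- generate_outcomes(cfg0, tx, mr, covars)
  expect_lt(abs(mean(out0$chc1_status) - 0.5), 0.02)

  cfg2 <- sim_config(
    n_samples = 10000, n_cpgs = 3, seed = 4,
    outcome_models = list(chc1 = list(intercept = -2))
  )
  out2 <- generate_outcomes(cfg2, tx, mr, covars)
  expect_lt(abs(mean(out2$chc1_status) - 0.1192), 0.02)
})

test_that("a positive mediated path raises outcome prevalence in the exposed", {
  cfg <- sim_config(
    n_samples = 4000, n_cpgs = 3, n_cell_types = 1, dirichlet_alpha = 1,
    causal_cpgs = list(tx1 = data.frame(cpg = 1L, delta = 1.0)),
    noise_sd = 0.3,
    outcome_models = list(chc1 = list(
      intercept = -0.5, treatments = c(tx1 = 0),
      cpgs = stats::setNames(list(1.0), "1")
    )),
    seed = 6
  )
  co <- simulate_cohort(cfg)
  prev <- tapply(co$sample_sheet$chc1_status, co$sample_sheet$tx1, mean)
  expect_gt(prev["1"], prev["0"])
})

test_that("outcome models reject coefficients on unknown CpG indices", {
  expect_error(
    sim_config(
      n_samples = 10, n_cpgs = 3, seed = 1,
      outcome_models = list(chc1 = list(intercept = 0, cpgs = setNames(list(1), "9")))
    ),
    "unknown CpG index"
  )
})

test_that("genotype dosages follow Hardy-Weinberg and are reproducible", {
  cfg <- sim_config(n_samples = 10000, n_cpgs = 2, maf = c(0.5, 0.1), seed = 9)
  g <- generate_genotypes(cfg)
  expect_lt(abs(mean(g[, 1]) - 1.0), 0.03)
  expect_lt(abs(mean(g[, 2] == 2) - 0.01), 0.01)
  expect_identical(g, generate_genotypes(cfg))
  expect_error(
    sim_config(n_samples = 10, n_cpgs = 2, maf = c(0.7), seed = 1),
    "maf"
  )
})

test_that("the full cohort is reproducible and ground truth is internally consistent", {
  cfg <- mediation_design_config(0.55, n_samples = 300, seed = 21)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$beta, co2$beta)
  expect_identical(co1$sample_sheet, co2$sample_sheet)
  tr <- co1$ground_truth$mediation_triples
  expect_equal(tr$prop_mediated, tr$a * tr$b / (tr$a * tr$b + tr$direct))
  expect_equal(tr$prop_mediated, 0.55, tolerance = 1e-12)
})

test_that("with zero injected effects the downstream EWAS is calibrated", {
  cfg <- sim_config(n_samples = 200, n_cpgs = 1000, noise_sd = 0.5, seed = 33)
  co <- simulate_cohort(cfg)
  m <- to_m(co$beta)
  cov <- data.frame(age = co$sample_sheet$age, sex = co$sample_sheet$sex)
  r <- run_ewas(m, co$sample_sheet$tx1, cov)
  frac <- mean(r$p_raw < 0.05, na.rm = TRUE)
  # binomial 99.9% band around 0.05 with 1000 CpGs
  expect_lt(abs(frac - 0.05), 3.29 * sqrt(0.05 * 0.95 / 1000))
})
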