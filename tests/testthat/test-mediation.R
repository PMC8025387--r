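sim_triple <- function(n = 1500, a = 0.8, b = 0.5, cdir = 0.3,
                       family = "gaussian", seed = 1) {
  set.seed(seed)
  t_ <- rbinom(n, 1, 0.5)
  m_ <- a * t_ + rnorm(n)
  if (family == "gaussian") {
    y_ <- b * m_ + cdir * t_ + rnorm(n)
  } else {
    y_ <- rbinom(n, 1, expit(b * m_ + cdir * t_ - 0.2))
  }
  list(t = t_, m = m_, y = y_)
}

test_that("identity-link mediation matches the product-of-coefficients oracle", {
  d <- sim_triple(seed = 2)
  r <- mediate_single(d$t, d$m, d$y, family = "gaussian", n_draws = 1000, seed = 5)
  a_hat <- coef(lm(d$m ~ d$t))[2]
  fit_y <- coef(lm(d$y ~ d$t + d$m))
  oracle_acme <- unname(a_hat * fit_y[3])
  oracle_ade <- unname(fit_y[2])
  expect_lt(abs(r$acme - oracle_acme), 3 * r$acme_mcse)
  expect_lt(abs(r$ade - oracle_ade), 3 * r$ade_mcse)
  expect_lt(abs(r$prop_mediated - oracle_acme / (oracle_acme + oracle_ade)), 0.05)
})

test_that("ACME + ADE equals the total effect and the CIs bracket the points", {
  for (fam in c("gaussian", "binomial")) {
    d <- sim_triple(family = fam, seed = 3)
    r <- mediate_single(d$t, d$m, d$y, family = fam, n_draws = 300, seed = 7)
    expect_lt(abs(r$acme + r$ade - r$total), 1e-12)
    expect_true(r$acme_ci[1] <= r$acme && r$acme <= r$acme_ci[2])
    expect_true(r$total_ci[1] <= r$total && r$total <= r$total_ci[2])
  }
})

test_that("a nil mediator path gives an ACME interval covering zero", {
  d <- sim_triple(a = 0, b = 0.5, cdir = 0.5, family = "binomial", seed = 4)
  r <- mediate_single(d$t, d$m, d$y, family = "binomial", n_draws = 500, seed = 9)
  expect_true(r$acme_ci[1] < 0 && r$acme_ci[2] > 0)
  expect_lt(abs(r$prop_mediated), 0.15)
})

test_that("mediation is deterministic for a fixed seed and guards n_draws", {
  d <- sim_triple(n = 300, family = "binomial", seed = 5)
  r1 <- mediate_single(d$t, d$m, d$y, family = "binomial", n_draws = 200, seed = 11)
  r2 <- mediate_single(d$t, d$m, d$y, family = "binomial", n_draws = 200, seed = 11)
  expect_identical(r1$acme, r2$acme)
  expect_identical(r1$acme_ci, r2$acme_ci)
  expect_error(
    mediate_single(d$t, d$m, d$y, family = "binomial", n_draws = 50),
    "n_draws"
  )
})

test_that("doubling the draws shrinks the Monte-Carlo error by about sqrt(2)", {
  d <- sim_triple(n = 800, family = "binomial", seed = 6)
  se1 <- mediate_single(d$t, d$m, d$y,
    family = "binomial",
    n_draws = 400, seed = 13
  )$acme_mcse
  se2 <- mediate_single(d$t, d$m, d$y,
    family = "binomial",
    n_draws = 800, seed = 13
  )$acme_mcse
  expect_lt(se2 / se1, 1 / sqrt(2) * 1.35)
  expect_gt(se2 / se1, 1 / sqrt(2) / 1.35)
})

test_that("FDR mediator selection keeps the strong mediator and is a subset of raw hits", {
  set.seed(7)
  n <- 1200
  t_ <- rbinom(n, 1, 0.5)
  strong_m <- 0.9 * t_ + rnorm(n)
  y_ <- rbinom(n, 1, expit(0.8 * strong_m))
  results <- list(mediate_single(t_, strong_m, y_,
    family = "binomial",
    n_draws = 300, seed = 1, mediator_id = "cg_strong"
  ))
  for (i in 1:5) {
    null_m <- rnorm(n)
    results[[i + 1]] <- mediate_single(t_, null_m, y_,
      family = "binomial",
      n_draws = 300, seed = i + 1, mediator_id = paste0("cg_null", i)
    )
  }
  sel <- select_mediators(results)
  expect_true("cg_strong" %in% sel$mediator)
  tab <- mediation_table(results)
  raw_sig <- tab$mediator[tab$acme_p < 0.05]
  expect_true(all(sel$mediator %in% raw_sig))
  expect_error(select_mediators(list()), "empty")
})

test_that("mediator pruning follows the greedy ACME-ordered rule", {
  set.seed(8)
  base <- rnorm(100)
  R <- rbind(
    cgA = base + rnorm(100, sd = 0.1),
    cgB = base + rnorm(100, sd = 0.1), # r2 with cgA ~ 1
    cgC = rnorm(100),
    cgD = rnorm(100)
  )
  meds <- data.frame(
    mediator = c("cgA", "cgB", "cgC", "cgD"),
    acme = c(0.5, 0.4, 0.3, 0.2)
  )
  kept <- prune_mediators(meds, R, r2_threshold = 0.05)
  expect_equal(kept, c("cgA", "cgC", "cgD"))

  # all mutually correlated: only the top-ACME CpG survives
  R2 <- rbind(cgA = base, cgB = base + 0.01, cgC = 2 * base)
  meds2 <- data.frame(mediator = c("cgB", "cgA", "cgC"), acme = c(0.1, 0.9, 0.5))
  expect_equal(prune_mediators(meds2, R2), "cgA")
  expect_equal(prune_mediators(meds2[2, ], R2), "cgA")
})

test_that("pruning equals the brute-force rule on random instances up to size 12", {
  set.seed(9)
  for (rep in 1:15) {
    k <- sample(2:12, 1)
    n <- 60
    shared <- rnorm(n)
    R <- t(sapply(seq_len(k), function(i) {
      w <- runif(1)
      w * shared + (1 - w) * rnorm(n)
    }))
    rownames(R) <- paste0("cg", sprintf("%02d", seq_len(k)))
    acmes <- runif(k)
    meds <- data.frame(mediator = rownames(R), acme = acmes)
    kept <- prune_mediators(meds, R, r2_threshold = 0.3)
    ord <- order(-abs(acmes), rownames(R))
    oracle_kept <- character(0)
    for (id in rownames(R)[ord]) {
      ok <- all(vapply(
        oracle_kept,
        function(kk) cor(R[id, ], R[kk, ])^2 < 0.3, logical(1)
      ))
      if (ok) oracle_kept <- c(oracle_kept, id)
    }
    expect_equal(kept, oracle_kept)
  }
})

test_that("the combined score is the exact sum and reduces to single-CpG mediation", {
  R <- rbind(cg1 = c(0.5, -0.2, 0.1), cg2 = c(0.1, 0.1, 0.1))
  colnames(R) <- paste0("s", 1:3)
  sc <- combined_score(c("cg1", "cg2"), R)
  expect_equal(unname(sc), c(0.6, -0.1, 0.2), ignore_attr = TRUE)
  expect_equal(
    unname(combined_score(c("cg2", "cg1"), R)),
    unname(sc),
    ignore_attr = TRUE
  ) # order invariant
  expect_equal(unname(combined_score("cg1", R)), unname(R["cg1", ]), ignore_attr = TRUE)
  expect_error(combined_score(character(0), R), "at least one")

  d <- sim_triple(n = 500, family = "binomial", seed = 10)
  R2 <- matrix(d$m, 1, 500, dimnames = list("cgX", NULL))
  single <- mediate_single(d$t, d$m, d$y,
    family = "binomial",
    n_draws = 200, seed = 17, mediator_id = "cgX"
  )
  comb <- mediate_combined(d$t, combined_score("cgX", R2), d$y,
    family = "binomial", n_draws = 200, seed = 17
  )
  expect_equal(comb$acme, single$acme)
  expect_equal(comb$prop_mediated, single$prop_mediated)
})

test_that("same-signed ACME and ADE give a proportion mediated inside [0, 1]", {
  d <- sim_triple(a = 0.8, b = 0.6, cdir = 0.4, family = "binomial", seed = 11)
  r <- mediate_single(d$t, d$m, d$y, family = "binomial", n_draws = 300, seed = 19)
  expect_gt(sign(r$acme) * sign(r$ade), 0)
  expect_true(r$prop_mediated >= 0 && r$prop_mediated <= 1)
  expect_equal(r$pct_mediated, 100 * r$prop_mediated)
})

test_that("significant treatments are picked by multivariable logistic screening", {
  set.seed(12)
  n <- 2000
  tx <- cbind(t1 = rbinom(n, 1, 0.5), t2 = rbinom(n, 1, 0.4), t3 = rbinom(n, 1, 0.3))
  age <- rnorm(n, 35, 8)
  sex <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * tx[, 1] + 0 * tx[, 2] + 0.02 * (age - 35)))
  sig <- significant_treatments(tx, y, age, sex)
  expect_true("t1" %in% sig)
  expect_false("t2" %in% sig)
})
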