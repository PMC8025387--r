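test_that("phi coefficients match the closed form and flag degenerate margins", {
  x <- rbinom(50, 1, 0.5)
  ph <- phi_matrix(cbind(a = x, b = x))
  expect_equal(ph$phi[1, 2], 1)

  # 2x2 table a=30, b=10, c=10, d=50: phi = 1400/2400
  a <- c(rep(1, 40), rep(0, 60))
  b <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 50))
  ph2 <- phi_matrix(cbind(a = a, b = b))
  expect_equal(ph2$phi[1, 2], 1400 / 2400, tolerance = 1e-12)
  expect_equal(ph2$p[1, 2], pchisq(100 * (1400 / 2400)^2, 1, lower.tail = FALSE))

  expect_warning(
    ph3 <- phi_matrix(cbind(a = rep(1, 20), b = rbinom(20, 1, 0.5))),
    "degenerate"
  )
  expect_true(is.na(ph3$phi[1, 2]))
})

test_that("strongly correlated co-treatments are excluded from the adjustment set", {
  ph <- structure(
    list(
      phi = matrix(c(1, 0.5, 0.2, 0.5, 1, 0.1, 0.2, 0.1, 1), 3,
        dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3"))
      ),
      p = matrix(c(0, 1e-40, 1e-10, 1e-40, 0, 0.5, 1e-10, 0.5, 0), 3,
        dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3"))
      ),
      n = 100
    ),
    class = "PhiMatrix"
  )
  expect_equal(select_adjustment_set(ph, "t1"), "t3") # t2: phi 0.5, p tiny -> out
  expect_error(select_adjustment_set(ph, "nope"), "unknown treatment")

  single <- phi_matrix(cbind(only = rbinom(30, 1, 0.5)))
  expect_equal(select_adjustment_set(single, "only"), character(0))
})

test_that("run_ewas matches the normal-equations oracle", {
  set.seed(1)
  for (rep in 1:10) {
    n <- 20
    Y <- matrix(rnorm(4 * n), 4, n)
    x <- rbinom(n, 1, 0.5)
    cv <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
    r <- run_ewas(Y, x, cv)
    X <- cbind(1, x, cv)
    for (i in 1:4) {
      o <- oracle_ols(Y[i, ], X, j = 2)
      expect_equal(r$beta[i], o$beta, tolerance = 1e-8)
      expect_equal(r$se[i], o$se, tolerance = 1e-8)
      expect_equal(r$p_raw[i], o$p, tolerance = 1e-6)
    }
  }
})

test_that("a noise-free injected effect is recovered exactly", {
  set.seed(2)
  n <- 60
  x <- rep(c(0, 1), each = 30)
  cv <- matrix(rnorm(n * 2), n, 2)
  cv <- qr.Q(qr(cbind(1, x, cv)))[, 3:4] # orthogonal covariates
  y <- 1.0 * x + cv %*% c(0.5, -0.3)
  r <- run_ewas(matrix(y, 1, n), x, cv)
  expect_equal(r$beta[1], 1.0, tolerance = 1e-8)
})

test_that("missing methylation falls back to per-CpG complete cases", {
  set.seed(3)
  n <- 40
  Y <- matrix(rnorm(3 * n), 3, n)
  Y[2, 1:5] <- NA
  x <- rbinom(n, 1, 0.5)
  r <- run_ewas(Y, x, NULL)
  expect_equal(r$n_used, c(40L, 35L, 40L))
  keep <- !is.na(Y[2, ])
  o <- oracle_ols(Y[2, keep], cbind(1, x[keep]), j = 2)
  expect_equal(r$beta[2], o$beta, tolerance = 1e-10)
})

test_that("a permuted exposure gives calibrated null p-values", {
  set.seed(4)
  n <- 100
  Y <- matrix(rnorm(1000 * n), 1000, n)
  x <- sample(rep(c(0, 1), each = 50))
  r <- run_ewas(Y, x, NULL)
  expect_lt(abs(mean(r$p_raw < 0.05) - 0.05), 3.29 * sqrt(0.05 * 0.95 / 1000))
})

test_that("genomic control rescales by the median chi-square", {
  set.seed(5)
  p_null <- runif(1e5)
  r <- data.frame(p_raw = p_null)
  adj <- genomic_control_adjust(r)
  expect_lt(abs(attr(adj, "lambda") - 1), 0.03)

  # all statistics at the null median: lambda exactly 1, p untouched
  p_med <- rep(pchisq(qchisq(0.5, 1), 1, lower.tail = FALSE), 200)
  adj2 <- genomic_control_adjust(data.frame(p_raw = p_med))
  expect_equal(attr(adj2, "lambda"), 1)
  expect_equal(adj2$p_gc, adj2$p_raw)

  # doubling every chi-square gives lambda 2 and adjustment restores the null
  chi_null <- qchisq(p_null[1:5000], 1, lower.tail = FALSE)
  p_infl <- pchisq(2 * chi_null, 1, lower.tail = FALSE)
  adj3 <- genomic_control_adjust(data.frame(p_raw = p_infl))
  expect_equal(attr(adj3, "lambda"), 2, tolerance = 0.05)
  lam <- attr(adj3, "lambda")
  oracle <- pchisq(2 * chi_null / lam, 1, lower.tail = FALSE)
  expect_equal(adj3$p_gc, oracle, tolerance = 1e-12)
  # idempotent once deflated to the null
  adj4 <- genomic_control_adjust(data.frame(p_raw = adj3$p_gc))
  expect_lte(attr(adj4, "lambda"), 1 + 0.05)
  expect_true(all(adj3$p_gc >= adj3$p_raw))
})

test_that("significance calling is strict at the threshold", {
  r <- data.frame(cpg_id = c("a", "b", "c"), p_gc = c(8.9e-8, 9e-8, 0.5))
  hits <- call_significant(r)
  expect_equal(hits$cpg_id, "a")
  expect_equal(nrow(call_significant(r[0, ])), 0)
})

test_that("dose tertiles follow the hand binning and detect monotone trends", {
  dose <- c(0, 0, 0, 1:9)
  m <- matrix(rnorm(12), 1, 12)
  r <- dose_response_trend(m, dose)
  expect_equal(attr(r, "ordinal"), c(0, 0, 0, 1, 1, 1, 2, 2, 2, 3, 3, 3))

  # noise-free increasing M with ordinal dose
  m2 <- matrix(attr(r, "ordinal") * 0.5 + 0.01 * seq_along(dose), 1, 12)
  r2 <- dose_response_trend(m2, dose)
  expect_lt(r2$trend_p[1], 0.05)
  expect_gt(r2$beta[1], 0)

  expect_error(dose_response_trend(m, c(0, 0, 0, rep(1, 9))), "tertile")
})

test_that("shuffled dose gives a calibrated trend null", {
  set.seed(6)
  n <- 80
  dose <- c(rep(0, 40), runif(40, 1, 10))
  Y <- matrix(rnorm(1000 * n), 1000, n)
  r <- dose_response_trend(Y, dose)
  expect_lt(abs(mean(r$trend_p < 0.05) - 0.05), 3.29 * sqrt(0.05 * 0.95 / 1000))
})

test_that("paired-exposure scan restricts to concordant samples", {
  set.seed(7)
  n <- 250
  a <- c(rep(1, 100), rep(0, 100), rep(1, 50))
  b <- c(rep(1, 100), rep(0, 100), rep(0, 50))
  Y <- matrix(rnorm(5 * n), 5, n)
  r <- paired_exposure_ewas(Y, a, b)
  expect_true(all(r$n_used == 200))

  # identical exposures: equals the single-treatment scan
  r2 <- paired_exposure_ewas(Y, a, a)
  r3 <- run_ewas(Y, a)
  expect_equal(r2$beta, r3$beta, tolerance = 1e-12)
  expect_equal(r2$p_raw, r3$p_raw, tolerance = 1e-12)

  expect_error(paired_exposure_ewas(Y, c(rep(1, 5), rep(0, n - 5)), b), "both = ")
})

test_that("joint-only effects are visible to the paired scan but not the single scans", {
  set.seed(8)
  n <- 400
  a <- rbinom(n, 1, 0.5)
  b <- rbinom(n, 1, 0.5)
  y <- 1.5 * (a & b) + rnorm(n, sd = 0.5) # pure interaction
  Y <- matrix(y, 1, n)
  rp <- paired_exposure_ewas(Y, a, b)
  ra <- run_ewas(Y, a, cbind(b = b))
  expect_lt(rp$p_raw[1], 1e-10)
  expect_gt(ra$p_raw[1] / rp$p_raw[1], 1e6)
})

test_that("annotation enrichment reproduces the hand odds ratio and a flat null", {
  ann <- data.frame(
    cpg_id = paste0("cg", 1:10000),
    island_region = c(rep("island", 200), rep("open_sea", 9800))
  )
  # hit-in = 10, hit-out = 90 -> bg-in = 190, bg-out = 9710... construct the
  # printed 2x2 exactly: in-category 110 total, hits 10 of them
  ann2 <- data.frame(
    cpg_id = paste0("cg", 1:10100),
    island_region = c(rep("island", 110), rep("open_sea", 9990))
  )
  hits <- c(paste0("cg", 1:10), paste0("cg", 111:200)) # 10 in, 90 out
  enr <- annotation_enrichment(hits, ann2)
  isl <- enr[enr$category == "island", ]
  expect_equal(isl$or, (10 * 9900) / (90 * 100))
  # complementary categories give reciprocal sample ORs
  os <- enr[enr$category == "open_sea", ]
  expect_equal(os$or, 1 / isl$or, tolerance = 1e-12)
  # exact-test estimate agrees with fisher.test directly
  ft <- fisher.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE))
  expect_equal(isl$or_cmle, unname(ft$estimate))
  expect_equal(isl$p, ft$p.value)

  set.seed(9)
  null_hits <- sample(ann$cpg_id, 300)
  enr0 <- annotation_enrichment(null_hits, ann)
  expect_true(all(enr0$p_fdr > 0.05 | abs(log(enr0$or)) < 0.5))
})
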