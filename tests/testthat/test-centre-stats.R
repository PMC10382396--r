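test_that("standardise centres and scales to mean 0, sample SD 1", {
  expect_equal(standardise(c(2, 4, 6)), c(-1, 0, 1))
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:40, 1), mean = runif(1, -50, 50), sd = runif(1, 0.1, 9))
    z <- standardise(x)
    expect_equal(mean(z), 0)
    expect_equal(sd(z), 1)
    # idempotence and affine equivariance
    expect_equal(standardise(z), z)
    a <- runif(1, 0.1, 10); b <- runif(1, -20, 20)
    expect_equal(standardise(a * x + b), z)
  }
})

test_that("standardise rejects degenerate input with a traceable message", {
  expect_error(standardise(c(1)), "at least 2")
  expect_error(standardise(c(3, 3, 3), centre_id = "C07", trait_id = "hct"),
               "zero variance.*C07.*hct")
  expect_error(standardise(c(1, Inf)), "finite")
})

test_that("cohens_d matches the pooled-variance definition", {
  expect_equal(cohens_d(c(3, 4, 5), c(1, 2, 3)), 2)
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(2:30, 1)); b <- rnorm(sample(2:30, 1))
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
    expect_equal(cohens_d(a, b), -cohens_d(b, a))
  }
  x <- c(1, 2, 3)
  expect_equal(cohens_d(x, x), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("effect_se follows the large-sample formula and grows with |d|", {
  expect_equal(effect_se(0, 50, 50), 0.2)
  expect_equal(effect_se(0.5, 50, 50), sqrt(0.04 + 0.25 / 200))
  d <- seq(0, 3, by = 0.25)
  se <- vapply(d, effect_se, numeric(1), n_a = 40, n_b = 60)
  expect_true(all(diff(se) > 0))
  expect_error(effect_se(0.3, 1, 50), "at least 2")
})

test_that("fit_sex_model reduces to t-test + Cohen's d without covariates", {
  g <- make_group(males = c(3, 4, 5), females = c(1, 2, 3))
  res <- fit_sex_model(g)
  expect_equal(res$effect_size, 2)
  expect_equal(res$p_value, t.test(c(3, 4, 5), c(1, 2, 3),
                                   var.equal = TRUE)$p.value)
  expect_equal(res$n_male, 3L)
  expect_true(is.na(res$q_value))

  # swapping sex labels flips the sign
  g2 <- g
  g2$sex <- ifelse(g$sex == "male", "female", "male")
  expect_equal(fit_sex_model(g2)$effect_size, -2)

  # oracle equivalence on random two-group data
  set.seed(31)
  for (i in 1:10) {
    m <- rnorm(15, 0.6); f <- rnorm(12)
    gg <- make_group(m, f)
    r <- fit_sex_model(gg)
    expect_equal(r$effect_size, cohens_d(m, f))
    expect_equal(r$p_value, t.test(m, f, var.equal = TRUE)$p.value)
  }
})

test_that("fit_sex_model handles missing body weight and one-sex input", {
  g <- make_group(males = rnorm(5, 1), females = rnorm(5))
  g$body_weight[2] <- NA
  expect_message(res <- fit_sex_model(g), "missing body weight")
  expect_equal(res$n_male + res$n_female, 9L)

  g_one_sex <- g[g$sex == "male", ]
  expect_error(fit_sex_model(g_one_sex), "per sex")
})

test_that("fit_sex_model falls back to OLS when the batch effect is unfittable", {
  set.seed(41)
  n <- 30
  g <- make_group(rnorm(n, 0.8), rnorm(n),
                  bw = rnorm(2 * n, 27, 3),
                  batch = paste0("2024-01-", sprintf("%02d", 1:(2 * n))))
  # one batch per animal -> singular random effect -> logged fallback
  expect_message(res <- fit_sex_model(g), "fixed-effects")
  expect_true(is.finite(res$p_value) && res$effect_se > 0)
})

test_that("mixed-model and OLS paths agree closely on balanced batched data", {
  set.seed(43)
  cfg <- simulation_config(n_centres = 1L,
                           traits = list(list(trait_id = "t", true_d = 0.8,
                                              beta_bw = 0.03)),
                           n_per_sex = 100L, n_batches = 6L, batch_sd = 0.3,
                           seed = 7L)
  m <- simulate_measurements(cfg)
  res_mixed <- fit_sex_model(m)
  m_nobatch <- m; m_nobatch$batch <- "2024-01-01"
  res_ols <- fit_sex_model(m_nobatch)
  expect_equal(res_mixed$effect_size, res_ols$effect_size, tolerance = 0.1)
  expect_true(res_mixed$p_value < 0.001 && res_ols$p_value < 0.001)
})

test_that("per-centre affine shifts leave effect sizes and p-values unchanged", {
  set.seed(51)
  cfg <- impc_mimic_config(seed = 5, n_per_sex = 30)
  cfg$traits <- cfg$traits[1:2]
  m <- simulate_measurements(cfg)
  m2 <- m
  for (cid in unique(m2$centre_id)) {
    idx <- m2$centre_id == cid
    m2$value[idx] <- runif(1, 0.5, 3) * m2$value[idx] + runif(1, -100, 100)
  }
  r1 <- suppressMessages(centre_statistics(m))
  r2 <- suppressMessages(centre_statistics(m2))
  expect_equal(r1$effect_size, r2$effect_size)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("null sex effect yields approximately uniform p-values", {
  n_rep <- 200
  p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    m <- simulate_measurements(quick_config(true_d = 0, seed = 1000 + i))
    p[i] <- fit_sex_model(m)$p_value
  }
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("the estimator recovers the true standardised effect", {
  n_rep <- 200
  d_hat <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    m <- simulate_measurements(quick_config(true_d = 0.8, seed = 2000 + i))
    d_hat[i] <- fit_sex_model(m)$effect_size
  }
  expect_lt(abs(mean(d_hat) - 0.8), 0.05)
})

test_that("centre_statistics stacks one row per analysable centre x trait", {
  cfg <- scenario_preset("S1", n_per_sex = 20)
  m <- simulate_measurements(cfg)
  res <- suppressMessages(centre_statistics(m))
  expect_equal(nrow(res), 4L)
  expect_setequal(res$centre_id, sprintf("C%02d", 1:4))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$effect_se > 0))

  # the 50-per-sex consortium filter drops every group here
  expect_error(
    suppressMessages(centre_statistics(m, impc_mode = TRUE)),
    "no centre"
  )
})
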