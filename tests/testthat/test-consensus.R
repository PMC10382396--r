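test_that("direction_penalty is the absolute net sign fraction", {
  expect_equal(direction_penalty(c(0.5, 0.3, 0.9, 0.1)), 1)
  expect_equal(direction_penalty(c(0.5, 0.3, -0.9, -0.1)), 0)
  expect_equal(direction_penalty(c(0.5, 0.3, 0.9, -0.1)), 0.5)
  expect_equal(direction_penalty(c(0, 0.4, -0.4)), 0)  # sign(0) = 0
  expect_error(direction_penalty(numeric(0)), "empty")
})

test_that("exact cancellation at the expected values gives score 1", {
  res <- make_results(rep(0.5, 4), rep(0.05, 4))
  out <- consensus_score(res, consensus_params(M = 4))
  expect_equal(out$score, 1)
  expect_equal(out$neglog_score, 0)
  expect_equal(out$decision, "NO_CONSENSUS")
})

test_that("balanced effect directions trip the gate regardless of q-values", {
  res <- make_results(c(0.6, 0.4, -0.5, -0.3), c(0.001, 0.2, 0.9, 0.04))
  out <- consensus_score(res, consensus_params(M = 4))
  expect_identical(out$score, 1)
  expect_equal(out$decision, "INSUFFICIENT_INFO")
  expect_equal(out$direction, "NONE")
  expect_equal(out$penalty, 0)
})

test_that("a hand-evaluated strong-agreement case scores below 1", {
  res <- make_results(c(0.6, 0.5, 0.7, 0.55), c(0.01, 0.02, 0.03, 0.04))
  out <- consensus_score(res, consensus_params(M = 4))
  # frozen from independent hand arithmetic of the scoring formula
  expect_equal(out$score, 0.5420164189, tolerance = 1e-9)
  expect_equal(out$neglog_score, 0.2659875575, tolerance = 1e-9)
  expect_equal(out$decision, "CONSENSUS")
  expect_equal(out$direction, "MALE_HIGHER")
  expect_equal(out$mean_effect, mean(c(0.6, 0.5, 0.7, 0.55)))
})

test_that("too few reporting centres never produce a score", {
  res <- make_results(c(0.9, 0.8, 0.7), c(0.001, 0.001, 0.001))
  out <- consensus_score(res, consensus_params(M = 11))
  expect_equal(out$decision, "INSUFFICIENT_CENTRES")
  expect_true(is.na(out$score))
  expect_equal(classify(out),
               "Does not reach the minimum requirements for this analysis")
})

test_that("consensus_score validates q-values and the centre totals", {
  res <- make_results(rep(0.5, 4), rep(0.01, 4))
  res$q_value <- NA_real_
  expect_error(consensus_score(res, consensus_params(M = 4)), "apply_fdr")
  res2 <- make_results(rep(0.5, 5), rep(0.01, 5))
  expect_error(consensus_score(res2, consensus_params(M = 4)),
               "cannot be smaller")
})

test_that("scoring matches an independent transcription of the formula", {
  set.seed(71)
  for (i in 1:1000) {
    m_bar <- sample(1:10, 1)
    M <- m_bar + sample(0:4, 1)
    q <- runif(m_bar)
    rho <- rnorm(m_bar)
    res <- make_results(rho, q)
    out <- consensus_score(res, consensus_params(M = M))
    exp_score <- score_oracle(q, rho, M)
    if (is.na(exp_score)) {
      expect_true(is.na(out$score))
      expect_equal(out$decision, "INSUFFICIENT_CENTRES")
    } else {
      expect_equal(out$score, exp_score, tolerance = 1e-12)
    }
  }
})

test_that("score is monotone in q and |rho| and permutation invariant", {
  set.seed(81)
  base_q <- c(0.01, 0.03, 0.02, 0.04, 0.02)
  base_rho <- c(0.6, 0.5, 0.7, 0.4, 0.55)
  params <- consensus_params(M = 5)
  s0 <- consensus_score(make_results(base_rho, base_q), params)$score
  for (i in seq_along(base_q)) {
    q_up <- base_q; q_up[i] <- q_up[i] + 0.01
    expect_gte(consensus_score(make_results(base_rho, q_up), params)$score, s0)
    r_up <- base_rho; r_up[i] <- r_up[i] + 0.2
    expect_gte(consensus_score(make_results(r_up, base_q), params)$score, s0)
  }
  for (i in 1:10) {
    perm <- sample(5)
    sp <- consensus_score(make_results(base_rho[perm], base_q[perm]), params)
    expect_equal(sp$score, s0)
  }
})

test_that("the gate quantity M_bar * P is an exact integer", {
  set.seed(91)
  for (i in 1:200) {
    rho <- rnorm(sample(1:12, 1))
    p <- direction_penalty(rho)
    net <- p * length(rho)
    expect_equal(net, round(net))
    expect_equal(net, abs(sum(sign(rho))))
  }
})

test_that("qualitative scenarios behave as designed", {
  params <- consensus_params(M = 4)
  # q and rho all above the expected values -> score > 1
  worse <- consensus_score(make_results(c(0.8, 0.9, 1.1, 0.7),
                                        c(0.2, 0.3, 0.4, 0.25)), params)
  expect_gt(worse$score, 1)
  expect_equal(worse$decision, "NO_CONSENSUS")
  # all below the expected values -> score < 1 (full agreement)
  better <- consensus_score(make_results(c(0.3, 0.4, 0.45, 0.35),
                                         c(0.01, 0.02, 0.01, 0.03)), params)
  expect_lt(better$score, 1)
  expect_equal(better$decision, "CONSENSUS")
  # mixed large/small effects stay finite and valid via the sqrt damping
  mixed <- consensus_score(make_results(c(2.5, 1.8, 0.2, 0.3),
                                        c(0.01, 0.01, 0.02, 0.02)), params)
  expect_true(is.finite(mixed$score) && mixed$score > 0)
  x <- c(0.04, 0.5, 0.99, 1, 1.5, 4)
  expect_true(all(sqrt(x[x < 1]) > x[x < 1]))
  expect_true(all(sqrt(x[x >= 1]) <= x[x >= 1]))
  # female-led consensus reports the opposite direction
  fem <- consensus_score(make_results(-c(0.3, 0.4, 0.45, 0.35),
                                      c(0.01, 0.02, 0.01, 0.03)), params)
  expect_equal(fem$direction, "FEMALE_HIGHER")
  expect_equal(classify(fem), "Female Higher")
})

test_that("neglog_score uses base 10 (pinned by reported score pairs)", {
  expect_equal(neglog_score(1), 0)
  expect_equal(round(neglog_score(0.45), 2), 0.35)
  expect_equal(round(neglog_score(0.69), 2), 0.16)
  expect_error(neglog_score(0), "positive")
  expect_error(neglog_score(-2), "positive")
})

test_that("calibrate_rho_hat trims symmetric tails of the magnitudes", {
  expect_equal(calibrate_rho_hat(1:10, trim_fraction = 0.1), 5.5)
  expect_equal(calibrate_rho_hat(c(-3, 1, 2), trim_fraction = 0), 2)
  expect_equal(calibrate_rho_hat(rep(0.7, 9), trim_fraction = 0.3), 0.7)
  expect_error(calibrate_rho_hat(numeric(0)), "empty")
  expect_error(calibrate_rho_hat(1:3, trim_fraction = 0.5), "0.5")
})

test_that("score_traits summarises every trait with report phrases", {
  res <- rbind(
    make_results(c(0.3, 0.4, 0.45, 0.35), c(0.01, 0.02, 0.01, 0.03), "lead"),
    make_results(c(0.6, 0.4, -0.5, -0.3), c(0.01, 0.2, 0.9, 0.04), "split")
  )
  tab <- score_traits(res, consensus_params(M = 4), rounding = 2)
  expect_equal(nrow(tab), 2L)
  lead <- tab[tab$trait_id == "lead", ]
  expect_equal(lead$inference, "Males Higher")
  split <- tab[tab$trait_id == "split", ]
  expect_equal(split$score, 1)
  expect_equal(split$inference,
               "Not enough signal between or across centres to detect SD")
})
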