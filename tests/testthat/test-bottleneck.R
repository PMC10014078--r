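test_that("equal-n0 loss MLE equals the closed form", {
  cases <- list(c(n0 = 100, w = 6, k = 3), c(n0 = 23, w = 90, k = 45),
                c(n0 = 500, w = 12, k = 2), c(n0 = 10, w = 30, k = 25))
  for (cs in cases) {
    tab <- data.frame(n0 = rep(cs["n0"], cs["w"]),
                      lost = rep(c(1, 0), c(cs["k"], cs["w"] - cs["k"])))
    est <- beta_mle_loss(tab)
    closed <- -log(cs["k"] / cs["w"]) / cs["n0"]
    expect_lt(abs(est$beta_hat - closed) / closed, 1e-10)
  }
})

test_that("optimizer MLE matches a dense likelihood grid search", {
  set.seed(4)
  for (i in 1:6) {
    w <- sample(4:12, 1)
    n <- sample(c(20, 50, 100, 200), w, replace = TRUE)
    lost <- rbinom(w, 1, exp(-0.01 * n))
    if (all(lost == 1) || all(lost == 0)) next
    est <- beta_mle_loss(data.frame(n0 = n, lost = lost))
    oracle <- grid_mle_loss(n, lost)
    # agreement to the grid's own resolution (log-spaced, 1e5 points)
    expect_lt(abs(log(est$beta_hat) - log(oracle)),
              2 * (log(1) - log(1e-6)) / 1e5)
  }
})

test_that("profile interval endpoints sit at the 1.92 log-likelihood drop", {
  tab <- data.frame(n0 = c(rep(100, 8), rep(40, 4)),
                    lost = c(1, 1, 1, 0, 0, 0, 0, 1, 0, 0, 1, 0))
  est <- beta_mle_loss(tab)
  llmax <- loss_loglik_oracle(est$beta_hat, tab$n0, tab$lost)
  for (b in c(est$ci_low, est$ci_high)) {
    expect_lt(abs(loss_loglik_oracle(b, tab$n0, tab$lost) -
                    (llmax - 1.92)), 1e-6)
  }
  expect_true(est$ci_low < est$beta_hat && est$beta_hat < est$ci_high)
})

test_that("degenerate loss patterns yield one-sided bounds", {
  # all lost: analytic upper bound 1.35 / sum(n)
  all_lost <- data.frame(n0 = rep(100, 6), lost = rep(1, 6))
  est <- beta_bounds(all_lost)
  expect_equal(est$ci_high, 1.35 / 600)
  expect_identical(est$bound_type, "upper-only")
  # delegation from the MLE front-end
  expect_equal(beta_mle_loss(all_lost)$ci_high, 1.35 / 600)

  # all retained at n = 1: bound solves the one-sided profile criterion
  all_kept <- data.frame(n0 = rep(1, 6), lost = rep(0, 6))
  est2 <- beta_bounds(all_kept)
  expect_identical(est2$bound_type, "lower-only")
  llmax <- 6 * log1p(-exp(-1))
  expect_lt(abs(6 * log1p(-exp(-est2$ci_low)) - (llmax - 1.35)), 1e-8)

  # boundary MLE: a single retained single-cell tag
  one <- beta_mle_loss(data.frame(n0 = 1, lost = 0))
  expect_equal(one$beta_hat, 1)
  expect_identical(one$bound_type, "lower-only")

  expect_error(beta_bounds(data.frame(n0 = numeric(0),
                                      lost = numeric(0))), "empty")
  expect_error(beta_bounds(data.frame(n0 = c(10, 10), lost = c(0, 1))),
               "mixed")
})

test_that("challenge estimator matches its closed form and limits", {
  est <- challenge_beta(rep(2000, 12), rep(c(1, 0), 6))
  closed <- 1 - 0.5^(1 / 2000)
  expect_lt(abs(est$beta_hat - closed) / closed, 1e-6)
  # full survival: beta = 1 implies loss probability 0 for any n0 >= 1;
  # an all-retained pattern therefore keeps beta = 1 in the interval
  kept <- challenge_beta(rep(5, 8), rep(0, 8))
  expect_identical(kept$bound_type, "lower-only")
  expect_equal(kept$ci_high, 1)
  # below-detection tags are excluded, not counted as losses
  est2 <- challenge_beta(c(2000, 2000, NA), c(1, 0, NA))
  expect_equal(est2$n_obs, 2L)
  expect_error(challenge_beta(c(0.5, 2), c(0, 1)), ">= 1")
})

test_that("variance-based estimator recovers beta and flags degeneracy", {
  # no drift: endpoint proportions identical to the inoculum in all mice
  p <- matrix(1 / 6, nrow = 4, ncol = 6)
  est <- beta_variance(p, 600)
  expect_true(est$degenerate)
  expect_identical(est$bound_type, "lower-only")
  expect_error(beta_variance(matrix(1, 2, 1), 100), "h >= 2")

  # parameter recovery against the simulator at the published design
  beta <- 0.03; n0 <- 100
  des <- inoculum_design(rep(n0, 6), untagged_dose = 1e7)
  dyn <- strain_dynamics(q = beta, r = 0.62, c = 0, tau = 3.2)
  st <- competition_state(1e10, 48)
  est_cohort <- vapply(1:40, function(s) {
    co <- simulate_cohort(des, dyn, st, n_mice = 20, seed = 1000 + s)
    beta_variance(proportion_matrix(co), 6 * n0)$beta_hat
  }, 0)
  expect_lt(abs(median(est_cohort) / beta - 1), 0.15)
})

test_that("loss estimator is scale-consistent in the spike-in size", {
  # losses generated at the true n, but analysed as if every spike-in
  # had been doubled: the estimate halves in expectation
  beta <- 0.02; n <- rep(50, 60)
  set.seed(6)
  est <- replicate(200, {
    lost <- rbinom(length(n), 1, exp(-beta * n))
    if (all(lost == 1) || all(lost == 0)) return(NA_real_)
    beta_mle_loss(data.frame(n0 = 2 * n, lost = lost))$beta_hat
  })
  expect_lt(abs(mean(est, na.rm = TRUE) / (beta / 2) - 1), 0.1)
})

test_that("leave-one-out estimates are stable for neutral barcodes", {
  # symmetric data: every barcode has the same loss pattern
  tab <- data.frame(barcode = rep(paste0("BC", 1:6), each = 10),
                    n0 = 30,
                    lost = rep(rep(c(1, 0), 5), 6))
  loo <- leave_one_out(tab)
  expect_identical(nrow(loo), 6L)
  expect_true(all(abs(loo$beta_hat - loo$beta_hat[1]) < 1e-12))

  # simulated neutral data: no exclusion leaves the full-data interval
  set.seed(7)
  tab2 <- data.frame(barcode = rep(paste0("BC", 1:6), each = 15), n0 = 23)
  tab2$lost <- rbinom(nrow(tab2), 1, exp(-0.03 * tab2$n0))
  full <- beta_mle_loss(tab2)
  loo2 <- leave_one_out(tab2)
  expect_true(all(loo2$beta_hat >= full$ci_low &
                    loo2$beta_hat <= full$ci_high))

  expect_identical(nrow(leave_one_out(
    data.frame(barcode = c("a", "a", "b"), n0 = 10,
               lost = c(1, 0, 0)))), 2L)
  expect_error(leave_one_out(data.frame(barcode = "a", n0 = 10, lost = 1)),
               "2 distinct")
})

test_that("spike-in design helper returns both optimality criteria", {
  expect_equal(optimal_n0(log(2))$n0_half_loss, 1)
  rec <- optimal_n0(10^-1.5)
  expect_lt(abs(rec$n0_half_loss - 21.92), 0.01)
  expect_gt(rec$n0_half_loss, 10); expect_lt(rec$n0_half_loss, 100)
  # Fisher optimum against a direct numerical maximization oracle
  x_opt <- optimize(function(x) x^2 / (exp(x) - 1), c(0.1, 5),
                    maximum = TRUE)$maximum
  expect_lt(abs(rec$x_star - x_opt), 1e-4)
  expect_error(optimal_n0(0), "\\(0, 1\\]")
})

test_that("day-0 population sizes convert fecal densities to cecal cells", {
  expect_identical(estimate_day0_n0(500, 1, 1), 500L)
  expect_identical(estimate_day0_n0(100, 2, 2.83), 566L)
  # censored barcodes are flagged, detected ones never round to zero
  out <- estimate_day0_n0(c(0, 0.1), 1, 1)
  expect_true(is.na(out[1]))
  expect_identical(out[2], 1L)
  expect_error(estimate_day0_n0(100, NULL, 1), "control-arm")
  expect_error(estimate_day0_n0(100, -1, 1), "> 0")
})

test_that("beta_est methods expose the estimate consistently", {
  tab <- data.frame(n0 = rep(100, 6), lost = c(1, 1, 1, 0, 0, 0))
  est <- beta_mle_loss(tab)
  expect_equal(unname(coef(est)), est$beta_hat)
  ci <- confint(est)
  expect_equal(unname(ci[1, ]), c(est$ci_low, est$ci_high))
  expect_equal(as.numeric(logLik(est)), est$loglik)
  s <- summary(est)
  expect_lt(abs(s$log10_beta - log10(log(2) / 100)), 1e-10)
  expect_output(print(est), "loss method")
})
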