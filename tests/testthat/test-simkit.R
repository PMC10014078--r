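state48 <- competition_state(K = 1e10, t_tot = 48)

test_that("inoculum draws are Poisson around the spike-in means", {
  # degenerate at zero means
  expect_identical(unname(draw_inoculum(inoculum_design(c(0, 0, 0)),
                                        seed = 1)),
                   c(0L, 0L, 0L))
  # reproducible under a fixed seed
  expect_identical(draw_inoculum(inoculum_design(rep(30, 6)), seed = 42),
                   draw_inoculum(inoculum_design(rep(30, 6)), seed = 42))
  # law of large numbers: sample mean of 1e5 draws within 3 SE of 30
  x <- draw_inoculum(inoculum_design(rep(30, 1e5)), seed = 7)
  se <- sqrt(30 / 1e5)
  expect_lt(abs(mean(x) - 30), 3 * se)
})

test_that("colonization endpoints honour the trivial limits", {
  des <- inoculum_design(rep(30, 6), untagged_dose = 1e7)
  # no early survivors, no colonization
  sim <- simulate_colonization(des, strain_dynamics(q = 0, r = 0.7),
                               state48, seed = 1)
  expect_true(all(sim$cells == 0))

  # deterministic logistic limit: a single tag with many certain founders
  # and no clearance fills the whole niche
  simK <- simulate_colonization(inoculum_design(300),
                                strain_dynamics(q = 1, r = 0.6, c = 0,
                                                tau = 0),
                                state48, seed = 2)
  expect_lt(abs(sum(simK$cells) / 1e10 - 1), 0.15)

  # fixed seed => bit-identical output
  a <- simulate_colonization(des, strain_dynamics(q = 0.05, r = 0.7,
                                                  c = 0.07, tau = 2),
                             state48, seed = 11)
  b <- simulate_colonization(des, strain_dynamics(q = 0.05, r = 0.7,
                                                  c = 0.07, tau = 2),
                             state48, seed = 11)
  expect_identical(a, b)
})

test_that("high-dose inocula essentially never lose a tag", {
  # one tag at 2e6 cells, per-cell survival 1e-4: loss probability
  # exp(-200) is negligible, so no replicate loses the tag
  des <- inoculum_design(2e6)
  dyn <- strain_dynamics(q = 1e-4, r = 0.7, c = 0, tau = 0)
  lost <- vapply(1:25, function(s) {
    sum(simulate_colonization(des, dyn, state48, seed = s)$cells) == 0
  }, logical(1))
  expect_identical(sum(lost), 0L)
})

test_that("tag-loss fraction is self-consistent with exp(-beta_eff * n0)", {
  dyn <- strain_dynamics(q = 0.02, r = 0.7, c = 0.07, tau = 2)
  # per-cell lineage-survival probability measured from single-cell tags
  des1 <- inoculum_design(rep(1, 30), untagged_dose = 1e7)
  set.seed(101)
  surv <- unlist(lapply(1:800, function(i) {
    sim <- simulate_colonization(des1, dyn, state48, seed = NULL)
    sim$cells[sim$n0_drawn == 1] > 0   # condition on exactly one cell
  }))
  beta_eff <- mean(surv)
  se_beta <- sqrt(beta_eff * (1 - beta_eff) / length(surv))

  # tag-loss fraction at n0 = 30
  des30 <- inoculum_design(rep(30, 6), untagged_dose = 1e7)
  set.seed(202)
  lost <- unlist(lapply(1:400, function(i) {
    simulate_colonization(des30, dyn, state48, seed = NULL)$cells == 0
  }))
  p_obs <- mean(lost)
  p_pred <- exp(-beta_eff * 30)
  se_obs <- sqrt(p_obs * (1 - p_obs) / length(lost))
  se_pred <- 30 * p_pred * se_beta
  expect_lt(abs(p_obs - p_pred), 3 * sqrt(se_obs^2 + se_pred^2))
})

test_that("hybrid and pure-Gillespie runs agree in endpoint mean", {
  # small niche so the full stochastic run is feasible
  st <- competition_state(K = 1e4, t_tot = 30)
  des <- inoculum_design(3)
  dyn <- strain_dynamics(q = 1, r = 0.5, c = 0.1, tau = 0)
  ends <- function(switch_size, seed0) {
    vapply(seq_len(1000), function(i) {
      sum(simulate_colonization(des, dyn, st, seed = seed0 + i,
                                switch_size = switch_size)$cells)
    }, 0)
  }
  hybrid <- ends(200, 1000)
  pure <- ends(Inf, 5000)
  expect_lt(abs(mean(hybrid) - mean(pure)) / mean(pure), 0.05)
})

test_that("identical dynamics give a competitive index centred on 1", {
  # two barcoded strains with the same parameters, measured as pooled
  # endpoint ratios across replicate mice
  des <- inoculum_design(rep(100, 3), untagged_dose = 1e7)
  dyn <- strain_dynamics(q = 0.5, r = 0.7, c = 0.07, tau = 2)
  set.seed(33)
  ci <- vapply(1:60, function(i) {
    a <- sum(simulate_colonization(des, dyn, state48, seed = NULL)$cells)
    b <- sum(simulate_colonization(des, dyn, state48, seed = NULL)$cells)
    a / b
  }, 0)
  lci <- log(ci)
  expect_lt(abs(mean(lci)), 3 * sd(lci) / sqrt(length(lci)))
})

test_that("challenge windows behave at their limits", {
  pre <- c(2e9, 1e9, 5e8)
  expect_identical(simulate_challenge(pre, 0.12, 0.3, 0, seed = 1), pre)
  # clearance equal to baseline turnover: critical process, no tag loss
  # at realistic clone sizes
  post <- simulate_challenge(rep(1e9, 50), 0.12, 0.12, 72, seed = 2)
  expect_true(all(post > 0))
  expect_error(simulate_challenge(pre, -1, 0.1, 10), ">= 0")
  expect_error(simulate_challenge(c(-5, 1), 0.1, 0.1, 10), "nonnegative")
})

test_that("challenge tag loss inverts the binomial survival law", {
  # pick the death rate so one cell's lineage survives with probability
  # beta* satisfying (1 - beta*)^2000 = 0.5, then check half the tags die
  b <- 0.12; dur <- 72
  beta_star <- 1 - 0.5^(1 / 2000)
  d <- uniroot(function(d) {
    1 - extinction_probability_bd(b, d, dur) - beta_star
  }, c(b, 2))$root
  post <- simulate_challenge(rep(2000, 600), b, d, dur, seed = 9)
  frac_lost <- mean(post == 0)
  expect_lt(abs(frac_lost - 0.5), 3 * sqrt(0.25 / 600))
})

test_that("measurement reconstructs truth exactly in noise-free mode", {
  mm0 <- measurement_model(qpcr_cv = 0, poisson_noise = FALSE,
                           detection_limit = 1)
  truth <- c(4e5, 3e5, 2e5, 1e5)
  meas <- apply_measurement(truth, mm0)
  expect_equal(meas$cfu_per_g, truth)
  expect_false(any(meas$censored))

  # all-zero population: everything censored
  z <- apply_measurement(rep(0, 6), measurement_model())
  expect_true(all(z$plate_counts == 0))
  expect_true(all(z$censored))
  expect_error(apply_measurement(numeric(0), measurement_model()), "empty")
})

test_that("dilution plating is unbiased across replicates", {
  mm <- measurement_model(dilution_factors = 10^(1:5), qpcr_cv = 0)
  D <- 2e6
  set.seed(55)
  est <- vapply(seq_len(1e4), function(i) {
    apply_measurement(D, mm)$total_cfu_per_g
  }, 0)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - D), 3 * se)
})

test_that("cohorts are reproducible and tidily shaped", {
  des <- inoculum_design(rep(30, 6), untagged_dose = 1e7)
  dyn <- strain_dynamics(q = 0.05, r = 0.7, c = 0.07, tau = 2)
  a <- simulate_cohort(des, dyn, state48, n_mice = 3, seed = 5)
  b <- simulate_cohort(des, dyn, state48, n_mice = 3, seed = 5)
  expect_identical(a, b)
  expect_identical(nrow(a), 18L)
  expect_identical(names(a), c("mouse_id", "strain", "barcode",
                               "n0_intended", "n0_drawn", "cfu_per_g",
                               "censored"))
})
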