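#' Fit a lag/exponential/plateau growth curve to censored CFU data
#'
#' Fits the piecewise model
#' \eqn{N(t) = \min(K,\; N_a e^{net \cdot \max(0, t-\tau)})}
#' to a longitudinal CFU/g time course by least squares on the log10 scale.
#' Censored observations (below the detection limit) enter through a
#' one-sided penalty: the fitted curve must lie at or below the detection
#' limit there, and any excess is penalized quadratically. The lag is
#' profiled over a deterministic grid and the best candidate is polished by
#' a joint quasi-Newton refinement, so the fit is fully deterministic given
#' the data.
#'
#' @param times sampling times (hr), strictly increasing.
#' @param cfu_per_g observed densities (CFU/g); censored entries may be 0.
#' @param censored logical vector (default: `cfu_per_g` below
#'   `detection_limit`).
#' @param detection_limit detection limit (CFU/g) used for the censoring
#'   penalty; required when any point is censored.
#' @param K optional fixed plateau; `NULL` (default) estimates it jointly,
#'   falling back to the maximum observed density when the plateau is not
#'   identifiable.
#' @return an object of class `growth_fit` with components `net`, `tau`,
#'   `K`, `N_arrival`, `sigma` (residual SD, log10), `convergence`,
#'   `K_fixed`, and the data used.
#' @seealso [simulate_time_course()] for generating test data;
#'   [predict.growth_fit()], [plot.growth_fit()]
#' @export
fit_growth_curve <- function(times, cfu_per_g, censored = NULL,
                             detection_limit = NULL, K = NULL) {
  if (is.data.frame(times)) {  # accept a simulate_time_course() frame
    df <- times
    if (is.null(detection_limit)) {
      detection_limit <- attr(df, "detection_limit")
    }
    times <- df$time_hr
    cfu_per_g <- df$cfu_per_g
    censored <- df$censored
  }
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (is.null(censored)) {
    censored <- if (is.null(detection_limit)) rep(FALSE, length(times))
                else cfu_per_g < detection_limit
  }
  if (any(censored) && is.null(detection_limit)) {
    stop("'detection_limit' is required when observations are censored")
  }
  unc <- !censored
  if (!any(unc)) stop("no uncensored observations: nothing to fit")
  if (sum(unc) < 4) {
    warning("fewer than 4 uncensored points: parameters weakly identified")
  }
  y <- log10(cfu_per_g[unc])
  tu <- times[unc]
  ymax <- max(y)
  if (diff(range(y)) < 0.5) {
    stop("all uncensored points lie at the plateau: net growth rate is ",
         "not identifiable")
  }
  ldl <- if (any(censored)) log10(detection_limit) else -Inf
  tc <- times[censored]

  model_log10 <- function(la, net, tau, lk, t) {
    pmin(lk, la + net / log(10) * pmax(0, t - tau))
  }
  obj <- function(par) {
    m <- model_log10(par[1], par[2], par[3], par[4], tu)
    ss <- sum((y - m)^2)
    if (length(tc)) {
      mc <- model_log10(par[1], par[2], par[3], par[4], tc)
      ss <- ss + sum(pmax(0, mc - ldl)^2)
    }
    ss
  }

  K_fixed <- !is.null(K)
  lk0 <- if (K_fixed) log10(K) else ymax
  # crude slope-based initial net from the steepest rise
  slopes <- diff(y) / diff(tu)
  net0 <- max(max(slopes, na.rm = TRUE) * log(10), 0.05)
  tau_grid <- seq(0, max(tu[which.max(y)], 1), length.out = 25)

  best <- NULL
  for (tau0 in tau_grid) {
    la0 <- min(y) - net0 / log(10) * max(0, tu[which.min(y)] - tau0)
    par0 <- c(la0, net0, tau0, lk0)
    lower <- c(-20, -5, 0, ymax - 0.5)
    upper <- c(lk0 + 2, 10, max(times), 20)
    if (K_fixed) { lower[4] <- lk0; upper[4] <- lk0 }
    fit <- tryCatch(
      nlminb(par0, obj, lower = lower, upper = upper,
             control = list(rel.tol = 1e-14, x.tol = 1e-12,
                            iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$objective < best$objective)) best <- fit
  }
  if (is.null(best)) stop("growth-curve fit failed to converge")

  par <- best$par
  # plateau identifiability: if the fitted K escaped above the data there
  # was no plateau information; pin it to the maximum observed density.
  k_identifiable <- K_fixed ||
    any(y > par[4] - 0.1) # some point within 0.1 log10 of the plateau
  if (!k_identifiable) {
    par[4] <- ymax
    fit2 <- nlminb(par, function(p) obj(c(p[1], p[2], p[3], par[4])),
                   lower = c(-20, -5, 0), upper = c(par[4] + 2, 10,
                                                    max(times)))
    # refit the free parameters with K pinned
    par <- c(fit2$par[1:3], par[4])
    best$objective <- fit2$objective
    K_fixed <- TRUE
  }

  n_unc <- sum(unc)
  dof <- max(1, n_unc - 4 + K_fixed)
  structure(
    list(net = par[2], tau = par[3], K = 10^par[4],
         N_arrival = 10^par[1],
         sigma = sqrt(best$objective / dof),
         convergence = best$convergence == 0,
         K_fixed = K_fixed, rss = best$objective,
         times = times, cfu_per_g = cfu_per_g, censored = censored,
         detection_limit = if (is.finite(ldl)) 10^ldl else NA_real_),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Lag/exponential/plateau growth fit\n")
  cat(sprintf("  net growth rate: %.4g /hr\n", x$net))
  cat(sprintf("  lag tau:         %.4g hr\n", x$tau))
  cat(sprintf("  plateau K:       %.4g CFU/g%s\n", x$K,
              if (x$K_fixed) " (fixed)" else ""))
  cat(sprintf("  arrival density: %.4g CFU/g\n", x$N_arrival))
  cat(sprintf("  residual SD (log10): %.3g; converged: %s\n",
              x$sigma, x$convergence))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(net = object$net, tau = object$tau, K = object$K,
    N_arrival = object$N_arrival)
}

#' @export
summary.growth_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Predicted densities from a growth fit
#'
#' @param object a `growth_fit`.
#' @param newdata optional vector of times (hr); defaults to the fitted
#'   times.
#' @param ... unused.
#' @return predicted CFU/g at the requested times.
#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times else as.numeric(newdata)
  pmin(object$K,
       object$N_arrival * exp(object$net * pmax(0, t - object$tau)))
}

#' @export
residuals.growth_fit <- function(object, ...) {
  unc <- !object$censored
  log10(object$cfu_per_g[unc]) -
    log10(predict(object, object$times[unc]))
}

#' Simulate replicate time courses from a fitted growth curve
#'
#' @param object a `growth_fit`.
#' @param nsim number of replicate time courses.
#' @param seed optional integer seed.
#' @param times sampling times (defaults to the fitted times).
#' @param mm a [measurement_model()] governing plating noise.
#' @param ... unused.
#' @return list of `nsim` data frames as from [simulate_time_course()].
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL,
                                times = NULL, mm = measurement_model(),
                                ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(times)) times <- object$times
  replicate(nsim,
            simulate_time_course(object$net, object$tau, object$K,
                                 object$N_arrival, times, mm),
            simplify = FALSE)
}

#' Plot a growth fit
#'
#' @param x a `growth_fit`.
#' @param ... passed to [plot()].
#' @export
plot.growth_fit <- function(x, ...) {
  unc <- !x$censored
  yl <- range(log10(pmax(x$cfu_per_g[unc], 1)), log10(x$K))
  plot(x$times[unc], log10(x$cfu_per_g[unc]),
       xlab = "time (hr)", ylab = "log10 CFU/g", ylim = yl, pch = 19, ...)
  tt <- seq(min(x$times), max(x$times), length.out = 200)
  lines(tt, log10(predict(x, tt)), col = "steelblue", lwd = 2)
  if (any(x$censored) && !is.na(x$detection_limit)) {
    abline(h = log10(x$detection_limit), lty = 3)
    points(x$times[x$censored], rep(log10(x$detection_limit),
                                    sum(x$censored)), pch = 6)
  }
  invisible(x)
}

#' Analytic competitive index of the two-strain colonization model
#'
#' Under the shared-logistic competition model (equal replication rates,
#' clearance during the lag, growth gated by the common saturation factor)
#' the endpoint abundance ratio of the two strains is
#' \deqn{CI = \frac{q_w}{q_a}
#'   \exp\{(net_w + c_w)(\tau_a - \tau_w)\}
#'   \exp\{(net_w - net_a)\, t_{tot}\},}
#' which grows with experiment duration whenever the wildtype's net rate
#' exceeds the mutant's. The formula is exact whenever the total population
#' is far below carrying capacity during the lag-difference window.
#'
#' @param wt,ac [strain_dynamics()] for the wildtype (numerator) and the
#'   competitor (denominator).
#' @param t_tot experiment duration (hr), must exceed both lags.
#' @return predicted competitive index.
#' @seealso [solve_competition()] for the numerical two-strain solver.
#' @export
predict_competitive_index <- function(wt, ac, t_tot) {
  stopifnot(inherits(wt, "strain_dynamics"),
            inherits(ac, "strain_dynamics"))
  if (!is.finite(t_tot) || t_tot <= max(wt$tau, ac$tau)) {
    stop("'t_tot' must exceed both lags")
  }
  (wt$q / ac$q) *
    exp((wt$net + wt$c) * (ac$tau - wt$tau)) *
    exp((wt$net - ac$net) * t_tot)
}

#' Numerical two-strain competition solver
#'
#' Integrates the deterministic competition ODEs
#' \deqn{\dot A = 1_{t>\tau_a} r_a A (1 - (A+W)/K) - c_a A}
#' (and the analogous equation for `W`) with `deSolve`, starting from the
#' post-bottleneck inocula \eqn{q_i N_{0,i}}.
#'
#' @param wt,ac [strain_dynamics()] for the two strains.
#' @param state a [competition_state()].
#' @param N0_wt,N0_ac inoculated CFU of each strain (before early killing).
#' @param n_steps output time resolution.
#' @return data frame with columns `time`, `W`, `A`; the endpoint ratio
#'   `W/A` is attached as attribute `"endpoint_ratio"`.
#' @export
solve_competition <- function(wt, ac, state, N0_wt, N0_ac,
                              n_steps = 400) {
  stopifnot(inherits(state, "competition_state"))
  if (state$K <= 0) stop("'K' must be > 0")
  y0 <- c(W = wt$q * N0_wt, A = ac$q * N0_ac)
  if (any(y0 <= 0)) stop("both strains need a positive starting population")
  rhs <- function(t, y, parms) {
    B <- sum(y) / state$K
    dW <- (t > wt$tau) * wt$r * y[1] * (1 - B) - wt$c * y[1]
    dA <- (t > ac$tau) * ac$r * y[2] * (1 - B) - ac$c * y[2]
    list(c(dW, dA))
  }
  times <- seq(0, state$t_tot, length.out = n_steps + 1)
  sol <- deSolve::ode(y0, times, rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-6)
  out <- data.frame(time = sol[, 1], W = sol[, 2], A = sol[, 3])
  attr(out, "endpoint_ratio") <- out$W[nrow(out)] / out$A[nrow(out)]
  out
}

#' Extinction probability of a linear birth-death lineage
#'
#' Closed-form probability that a lineage started from a single cell, with
#' per-capita birth rate `birth` and death rate `death`, is extinct by time
#' `t`. Critical case (`birth == death` = d): \eqn{dt/(1+dt)}.
#'
#' @param birth,death per-capita rates (1/hr), >= 0.
#' @param t elapsed time (hr), >= 0. May be a vector.
#' @return extinction probability in \[0, 1\].
#' @examples
#' extinction_probability_bd(0.12, 0.22, 24)
#' @export
extinction_probability_bd <- function(birth, death, t) {
  if (birth < 0 || death < 0) stop("rates must be >= 0")
  if (any(t < 0)) stop("'t' must be >= 0")
  vapply(t, function(tt) {
    if (tt == 0 || death == 0) return(0)
    if (abs(birth - death) < 1e-12) {
      death * tt / (1 + death * tt)
    } else {
      ert <- exp((birth - death) * tt)
      unname(death * (ert - 1) / (birth * ert - death))
    }
  }, 0)
}

#' Colonization probability under competition
#'
#' In a competition experiment the single-colonization probability
#' `beta_single` of the focal (slower) strain is further reduced by loss
#' after the wildtype fills the niche: once the bulk population reaches
#' carrying capacity (time \eqn{t_K}, defined as the wildtype trajectory
#' attaining 95% of K), every focal lineage behaves as a linear birth-death
#' process with birth rate `c_w` (replication compensating bulk clearance)
#' and death rate `c_a`, and only lineages escaping extinction by
#' \eqn{t_{tot}} remain countable. Hence
#' \deqn{\beta_{comp} = \beta_{single} \times
#'       [1 - p_{ext}(c_w, c_a, t_{tot} - t_K)].}
#'
#' @param beta_single single-colonization probability, in (0, 1\].
#' @param wt,ac [strain_dynamics()] of the bulk (wildtype) and focal
#'   strains; `ac$c < wt$c` triggers a warning (supercritical survival,
#'   still valid).
#' @param state a [competition_state()].
#' @param N0_wt wildtype inoculum size (CFU) used to locate \eqn{t_K}
#'   (default `1e7`).
#' @return list with `beta_comp`, `decline_factor`, `t_K`.
#' @export
predict_competition_beta <- function(beta_single, wt, ac, state,
                                     N0_wt = 1e7) {
  if (beta_single <= 0 || beta_single > 1) {
    stop("'beta_single' must lie in (0, 1]")
  }
  stopifnot(inherits(state, "competition_state"))
  if (ac$c < wt$c) {
    warning("focal clearance below bulk clearance: lineage growth is ",
            "supercritical after saturation")
  }
  W0 <- wt$q * N0_wt
  target <- 0.95 * state$K * max(wt$net, 1e-12) / max(wt$r, 1e-12)
  f <- function(t) bulk_density(t, W0, wt$r, wt$c, wt$tau, state$K) - target
  t_K <- if (f(state$t_tot) < 0) {
    state$t_tot   # never saturates within the experiment
  } else {
    uniroot(f, c(wt$tau, state$t_tot), tol = 1e-10)$root
  }
  surv <- 1 - extinction_probability_bd(wt$c, ac$c, state$t_tot - t_K)
  list(beta_comp = beta_single * surv, decline_factor = surv, t_K = t_K)
}

#' Cecal turnover rate from gut physiology
#'
#' Three-step arithmetic: the wet mass excreted per day is the dry fecal
#' excretion inflated by the cecal water fraction (assuming minimal change
#' in dry mass during colon transit), and dividing by the wet cecal content
#' mass gives the number of cecal volumes turned over per day (and per
#' hour). This flow rate is a lower bound on the per-capita clearance rate
#' of a non-adherent bacterium in the cecum.
#'
#' @param phys a [gut_physiology()].
#' @return list with `wet_excretion` (g/day), `turnover_per_day`
#'   (volumes/day) and `turnover_per_hr` (volumes/hr).
#' @examples
#' cecal_turnover(gut_physiology(0.809, 1.55, 2.83))  # germ-free: 0.12/hr
#' @export
cecal_turnover <- function(phys) {
  stopifnot(inherits(phys, "gut_physiology"))
  wet_excretion <- phys$dry_excretion / (1 - phys$water_fraction)
  per_day <- wet_excretion / phys$wet_cecal_mass
  list(wet_excretion = wet_excretion,
       turnover_per_day = per_day,
       turnover_per_hr = per_day / 24)
}
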