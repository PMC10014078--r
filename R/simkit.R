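#' Draw a Poisson inoculum
#'
#' Draws the realised per-barcode cell counts of one gavage dose. Because
#' each barcode occupies a vanishing volume fraction of the prepared
#' suspension, the count delivered to an animal is Poisson-distributed
#' around the intended spike-in mean.
#'
#' @param design an [inoculum_design()].
#' @param seed optional integer seed (set for reproducibility; `NULL` uses
#'   the current RNG stream).
#' @return named integer vector of drawn cell counts, one per barcode.
#' @examples
#' draw_inoculum(inoculum_design(rep(30, 6)), seed = 1)
#' @export
draw_inoculum <- function(design, seed = NULL) {
  stopifnot(inherits(design, "inoculum_design"))
  if (!is.null(seed)) set.seed(seed)
  setNames(rpois(length(design$barcode_means), design$barcode_means),
           design$labels)
}

## Deterministic bulk/total population trajectory: clearance-only decline
## during the lag, then logistic growth with clearance. Closed form of
##   dW/dt = r W (1 - W/K) - c W   (t > tau),
## whose effective capacity is K (r - c) / r.
bulk_density <- function(t, W0, r, c, tau, K) {
  out <- numeric(length(t))
  if (W0 <= 0) return(out)
  lagging <- t <= tau
  out[lagging] <- W0 * exp(-c * t[lagging])
  if (any(!lagging)) {
    Wt0 <- W0 * exp(-c * tau)
    dt <- t[!lagging] - tau
    net <- r - c
    if (abs(net) > 1e-12) {
      Keff <- K * net / r
      out[!lagging] <- Keff / (1 + (Keff / Wt0 - 1) * exp(-net * dt))
    } else if (r > 0) {
      out[!lagging] <- 1 / (1 / Wt0 + (r / K) * dt)
    } else {
      out[!lagging] <- Wt0
    }
  }
  out
}

## Tabulate the per-capita birth rate b(t) = r (1 - B(t)/K) of a tagged
## strain against the mean-field total density B(t), together with the
## running maximum (thinning bound) and cumulative integral used by the
## hybrid simulator.
birth_rate_tables <- function(dyn, state, B0, bulk_dyn, grid_n = 2001) {
  t_tot <- state$t_tot
  grid_t <- seq(0, max(t_tot, 1e-9), length.out = grid_n)
  B <- bulk_density(grid_t, B0, bulk_dyn$r, bulk_dyn$c, bulk_dyn$tau, state$K)
  b <- pmax(0, dyn$r * (1 - B / state$K))
  b[grid_t < dyn$tau] <- 0
  b_runmax <- rev(cummax(rev(b)))
  dt <- diff(grid_t)
  cumb <- c(0, cumsum((b[-1] + b[-length(b)]) / 2 * dt))
  list(grid_t = grid_t, b = b, b_runmax = b_runmax, cumb = cumb, B = B)
}

#' Simulate colonization of one animal
#'
#' Forward-simulates the colonization model for a single animal: per-barcode
#' cell counts are drawn Poisson around the spike-in means, each cell
#' independently survives stomach/small-intestine transit with probability
#' `q`, and each surviving founder lineage waits out the lag `tau` (dying at
#' rate `c`) before growing by a continuous-time birth-death process with
#' per-capita birth rate \eqn{r (1 - B(t)/K)} and death rate `c`. The shared
#' saturation term uses a deterministic mean-field total \eqn{B(t)} seeded
#' from the untagged bulk dose plus the expected tagged biomass (tagged
#' clones are a negligible population fraction in all study designs).
#' Clones are simulated stochastically while small and switched to
#' deterministic growth above `switch_size` cells, where extinction risk is
#' negligible.
#'
#' @param design an [inoculum_design()].
#' @param dyn a [strain_dynamics()] for the barcoded strain.
#' @param state a [competition_state()]; `state$K` must be > 0 and
#'   `state$t_tot` >= 0.
#' @param seed optional integer seed.
#' @param bulk_dyn a [strain_dynamics()] for the untagged bulk (defaults to
#'   `dyn`, i.e. untagged cells of the same strain).
#' @param switch_size clone size at which the stochastic simulation hands
#'   over to deterministic growth (default `1e4`); `Inf` forces a pure
#'   Gillespie run.
#' @param grid_n number of time-grid points for the tabulated rates.
#' @return a data frame with one row per barcode and columns `barcode`,
#'   `n0_intended`, `n0_drawn`, `founders`, `cells` (endpoint cell count) and
#'   `cfu_per_g`. The deterministic bulk endpoint density is attached as
#'   attribute `"bulk_cfu_per_g"`.
#' @export
simulate_colonization <- function(design, dyn, state, seed = NULL,
                                  bulk_dyn = dyn, switch_size = 1e4,
                                  grid_n = 2001) {
  stopifnot(inherits(design, "inoculum_design"),
            inherits(dyn, "strain_dynamics"),
            inherits(state, "competition_state"))
  if (!is.null(seed)) set.seed(seed)

  n0_drawn <- rpois(length(design$barcode_means), design$barcode_means)
  founders <- rbinom(length(n0_drawn), n0_drawn, dyn$q)

  # mean-field total population: untagged bulk plus expected tagged biomass
  B0 <- bulk_dyn$q * design$untagged_dose + dyn$q * sum(design$barcode_means)
  tab <- birth_rate_tables(dyn, state, B0, bulk_dyn, grid_n)

  cells <- simulate_clones_cpp(as.integer(founders), dyn$tau, dyn$c,
                               tab$grid_t, tab$b, tab$b_runmax, tab$cumb,
                               state$t_tot, switch_size)

  bulk_end <- bulk_density(state$t_tot, bulk_dyn$q * design$untagged_dose,
                           bulk_dyn$r, bulk_dyn$c, bulk_dyn$tau, state$K)
  out <- data.frame(barcode = design$labels,
                    n0_intended = design$barcode_means,
                    n0_drawn = n0_drawn,
                    founders = founders,
                    cells = cells,
                    cfu_per_g = cells / state$cecal_mass,
                    stringsAsFactors = FALSE)
  attr(out, "bulk_cfu_per_g") <- bulk_end / state$cecal_mass
  out
}

#' Simulate a cohort of animals
#'
#' Runs [simulate_colonization()] for `n_mice` independent animals and,
#' when a [measurement_model()] is supplied, passes each animal's endpoint
#' populations through [apply_measurement()] so the output mimics a real
#' plating + qPCR dataset. Per-mouse RNG substreams are derived from the
#' master seed (one `sample.int(.Machine$integer.max, n_mice)` draw under
#' `set.seed(seed)`), so any mouse can be re-simulated in isolation.
#'
#' @inheritParams simulate_colonization
#' @param mm a [measurement_model()] or `NULL` for noise-free truth (a
#'   barcode is then censored only when its lineage is extinct).
#' @param n_mice number of animals.
#' @param seed master integer seed.
#' @param strain label stored in the `strain` column.
#' @return tidy data frame with one row per (mouse, barcode) and columns
#'   `mouse_id`, `strain`, `barcode`, `n0_intended`, `n0_drawn`,
#'   `cfu_per_g`, `censored`.
#' @export
simulate_cohort <- function(design, dyn, state, mm = measurement_model(),
                            n_mice = 15, seed = 1, bulk_dyn = dyn,
                            strain = "tagged", switch_size = 1e4) {
  stopifnot(n_mice >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_mice)
  rows <- vector("list", n_mice)
  for (m in seq_len(n_mice)) {
    set.seed(sub_seeds[m])
    sim <- simulate_colonization(design, dyn, state, seed = NULL,
                                 bulk_dyn = bulk_dyn,
                                 switch_size = switch_size)
    if (is.null(mm)) {
      cfu <- sim$cfu_per_g
      censored <- cfu <= 0
    } else {
      meas <- apply_measurement(sim$cfu_per_g, mm, seed = NULL)
      cfu <- meas$cfu_per_g
      censored <- meas$censored
    }
    rows[[m]] <- data.frame(mouse_id = sprintf("m%03d", m),
                            strain = strain,
                            barcode = sim$barcode,
                            n0_intended = sim$n0_intended,
                            n0_drawn = sim$n0_drawn,
                            cfu_per_g = cfu,
                            censored = censored,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

## Endpoint law of a linear birth-death process started from one cell:
## extinction probability alpha(t) and the geometric tail parameter eta(t)
## (conditional on survival, the size is Geometric on {1,2,...} with
## success probability 1 - eta).
bd_endpoint_law <- function(birth, death, t) {
  if (t <= 0) return(list(alpha = 0, eta = if (birth > 0) 0 else 0))
  if (birth == 0 && death == 0) return(list(alpha = 0, eta = 0))
  if (abs(birth - death) < 1e-12) {
    a <- birth * t / (1 + birth * t)
    return(list(alpha = a, eta = a))
  }
  rho <- birth - death
  ert <- exp(rho * t)
  alpha <- death * (ert - 1) / (birth * ert - death)
  eta <- birth * (ert - 1) / (birth * ert - death)
  list(alpha = alpha, eta = eta)
}

#' Simulate a post-colonization challenge window
#'
#' Models a transient challenge (for example enteric inflammation) applied
#' to a population sitting at carrying capacity. During the window every
#' cell dies at the elevated clearance rate `challenge_clearance` while
#' replication stays capped at the pre-challenge turnover rate `birth`, so
#' the total population declines as the net of the two. Each pre-challenge
#' cell's lineage is an independent linear birth-death process; clone
#' endpoints are drawn from the exact endpoint law (binomial number of
#' surviving founder lineages, geometric lineage sizes), which is fast for
#' arbitrarily large clones.
#'
#' @param pre_pops integer-like vector of pre-challenge clone sizes (cells).
#' @param birth per-capita replication rate during the challenge (1/hr);
#'   at carrying capacity this equals the baseline clearance rate.
#' @param challenge_clearance per-capita death rate during the challenge
#'   (1/hr).
#' @param duration challenge duration (hr).
#' @param seed optional integer seed.
#' @return numeric vector of post-challenge clone sizes (0 = clone lost).
#' @export
simulate_challenge <- function(pre_pops, birth, challenge_clearance,
                               duration, seed = NULL) {
  pre_pops <- as.numeric(pre_pops)
  if (any(pre_pops < 0) || anyNA(pre_pops)) {
    stop("'pre_pops' must be nonnegative")
  }
  if (birth < 0 || challenge_clearance < 0) stop("rates must be >= 0")
  if (duration < 0) stop("'duration' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (duration == 0) return(pre_pops)
  law <- bd_endpoint_law(birth, challenge_clearance, duration)
  vapply(round(pre_pops), function(n0) {
    if (n0 == 0) return(0)
    k <- rbinom(1, n0, 1 - law$alpha)
    if (k == 0) return(0)
    # sum of k geometric({1,2,...}; 1 - eta) sizes
    k + rnbinom(1, size = k, prob = 1 - law$eta)
  }, 0)
}

#' Apply the measurement model to true densities
#'
#' Turns a vector of true per-barcode densities into the observable readout:
#' the pooled barcoded density is measured by serial-dilution plating
#' (Poisson colony counts, countable window, detection limit) and the
#' barcode relative frequencies by qPCR (multiplicative log-normal noise of
#' the stated CV, calling floor, renormalization). Reconstructed per-barcode
#' densities are frequency times total, with a censored flag where the
#' reconstruction falls below the detection limit.
#'
#' @param true_populations numeric vector of true densities (CFU/g), one
#'   entry per barcode (length 1 is allowed for single-strain plating).
#' @param mm a [measurement_model()].
#' @param seed optional integer seed.
#' @return list with elements `total_cfu_per_g` (estimated pooled density;
#'   0 when below detection), `frequencies` (qPCR frequencies after noise,
#'   floor and renormalization), `cfu_per_g` (reconstructed per-barcode
#'   densities), `censored` (logical), `plate_counts` and
#'   `dilutions_used`.
#' @export
apply_measurement <- function(true_populations, mm, seed = NULL) {
  stopifnot(inherits(mm, "measurement_model"))
  true_populations <- as.numeric(true_populations)
  if (length(true_populations) == 0L) {
    stop("empty population vector")
  }
  if (any(true_populations < 0) || anyNA(true_populations)) {
    stop("'true_populations' must be nonnegative")
  }
  if (!is.null(seed)) set.seed(seed)

  D <- sum(true_populations)
  means <- D / mm$dilution_factors
  counts <- if (mm$poisson_noise) rpois(length(means), means) else means
  usable <- counts >= mm$min_countable_colonies &
    counts <= mm$max_countable_colonies

  if (any(usable)) {
    D_hat <- sum(counts[usable]) / sum(1 / mm$dilution_factors[usable])
    used <- mm$dilution_factors[usable]
  } else if (all(counts < mm$min_countable_colonies)) {
    D_hat <- 0 # below detection
    used <- numeric(0)
  } else {
    # every plate a lawn: fall back to the most dilute plate
    i <- length(counts)
    D_hat <- counts[i] * mm$dilution_factors[i]
    used <- mm$dilution_factors[i]
  }

  # qPCR relative frequencies
  if (D > 0) {
    f <- true_populations / D
    if (mm$qpcr_cv > 0) {
      sdlog <- sqrt(log(1 + mm$qpcr_cv^2))
      f <- f * rlnorm(length(f), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    f[f < mm$qpcr_floor] <- 0
    f <- if (sum(f) > 0) f / sum(f) else f
  } else {
    f <- numeric(length(true_populations))
  }

  cfu <- D_hat * f
  censored <- cfu < mm$detection_limit
  cfu[censored] <- 0
  list(total_cfu_per_g = D_hat,
       frequencies = f,
       cfu_per_g = cfu,
       censored = censored,
       plate_counts = counts,
       dilutions_used = used)
}

#' Simulate a longitudinal CFU time course
#'
#' Generates fecal-density observations from the lag/exponential/plateau
#' growth model \eqn{N(t) = \min(K, N_a e^{net \cdot \max(0, t - \tau)})},
#' measured at each time point by dilution plating (no qPCR step; a single
#' strain is tracked). Densities below the detection limit are censored.
#'
#' @param net net growth rate (1/hr).
#' @param tau lag before exponential growth (hr).
#' @param K plateau density (CFU/g).
#' @param N_arrival effective density at growth onset (CFU/g).
#' @param times sampling times (hr).
#' @param mm a [measurement_model()] or `NULL` for noise-free values.
#' @param seed optional integer seed.
#' @return a data frame with columns `time_hr`, `cfu_per_g`, `censored`,
#'   plus attribute `"detection_limit"`.
#' @export
simulate_time_course <- function(net, tau, K, N_arrival, times,
                                 mm = measurement_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- pmin(K, N_arrival * exp(net * pmax(0, times - tau)))
  if (is.null(mm)) {
    cfu <- truth
    censored <- rep(FALSE, length(times))
    dl <- 0
  } else {
    cfu <- numeric(length(times))
    censored <- logical(length(times))
    for (i in seq_along(times)) {
      meas <- apply_measurement(truth[i], mm, seed = NULL)
      cfu[i] <- meas$total_cfu_per_g
      censored[i] <- meas$total_cfu_per_g < mm$detection_limit
      if (censored[i]) cfu[i] <- 0
    }
    dl <- mm$detection_limit
  }
  out <- data.frame(time_hr = times, cfu_per_g = cfu, censored = censored)
  attr(out, "detection_limit") <- dl
  out
}
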