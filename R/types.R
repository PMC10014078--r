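#' Inoculum design
#'
#' Describes the intended composition of a gavage inoculum: the expected
#' number of cells of each neutral barcode (the spike-in means \eqn{n_0}) and
#' the dose of the untagged bulk strain they are spiked into. Actual
#' per-barcode cell numbers in a prepared dose are Poisson-distributed around
#' these means, because the barcodes are a vanishing volume fraction of the
#' prepared suspension.
#'
#' @param barcode_means numeric vector of expected CFU per barcode
#'   (\eqn{n_0}, cells). All entries must be >= 0.
#' @param untagged_dose expected CFU of the untagged competitor strain
#'   delivered alongside the barcodes (default 0).
#' @param labels optional barcode labels; defaults to `"BC1"`, `"BC2"`, ...
#' @return an object of class `inoculum_design`.
#' @examples
#' inoculum_design(rep(30, 6), untagged_dose = 1e7)
#' @export
inoculum_design <- function(barcode_means, untagged_dose = 0, labels = NULL) {
  barcode_means <- as.numeric(barcode_means)
  if (length(barcode_means) < 1L || anyNA(barcode_means)) {
    stop("'barcode_means' must be a non-empty numeric vector without NAs")
  }
  if (any(barcode_means < 0)) {
    stop("negative barcode mean: spike-in means must be >= 0")
  }
  if (!is.numeric(untagged_dose) || length(untagged_dose) != 1L ||
      is.na(untagged_dose) || untagged_dose < 0) {
    stop("'untagged_dose' must be a single number >= 0")
  }
  if (is.null(labels)) labels <- paste0("BC", seq_along(barcode_means))
  if (length(labels) != length(barcode_means)) {
    stop("'labels' must match 'barcode_means' in length")
  }
  structure(
    list(barcode_means = barcode_means,
         untagged_dose = as.numeric(untagged_dose),
         labels = as.character(labels)),
    class = "inoculum_design")
}

#' @export
print.inoculum_design <- function(x, ...) {
  cat("Inoculum design:", length(x$barcode_means), "barcodes\n")
  cat("  spike-in means (CFU):",
      paste(format(x$barcode_means, trim = TRUE), collapse = ", "), "\n")
  cat("  untagged dose (CFU): ", format(x$untagged_dose), "\n", sep = "")
  invisible(x)
}

#' Strain dynamics parameters
#'
#' Per-strain parameters of the colonization model: an instantaneous
#' early-survival probability `q` applied to each inoculated cell during
#' stomach/small-intestine transit, then (after a lag `tau` during which cells
#' are cleared but do not divide) logistic growth at replication rate `r`
#' against a clearance rate `c`. Only the net rate `r - c` is identifiable
#' from total-CFU time courses; `c` can be anchored independently via
#' [cecal_turnover()].
#'
#' @param q early-survival probability per cell, in \[0, 1\].
#' @param r replication rate (1/hr), >= 0.
#' @param c clearance rate (1/hr), >= 0 (fecal flow plus death).
#' @param tau lag before exponential growth (hr), >= 0.
#' @return an object of class `strain_dynamics` with derived field
#'   `net = r - c`.
#' @examples
#' strain_dynamics(q = 0.03, r = 0.62, c = 0.12, tau = 3.2)
#' @export
strain_dynamics <- function(q = 1, r = 0.5, c = 0, tau = 0) {
  for (nm in c("q", "r", "c", "tau")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("'%s' must be a single finite number", nm))
    }
  }
  if (q < 0 || q > 1) stop("'q' must lie in [0, 1]")
  if (r < 0) stop("'r' must be >= 0")
  if (c < 0) stop("'c' must be >= 0")
  if (tau < 0) stop("'tau' must be >= 0")
  structure(list(q = q, r = r, c = c, tau = tau, net = r - c),
            class = "strain_dynamics")
}

#' @export
print.strain_dynamics <- function(x, ...) {
  cat(sprintf(
    "Strain dynamics: q = %g, r = %g /hr, c = %g /hr, tau = %g hr (net = %g /hr)\n",
    x$q, x$r, x$c, x$tau, x$net))
  invisible(x)
}

#' Shared competition state
#'
#' Environment-level constants of a colonization experiment: the cecal
#' carrying capacity, the experiment duration, and the wet mass of cecal
#' content used to convert absolute cell numbers to CFU per gram.
#'
#' @param K carrying capacity (CFU/g), > 0. Default `1e10`, the typical
#'   dense-colonization cecal density.
#' @param t_tot experiment duration (hr), >= 0. Default 48.
#' @param cecal_mass wet mass of cecal content (g), > 0. Default 1, so that
#'   cell counts and CFU/g coincide numerically.
#' @return an object of class `competition_state`.
#' @export
competition_state <- function(K = 1e10, t_tot = 48, cecal_mass = 1) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0) {
    stop("'K' must be a single number > 0")
  }
  if (!is.numeric(t_tot) || length(t_tot) != 1L || is.na(t_tot) || t_tot < 0) {
    stop("'t_tot' must be a single number >= 0")
  }
  if (!is.numeric(cecal_mass) || length(cecal_mass) != 1L ||
      is.na(cecal_mass) || cecal_mass <= 0) {
    stop("'cecal_mass' must be a single number > 0")
  }
  structure(list(K = K, t_tot = t_tot, cecal_mass = cecal_mass),
            class = "competition_state")
}

#' @export
print.competition_state <- function(x, ...) {
  cat(sprintf("Competition state: K = %g CFU/g, t_tot = %g hr, cecal mass = %g g\n",
              x$K, x$t_tot, x$cecal_mass))
  invisible(x)
}

#' Measurement model for plating and qPCR readouts
#'
#' Describes how true bacterial densities are turned into observations:
#' serial-dilution plating with Poisson colony counts and a countable-plate
#' window, a detection limit below which a barcode is reported as censored,
#' and multiplicative qPCR noise on barcode relative frequencies with a
#' calling floor below which a frequency is set to zero.
#'
#' @param dilution_factors numeric vector of dilution factors (each plate
#'   receives density / factor expected colonies). Default `10^(0:5)`.
#' @param min_countable_colonies plates with fewer colonies are discarded
#'   (default 30).
#' @param max_countable_colonies plates with more colonies are discarded as
#'   uncountable lawns (default 300).
#' @param detection_limit density (CFU/g) below which a barcode is reported
#'   censored. Default 30 (one countable plate at the lowest dilution).
#' @param qpcr_cv coefficient of variation of the multiplicative
#'   relative-frequency noise (default 0.1); 0 means noise-free frequencies.
#' @param qpcr_floor relative frequencies below this are set to 0 before
#'   renormalization (default 1e-4, the approximate qPCR calling limit over a
#'   five-order dynamic range).
#' @param poisson_noise logical; `FALSE` turns plate counts into exact
#'   expected values (useful for noise-free identity checks).
#' @return an object of class `measurement_model`.
#' @export
measurement_model <- function(dilution_factors = 10^(0:5),
                              min_countable_colonies = 30,
                              max_countable_colonies = 300,
                              detection_limit = 30,
                              qpcr_cv = 0.1,
                              qpcr_floor = 1e-4,
                              poisson_noise = TRUE) {
  dilution_factors <- sort(as.numeric(dilution_factors))
  if (length(dilution_factors) < 1L || any(dilution_factors <= 0)) {
    stop("'dilution_factors' must be positive")
  }
  if (detection_limit <= 0) stop("'detection_limit' must be > 0")
  if (qpcr_cv < 0) stop("'qpcr_cv' must be >= 0")
  if (qpcr_floor < 0 || qpcr_floor >= 1) stop("'qpcr_floor' must lie in [0, 1)")
  if (min_countable_colonies < 1 ||
      max_countable_colonies < min_countable_colonies) {
    stop("countable-colony window is empty")
  }
  structure(
    list(dilution_factors = dilution_factors,
         min_countable_colonies = min_countable_colonies,
         max_countable_colonies = max_countable_colonies,
         detection_limit = detection_limit,
         qpcr_cv = qpcr_cv,
         qpcr_floor = qpcr_floor,
         poisson_noise = isTRUE(poisson_noise)),
    class = "measurement_model")
}

#' @export
print.measurement_model <- function(x, ...) {
  cat("Measurement model:\n")
  cat("  dilutions:", paste(format(x$dilution_factors, trim = TRUE),
                            collapse = ", "), "\n")
  cat(sprintf("  countable window: %g-%g colonies; detection limit %g CFU/g\n",
              x$min_countable_colonies, x$max_countable_colonies,
              x$detection_limit))
  cat(sprintf("  qPCR: CV = %g, calling floor = %g, plating noise %s\n",
              x$qpcr_cv, x$qpcr_floor,
              if (x$poisson_noise) "on" else "off"))
  invisible(x)
}

#' Gut physiology measurements
#'
#' The three measurements needed to infer the cecal turnover (flow clearance)
#' rate: the water fraction of cecal content, the dry fecal mass excreted per
#' day, and the wet mass of cecal content.
#'
#' @param water_fraction water fraction of cecal content, in \[0, 1).
#'   Accepts percentages > 1 and rescales them (80.9 is read as 0.809).
#' @param dry_excretion dry fecal excretion (g/day), > 0.
#' @param wet_cecal_mass wet cecal content mass (g), > 0.
#' @return an object of class `gut_physiology`.
#' @seealso [cecal_turnover()]
#' @export
gut_physiology <- function(water_fraction, dry_excretion, wet_cecal_mass) {
  if (water_fraction > 1 && water_fraction < 100) {
    water_fraction <- water_fraction / 100
  }
  if (water_fraction < 0 || water_fraction >= 1) {
    stop("'water_fraction' must lie in [0, 1)")
  }
  if (dry_excretion <= 0) stop("'dry_excretion' must be > 0")
  if (wet_cecal_mass <= 0) stop("'wet_cecal_mass' must be > 0")
  structure(list(water_fraction = water_fraction,
                 dry_excretion = dry_excretion,
                 wet_cecal_mass = wet_cecal_mass),
            class = "gut_physiology")
}

#' @export
print.gut_physiology <- function(x, ...) {
  cat(sprintf(
    "Gut physiology: water fraction %.3f, dry excretion %.3g g/day, wet cecal mass %.3g g\n",
    x$water_fraction, x$dry_excretion, x$wet_cecal_mass))
  invisible(x)
}
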