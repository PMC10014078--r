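## Likelihood building blocks. Two observation models share one engine:
##  - "loss":      a barcode with spike-in mean n is lost with probability
##                 exp(-beta * n)   (Poisson founders, Eqns of the initial
##                 bottleneck model);
##  - "challenge": a barcode carried by exactly n cells at challenge start is
##                 lost with probability (1 - beta)^n (independent lineage
##                 survival).
log_ploss <- function(beta, n, model) {
  switch(model,
         loss = -beta * n,
         challenge = n * log1p(-beta),
         stop("unknown model"))
}

log_pkeep <- function(beta, n, model) {
  log1p(-exp(log_ploss(beta, n, model)))
}

tag_loglik <- function(beta, n, lost, model) {
  sum(lost * log_ploss(beta, n, model) +
        (1 - lost) * log_pkeep(beta, n, model))
}

## Analytic score dLL/dbeta, used to polish the golden-section maximum to
## near machine precision.
tag_score <- function(beta, n, lost, model) {
  if (model == "loss") {
    e <- exp(-beta * n)
    sum(lost * (-n) + (1 - lost) * n * e / (1 - e))
  } else {
    p <- (1 - beta)^n
    sum(lost * (-n / (1 - beta)) +
          (1 - lost) * n * (1 - beta)^(n - 1) / (1 - p))
  }
}

new_beta_est <- function(beta_hat, ci_low, ci_high, method,
                         bound_type = "two-sided", loglik = NA_real_,
                         n_obs = NA_integer_, degenerate = FALSE,
                         extra = list()) {
  structure(c(list(beta_hat = beta_hat, ci_low = ci_low, ci_high = ci_high,
                   method = method, bound_type = bound_type,
                   loglik = loglik, n_obs = n_obs, degenerate = degenerate),
              extra),
            class = "beta_est")
}

## Deterministic 1-d maximization of the tag log-likelihood over log(beta),
## followed by profile-likelihood interval construction (chi-square(1)
## cutoffs: drop of 1.92 two-sided, 1.35 one-sided).
profile_engine <- function(n, lost, model, method_label) {
  upper <- if (model == "challenge") 1 - 1e-12 else 1
  f <- function(lb) tag_loglik(exp(lb), n, lost, model)
  opt <- optimize(f, interval = c(log(1e-9), log(upper)),
                  maximum = TRUE, tol = 1e-10)
  bhat <- exp(opt$maximum)
  # polish with the analytic score when the maximum is interior
  lo_b <- bhat * 0.9
  hi_b <- min(upper, bhat * 1.1)
  s_lo <- tag_score(lo_b, n, lost, model)
  s_hi <- tag_score(hi_b, n, lost, model)
  if (is.finite(s_lo) && is.finite(s_hi) && s_lo > 0 && s_hi < 0) {
    bhat <- uniroot(function(b) tag_score(b, n, lost, model),
                    c(lo_b, hi_b), tol = 1e-16)$root
  }
  llmax <- tag_loglik(bhat, n, lost, model)
  target <- llmax - 1.92

  g <- function(b) tag_loglik(b, n, lost, model) - target
  # lower end: log-likelihood -> -Inf as beta -> 0 when any tag is retained
  lo <- uniroot(function(lb) g(exp(lb)), c(log(1e-14), log(bhat)),
                tol = 1e-14)$root
  ci_low <- exp(lo)
  # upper end: may run into the domain boundary beta = 1
  if (g(upper) > 0) {
    ci_high <- 1
  } else {
    ci_high <- uniroot(g, c(bhat, upper), tol = 1e-14)$root
  }
  new_beta_est(bhat, ci_low, ci_high, method_label,
               bound_type = "two-sided", loglik = llmax,
               n_obs = length(n))
}

validate_tag_loss <- function(table) {
  if (!is.data.frame(table)) stop("'table' must be a data frame")
  need <- c("n0", "lost")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(table) < 1L) stop("empty tag-loss table")
  if (any(!is.finite(table$n0)) || any(table$n0 <= 0)) {
    stop("'n0' must be positive")
  }
  l <- as.numeric(table$lost)
  if (!all(l %in% c(0, 1))) stop("'lost' must be 0/1 (or logical)")
  table$lost <- l
  table
}

#' Maximum-likelihood colonization probability from barcode loss
#'
#' Estimates the per-cell colonization probability \eqn{\beta} — the
#' probability that one inoculated cell founds a lineage still detectable at
#' the endpoint — from the pattern of lost and retained barcodes pooled
#' across animals and experiments. Each barcode observation contributes a
#' Bernoulli term with loss probability \eqn{e^{-\beta n_i}} where
#' \eqn{n_i} is its (possibly experiment-specific) spike-in mean; the
#' log-likelihood is maximized deterministically over \eqn{\log\beta} and a
#' 95% confidence interval is obtained by profile likelihood (log-likelihood
#' drop of 1.92). When every barcode shares the same \eqn{n_0} the MLE
#' coincides with the closed form \eqn{-\ln(\hat p_{loss})/n_0}.
#'
#' Degenerate loss patterns (all barcodes lost, or all retained) carry no
#' two-sided information; the call is delegated to [beta_bounds()], which
#' returns a one-sided estimate.
#'
#' @param table data frame with columns `n0` (spike-in mean per barcode
#'   observation, > 0) and `lost` (1/TRUE = barcode absent at endpoint);
#'   optional columns `barcode` and `mouse_id` are carried by helpers.
#' @return an object of class `beta_est` with fields `beta_hat`, `ci_low`,
#'   `ci_high`, `method`, `bound_type`, `loglik`, `n_obs`.
#' @seealso [beta_bounds()], [beta_variance()], [challenge_beta()],
#'   [leave_one_out()], [optimal_n0()]
#' @examples
#' tab <- data.frame(n0 = rep(100, 6), lost = c(1, 1, 1, 0, 0, 0))
#' beta_mle_loss(tab)   # log(2)/100
#' @export
beta_mle_loss <- function(table) {
  table <- validate_tag_loss(table)
  if (all(table$lost == 1) || all(table$lost == 0)) {
    return(beta_bounds(table))
  }
  profile_engine(table$n0, table$lost, "loss", "loss")
}

#' One-sided bounds for the colonization probability
#'
#' When every barcode is lost (or every barcode retained) the likelihood is
#' monotone in \eqn{\beta} and only a one-sided 95% bound is available, from
#' the one-sided likelihood-ratio criterion (log-likelihood drop of 1.35
#' from its supremum). All lost: \eqn{\beta \le 1.35/\sum n_i}. All
#' retained: the lower bound solves
#' \eqn{\sum \log(1 - e^{-\beta n_i}) = LL_{max} - 1.35}, which reduces to
#' the absolute criterion \eqn{\sum \log(1-e^{-\beta n_i}) = -1.35} when the
#' \eqn{n_i} are large.
#'
#' @inheritParams beta_mle_loss
#' @param model `"loss"` (colonization, Poisson founders) or `"challenge"`
#'   (binomial lineage survival of a known starting population).
#' @return a one-sided `beta_est` (`bound_type` `"upper-only"` or
#'   `"lower-only"`).
#' @export
beta_bounds <- function(table, model = c("loss", "challenge")) {
  model <- match.arg(model)
  table <- validate_tag_loss(table)
  n <- table$n0
  lost <- table$lost
  if (!(all(lost == 1) || all(lost == 0))) {
    stop("mixed loss pattern: use beta_mle_loss() for a two-sided estimate")
  }
  if (all(lost == 1)) {
    # likelihood is maximal at beta -> 0 where it equals 1
    g <- function(b) sum(log_ploss(b, n, model)) + 1.35
    up <- if (model == "loss") {
      1.35 / sum(n)
    } else {
      uniroot(g, c(1e-14, 1 - 1e-12), tol = 1e-14)$root
    }
    new_beta_est(0, 0, min(up, 1), model, bound_type = "upper-only",
                 loglik = 0, n_obs = length(n))
  } else {
    # likelihood is maximal at the domain boundary beta = 1
    upper <- if (model == "challenge") 1 - 1e-12 else 1
    llmax <- sum(log_pkeep(upper, n, model))
    g <- function(lb) sum(log_pkeep(exp(lb), n, model)) - (llmax - 1.35)
    lo <- exp(uniroot(g, c(log(1e-14), log(upper)), tol = 1e-14)$root)
    new_beta_est(1, lo, 1, model, bound_type = "lower-only",
                 loglik = llmax, n_obs = length(n))
  }
}

#' Colonization probability from barcode-proportion variance
#'
#' Estimates \eqn{\beta} from the drift of barcode proportions rather than
#' outright loss. For each animal the excess of the endpoint proportion
#' variance over the inoculum proportion variance is scaled to the relative
#' variance contributed by a single founding cell,
#' \eqn{v_m = h \sum n_{j,0} (\mathrm{var}(p) - \mathrm{var}(p_0))},
#' which under the bottleneck-plus-stochastic-growth model has expectation
#' \eqn{2/\beta}. The estimator is \eqn{\hat\beta = 2/\bar v}; the 95%
#' interval comes from the standard error of \eqn{\bar v} transformed
#' through the monotone map \eqn{x \mapsto 2/x}.
#'
#' Animals that lost every barcode carry no proportion information and are
#' dropped (counted in `n_dropped`). A nonpositive mean excess variance
#' (no measurable drift) yields a degenerate lower-only bound clamped at
#' \eqn{\beta \le 1}.
#'
#' @param p matrix of endpoint barcode proportions, one row per animal, one
#'   column per barcode (rows summing to 1; all-zero rows allowed and
#'   dropped). At least 2 animals and 2 barcodes.
#' @param total_inoculum total barcoded inoculum \eqn{\sum n_{j,0}} (cells).
#' @param p0 inoculum proportions (default: uniform design, variance 0).
#' @return a `beta_est` with extra fields `var_one_founder` (mean
#'   \eqn{v_m}), `var_se` and `n_dropped`.
#' @export
beta_variance <- function(p, total_inoculum, p0 = NULL) {
  p <- as.matrix(p)
  h <- ncol(p)
  if (h < 2) stop("need at least 2 barcodes (h >= 2)")
  if (nrow(p) < 2) stop("need at least 2 animals")
  if (total_inoculum <= 0) stop("'total_inoculum' must be > 0")
  var0 <- if (is.null(p0)) 0 else var(as.numeric(p0))

  keep <- rowSums(p) > 0
  n_dropped <- sum(!keep)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 2) stop("fewer than 2 animals with surviving barcodes")
  p <- p / rowSums(p)

  v <- apply(p, 1, var)                      # var around the row mean 1/h
  vm <- h * total_inoculum * (v - var0)
  vbar <- mean(vm)
  se <- sd(vm) / sqrt(length(vm))

  if (vbar <= 0) {
    lo <- if (vbar + 1.96 * se > 0) min(1, 2 / (vbar + 1.96 * se)) else 0
    return(new_beta_est(1, lo, 1, "variance", bound_type = "lower-only",
                        n_obs = length(vm), degenerate = TRUE,
                        extra = list(var_one_founder = vbar, var_se = se,
                                     n_dropped = n_dropped)))
  }
  bhat <- min(1, 2 / vbar)
  ci_low <- min(1, 2 / (vbar + 1.96 * se))
  hi_edge <- vbar - 1.96 * se
  ci_high <- if (hi_edge > 0) min(1, 2 / hi_edge) else 1
  new_beta_est(bhat, ci_low, ci_high, "variance",
               bound_type = if (hi_edge > 0) "two-sided" else "upper-open",
               n_obs = length(vm),
               extra = list(var_one_founder = vbar, var_se = se,
                            n_dropped = n_dropped))
}

#' Leave-one-barcode-out sensitivity analysis
#'
#' Re-estimates \eqn{\beta} excluding each barcode in turn, to detect a
#' non-neutral barcode (for example one under selection) that drags the
#' pooled estimate. Under neutrality no exclusion should move the estimate
#' outside the full-data confidence interval.
#'
#' @param table tag-loss data frame with columns `barcode`, `n0`, `lost`.
#' @return data frame with one row per excluded barcode and columns
#'   `excluded`, `beta_hat`, `ci_low`, `ci_high`, `bound_type`.
#' @export
leave_one_out <- function(table) {
  table <- validate_tag_loss(table)
  if (!"barcode" %in% names(table)) stop("'table' needs a 'barcode' column")
  bcs <- unique(table$barcode)
  if (length(bcs) < 2) stop("need at least 2 distinct barcodes")
  rows <- lapply(bcs, function(bc) {
    est <- beta_mle_loss(table[table$barcode != bc, , drop = FALSE])
    data.frame(excluded = bc, beta_hat = est$beta_hat,
               ci_low = est$ci_low, ci_high = est$ci_high,
               bound_type = est$bound_type, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recommended spike-in size for a target colonization probability
#'
#' The loss-based estimator is most robust when roughly half of the
#' barcodes are lost, giving \eqn{n_0 = \ln 2/\beta}. For reference the
#' Fisher-information optimum of a single Bernoulli loss observation,
#' maximizing \eqn{x^2/(e^x - 1)} over \eqn{x = \beta n_0}, is also
#' reported (\eqn{x^* \approx 1.594}, i.e. about 20% of tags lost).
#'
#' @param beta_guess anticipated colonization probability, in (0, 1\].
#' @return list with `n0_half_loss`, `n0_fisher` and the Fisher optimum
#'   `x_star`.
#' @examples
#' optimal_n0(10^-1.5)   # about 22 cells per barcode
#' @export
optimal_n0 <- function(beta_guess) {
  if (!is.numeric(beta_guess) || length(beta_guess) != 1L ||
      is.na(beta_guess) || beta_guess <= 0 || beta_guess > 1) {
    stop("'beta_guess' must lie in (0, 1]")
  }
  # stationarity of x^2 / (e^x - 1):  2 (1 - e^-x) = x
  x_star <- uniroot(function(x) 2 * (1 - exp(-x)) - x, c(1, 2),
                    tol = 1e-12)$root
  list(n0_half_loss = log(2) / beta_guess,
       n0_fisher = x_star / beta_guess,
       x_star = x_star)
}

#' Lineage-survival probability through a challenge
#'
#' Estimates the probability \eqn{\beta} that a single cell present at the
#' start of a challenge (for example Salmonella-induced inflammation) has a
#' lineage still detectable afterwards. A barcode carried by \eqn{n_0}
#' cells is lost with probability \eqn{(1-\beta)^{n_0}}; the likelihood is
#' maximized and profiled exactly as in [beta_mle_loss()]. With equal
#' \eqn{n_0} the MLE has the closed form
#' \eqn{\hat\beta = 1 - \hat p_{loss}^{1/n_0}}.
#'
#' @param n0 per-barcode cell numbers at challenge start (>= 1); `NA`
#'   entries (barcodes below detection before the challenge) are excluded.
#' @param lost 1/TRUE where the barcode is absent after the challenge.
#' @return a `beta_est` (method `"challenge"`).
#' @examples
#' challenge_beta(rep(2000, 12), rep(c(1, 0), 6))  # 1 - 0.5^(1/2000)
#' @export
challenge_beta <- function(n0, lost) {
  keep <- !is.na(n0)
  n0 <- n0[keep]
  lost <- as.numeric(lost[keep])
  if (length(n0) < 1) stop("no usable barcode observations")
  if (any(n0 < 1)) stop("'n0' must be >= 1")
  if (!all(lost %in% c(0, 1))) stop("'lost' must be 0/1")
  if (all(lost == 1) || all(lost == 0)) {
    return(beta_bounds(data.frame(n0 = n0, lost = lost),
                       model = "challenge"))
  }
  profile_engine(n0, lost, "challenge", "challenge")
}

#' Estimate pre-challenge cecal cell numbers from day-0 feces
#'
#' Converts day-0 fecal barcode densities into absolute cecal cell numbers,
#' using the average feces-to-cecum concentration relationship measured in
#' control animals and the wet cecal content mass:
#' \eqn{n_0 = \mathrm{CFU/g}_{feces} \times ratio \times mass}, rounded to
#' the nearest integer and at least 1 for any detected barcode. Barcodes
#' below detection are returned as `NA` and must be excluded from the
#' challenge likelihood.
#'
#' @param fecal_cfu_per_g day-0 fecal per-barcode densities (CFU/g).
#' @param cecum_feces_ratio control-arm cecum:feces concentration ratio
#'   (> 0).
#' @param wet_cecal_mass wet cecal content mass (g, > 0).
#' @return integer vector of estimated cell numbers (`NA` = below
#'   detection).
#' @examples
#' estimate_day0_n0(c(500, 100, 0), 2, 2.83)
#' @export
estimate_day0_n0 <- function(fecal_cfu_per_g, cecum_feces_ratio,
                             wet_cecal_mass) {
  if (missing(cecum_feces_ratio) || is.null(cecum_feces_ratio) ||
      missing(wet_cecal_mass) || is.null(wet_cecal_mass)) {
    stop("control-arm data (cecum:feces ratio, cecal mass) are required")
  }
  if (cecum_feces_ratio <= 0 || wet_cecal_mass <= 0) {
    stop("ratio and mass must be > 0")
  }
  fecal_cfu_per_g <- as.numeric(fecal_cfu_per_g)
  if (any(fecal_cfu_per_g < 0, na.rm = TRUE)) stop("negative CFU density")
  n0 <- round(fecal_cfu_per_g * cecum_feces_ratio * wet_cecal_mass)
  detected <- !is.na(fecal_cfu_per_g) & fecal_cfu_per_g > 0
  n0[detected] <- pmax(1, n0[detected])
  n0[!detected] <- NA_integer_
  as.integer(n0)
}

## ---- beta_est methods ------------------------------------------------

#' @export
print.beta_est <- function(x, ...) {
  cat(sprintf("Colonization probability estimate (%s method)\n", x$method))
  if (x$bound_type == "two-sided") {
    cat(sprintf("  beta = %.4g  [95%% CI %.4g - %.4g]\n",
                x$beta_hat, x$ci_low, x$ci_high))
  } else {
    cat(sprintf("  %s bound: beta %s %.4g\n",
                x$bound_type,
                if (x$bound_type == "upper-only") "<=" else ">=",
                if (x$bound_type == "upper-only") x$ci_high else x$ci_low))
  }
  cat(sprintf("  n = %d barcode observations\n", x$n_obs))
  if (isTRUE(x$degenerate)) cat("  (degenerate: no measurable drift)\n")
  invisible(x)
}

#' @export
summary.beta_est <- function(object, ...) {
  out <- unclass(object)
  if (object$bound_type == "two-sided" && object$beta_hat > 0) {
    out$log10_beta <- log10(object$beta_hat)
    half <- (log10(object$ci_high) - log10(object$ci_low)) / 2
    out$log10_sd <- half / 1.96
  }
  class(out) <- "summary.beta_est"
  out
}

#' @export
print.summary.beta_est <- function(x, ...) {
  print.beta_est(structure(x, class = "beta_est"))
  if (!is.null(x$log10_beta)) {
    cat(sprintf("  log10(beta) = %.2f +/- %.2f (2 SD)\n",
                x$log10_beta, 2 * x$log10_sd))
  }
  invisible(x)
}

#' @export
coef.beta_est <- function(object, ...) {
  c(beta = object$beta_hat)
}

#' @export
confint.beta_est <- function(object, parm = "beta", level = 0.95, ...) {
  if (level != 0.95) {
    warning("profile intervals are computed at the 95% level only")
  }
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("beta", c("2.5 %", "97.5 %")))
}

#' @export
logLik.beta_est <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n_obs, class = "logLik")
}
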