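ct_log <- function(level, ...) {
  if (isTRUE(getOption("clonetrace.quiet", FALSE))) return(invisible())
  message(sprintf("[%s] %s", level, paste0(...)))
}

## Polynomial rolling hash of a character representation; used only to
## fingerprint a configuration in reports.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

endpoint_required_cols <- c("mouse_id", "barcode", "n0_intended",
                            "cfu_per_g", "censored")

#' Read a per-mouse per-barcode endpoint table
#'
#' Reads a tidy CSV with one row per (mouse, barcode) — the format written
#' by [simulate_cohort()] / [run_pipeline()] — validates it, and derives
#' the structures the estimators consume: a tag-loss table (loss indicators
#' from the censoring flags) and per-mouse endpoint summaries.
#'
#' Required columns: `mouse_id`, `barcode`, `n0_intended`, `cfu_per_g`,
#' `censored`. Malformed rows are reported with their file line numbers.
#'
#' @param path CSV file path.
#' @return list with `data` (the validated data frame), `tag_loss`
#'   (columns `mouse_id`, `barcode`, `n0`, `lost`), and `endpoints` (one
#'   entry per mouse: `mouse_id`, per-barcode `cfu_per_g`, `proportions`,
#'   `total`, `h`).
#' @export
read_endpoint_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(endpoint_required_cols, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  df$censored <- as.logical(df$censored)
  lines <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(!is.finite(df$cfu_per_g) | df$cfu_per_g < 0)
  if (length(bad)) {
    stop("negative or non-numeric cfu_per_g at line(s) ",
         paste(lines[bad], collapse = ", "))
  }
  bad <- which(!is.finite(df$n0_intended) | df$n0_intended <= 0)
  if (length(bad)) {
    stop("nonpositive n0_intended at line(s) ",
         paste(lines[bad], collapse = ", "))
  }
  bad <- which(is.na(df$censored))
  if (length(bad)) {
    stop("unreadable censored flag at line(s) ",
         paste(lines[bad], collapse = ", "))
  }
  list(data = df,
       tag_loss = tag_loss_table(df),
       endpoints = endpoint_list(df))
}

#' Tag-loss table from a tidy cohort data frame
#'
#' @param df data frame with columns `mouse_id`, `barcode`, `n0_intended`,
#'   `censored`.
#' @return data frame with columns `mouse_id`, `barcode`, `n0`, `lost`
#'   suitable for [beta_mle_loss()].
#' @export
tag_loss_table <- function(df) {
  data.frame(mouse_id = df$mouse_id,
             barcode = df$barcode,
             n0 = df$n0_intended,
             lost = as.numeric(df$censored),
             stringsAsFactors = FALSE)
}

#' Per-mouse barcode proportion matrix
#'
#' @param df tidy cohort data frame (`mouse_id`, `barcode`, `cfu_per_g`).
#' @return matrix with one row per mouse and one column per barcode;
#'   rows of all-extinct mice are left as zeros.
#' @export
proportion_matrix <- function(df) {
  tab <- tapply(df$cfu_per_g, list(df$mouse_id, df$barcode), sum,
                default = 0)
  tot <- rowSums(tab)
  p <- tab
  pos <- tot > 0
  p[pos, ] <- tab[pos, , drop = FALSE] / tot[pos]
  p
}

endpoint_list <- function(df) {
  lapply(split(df, df$mouse_id), function(d) {
    total <- sum(d$cfu_per_g)
    list(mouse_id = d$mouse_id[1],
         barcode = d$barcode,
         cfu_per_g = d$cfu_per_g,
         proportions = if (total > 0) d$cfu_per_g / total
                       else numeric(nrow(d)),
         total = total,
         h = nrow(d))
  })
}

run_config_schema <- list(
  experiment = c("n_mice", "barcode_means", "untagged_dose"),
  strain = c("q", "r", "c", "tau"),
  state = c("K", "t_tot", "cecal_mass"),
  measurement = c("dilution_factors", "min_countable_colonies",
                  "max_countable_colonies", "detection_limit", "qpcr_cv",
                  "qpcr_floor", "poisson_noise"),
  seed = NULL)

#' Read a simulation/estimation run configuration
#'
#' Reads a YAML configuration describing a complete in-silico experiment
#' (inoculum design, strain dynamics, environment, measurement model,
#' seed). Unknown keys are rejected so typos cannot silently change a run.
#' The configuration round-trips losslessly through
#' [write_run_config()].
#'
#' @param path YAML file path.
#' @return named list (classed `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(run_config_schema))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (section in names(run_config_schema)) {
    allowed <- run_config_schema[[section]]
    if (is.null(allowed) || is.null(cfg[[section]])) next
    unknown <- setdiff(names(cfg[[section]]), allowed)
    if (length(unknown)) {
      stop("unknown key(s) in '", section, "': ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' @param cfg a configuration list as returned by [read_run_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Default demonstration configuration
#'
#' A cohort of 15 mice, six barcodes at the half-loss spike-in for a true
#' colonization probability of 0.03, on top of an untagged bulk dose of
#' 1e7 CFU.
#'
#' @return a `run_config` list.
#' @export
default_run_config <- function() {
  structure(list(
    experiment = list(n_mice = 15, barcode_means = rep(23, 6),
                      untagged_dose = 1e7),
    strain = list(q = 0.03, r = 0.62, c = 0, tau = 3.2),
    state = list(K = 1e10, t_tot = 48, cecal_mass = 1),
    measurement = list(detection_limit = 30, qpcr_cv = 0.1),
    seed = 1), class = "run_config")
}

config_objects <- function(cfg) {
  ex <- cfg$experiment
  st <- cfg$state
  me <- cfg$measurement
  mm_args <- me[!vapply(me, is.null, TRUE)]
  list(design = inoculum_design(ex$barcode_means,
                                untagged_dose = ex$untagged_dose %||% 0),
       dyn = do.call(strain_dynamics, cfg$strain),
       state = competition_state(K = st$K %||% 1e10,
                                 t_tot = st$t_tot %||% 48,
                                 cecal_mass = st$cecal_mass %||% 1),
       mm = do.call(measurement_model, mm_args),
       n_mice = ex$n_mice %||% 15)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulate-measure-quantify-estimate pipeline
#'
#' Executes a full in-silico experiment from a configuration: simulates a
#' cohort, applies the measurement model, writes the tidy endpoint CSV,
#' re-reads it through the validating reader, and estimates the
#' colonization probability with both the loss and the variance method.
#' A JSON report with the estimates, seeds, package version and a
#' configuration fingerprint is written alongside.
#'
#' @param cfg a `run_config` (default [default_run_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; defaults to `cfg$seed`.
#' @return invisibly, a list with `cohort`, `beta_loss`, `beta_variance`,
#'   `report` and the output paths.
#' @export
run_pipeline <- function(cfg = default_run_config(), out_dir = tempdir(),
                         seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (!inherits(cfg, "run_config")) {
    stop("pipeline stage 'config' failed: not a run_config")
  }
  seed <- seed %||% cfg$seed %||% 1
  obj <- stage("config", config_objects(cfg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ct_log("INFO", "simulating cohort (seed ", seed, ", n_mice ",
         obj$n_mice, ")")
  cohort <- stage("simulate",
                  simulate_cohort(obj$design, obj$dyn, obj$state, obj$mm,
                                  n_mice = obj$n_mice, seed = seed))
  csv_path <- file.path(out_dir, "cohort.csv")
  stage("write", write.csv(cohort, csv_path, row.names = FALSE))

  parsed <- stage("read", read_endpoint_table(csv_path))
  est_loss <- stage("estimate-loss", beta_mle_loss(parsed$tag_loss))
  est_var <- stage("estimate-variance", {
    p <- proportion_matrix(parsed$data)
    beta_variance(p, sum(obj$design$barcode_means))
  })

  report <- list(
    provenance = list(package = "clonetrace",
                      version = as.character(packageVersion("clonetrace")),
                      r_version = R.version.string,
                      seed = seed,
                      config_hash = fnv1a(unclass(cfg))),
    beta_loss = est_loss[c("beta_hat", "ci_low", "ci_high", "bound_type",
                           "n_obs")],
    beta_variance = est_var[c("beta_hat", "ci_low", "ci_high",
                              "bound_type", "n_obs")])
  report_path <- file.path(out_dir, "report.json")
  stage("report",
        jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE))
  ct_log("INFO", "report written to ", report_path)
  invisible(list(cohort = cohort, beta_loss = est_loss,
                 beta_variance = est_var, report = report,
                 paths = list(cohort = csv_path, report = report_path)))
}
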