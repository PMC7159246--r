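property_columns <- function() {
  c("ultimate_force_N", "ultimate_stress_MPa", "stiffness_N_mm",
    "elastic_modulus_MPa", "work_to_failure_mJ", "strain_at_failure",
    "relative_stress_relaxation", "csa_mm2")
}

summary_pairs <- function() {
  list(c("C", "GP"), c("Col", "ColGP"), c("C", "Col"), c("C", "ColGP"))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the full study pipeline: group sizes, loading
#' protocol, per-group material parameters, spectral and calibration
#' generator settings, the stiffness window and analysis-range mode, the
#' Dunn adjustment, the spatial design distances and the master seed. Every
#' random stage derives its seed deterministically from `seed` (traces:
#' `seed`, spectral: `seed + 1`, calibration: `seed + 2`).
#'
#' @param seed Master integer seed (< 2^31 - 2).
#' @param out_dir Output directory for the report tables, or `NULL` to skip
#'   writing.
#' @param n_per_group Named group sizes; default the study's 25/25/45/45.
#' @param protocol A [loading_protocol()].
#' @param material Named list of [tendon_material_params()].
#' @param spectral A [spatial_profile_params()].
#' @param n_spectral_per_group Tendons per group in the spectral assay.
#' @param calibration List of [generate_calibration_samples()] arguments
#'   (levels, n_per_level, n_zero, beta0, beta1, noise_sd).
#' @param window,range_mode Stiffness estimation settings (see
#'   [stiffness_max_gradient()]).
#' @param dunn_adjustment `"none"` or `"holm"`.
#' @param distances Spatial design distances, mm.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = NULL,
                            n_per_group = reference_group_sizes(),
                            protocol = loading_protocol(),
                            material = default_material_params(protocol),
                            spectral = spatial_profile_params(),
                            n_spectral_per_group = 9L,
                            calibration = default_calibration_params(),
                            window = NULL,
                            range_mode = c("ramp_only", "from_preload_end"),
                            dunn_adjustment = c("none", "holm"),
                            distances = c(3, 9, 15)) {
  range_mode <- match.arg(range_mode)
  dunn_adjustment <- match.arg(dunn_adjustment)
  if (!is.numeric(seed) || seed != round(seed) || abs(seed) > 2^31 - 10)
    stop("seed must be an integer below 2^31")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_per_group = n_per_group, protocol = protocol,
                 material = material, spectral = spectral,
                 n_spectral_per_group = n_spectral_per_group,
                 calibration = calibration, window = window,
                 range_mode = range_mode, dunn_adjustment = dunn_adjustment,
                 distances = distances),
            class = "pipeline_config")
}

config_checksum <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 251 + 1)) %% 2^31)
}

#' Group summary of a per-specimen properties table
#'
#' Builds the study-style summary: for every property and every group
#' pairing (control, treated), the two group medians with ranges, the
#' percent difference of the medians, the Dunn pairwise p-value, and the
#' Kruskal-Wallis omnibus statistic over all four groups. The percent-
#' difference column always equals [median_percent_difference()] applied to
#' the two median columns.
#'
#' @param properties Per-specimen properties data.frame (from
#'   [extract_all()] rows or [extract_cohort_properties()]).
#' @param dunn_adjustment Passed to [dunn_pairwise()].
#' @return data.frame, one row per property x pairing.
#' @export
summarize_properties <- function(properties, dunn_adjustment = "none") {
  need <- group_labels()
  have <- unique(properties$group)
  if (!all(need %in% have))
    stop("properties table missing group(s): ",
         paste(setdiff(need, have), collapse = ", "))
  pairs <- summary_pairs()
  rows <- list()
  for (prop in property_columns()) {
    groups <- split(properties[[prop]], factor(properties$group, levels = need))
    kw <- kruskal_wallis(groups)
    dn <- dunn_pairwise(groups, pairs = pairs, adjustment = dunn_adjustment)
    med <- vapply(groups, stats::median, numeric(1))
    lo <- vapply(groups, min, numeric(1))
    hi <- vapply(groups, max, numeric(1))
    for (i in seq_along(pairs)) {
      a <- pairs[[i]][1]; b <- pairs[[i]][2]
      rows[[length(rows) + 1L]] <- data.frame(
        property = prop, control = a, treated = b,
        median_control = med[[a]], min_control = lo[[a]], max_control = hi[[a]],
        median_treated = med[[b]], min_treated = lo[[b]], max_treated = hi[[b]],
        percent_difference = median_percent_difference(med[[b]], med[[a]]),
        p_dunn = dn$p_adj[i], H_kruskal = kw$H, p_kruskal = kw$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full study pipeline
#'
#' Executes simulate -> extract -> stats -> spatial -> calibrate -> report on
#' synthetic data drawn under the configuration. Specimens are generated and
#' extracted one at a time (traces are not retained). Progress, versions,
#' the configuration checksum and per-stage counts are logged to stderr;
#' results are returned (and optionally written as CSV) only.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `study_report`: list with `properties`,
#'   `group_summary`, `spatial_coefficients`, `spatial_drops`,
#'   `calibration_fit`, `concentrations`, `concentration_summary`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  log_ <- function(...) message("[tendonmech] ", sprintf(...))
  log_("R %s, tendonmech %s", getRversion(),
       as.character(utils::packageVersion("tendonmech")))
  log_("seed %d, config checksum %s", config$seed, config_checksum(config))

  properties <- run_stage("simulate", {
    p <- extract_cohort_properties(config$material, config$n_per_group,
                                   config$protocol, seed = config$seed,
                                   window = config$window,
                                   range_mode = config$range_mode)
    log_("simulate+extract: %d specimens", nrow(p))
    p
  })

  group_summary <- run_stage("stats", {
    s <- summarize_properties(properties, config$dunn_adjustment)
    log_("stats: %d summary rows", nrow(s))
    s
  })

  spatial <- run_stage("spatial", {
    samples <- generate_spectral_profiles(config$spectral,
                                          config$n_spectral_per_group,
                                          seed = config$seed + 1L)
    coefs <- list(); drops <- list()
    for (resp in c("fluorescence", "absorption")) {
      fit <- fit_spatial_model(samples, resp, config$distances)
      co <- fit$coefficients
      co <- data.frame(response = resp, co, stringsAsFactors = FALSE)
      coefs[[resp]] <- co
      for (g in c("GP", "ColGP")) {
        for (d in config$distances) {
          pd <- percent_drop(fit, g, d)
          drops[[length(drops) + 1L]] <- data.frame(
            response = resp, group = g, distance_mm = d,
            percent_drop = pd$percent, p = pd$p, stringsAsFactors = FALSE)
        }
      }
    }
    log_("spatial: %d biopsies, %d coefficients",
         nrow(samples), sum(vapply(coefs, nrow, integer(1))))
    list(samples = samples,
         coefficients = do.call(rbind, c(coefs, list(make.row.names = FALSE))),
         drops = do.call(rbind, c(drops, list(make.row.names = FALSE))))
  })

  calib <- run_stage("calibrate", {
    cal <- config$calibration
    tab <- generate_calibration_samples(levels = cal$levels,
                                        n_per_level = cal$n_per_level,
                                        n_zero = cal$n_zero,
                                        beta0 = cal$beta0, beta1 = cal$beta1,
                                        noise_sd = cal$noise_sd,
                                        seed = config$seed + 2L)
    fit <- fit_calibration(tab)
    treated <- spatial$samples[spatial$samples$group %in% c("GP", "ColGP"), ]
    est <- estimate_concentration(treated$fluorescence_au, fit)
    conc <- data.frame(specimen_id = treated$specimen_id, group = treated$group,
                       distance_mm = treated$distance_mm,
                       concentration_mM = est$concentration_mM,
                       below_detection = est$below_detection,
                       stringsAsFactors = FALSE)
    agg <- stats::aggregate(concentration_mM ~ group + distance_mm, data = conc,
                            FUN = function(v) c(mean = mean(v), se = stats::sd(v) / sqrt(length(v))),
                            na.action = stats::na.omit)
    csum <- data.frame(group = agg$group, distance_mm = agg$distance_mm,
                       mean_concentration_mM = agg$concentration_mM[, "mean"],
                       se_concentration_mM = agg$concentration_mM[, "se"],
                       stringsAsFactors = FALSE)
    csum <- csum[order(csum$group, csum$distance_mm), ]
    rownames(csum) <- NULL
    log_("calibrate: %d calibration samples, slope/%%=%.4f, adj R^2=%.3f",
         nrow(tab), slope_per_percent(fit), fit$r2_adj)
    list(fit = fit, concentrations = conc, summary = csum)
  })

  report <- structure(list(properties = properties,
                           group_summary = group_summary,
                           spatial_coefficients = spatial$coefficients,
                           spatial_drops = spatial$drops,
                           calibration_fit = calib$fit,
                           concentrations = calib$concentrations,
                           concentration_summary = calib$summary,
                           config = config),
                      class = "study_report")

  if (!is.null(config$out_dir)) {
    run_stage("report", {
      write_report(report, config$out_dir)
      log_("report: tables written to %s", config$out_dir)
    })
  }
  report
}

#' Write a study report's tables to a directory
#'
#' Emits `properties.csv`, `group_summary.csv`, `spatial_coefficients.csv`,
#' `spatial_drops.csv`, `concentrations.csv`, `concentration_summary.csv`
#' and a key-value `calibration_fit.txt`. Reruns with identical
#' configuration and seed are byte-identical.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "study_report")) stop("report must be a study_report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) data.table::fwrite(df, file.path(dir, f), sep = ",", dec = ".")
  w(report$properties, "properties.csv")
  w(report$group_summary, "group_summary.csv")
  w(report$spatial_coefficients, "spatial_coefficients.csv")
  w(report$spatial_drops, "spatial_drops.csv")
  w(report$concentrations, "concentrations.csv")
  w(report$concentration_summary, "concentration_summary.csv")
  fit <- report$calibration_fit
  kv <- c(sprintf("beta0=%.15g", fit$beta0),
          sprintf("beta1=%.15g", fit$beta1),
          sprintf("r2_adj=%.15g", fit$r2_adj),
          sprintf("n_used=%d", fit$n_used),
          sprintf("background_mean=%.15g", fit$background_mean),
          sprintf("slope_per_percent=%.15g", slope_per_percent(fit)))
  writeLines(kv, file.path(dir, "calibration_fit.txt"))
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n")
  tb <- table(factor(x$properties$group, levels = group_labels()))
  cat(sprintf("  specimens: %d (%s)\n", nrow(x$properties),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  uf <- x$group_summary[x$group_summary$property == "ultimate_force_N" &
                          x$group_summary$control == "Col" &
                          x$group_summary$treated == "ColGP", ]
  cat(sprintf("  ultimate force, degenerated: %.0f -> %.0f N (%+.0f%%, Dunn p = %.3g)\n",
              uf$median_control, uf$median_treated, uf$percent_difference, uf$p_dunn))
  cat(sprintf("  calibration: slope %.3f a.u./+1%%, adj R^2 = %.2f\n",
              slope_per_percent(x$calibration_fit), x$calibration_fit$r2_adj))
  cat(sprintf("  concentration summary rows: %d; spatial drops: %d\n",
              nrow(x$concentration_summary), nrow(x$spatial_drops)))
  invisible(x)
}
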