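#' Simulate one tensile test
#'
#' Generates a complete force-displacement-time trace following the loading
#' protocol (constant-stress preload, sinusoidal strain cycles, constant-rate
#' ramp to failure) under the toe-then-linear material law, together with the
#' generative ground truth needed for parameter-recovery testing.
#'
#' Cyclic peak forces decay over the cycle index n as
#' `peak(n) = p_inf + (p1 - p_inf) exp(-(n-1)/tau)` with
#' `p_inf = relaxation_fraction * p1`, so the first observed peak equals the
#' undecayed peak exactly. The ramp is truncated at the specimen's drawn
#' failure strain; a short post-rupture tail with collapsing force is
#' appended so the ultimate point is an interior maximum, as in recorded
#' machine data. Additive Gaussian force noise is applied throughout and
#' forces are floored at zero (load cells do not report tension as negative
#' here). Displacement carries no noise: it is the commanded machine
#' position.
#'
#' @param params A [tendon_material_params()].
#' @param protocol A [loading_protocol()].
#' @param seed Integer seed; `NULL` continues from the current RNG state.
#' @return A list with elements `trace` (a [load_trace()]) and `truth`
#'   (phase boundary indices, cycle boundaries, and the noise-free values of
#'   all seven extracted properties plus the per-specimen draws).
#' @export
generate_load_trace <- function(params, protocol = loading_protocol(), seed = NULL) {
  if (!inherits(params, "tendon_material_params")) stop("params must be tendon_material_params")
  if (!inherits(protocol, "loading_protocol")) stop("protocol must be a loading_protocol")
  if (!is.null(seed)) set.seed(seed)
  if (params$failure_strain_mean <= protocol$cycle_strain_amplitude)
    stop("failure_strain_mean must exceed cycle_strain_amplitude")

  fs <- protocol$sampling_rate
  dt <- 1 / fs
  L <- protocol$gauge_length
  k <- params$linear_stiffness
  xt <- params$toe_strain * L
  cc <- protocol$cycle_count

  csa <- max(1, stats::rnorm(1, params$csa_mean, params$csa_spread))
  s_fail <- max(protocol$cycle_strain_amplitude + 0.01,
                stats::rnorm(1, params$failure_strain_mean, params$failure_strain_spread))

  ## preload: hold the displacement that realizes the preload stress
  n_pre <- round(protocol$preload_duration * fs)
  f_pre <- protocol$preload_stress * csa
  x_pre <- invert_force_law(f_pre, k, xt)

  ## cyclic block
  n_cyc <- round(cc / protocol$cycle_frequency * fs)
  x_amp <- protocol$cycle_strain_amplitude * L
  peaks <- numeric(0)
  x_c <- f_c <- numeric(0)
  if (cc > 0 && n_cyc > 0) {
    t_c <- (0:(n_cyc - 1)) * dt
    x_c <- x_amp * (1 - cos(2 * pi * protocol$cycle_frequency * t_c)) / 2
    ci <- pmin(cc, floor(t_c * protocol$cycle_frequency + 1e-9) + 1L)
    p1 <- force_law(x_amp, k, xt)
    p_inf <- params$relaxation_fraction * p1
    peaks <- p_inf + (p1 - p_inf) *
      exp(-(seq_len(cc) - 1) / params$relaxation_time_constant)
    f_c <- (peaks[ci] / p1) * force_law(x_c, k, xt)
  }

  ## ramp to failure; the rupture sample itself is recorded at the drawn
  ## failure strain (off the regular grid when the two do not coincide)
  n_grid <- floor(s_fail / (protocol$ramp_strain_rate * dt)) + 1L
  s_r <- (0:(n_grid - 1)) * protocol$ramp_strain_rate * dt
  if (s_r[n_grid] < s_fail - 1e-12) s_r <- c(s_r, s_fail)
  n_ramp <- length(s_r)
  x_r <- s_r * L
  f_r <- force_law(x_r, k, xt)
  f_star <- f_r[n_ramp]
  x_star <- x_r[n_ramp]
  t_ramp0 <- (n_pre + n_cyc) * dt
  t_r <- t_ramp0 + s_r / protocol$ramp_strain_rate

  ## post-rupture tail: force collapses while the crosshead keeps moving
  n_post <- max(2L, round(0.2 * fs))
  x_p <- x_star + (1:n_post) * protocol$ramp_strain_rate * dt * L
  f_p <- f_star * seq(0.4, 0.02, length.out = n_post)
  t_p <- t_r[n_ramp] + (1:n_post) * dt

  n_tot <- n_pre + n_cyc + n_ramp + n_post
  force <- c(rep(f_pre, n_pre), f_c, f_r, f_p)
  if (params$noise_sd > 0) force <- force + stats::rnorm(n_tot, 0, params$noise_sd)
  force <- pmax(force, 0)
  displacement <- c(rep(x_pre, n_pre), x_c, x_r, x_p)
  time <- c(if (n_pre + n_cyc > 0) (0:(n_pre + n_cyc - 1)) * dt, t_r, t_p)
  phase <- rep(c("preload", "cyclic", "ramp"), c(n_pre, n_cyc, n_ramp + n_post))

  cyc_bounds <- NULL
  if (cc > 0 && n_cyc > 0) {
    starts <- n_pre + round((0:(cc - 1)) * fs / protocol$cycle_frequency) + 1L
    cyc_bounds <- cbind(start = starts, end = c(starts[-1] - 1L, n_pre + n_cyc))
  }
  relax_true <- if (cc >= 2) (peaks[cc] - peaks[1]) / peaks[1] else NA_real_

  truth <- list(
    preload_end = n_pre + 1L,
    ramp_start = n_pre + n_cyc + 1L,
    cycle_boundaries = cyc_bounds,
    ultimate_index = n_pre + n_cyc + n_ramp,
    ultimate_force = f_star,
    ultimate_stress = f_star / csa,
    stiffness = k,
    elastic_modulus = k * L / csa,
    work_to_failure = work_under_law(x_star, k, xt),
    strain_at_failure = x_star / L,
    relative_stress_relaxation = relax_true,
    csa = csa,
    failure_strain_drawn = s_fail,
    params = params)

  list(trace = load_trace(time, force, displacement, phase), truth = truth)
}

check_group_config <- function(config, n_per_group) {
  need <- group_labels()
  if (!all(need %in% names(config)))
    stop("material config missing group(s): ",
         paste(setdiff(need, names(config)), collapse = ", "))
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% need) ||
      length(n_per_group) == 0)
    stop("n_per_group must be named with labels among: ", paste(need, collapse = ", "))
  if (!all(need %in% names(n_per_group)))
    stop("n_per_group missing group(s): ",
         paste(setdiff(need, names(n_per_group)), collapse = ", "))
  if (any(n_per_group <= 0) || any(n_per_group != round(n_per_group)))
    stop("group sizes must be positive integers")
  invisible(TRUE)
}

#' Simulate a full study cohort
#'
#' Draws `n_per_group` specimens for each of the four treatment groups and
#' simulates one tensile test per specimen. Default group sizes are the
#' study's (25/25/45/45). For large Monte Carlo cohorts prefer
#' [extract_cohort_properties()], which streams extraction instead of
#' holding every trace in memory.
#'
#' @param config Named list of [tendon_material_params()], one per group;
#'   defaults to [default_material_params()].
#' @param n_per_group Named integer vector of group sizes.
#' @param protocol A [loading_protocol()].
#' @param seed Integer seed.
#' @return An object of class `tendon_cohort`: a list with `specimens`
#'   (metadata data.frame), `traces` and `truths` (named lists).
#' @export
generate_cohort <- function(config = default_material_params(),
                            n_per_group = reference_group_sizes(),
                            protocol = loading_protocol(),
                            seed = 1L) {
  check_group_config(config, n_per_group)
  set.seed(seed)
  traces <- list()
  truths <- list()
  meta <- list()
  for (g in group_labels()) {
    for (i in seq_len(n_per_group[[g]])) {
      id <- sprintf("%s_%03d", g, i)
      sim <- generate_load_trace(config[[g]], protocol, seed = NULL)
      traces[[id]] <- sim$trace
      truths[[id]] <- sim$truth
      meta[[id]] <- data.frame(specimen_id = id, group = g,
                               csa_mm2 = sim$truth$csa,
                               gauge_length_mm = protocol$gauge_length,
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(specimens = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                 traces = traces, truths = truths, protocol = protocol),
            class = "tendon_cohort")
}

#' @export
print.tendon_cohort <- function(x, ...) {
  tb <- table(factor(x$specimens$group, levels = group_labels()))
  cat(sprintf("Tendon cohort: %d specimens (%s)\n", nrow(x$specimens),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Simulate a cohort and extract properties, streaming
#'
#' Generates one specimen at a time, extracts the seven mechanical
#' properties immediately and discards the trace, so cohorts of thousands of
#' specimens stay within ordinary memory. Identical draws to
#' [generate_cohort()] at the same seed.
#'
#' @inheritParams generate_cohort
#' @param window,range_mode Passed to [extract_all()].
#' @return Per-specimen properties data.frame (see [extract_all()]).
#' @export
extract_cohort_properties <- function(config = default_material_params(),
                                      n_per_group = reference_group_sizes(),
                                      protocol = loading_protocol(),
                                      seed = 1L,
                                      window = NULL,
                                      range_mode = c("ramp_only", "from_preload_end")) {
  range_mode <- match.arg(range_mode)
  check_group_config(config, n_per_group)
  set.seed(seed)
  rows <- vector("list", sum(n_per_group))
  j <- 0L
  for (g in group_labels()) {
    for (i in seq_len(n_per_group[[g]])) {
      id <- sprintf("%s_%03d", g, i)
      sim <- generate_load_trace(config[[g]], protocol, seed = NULL)
      sp <- specimen(id, g, sim$truth$csa, protocol$gauge_length)
      props <- extract_all(sim$trace, sp, protocol, window = window,
                           range_mode = range_mode)
      j <- j + 1L
      rows[[j]] <- as.data.frame(props)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
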