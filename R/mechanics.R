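#' Segment a trace into preload, cyclic and ramp phases
#'
#' If the trace carries phase labels they are taken verbatim for the block
#' boundaries; otherwise boundaries are inferred from the protocol timing
#' (preload duration, cycle count / frequency) relative to the first time
#' stamp. Individual cycle boundaries are placed at successive displacement
#' minima within the cyclic block: candidates on the protocol's cycle grid
#' are refined to the nearest local displacement minimum.
#'
#' Index conventions: `preload_end` is the first sample *after* the preload
#' block and `ramp_start` the first sample of the ramp block, so with zero
#' cycles `preload_end == ramp_start`.
#'
#' @param trace A [load_trace()].
#' @param protocol A [loading_protocol()].
#' @return An object of class `phase_segmentation`: list with `preload_end`,
#'   `cycle_boundaries` (matrix with columns start/end, one row per cycle, or
#'   `NULL`), and `ramp_start`.
#' @export
segment_phases <- function(trace, protocol) {
  n <- nrow(trace)
  cc <- protocol$cycle_count
  if (!is.null(trace$phase)) {
    ph <- trace$phase
    if (all(ph == "preload")) stop("trace contains only preload samples")
    preload_end <- which(ph != "preload")[1]
    if (!any(ph == "ramp")) stop("labelled trace has no ramp phase")
    ramp_start <- which(ph == "ramp")[1]
  } else {
    t0 <- trace$time_s[1]
    preload_end <- which(trace$time_s - t0 >= protocol$preload_duration)[1]
    if (is.na(preload_end)) stop("trace shorter than the preload phase")
    cyc_dur <- if (cc > 0) cc / protocol$cycle_frequency else 0
    ramp_start <- which(trace$time_s - t0 >= protocol$preload_duration + cyc_dur)[1]
    if (is.na(ramp_start)) stop("trace ends before the ramp phase")
  }

  cyc <- NULL
  if (cc > 0) {
    spc <- protocol$sampling_rate / protocol$cycle_frequency
    found <- floor((ramp_start - preload_end) / spc + 1e-9)
    if (found < cc)
      stop(sprintf("detected only %d of %d protocol cycles in the cyclic block",
                   max(0L, found), cc))
    cand <- preload_end + round((0:cc) * spc)
    cand[cand > ramp_start] <- ramp_start
    ## refine interior candidates to the local displacement minimum
    x <- trace$displacement_mm
    ref <- cand
    for (j in seq_along(cand)) {
      lo <- max(preload_end, cand[j] - 3L)
      hi <- min(ramp_start, cand[j] + 3L)
      w <- lo:hi
      ref[j] <- w[which.min(x[w])]
    }
    if (any(diff(ref) <= 0)) ref <- cand  # fall back to the protocol grid
    cyc <- cbind(start = ref[1:cc], end = c(ref[2:cc] - 1L, ramp_start - 1L))
  }
  structure(list(preload_end = preload_end, cycle_boundaries = cyc,
                 ramp_start = ramp_start),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  nc <- if (is.null(x$cycle_boundaries)) 0L else nrow(x$cycle_boundaries)
  cat(sprintf("Phase segmentation: preload ends at %d, %d cycles, ramp starts at %d\n",
              x$preload_end, nc, x$ramp_start))
  invisible(x)
}

#' Ultimate point of a test
#'
#' Global force maximum; ties are broken by the earliest index.
#'
#' @param trace A [load_trace()].
#' @return List with `force` (N), `displacement` (mm) and `index`.
#' @export
ultimate_point <- function(trace) {
  if (is.null(trace) || nrow(trace) == 0) stop("empty trace")
  i <- which.max(trace$force_N)
  list(force = trace$force_N[i], displacement = trace$displacement_mm[i], index = i)
}

#' Ultimate stress
#'
#' @param force Ultimate force, N.
#' @param csa Cross-sectional area, mm^2 (> 0).
#' @return Stress in MPa (N/mm^2).
#' @export
ultimate_stress <- function(force, csa) {
  if (any(csa <= 0)) stop("csa must be > 0")
  force / csa
}

#' Strain at failure
#'
#' @param displacement_at_ultimate Displacement at the ultimate point, mm.
#' @param gauge_length Clamp-to-clamp distance, mm (> 0).
#' @return Dimensionless strain.
#' @export
strain_at_failure <- function(displacement_at_ultimate, gauge_length) {
  if (any(gauge_length <= 0)) stop("gauge_length must be > 0")
  displacement_at_ultimate / gauge_length
}

# Resolve the stiffness/work analysis range: sample indices from the start of
# the chosen range up to (and including) the global ultimate point.
analysis_range <- function(trace, seg, range_mode) {
  start <- if (range_mode == "ramp_only") seg$ramp_start else seg$preload_end
  ui <- ultimate_point(trace)$index
  if (ui <= start) stop("ultimate point precedes the analysis range")
  start:ui
}

#' Stiffness as the maximum sliding-window regression gradient
#'
#' Slides a fixed-width window (stride 1) over the analysis range, fits
#' `force = a + b * displacement` by ordinary least squares in each window,
#' and returns the maximum slope `b`. The analysis range runs from the ramp
#' start (default) or from the end of preload up to the ultimate point.
#'
#' @param trace A [load_trace()].
#' @param seg A [segment_phases()] result.
#' @param window Window width in samples (>= 3); default
#'   `max(5, 10%% of the analysis range)`.
#' @param range_mode `"ramp_only"` (default) restricts the regressions to the
#'   ramp phase; `"from_preload_end"` spans the cyclic block too.
#' @return Stiffness in N/mm.
#' @export
stiffness_max_gradient <- function(trace, seg, window = NULL,
                                   range_mode = c("ramp_only", "from_preload_end")) {
  range_mode <- match.arg(range_mode)
  idx <- analysis_range(trace, seg, range_mode)
  n <- length(idx)
  if (is.null(window)) window <- max(5L, as.integer(round(0.1 * n)))
  window <- as.integer(window)
  if (window < 3) stop("window must span at least 3 samples")
  if (n < window)
    stop(sprintf("analysis range (%d samples) is shorter than the window (%d)", n, window))
  x <- trace$displacement_mm[idx]
  y <- trace$force_N[idx]
  x <- x - mean(x)
  y <- y - mean(y)
  cx <- c(0, cumsum(x))
  cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x))
  cxy <- c(0, cumsum(x * y))
  w <- window
  i <- seq_len(n - w + 1L)
  sx <- cx[i + w] - cx[i]
  sy <- cy[i + w] - cy[i]
  sxx <- cxx[i + w] - cxx[i]
  sxy <- cxy[i + w] - cxy[i]
  den <- w * sxx - sx^2
  num <- w * sxy - sx * sy
  tol <- 1e-12 * max(1, max(sxx))
  slope <- ifelse(den > tol, num / den, NA_real_)
  if (all(is.na(slope)))
    stop("zero displacement variance within every window")
  max(slope, na.rm = TRUE)
}

#' Elastic modulus from stiffness and geometry
#'
#' @param stiffness Stiffness, N/mm.
#' @param csa Cross-sectional area, mm^2 (> 0).
#' @param gauge_length Gauge length, mm (> 0).
#' @return Modulus in MPa.
#' @export
elastic_modulus <- function(stiffness, csa, gauge_length) {
  if (any(csa <= 0) || any(gauge_length <= 0)) stop("csa and gauge_length must be > 0")
  stiffness * gauge_length / csa
}

#' Work to failure
#'
#' Trapezoidal integral of force over recorded displacement across the
#' analysis range up to the ultimate point. 1 N.mm = 1 mJ.
#'
#' @inheritParams stiffness_max_gradient
#' @return Work in mJ.
#' @export
work_to_failure <- function(trace, seg,
                            range_mode = c("ramp_only", "from_preload_end")) {
  range_mode <- match.arg(range_mode)
  idx <- analysis_range(trace, seg, range_mode)
  if (length(idx) < 2) stop("analysis range too short to integrate")
  x <- trace$displacement_mm[idx]
  y <- trace$force_N[idx]
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Relative stress relaxation over the cyclic block
#'
#' `(Fpeak_last - Fpeak_first) / Fpeak_first`, where `Fpeak_n` is the maximum
#' force within cycle n; negative when peak force relaxes. The last complete
#' detected cycle is used as the final cycle.
#'
#' @param trace A [load_trace()].
#' @param seg A [segment_phases()] result with at least two cycles.
#' @return Dimensionless relative change.
#' @export
relative_stress_relaxation <- function(trace, seg) {
  cb <- seg$cycle_boundaries
  if (is.null(cb) || nrow(cb) < 2) stop("at least two cycles are required")
  f <- trace$force_N
  peaks <- vapply(seq_len(nrow(cb)),
                  function(i) max(f[cb[i, 1]:cb[i, 2]]), numeric(1))
  if (peaks[1] <= 0) stop("first-cycle peak force must be > 0")
  (peaks[length(peaks)] - peaks[1]) / peaks[1]
}

#' Extract all mechanical properties of one specimen
#'
#' Composes the individual extractors into the seven-property set: ultimate
#' force/stress, max-gradient stiffness, elastic modulus, work to failure,
#' strain at failure and relative stress relaxation, plus the specimen CSA.
#' Ultimate stress and elastic modulus are recomputed from the same ultimate
#' point and stiffness, so the unit identities
#' `ultimate_stress * csa == ultimate_force` and
#' `elastic_modulus * csa / gauge_length == stiffness` hold exactly.
#'
#' @param trace A [load_trace()].
#' @param spec A [specimen()].
#' @param protocol A [loading_protocol()].
#' @inheritParams stiffness_max_gradient
#' @return An object of class `mechanical_properties` (named list; coerce
#'   with `as.data.frame()`).
#' @export
extract_all <- function(trace, spec, protocol = loading_protocol(),
                        window = NULL,
                        range_mode = c("ramp_only", "from_preload_end")) {
  range_mode <- match.arg(range_mode)
  if (!inherits(spec, "tendon_specimen")) stop("spec must be a tendon_specimen")
  seg <- segment_phases(trace, protocol)
  up <- ultimate_point(trace)
  stiff <- stiffness_max_gradient(trace, seg, window, range_mode)
  out <- list(
    specimen_id = spec$id,
    group = spec$group,
    ultimate_force_N = up$force,
    ultimate_stress_MPa = ultimate_stress(up$force, spec$csa),
    stiffness_N_mm = stiff,
    elastic_modulus_MPa = elastic_modulus(stiff, spec$csa, spec$gauge_length),
    work_to_failure_mJ = work_to_failure(trace, seg, range_mode),
    strain_at_failure = strain_at_failure(up$displacement, spec$gauge_length),
    relative_stress_relaxation = relative_stress_relaxation(trace, seg),
    csa_mm2 = spec$csa)
  structure(out, class = "mechanical_properties")
}

#' @export
as.data.frame.mechanical_properties <- function(x, ...) {
  data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' @export
print.mechanical_properties <- function(x, ...) {
  cat(sprintf("Mechanical properties of %s (%s):\n", x$specimen_id, x$group))
  cat(sprintf("  ultimate force  %8.1f N     ultimate stress %7.2f MPa\n",
              x$ultimate_force_N, x$ultimate_stress_MPa))
  cat(sprintf("  stiffness       %8.1f N/mm  elastic modulus %7.1f MPa\n",
              x$stiffness_N_mm, x$elastic_modulus_MPa))
  cat(sprintf("  work to failure %8.0f mJ    strain at failure %5.3f\n",
              x$work_to_failure_mJ, x$strain_at_failure))
  cat(sprintf("  stress relaxation %6.3f      CSA %6.1f mm^2\n",
              x$relative_stress_relaxation, x$csa_mm2))
  invisible(x)
}
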