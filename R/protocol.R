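#' Tensile-test loading protocol
#'
#' Describes the machine schedule used for every specimen: a constant stress
#' preload, a block of sinusoidal strain cycles, and a constant-rate ramp to
#' failure. Defaults reproduce the study protocol: 0.1 MPa preload held for
#' one minute, 500 cycles between 0% and 5% strain at 1 Hz, ramp at 15%
#' strain/s, 100 Hz sampling, 45 mm clamp-to-clamp gauge length.
#'
#' @param preload_stress Preload stress in MPa.
#' @param preload_duration Preload hold time in seconds.
#' @param cycle_count Number of strain cycles (>= 0).
#' @param cycle_strain_amplitude Peak cyclic strain (dimensionless).
#' @param cycle_frequency Cycle frequency in Hz.
#' @param ramp_strain_rate Ramp-to-failure strain rate in 1/s.
#' @param sampling_rate Acquisition rate in Hz; must be at least twice
#'   `cycle_frequency`.
#' @param gauge_length Clamp-to-clamp distance in mm.
#' @return An object of class `loading_protocol`.
#' @export
loading_protocol <- function(preload_stress = 0.1,
                             preload_duration = 60,
                             cycle_count = 500,
                             cycle_strain_amplitude = 0.05,
                             cycle_frequency = 1,
                             ramp_strain_rate = 0.15,
                             sampling_rate = 100,
                             gauge_length = 45) {
  p <- list(preload_stress = preload_stress,
            preload_duration = preload_duration,
            cycle_count = as.integer(cycle_count),
            cycle_strain_amplitude = cycle_strain_amplitude,
            cycle_frequency = cycle_frequency,
            ramp_strain_rate = ramp_strain_rate,
            sampling_rate = sampling_rate,
            gauge_length = gauge_length)
  num <- unlist(p)
  if (any(!is.finite(num)))
    stop("all loading_protocol fields must be finite")
  pos <- p[setdiff(names(p), "cycle_count")]
  if (any(unlist(pos) <= 0))
    stop("all loading_protocol fields except cycle_count must be strictly positive")
  if (p$cycle_count < 0) stop("cycle_count must be >= 0")
  if (p$sampling_rate < 2 * p$cycle_frequency)
    stop("sampling_rate must be at least twice cycle_frequency")
  structure(p, class = "loading_protocol")
}

#' @export
print.loading_protocol <- function(x, ...) {
  cat("Tensile-test loading protocol\n")
  cat(sprintf("  preload : %.3g MPa for %.3g s\n", x$preload_stress, x$preload_duration))
  cat(sprintf("  cyclic  : %d cycles, 0-%.1f%% strain at %.3g Hz\n",
              x$cycle_count, 100 * x$cycle_strain_amplitude, x$cycle_frequency))
  cat(sprintf("  ramp    : %.3g %%strain/s to failure\n", 100 * x$ramp_strain_rate))
  cat(sprintf("  sampling: %.3g Hz, gauge length %.3g mm\n", x$sampling_rate, x$gauge_length))
  invisible(x)
}

#' Canonical treatment-group labels
#'
#' `C` healthy control, `GP` healthy genipin-injected, `Col` collagenase-
#' degenerated control, `ColGP` degenerated genipin-injected.
#'
#' @return Character vector of the four group labels.
#' @export
group_labels <- function() c("C", "GP", "Col", "ColGP")

#' Generative material parameters for one tendon group
#'
#' Parameters of the synthetic constitutive model: an exponential toe region
#' blending into a linear force-displacement law, brittle failure at a
#' normally drawn strain, and exponential decay of cyclic peak forces.
#'
#' @param linear_stiffness Asymptotic stiffness of the linear region, N/mm.
#' @param failure_strain_mean,failure_strain_spread Mean and SD of the
#'   specimen failure strain (dimensionless). Draws are truncated just above
#'   the cyclic strain amplitude so no specimen fails during cycling.
#' @param relaxation_fraction Asymptotic cyclic peak force as a fraction of
#'   the first-cycle peak, in (0, 1].
#' @param relaxation_time_constant Peak-force decay constant, in cycles.
#' @param toe_strain Extent of the exponential toe region, strain units.
#' @param csa_mean,csa_spread Mean and SD of specimen cross-sectional area, mm^2.
#' @param noise_sd Additive force noise SD, N.
#' @return An object of class `tendon_material_params`.
#' @export
tendon_material_params <- function(linear_stiffness,
                                   failure_strain_mean,
                                   relaxation_fraction,
                                   csa_mean,
                                   toe_strain = 0.015,
                                   failure_strain_spread = 0.02,
                                   relaxation_time_constant = 60,
                                   csa_spread = 3,
                                   noise_sd = 2) {
  p <- list(linear_stiffness = linear_stiffness,
            toe_strain = toe_strain,
            failure_strain_mean = failure_strain_mean,
            failure_strain_spread = failure_strain_spread,
            relaxation_fraction = relaxation_fraction,
            relaxation_time_constant = relaxation_time_constant,
            csa_mean = csa_mean,
            csa_spread = csa_spread,
            noise_sd = noise_sd)
  if (any(!is.finite(unlist(p)))) stop("non-finite material parameter")
  if (p$linear_stiffness <= 0) stop("linear_stiffness must be > 0")
  if (p$relaxation_fraction <= 0 || p$relaxation_fraction > 1)
    stop("relaxation_fraction must be in (0, 1]")
  if (p$toe_strain < 0) stop("toe_strain must be >= 0")
  if (p$failure_strain_mean <= 0) stop("failure_strain_mean must be > 0")
  if (p$failure_strain_spread < 0 || p$csa_spread < 0 || p$noise_sd < 0)
    stop("spread/noise parameters must be >= 0")
  if (p$relaxation_time_constant <= 0) stop("relaxation_time_constant must be > 0")
  if (p$csa_mean <= 0) stop("csa_mean must be > 0")
  structure(p, class = "tendon_material_params")
}

#' Default per-group material parameters
#'
#' One `tendon_material_params` per treatment group, calibrated against the
#' published group medians (see [reference_medians()]): `linear_stiffness` is
#' the published stiffness median, the failure-strain mean is solved so the
#' noise-free ultimate force equals the published ultimate-force median at
#' that stiffness, `relaxation_fraction` is one plus the published relative
#' stress relaxation, and the CSA mean is the published CSA median. A
#' bilinear brittle law cannot also reproduce the published strain-at-failure
#' and work medians; ultimate force (the headline outcome) takes priority.
#'
#' @param protocol A [loading_protocol()]; supplies the gauge length and the
#'   cyclic strain amplitude used for truncation checks.
#' @param toe_strain Toe-region extent shared by all groups.
#' @return Named list of `tendon_material_params`, one per group label.
#' @export
default_material_params <- function(protocol = loading_protocol(), toe_strain = 0.015) {
  ref <- reference_medians()
  med <- function(prop) unlist(ref[ref$property == prop, group_labels()])
  uf <- med("ultimate_force_N")
  k <- med("stiffness_N_mm")
  rel <- med("relative_stress_relaxation")
  csa <- med("csa_mm2")
  xt <- toe_strain * protocol$gauge_length
  out <- lapply(group_labels(), function(g) {
    x_fail <- invert_force_law(uf[[g]], k[[g]], xt)
    tendon_material_params(
      linear_stiffness = k[[g]],
      failure_strain_mean = x_fail / protocol$gauge_length,
      relaxation_fraction = 1 + rel[[g]],
      csa_mean = csa[[g]],
      toe_strain = toe_strain)
  })
  names(out) <- group_labels()
  out
}

#' Specimen metadata
#'
#' @param id Specimen identifier.
#' @param group One of [group_labels()].
#' @param csa Cross-sectional area, mm^2 (> 0).
#' @param gauge_length Clamp-to-clamp distance, mm.
#' @param failure_mode Optional free-text mode-of-failure note.
#' @return An object of class `tendon_specimen`.
#' @export
specimen <- function(id, group, csa, gauge_length = 45, failure_mode = NA_character_) {
  if (!is.numeric(csa) || !is.finite(csa) || csa <= 0) stop("csa must be > 0")
  if (gauge_length <= 0) stop("gauge_length must be > 0")
  if (!group %in% group_labels())
    stop("group must be one of: ", paste(group_labels(), collapse = ", "))
  structure(list(id = as.character(id), group = group, csa = csa,
                 gauge_length = gauge_length, failure_mode = failure_mode),
            class = "tendon_specimen")
}
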