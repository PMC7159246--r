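#' Published group medians of the reference tendon-augmentation study
#'
#' Median mechanical properties per treatment group as published for the
#' ex vivo bovine superficial digital flexor tendon experiment the package
#' re-analyzes (healthy and collagenase-degenerated tendons, with and
#' without genipin injection). These values calibrate the synthetic-data
#' generator defaults and drive the reporting-arithmetic checks
#' (percent and absolute median differences between groups).
#'
#' @return A data.frame with columns `property`, `C`, `GP`, `Col`, `ColGP`.
#' @export
reference_medians <- function() {
  data.frame(
    property = c("ultimate_force_N", "ultimate_stress_MPa", "stiffness_N_mm",
                 "elastic_modulus_MPa", "work_to_failure_mJ", "strain_at_failure",
                 "relative_stress_relaxation", "csa_mm2"),
    C     = c(685, 25.6, 152, 193, 2304, 0.22, -0.66, 26.4),
    GP    = c(833, 34.7, 218, 237, 2577, 0.27, -0.49, 25.3),
    Col   = c(530, 18.4, 111, 137, 1612, 0.28, -0.88, 27.8),
    ColGP = c(633, 22.7, 141, 170, 2294, 0.29, -0.78, 28.5),
    stringsAsFactors = FALSE)
}

#' Published group sizes of the reference study
#'
#' @return Named integer vector of specimens per group.
#' @export
reference_group_sizes <- function() {
  c(C = 25L, GP = 25L, Col = 45L, ColGP = 45L)
}
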