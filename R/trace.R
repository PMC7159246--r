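#' Construct a tensile-test load trace
#'
#' A synchronized record of one test: time (s), force (N) and clamp-to-clamp
#' displacement (mm), optionally with per-sample phase labels. Phase labels,
#' when present, must form contiguous blocks in the order
#' preload, cyclic, ramp (any phase may be absent).
#'
#' @param time_s Strictly increasing time stamps, s.
#' @param force_N Force, N.
#' @param displacement_mm Displacement, mm.
#' @param phase Optional character vector of labels in
#'   `c("preload", "cyclic", "ramp")`.
#' @return A data.frame of class `load_trace`.
#' @export
load_trace <- function(time_s, force_N, displacement_mm, phase = NULL) {
  n <- length(time_s)
  if (n < 2) stop("a load trace needs at least 2 samples")
  if (length(force_N) != n || length(displacement_mm) != n)
    stop("time, force and displacement must have equal length")
  if (!all(is.finite(time_s)) || !all(is.finite(force_N)) || !all(is.finite(displacement_mm)))
    stop("trace columns must be finite numeric")
  if (any(diff(time_s) <= 0)) {
    bad <- which(diff(time_s) <= 0)[1] + 1L
    stop(sprintf("time must be strictly increasing (violated at sample %d)", bad))
  }
  df <- data.frame(time_s = as.numeric(time_s),
                   force_N = as.numeric(force_N),
                   displacement_mm = as.numeric(displacement_mm))
  if (!is.null(phase)) {
    if (length(phase) != n) stop("phase must match the trace length")
    lev <- c("preload", "cyclic", "ramp")
    if (!all(phase %in% lev)) stop("phase labels must be preload/cyclic/ramp")
    r <- rle(phase)$values
    if (any(duplicated(r)) || is.unsorted(match(r, lev)))
      stop("phase labels must be contiguous blocks in preload->cyclic->ramp order")
    df$phase <- phase
  }
  class(df) <- c("load_trace", "data.frame")
  df
}

#' @export
print.load_trace <- function(x, ...) {
  cat(sprintf("Load trace: %d samples, %.2f s, force %.3g-%.3g N\n",
              nrow(x), x$time_s[nrow(x)] - x$time_s[1],
              min(x$force_N), max(x$force_N)))
  if (!is.null(x$phase)) {
    tb <- table(factor(x$phase, levels = c("preload", "cyclic", "ramp")))
    cat("  phases: ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
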