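# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Exhaustive sliding-window OLS: fits every window independently via
# cov/var, no shared cumulative sums.
brute_force_max_slope <- function(x, y, window) {
  n <- length(x)
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    xw <- x[i:(i + window - 1L)]
    yw <- y[i:(i + window - 1L)]
    v <- stats::var(xw)
    if (v == 0) return(NA_real_)
    stats::cov(xw, yw) / v
  }, numeric(1))
  max(slopes, na.rm = TRUE)
}

# Textbook Dunn z with O(N^2) mid-ranks computed by explicit comparison
# counting.
brute_force_dunn_z <- function(groups, pair) {
  v <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  N <- length(v)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mi <- mean(r[g == pair[1]])
  mj <- mean(r[g == pair[2]])
  ni <- sum(g == pair[1])
  nj <- sum(g == pair[2])
  (mi - mj) / sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni + 1 / nj))
}

# Short protocol for fast unit tests (not the study schedule).
fast_protocol <- function(...) {
  loading_protocol(preload_duration = 2, cycle_count = 5, sampling_rate = 50, ...)
}

# Switch all stochastic draws of a material parameter set off.
noise_free <- function(p) {
  p$noise_sd <- 0
  p$csa_spread <- 0
  p$failure_strain_spread <- 0
  p
}

# Minimal segmentation for hand-built ramp-only traces.
ramp_only_seg <- function() {
  structure(list(preload_end = 1L, cycle_boundaries = NULL, ramp_start = 1L),
            class = "phase_segmentation")
}

quiet_pipeline <- function(cfg) suppressMessages(run_pipeline(cfg))
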