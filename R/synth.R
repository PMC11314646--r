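# Synthetic RR-interval windows: regular (non-AF) vs irregular (AF)
# rhythms, so the whole pipeline is exercisable without recordings.

#' Parameters of the synthetic RR-interval generator
#'
#' Non-AF windows emulate a regular rhythm: a mean interval with a slow
#' sinusoidal modulation (respiratory-style, period about 12 beats) plus
#' small beat-to-beat jitter.  AF windows emulate an irregularly
#' irregular rhythm: a faster mean with serially independent noise and
#' occasional long pauses.  Values are loosely physiological (RR around
#' 0.6-1.0 s) but deliberately not fitted to any database; they exist to
#' exercise the pipeline.
#'
#' @param n_windows Windows generated per class.
#' @param window_length Intervals per window (default 30).
#' @param nonaf_mean Non-AF mean RR in seconds (default 0.85).
#' @param nonaf_sin_amp Sinusoidal modulation amplitude in seconds
#'   (default 0.03); the period is drawn uniformly in 10-14 beats per
#'   window with random phase.
#' @param nonaf_jitter_sd Non-AF beat-to-beat jitter SD in seconds
#'   (default 0.02).
#' @param af_mean AF mean RR in seconds (default 0.70).
#' @param af_sd AF serially independent noise SD in seconds (default
#'   0.13).
#' @param af_pause_prob Per-beat probability of a long pause (default
#'   0.05).
#' @param af_pause Pause length added to the interval in seconds
#'   (default 0.4).
#' @param noise_mult Multiplier applied to both classes' noise SDs
#'   (stress preset dial; default 1).
#' @param floor Lower clip for all intervals in seconds (default 0.25).
#' @param seed Integer seed; the same configuration always regenerates
#'   the identical dataset.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_windows = 1000L, window_length = 30L,
                         nonaf_mean = 0.85, nonaf_sin_amp = 0.03,
                         nonaf_jitter_sd = 0.02,
                         af_mean = 0.70, af_sd = 0.13,
                         af_pause_prob = 0.05, af_pause = 0.4,
                         noise_mult = 1, floor = 0.25, seed = 1L) {
  stopifnot(n_windows >= 0, window_length >= 2,
            nonaf_sin_amp >= 0, nonaf_jitter_sd >= 0, af_sd >= 0,
            af_pause_prob >= 0, af_pause_prob <= 1, af_pause >= 0,
            noise_mult >= 0, floor > 0,
            nonaf_mean > floor, af_mean > floor)
  structure(as.list(environment()), class = "synth_config")
}

.synth_nonaf_block <- function(n, cfg) {
  W <- cfg$window_length
  if (n == 0) return(matrix(numeric(0), 0, W))
  period <- stats::runif(n, 10, 14)
  phase <- stats::runif(n, 0, 2 * pi)
  beats <- matrix(seq_len(W), n, W, byrow = TRUE)
  x <- cfg$nonaf_mean +
    cfg$nonaf_sin_amp * sin(2 * pi * beats / period + phase) +
    matrix(stats::rnorm(n * W, 0, cfg$nonaf_jitter_sd * cfg$noise_mult), n, W)
  pmax(x, cfg$floor)
}

.synth_af_block <- function(n, cfg) {
  W <- cfg$window_length
  if (n == 0) return(matrix(numeric(0), 0, W))
  x <- cfg$af_mean +
    matrix(stats::rnorm(n * W, 0, cfg$af_sd * cfg$noise_mult), n, W) +
    cfg$af_pause * matrix(stats::rbinom(n * W, 1, cfg$af_pause_prob), n, W)
  pmax(x, cfg$floor)
}

#' Generate synthetic labeled windows (default preset)
#'
#' @param cfg A [synth_config()].
#' @return A window table with `cfg$n_windows` rows per class, each
#'   window its own record.
#' @export
synth_windows <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_windows
  with_seed(cfg$seed, {
    x0 <- .synth_nonaf_block(n, cfg)
    x1 <- .synth_af_block(n, cfg)
  })
  rbind(
    .window_table(x0, rep(0L, n), sprintf("synthN%05d", seq_len(n)),
                  rep(1L, n)),
    .window_table(x1, rep(1L, n), sprintf("synthA%05d", seq_len(n)),
                  rep(1L, n)))
}

#' Generate the hard synthetic preset
#'
#' Like [synth_windows()], but a fraction of the non-AF windows carry a
#' short irregular burst: `burst_len` consecutive intervals centred on
#' the non-AF mean but drawn with the AF noise SD and an elevated pause
#' probability.  Burst windows remain labeled non-AF.  Their
#' within-window SD overlaps the AF range, so a global SD threshold is
#' no longer sufficient and a classifier must use the temporal
#' localization of the irregularity.
#'
#' @param cfg A [synth_config()].
#' @param burst_frac Fraction of non-AF windows given a burst (default
#'   0.10).
#' @param burst_len Burst length in beats (default 5).
#' @param burst_pause_prob Per-beat pause probability inside the burst
#'   (default 0.4).
#' @return A window table; burst rows keep label 0.
#' @export
synth_hard_windows <- function(cfg = synth_config(), burst_frac = 0.10,
                               burst_len = 5L, burst_pause_prob = 0.4) {
  stopifnot(inherits(cfg, "synth_config"),
            burst_frac >= 0, burst_frac <= 1, burst_len >= 1,
            burst_len <= cfg$window_length)
  n <- cfg$n_windows
  W <- cfg$window_length
  with_seed(cfg$seed, {
    x0 <- .synth_nonaf_block(n, cfg)
    x1 <- .synth_af_block(n, cfg)
    nb <- floor(burst_frac * n)
    if (nb > 0) {
      rows <- sample.int(n, nb)
      starts <- sample.int(W - burst_len + 1L, nb, replace = TRUE)
      for (k in seq_len(nb)) {
        idx <- starts[k]:(starts[k] + burst_len - 1L)
        burst <- cfg$nonaf_mean +
          stats::rnorm(burst_len, 0, cfg$af_sd * cfg$noise_mult) +
          cfg$af_pause * stats::rbinom(burst_len, 1, burst_pause_prob)
        x0[rows[k], idx] <- pmax(burst, cfg$floor)
      }
    }
  })
  rbind(
    .window_table(x0, rep(0L, n), sprintf("synthN%05d", seq_len(n)),
                  rep(1L, n)),
    .window_table(x1, rep(1L, n), sprintf("synthA%05d", seq_len(n)),
                  rep(1L, n)))
}

#' Accuracy of the best within-window SD threshold
#'
#' Scores the naive time-invariant baseline: classify AF when the
#' within-window interval SD exceeds a threshold, with the threshold
#' chosen to maximize accuracy on the given data (the most favourable
#' case for the naive rule).
#'
#' @param windows A window table.
#' @return Best achievable accuracy in `[0, 1]`.
#' @export
sd_threshold_accuracy <- function(windows) {
  xy <- windows_to_xy(windows)
  sds <- apply(xy$x, 1, stats::sd)
  o <- order(sds)
  y <- xy$y[o]
  n <- length(y)
  # threshold between consecutive order statistics: accuracy =
  # (#AF above cut) + (#non-AF at or below cut)
  af_above <- sum(y == 1) - cumsum(y == 1)
  nonaf_below <- cumsum(y == 0)
  max(c(sum(y == 1), af_above + nonaf_below)) / n
}
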