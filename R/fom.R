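#' Latency-aware figure of merit for frame classifiers
#'
#' A frame classifier embedded in a pupillometer must be both accurate and
#' fast: discarded or mislabeled frames corrupt the pupillary-light-reflex
#' trace, and slow prediction breaks the instrument's real-time frame rate.
#' The figure of merit
#' \deqn{FOM = A^2 \, e^{-(SFPT/\tau)^2}}
#' combines classification accuracy \eqn{A \in [0,1]} with the single-frame
#' prediction time SFPT (seconds): accuracy enters squared so that
#' \eqn{A < \sqrt{0.5}} can never reach a passing score, and latency is
#' penalized with a Gaussian decay governed by the time constant \eqn{\tau}.
#'
#' `calibrate_tau()` solves for the \eqn{\tau} that awards a chosen score to
#' a reference operating point; with the defaults (score 0.5 at accuracy 0.8
#' and SFPT 10 ms, i.e. comfortably above a 50 fps frame budget)
#' \eqn{\tau = 0.01 / \sqrt{\ln(0.8^2 / 0.5)} \approx 0.02013} s.
#'
#' @param target_accuracy,target_sfpt,target_fom The reference operating
#'   point: accuracy fraction, single-frame prediction time in seconds, and
#'   the score it should receive.
#' @return `calibrate_tau()`: the time constant in seconds, unrounded.
#' @examples
#' tau <- calibrate_tau()
#' compute_fom(0.8, 0.010, tau)   # 0.5 by construction
#' sfpt_limit(1, tau)             # ~0.01675 s
#' @export
calibrate_tau <- function(target_accuracy = 0.8, target_sfpt = 0.010,
                          target_fom = 0.5) {
  if (target_sfpt <= 0) stop("target_sfpt must be positive")
  if (!(target_fom > 0 && target_fom < target_accuracy^2))
    stop("target_fom must lie in (0, target_accuracy^2)")
  target_sfpt / sqrt(log(target_accuracy^2 / target_fom))
}

#' @rdname calibrate_tau
#' @param A Accuracy fraction in \[0, 1\].
#' @param sfpt Single-frame prediction time in seconds (>= 0).
#' @param tau Time constant in seconds (> 0).
#' @return `compute_fom()`: the score in \[0, 1\], strictly increasing in
#'   `A` and strictly decreasing in `sfpt`.
#' @export
compute_fom <- function(A, sfpt, tau = calibrate_tau()) {
  if (any(A < 0) || any(A > 1)) stop("A must lie in [0, 1]")
  if (any(sfpt < 0)) stop("sfpt must be non-negative")
  if (any(tau <= 0)) stop("tau must be positive")
  A^2 * exp(-(sfpt / tau)^2)
}

#' @rdname calibrate_tau
#' @return `sfpt_limit()`: the largest SFPT (seconds) at which an algorithm
#'   of accuracy `A` still scores `target_fom`.
#' @export
sfpt_limit <- function(A, tau = calibrate_tau(), target_fom = 0.5) {
  if (any(A^2 <= target_fom))
    stop("A^2 must exceed target_fom for a positive SFPT limit")
  tau * sqrt(log(A^2 / target_fom))
}

#' Measure single-frame prediction times
#'
#' Times `classifier(frame)` for each pre-loaded frame individually (one at
#' a time, as a live instrument would), excluding the first `warmup` calls
#' from the statistics. The 90th percentile uses the nearest-rank
#' convention: the `ceiling(0.9 n)`-th smallest duration.
#'
#' @param classifier A function taking one frame and returning its label.
#' @param frames List of frames, already in memory (load time is excluded
#'   by construction).
#' @param warmup Number of leading calls excluded from the statistics.
#' @param clock Function returning the current time in seconds; replaceable
#'   for testing. Defaults to R's monotonic-enough high-resolution timer.
#' @return List of class `timing_stats` with `durations` (seconds),
#'   `mean_sfpt`, `p90_sfpt`, `n`.
#' @export
measure_sfpt <- function(classifier, frames, warmup = 10L, clock = NULL) {
  if (length(frames) <= warmup)
    stop("need more frames than warmup calls to measure timings")
  if (is.null(clock)) clock <- function() proc.time()[["elapsed"]]
  durations <- numeric(length(frames))
  for (i in seq_along(frames)) {
    t0 <- clock()
    classifier(frames[[i]])
    durations[i] <- clock() - t0
  }
  durations <- durations[-seq_len(warmup)]
  structure(list(durations = durations,
                 mean_sfpt = mean(durations),
                 p90_sfpt = percentile_nearest_rank(durations, 0.9),
                 n = length(durations)),
            class = "timing_stats")
}

# nearest-rank percentile: the ceil(q * n)-th smallest sample
percentile_nearest_rank <- function(x, q) {
  sort(x)[ceiling(q * length(x))]
}

#' Summarize an accuracy/latency operating point
#'
#' @param A Accuracy fraction.
#' @param sfpt Single-frame prediction time in seconds.
#' @param tau Time constant in seconds.
#' @return List of class `fom_result` with `A`, `sfpt`, `tau`, `fom`.
#' @export
fom_result <- function(A, sfpt, tau = calibrate_tau()) {
  structure(list(A = A, sfpt = sfpt, tau = tau,
                 fom = compute_fom(A, sfpt, tau)),
            class = "fom_result")
}

#' @export
print.fom_result <- function(x, ...) {
  cat(sprintf("accuracy %.3f, SFPT %.3f ms, tau %.5f s -> FOM %.3f\n",
              x$A, x$sfpt * 1000, x$tau, x$fom))
  invisible(x)
}
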