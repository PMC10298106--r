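# Synthetic single-molecule fluorescence data with the statistical structure
# the downstream analysis assumes: per-spot intensity traces on a uniform
# 100 ms grid, square fluorescence bursts whose durations come from an
# exponential law or from the two-step kinetic scheme, Gaussian baseline
# noise, Poisson event arrivals.  Lets every stage of the pipeline be tested
# without microscope data.

#' Configuration for a synthetic intensity trace
#'
#' Defaults emulate a TIRF recording: 100 ms frames, 10 min records, and an
#' intensity scale on which the conventional 5000 A.U. event-selection
#' threshold is meaningful (baseline 500 A.U., burst amplitude 8000 A.U.,
#' noise SD 300 A.U.).
#'
#' @param frame_interval Frame interval in seconds (default 0.1).
#' @param duration Record length in seconds (default 600).
#' @param baseline Baseline intensity, A.U. (default 500).
#' @param burst_amplitude Intensity added during a burst, A.U. (default 8000).
#' @param noise_sd Gaussian noise SD, A.U. (default 300).
#' @param arrival_rate Association rate while the spot is unbound, per
#'   second (default 0.01); inter-burst waits are exponential at this rate.
#' @param dwell_source Either a single positive number (exponential mean
#'   dwell, seconds) or a [scheme_spec()] to sample dwells from the kinetic
#'   scheme.
#' @param seed Integer seed (default 20230606).
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(frame_interval = 0.1, duration = 600,
                         baseline = 500, burst_amplitude = 8000,
                         noise_sd = 300, arrival_rate = 0.01,
                         dwell_source = 30, seed = 20230606) {
  stopifnot(frame_interval > 0, duration >= frame_interval,
            noise_sd >= 0, arrival_rate >= 0)
  if (!inherits(dwell_source, "scheme_spec")) {
    stopifnot(is.numeric(dwell_source), length(dwell_source) == 1L)
    if (dwell_source <= 0)
      stop("trace_config: exponential mean dwell must be > 0")
  }
  # the default 5000 A.U. selection threshold must sit well clear of both
  # levels; warn when bursts are within 3 noise SDs of it
  if (baseline + burst_amplitude < 5000 + 3 * noise_sd)
    warning("trace_config: burst level is within 3 noise SDs of the 5000 ",
            "A.U. detection threshold; detection will be unreliable")
  structure(list(frame_interval = frame_interval, duration = duration,
                 baseline = baseline, burst_amplitude = burst_amplitude,
                 noise_sd = noise_sd, arrival_rate = arrival_rate,
                 dwell_source = dwell_source, seed = as.integer(seed)),
            class = "trace_config")
}

#' Generate a set of ground-truth dwell times
#'
#' Dwells are either exponential with the given mean (the single-exponential
#' law the survival analysis assumes) or sampled exactly from a two-step
#' kinetic scheme via [simulate_ensemble()].
#'
#' @param n Number of dwells, >= 1.
#' @param mean Exponential mean dwell in seconds (ignored when `scheme` is
#'   given).
#' @param scheme Optional [scheme_spec()]; takes precedence over `mean`.
#' @param seed Integer seed, applied locally.
#' @param condition Label for the resulting [dwell_set()].
#' @return A [dwell_set()] with provenance `"simulated"`.
#' @examples
#' generate_dwells(100, mean = 29.6, seed = 1, condition = "ss_23bp")
#' @export
generate_dwells <- function(n, mean = NULL, scheme = NULL, seed = NULL,
                            condition = "") {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("generate_dwells: n must be a positive count")
  n <- as.integer(n)
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "scheme_spec"))
    sim <- simulate_ensemble(scheme, n, seed = seed)
    lab <- if (nzchar(condition)) condition else scheme$label
    return(dwell_set(sim$dwells, lab, "simulated"))
  }
  if (is.null(mean) || !is.numeric(mean) || mean <= 0)
    stop("generate_dwells: give a positive exponential 'mean' or a 'scheme'")
  draw <- function() stats::rexp(n, rate = 1 / mean)
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  dwell_set(d, condition, "simulated")
}

#' Generate a synthetic per-spot intensity trace
#'
#' Builds a uniform-grid trace of `baseline` plus Gaussian noise, then plants
#' square fluorescence bursts as an alternating renewal process — the exact
#' kinetics of a single surface-tethered duplex: while unbound, a complex
#' forms after an exponential wait at `arrival_rate` (pseudo-first-order
#' association, so waits are Poisson); while bound, the burst lasts a dwell
#' drawn from `dwell_source`; then the spot is unbound again. Bursts
#' therefore never overlap and the planted dwells are i.i.d. draws from the
#' requested law (no rejection step that would length-bias them). A burst
#' still on at the end of the record is truncated there and flagged
#' censored.
#'
#' @param config A [trace_config()].
#' @return An object of class `intensity_trace`: list with `times`,
#'   `intensities`, `ground_truth` (data.frame `start_s`, `end_s`,
#'   `censored`) and `config`.
#' @examples
#' tr <- generate_trace(trace_config(duration = 60, arrival_rate = 0.05))
#' nrow(tr$ground_truth)
#' @export
generate_trace <- function(config) {
  stopifnot(inherits(config, "trace_config"))
  with_seed(config$seed, {
    dt <- config$frame_interval
    n_frames <- as.integer(round(config$duration / dt))
    times <- (seq_len(n_frames) - 1L) * dt
    intens <- config$baseline + stats::rnorm(n_frames, 0, config$noise_sd)

    # alternating renewal process: unbound exponential wait, then a burst
    gt <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     censored = logical(0))
    if (config$arrival_rate > 0) {
      draw_dwell <- function()
        if (inherits(config$dwell_source, "scheme_spec"))
          sample_dwell(config$dwell_source)
        else stats::rexp(1L, 1 / config$dwell_source)
      t <- 0
      repeat {
        t <- t + stats::rexp(1L, config$arrival_rate)
        if (t >= config$duration) break
        e <- t + draw_dwell()
        gt <- rbind(gt, data.frame(start_s = t,
                                   end_s = min(e, config$duration),
                                   censored = e > config$duration))
        t <- e
        if (t >= config$duration) break
      }
      for (i in seq_len(nrow(gt))) {
        idx <- which(times >= gt$start_s[i] & times < gt$end_s[i])
        intens[idx] <- intens[idx] + config$burst_amplitude
      }
    }
    structure(list(times = times, intensities = intens,
                   ground_truth = gt, config = config),
              class = "intensity_trace")
  })
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf(
    "intensity_trace: %d frames @ %g s, %.0f s record, %d planted burst(s)\n",
    length(x$times), x$config$frame_interval, x$config$duration,
    nrow(x$ground_truth)))
  invisible(x)
}

#' Read and write intensity-trace CSV files
#'
#' Plain CSV with columns `time_s`, `intensity_au`. `write_trace()` also
#' writes a JSON sidecar (`<path>.json`) carrying the generating config, the
#' seed and the ground-truth intervals so the trace is fully reconstructible;
#' `read_trace()` restores it when present.
#'
#' @param x An `intensity_trace`.
#' @param path CSV file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` an
#'   `intensity_trace` (with empty ground truth if there is no sidecar).
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "intensity_trace"))
  utils::write.csv(data.frame(time_s = x$times, intensity_au = x$intensities),
                   path, row.names = FALSE)
  cfg <- x$config
  cfg$dwell_source <- if (inherits(cfg$dwell_source, "scheme_spec"))
    unclass(cfg$dwell_source) else cfg$dwell_source
  jsonlite::write_json(
    list(config = unclass(cfg), ground_truth = x$ground_truth),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "intensity_au") %in% names(df)))
  steps <- diff(df$time_s)
  if (length(steps) > 0 &&
      (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-9 * steps[1]))
    stop("read_trace: time grid is not uniform and strictly increasing")
  gt <- data.frame(start_s = numeric(0), end_s = numeric(0),
                   censored = logical(0))
  config <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$ground_truth) && length(meta$ground_truth))
      gt <- as.data.frame(meta$ground_truth)
    config <- meta$config
  }
  if (is.null(config))
    config <- list(frame_interval = if (length(steps)) steps[1] else NA_real_,
                   duration = max(df$time_s) + (if (length(steps)) steps[1] else 0))
  structure(list(times = df$time_s, intensities = df$intensity_au,
                 ground_truth = gt, config = config),
            class = "intensity_trace")
}
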