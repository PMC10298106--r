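# Shared fixtures: the published parameter set and the standard complexes.

published_params <- function() rate_params(x = 1.7, y = 5.0, u = 4.6)

# schemes for the three 23 bp complexes at the published parameters
scheme_23 <- function(kind) {
  scheme_from_config(published_params(), complex_config(kind, 23, 23))
}

# a trace config with a planted-event-friendly scale (fast, 60 s records)
quick_trace_config <- function(...) {
  trace_config(duration = 120, arrival_rate = 0.03, dwell_source = 5, ...)
}

# build an intensity_trace by hand from an intensity vector (0.1 s grid)
manual_trace <- function(intensities, frame_interval = 0.1) {
  structure(list(
    times = (seq_along(intensities) - 1) * frame_interval,
    intensities = as.numeric(intensities),
    ground_truth = data.frame(start_s = numeric(0), end_s = numeric(0),
                              censored = logical(0)),
    config = list(frame_interval = frame_interval,
                  duration = length(intensities) * frame_interval)),
    class = "intensity_trace")
}
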