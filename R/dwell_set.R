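# Container for extracted or simulated complex lifetimes, shared by the
# simulation, detection and survival-analysis stages.

#' A set of dwell times for one experimental condition
#'
#' @param dwells Numeric vector of strictly positive dwell times (seconds).
#' @param condition Condition label, e.g. `"ss_23bp"`.
#' @param provenance `"simulated"` or `"detected"`.
#' @param events Optional data.frame with per-event columns `start_s`,
#'   `end_s`, `censored` (one row per dwell, detection output only).
#' @return An object of class `dwell_set`.
#' @export
dwell_set <- function(dwells, condition = "", provenance = c("simulated", "detected"),
                      events = NULL) {
  provenance <- match.arg(provenance)
  dwells <- as.numeric(dwells)
  if (length(dwells) == 0L)
    stop("dwell_set: at least one dwell time is required")
  if (any(!is.finite(dwells)) || any(dwells <= 0))
    stop("dwell_set: dwell times must be finite and strictly positive")
  if (!is.null(events)) {
    stopifnot(is.data.frame(events),
              all(c("start_s", "end_s", "censored") %in% names(events)),
              nrow(events) == length(dwells))
  }
  structure(list(dwells = dwells, condition = as.character(condition),
                 n = length(dwells), provenance = provenance,
                 events = events),
            class = "dwell_set")
}

#' @export
print.dwell_set <- function(x, ...) {
  cat(sprintf("dwell_set [%s]: n = %d (%s), mean = %.2f s, range %.2f-%.2f s\n",
              x$condition, x$n, x$provenance, mean(x$dwells),
              min(x$dwells), max(x$dwells)))
  invisible(x)
}

#' Read and write dwell-time CSV files
#'
#' The on-disk format is a plain CSV with columns `condition` and `dwell_s`,
#' plus `start_s`, `end_s`, `censored` when per-event intervals are known.
#'
#' @param x A [dwell_set()].
#' @param path File path.
#' @return `write_dwells()` returns `path` invisibly; `read_dwells()` returns
#'   a [dwell_set()] (the file must contain a single condition).
#' @export
write_dwells <- function(x, path) {
  stopifnot(inherits(x, "dwell_set"))
  df <- data.frame(condition = x$condition, dwell_s = x$dwells)
  if (!is.null(x$events)) df <- cbind(df, x$events)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dwells
#' @export
read_dwells <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("condition", "dwell_s") %in% names(df)))
  cond <- unique(df$condition)
  if (length(cond) != 1L)
    stop("read_dwells: expected a single condition per file, found ",
         length(cond))
  ev <- if (all(c("start_s", "end_s", "censored") %in% names(df)))
    df[, c("start_s", "end_s", "censored")] else NULL
  dwell_set(df$dwell_s, cond,
            provenance = if (is.null(ev)) "simulated" else "detected",
            events = ev)
}
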