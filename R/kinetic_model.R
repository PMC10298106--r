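# Closed-form mean first-passage-time (MFPT) lifetimes for two-duplex
# protein-DNA complexes dissociating through the scheme
#   state 2 <-> state 1 -> state 0
# where state i holds i protein-DNA bonds.  Rebinding from state 1 is
# multiplied by the number of registers a footprint-f protein can occupy on an
# L-bp non-specific duplex, m = L - f + 1: the entropic stabilisation that
# makes a mixed specific/non-specific (pre-synaptic) complex outlive the fully
# specific one.

#' Bond-strength parameters of the two-step dissociation model
#'
#' The model is parameterised by two dimensionless bond parameters and a base
#' rate: `x = exp(En/2)` for the non-specific protein-DNA bond of energy `En`
#' (kT), `y = exp(Es/2)` for the specific bond of energy `Es` (kT), and `u`
#' (1/s), the rate of an energy-neutral elementary step. Breaking a
#' non-specific bond occurs at rate `u/x` and forming it at `u*x`, so the
#' single-bond equilibrium constant is `x^2 = exp(En)`; likewise `u/y`, `u*y`
#' and `y^2 = exp(Es)` for the specific bond.
#'
#' @param x Dimensionless non-specific bond parameter, > 0.
#' @param y Dimensionless specific bond parameter, > 0.
#' @param u Base rate in 1/s, > 0.
#' @return An object of class `rate_params`.
#' @examples
#' rate_params(x = 1.7, y = 5.0, u = 4.6)
#' @seealso [energy_from_param()], [lifetime_nn()], [predict_lifetime()]
#' @export
rate_params <- function(x, y, u) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x),
            is.numeric(y), length(y) == 1L, is.finite(y),
            is.numeric(u), length(u) == 1L, is.finite(u))
  if (x <= 0 || y <= 0 || u <= 0)
    stop("rate_params: x, y and u must all be strictly positive (got x=",
         x, ", y=", y, ", u=", u, ")")
  if (x < 1 || y < 1)
    warning("rate_params: x or y below 1 implies a negative bond energy; ",
            "allowed, but check the parameterisation")
  structure(list(x = x, y = y, u = u), class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf("rate_params: x = %g, y = %g, u = %g 1/s\n", x$x, x$y, x$u))
  cat(sprintf("  bond energies: En = %.3f kT, Es = %.3f kT\n",
              energy_from_param(x$x), energy_from_param(x$y)))
  invisible(x)
}

#' Geometry of a two-duplex complex
#'
#' Describes which of the two DNA duplexes carry the recognition site and how
#' long they are. `kind` is `"ss"` (both specific, the synaptic complex),
#' `"nn"` (both non-specific) or `"ns"` (one of each, the pre-synaptic
#' complex). For `"ns"`, `nonspecific` names the non-specific duplex (`"a"` or
#' `"b"`); when the two lengths are equal the designation is immaterial and
#' defaults to `"b"`. When lengths differ and no designation is given,
#' [predict_lifetime()] reports both branches.
#'
#' @param kind One of `"ss"`, `"nn"`, `"ns"`.
#' @param length_a,length_b Duplex lengths in base pairs; each must be at
#'   least `footprint`.
#' @param footprint Protein contact footprint in base pairs (default 13, the
#'   length of the SfiI recognition sequence GGCCNNNNNGGCC).
#' @param nonspecific For `kind = "ns"`: `"a"` or `"b"`, naming the
#'   non-specific duplex; `NULL` leaves it unspecified.
#' @return An object of class `complex_config`.
#' @examples
#' complex_config("ns", 23, 23)                     # pre-synaptic, 23 bp
#' complex_config("nn", 23, 33)                     # mixed-length non-specific
#' @export
complex_config <- function(kind = c("ss", "nn", "ns"),
                           length_a, length_b = length_a,
                           footprint = 13L, nonspecific = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(length_a), is.numeric(length_b), is.numeric(footprint))
  length_a <- as.integer(length_a); length_b <- as.integer(length_b)
  footprint <- as.integer(footprint)
  if (footprint < 1L) stop("complex_config: footprint must be >= 1 bp")
  if (length_a < footprint || length_b < footprint)
    stop("complex_config: duplex lengths (", length_a, ", ", length_b,
         " bp) must be at least the footprint (", footprint, " bp)")
  if (!is.null(nonspecific)) {
    nonspecific <- match.arg(nonspecific, c("a", "b"))
    if (kind != "ns")
      stop("complex_config: 'nonspecific' applies only to kind = \"ns\"")
  } else if (kind == "ns" && length_a == length_b) {
    nonspecific <- "b"
  }
  structure(list(kind = kind, length_a = length_a, length_b = length_b,
                 footprint = footprint, nonspecific = nonspecific),
            class = "complex_config")
}

#' @export
print.complex_config <- function(x, ...) {
  cat(sprintf("complex_config: %s, %d/%d bp, footprint %d bp",
              x$kind, x$length_a, x$length_b, x$footprint))
  if (!is.null(x$nonspecific))
    cat(sprintf(" (non-specific duplex: %s)", x$nonspecific))
  cat("\n")
  invisible(x)
}

#' Rebinding multiplicity of a duplex
#'
#' Number of distinct registers where a protein with a given footprint can
#' bind an L-bp duplex: `m = L - footprint + 1`. A 23 bp duplex with a 13 bp
#' footprint allows 11 registers; 33 bp allows 21.
#'
#' @param length Duplex length in base pairs.
#' @param footprint Footprint in base pairs (default 13).
#' @return A positive integer.
#' @examples
#' multiplicity(23, 13)  # 11
#' multiplicity(33)      # 21
#' @export
multiplicity <- function(length, footprint = 13L) {
  stopifnot(is.numeric(length), is.numeric(footprint))
  if (any(footprint < 1))
    stop("multiplicity: footprint must be >= 1 bp (got ", footprint, ")")
  if (any(length < footprint))
    stop("multiplicity: duplex length (", length,
         " bp) shorter than footprint (", footprint, " bp)")
  as.integer(length - footprint + 1L)
}

#' Elementary bond rates of the dissociation scheme
#'
#' @param params A [rate_params()] object.
#' @param m Rebinding multiplicity of the non-specific duplex (>= 1).
#' @return Named list: `break_ns = u/x`, `rebind_ns = m*u*x`,
#'   `break_s = u/y`, `rebind_s = u*y`, all in 1/s.
#' @examples
#' bond_rates(rate_params(1.7, 5.0, 4.6), m = 11)
#' @export
bond_rates <- function(params, m = 1L) {
  stopifnot(inherits(params, "rate_params"), m >= 1)
  with(params, list(break_ns  = u / x,
                    rebind_ns = m * u * x,
                    break_s   = u / y,
                    rebind_s  = u * y))
}

#' Closed-form MFPT lifetimes of nn, ss and ns complexes
#'
#' Mean first-passage times from the doubly bound state (state 2) to full
#' dissociation (state 0):
#' \describe{
#'   \item{nn}{both bonds non-specific, forward rates `u/x`, rebinding
#'     `m*u*x`: `T_nn = (2x + m*x^3)/u`.}
#'   \item{ss}{both bonds specific, no non-specific rebinding allowed:
#'     `T_ss = (2y + y^3)/u`, independent of duplex length.}
#'   \item{ns}{the weaker non-specific bond breaks first, rebinding
#'     `m*u*x`, final specific-bond break `u/y`:
#'     `T_ns = (x + y + m*x^2*y)/u`.}
#' }
#' `m` is always the multiplicity of the non-specific duplex.
#'
#' @param params A [rate_params()] object.
#' @param m Rebinding multiplicity (non-specific complexes only).
#' @return Lifetime in seconds.
#' @examples
#' p <- rate_params(1.7, 5.0, 4.6)
#' lifetime_nn(p, 11)   # ~12.49 s
#' lifetime_ss(p)       # ~29.35 s
#' lifetime_ns(p, 11)   # ~36.0 s
#' @name lifetimes
NULL

#' @rdname lifetimes
#' @export
lifetime_nn <- function(params, m) {
  stopifnot(inherits(params, "rate_params"), m >= 1)
  with(params, (2 * x + m * x^3) / u)
}

#' @rdname lifetimes
#' @export
lifetime_ss <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  with(params, (2 * y + y^3) / u)
}

#' @rdname lifetimes
#' @export
lifetime_ns <- function(params, m) {
  stopifnot(inherits(params, "rate_params"), m >= 1)
  with(params, (x + y + m * x^2 * y) / u)
}

#' Convert between bond parameters and bond energies
#'
#' `energy_from_param()` returns `E = 2*log(p)` in kT; `param_from_energy()`
#' is its inverse, `p = exp(E/2)`. The factor 2 reflects the symmetric split
#' of the bond energy between association (`u*p`) and dissociation (`u/p`),
#' so the equilibrium constant is `p^2 = exp(E)`.
#'
#' @param p Dimensionless bond parameter, > 0 (vectorised).
#' @param energy Bond energy in kT (vectorised).
#' @return Energy in kT, or the dimensionless parameter.
#' @examples
#' energy_from_param(5.0)   # ~3.22 kT
#' param_from_energy(0)     # 1: energy-neutral bond
#' @export
energy_from_param <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p <= 0))
    stop("energy_from_param: bond parameter must be > 0")
  2 * log(p)
}

#' @rdname energy_from_param
#' @export
param_from_energy <- function(energy) {
  stopifnot(is.numeric(energy))
  exp(energy / 2)
}

#' Exact MFPT of the three-state chain by first-step analysis
#'
#' Independent oracle for the closed-form lifetimes: solves the linear
#' first-step equations of the absorbing chain 2 -> 1 (rate `rate_2to1`),
#' 1 -> 2 (rate `rate_1to2`), 1 -> 0 (rate `rate_1to0`) for the mean
#' absorption time starting from state 2:
#' `T2 = 1/k21 + T1`, `T1 = (1 + k12 * T2)/(k12 + k10)`.
#'
#' @param rate_2to1 Forward rate out of state 2, > 0 (1/s).
#' @param rate_1to2 Rebinding rate from state 1 back to state 2, >= 0 (1/s).
#' @param rate_1to0 Final dissociation rate, > 0 (1/s).
#' @return Mean first-passage time from state 2 to state 0, in seconds.
#' @examples
#' mfpt_oracle(1, 1, 1)  # 3
#' @export
mfpt_oracle <- function(rate_2to1, rate_1to2, rate_1to0) {
  stopifnot(is.numeric(rate_2to1), is.numeric(rate_1to2),
            is.numeric(rate_1to0))
  if (rate_2to1 <= 0 || rate_1to0 <= 0)
    stop("mfpt_oracle: forward rates out of states 2 and 1 must be > 0, ",
         "otherwise the chain never absorbs")
  if (rate_1to2 < 0) stop("mfpt_oracle: rebinding rate must be >= 0")
  # first-step analysis: A %*% c(T2, T1) = b
  A <- rbind(c(1, -1),
             c(-rate_1to2 / (rate_1to2 + rate_1to0), 1))
  b <- c(1 / rate_2to1, 1 / (rate_1to2 + rate_1to0))
  solve(A, b)[1L]
}

#' Predicted lifetime for a complex configuration
#'
#' Dispatches on the complex kind:
#' * `ss`: [lifetime_ss()], independent of duplex lengths.
#' * `nn`, equal lengths: [lifetime_nn()] at that length's multiplicity.
#' * `nn`, unequal lengths: arithmetic mean of the two pure-length lifetimes
#'   (the model's stated mixed-length rule).
#' * `ns`: [lifetime_ns()] with the multiplicity of the non-specific duplex;
#'   if lengths differ and the non-specific duplex is not designated, both
#'   branches are returned, labelled by the non-specific length.
#'
#' @param params A [rate_params()] object.
#' @param config A [complex_config()] object.
#' @return An object of class `lifetime_prediction`: list with `config`,
#'   `lifetime` (named numeric, one value per branch) and `components`
#'   (per-duplex multiplicities).
#' @examples
#' p <- rate_params(1.7, 5.0, 4.6)
#' predict_lifetime(p, complex_config("ns", 23, 23))
#' predict_lifetime(p, complex_config("nn", 23, 33))
#' @export
predict_lifetime <- function(params, config) {
  stopifnot(inherits(params, "rate_params"),
            inherits(config, "complex_config"))
  m_a <- multiplicity(config$length_a, config$footprint)
  m_b <- multiplicity(config$length_b, config$footprint)
  lt <- switch(config$kind,
    ss = c(ss = lifetime_ss(params)),
    nn = if (config$length_a == config$length_b) {
      stats::setNames(lifetime_nn(params, m_a),
                      sprintf("nn_%dbp", config$length_a))
    } else {
      # mixed-length rule: average of the two pure-length lifetimes
      stats::setNames(
        mean(c(lifetime_nn(params, m_a), lifetime_nn(params, m_b))),
        sprintf("nn_%d/%dbp", config$length_a, config$length_b))
    },
    ns = {
      if (!is.null(config$nonspecific)) {
        m <- if (config$nonspecific == "a") m_a else m_b
        len <- if (config$nonspecific == "a") config$length_a else config$length_b
        stats::setNames(lifetime_ns(params, m), sprintf("ns_%dbp", len))
      } else {
        # unspecified designation: report both branches
        stats::setNames(c(lifetime_ns(params, m_a), lifetime_ns(params, m_b)),
                        sprintf("ns_%dbp", c(config$length_a, config$length_b)))
      }
    })
  structure(list(config = config, lifetime = lt,
                 components = c(m_a = m_a, m_b = m_b)),
            class = "lifetime_prediction")
}

#' @export
print.lifetime_prediction <- function(x, ...) {
  print(x$config)
  for (nm in names(x$lifetime))
    cat(sprintf("  %s: %.2f s\n", nm, x$lifetime[[nm]]))
  invisible(x)
}

#' Tidy table of lifetime predictions
#'
#' Flattens one prediction per branch into a data frame suitable for CSV
#' export.
#'
#' @param params A [rate_params()] object.
#' @param configs A list of [complex_config()] objects (a single config is
#'   accepted).
#' @return A data.frame with columns `kind`, `length_a`, `length_b`, `m`,
#'   `lifetime_s` (one row per prediction branch; `m` is NA for ss).
#' @export
prediction_table <- function(params, configs) {
  if (inherits(configs, "complex_config")) configs <- list(configs)
  rows <- lapply(configs, function(cfg) {
    pred <- predict_lifetime(params, cfg)
    n <- length(pred$lifetime)
    m <- switch(cfg$kind,
      ss = rep(NA_integer_, n),
      nn = if (n == 1L && cfg$length_a == cfg$length_b)
             pred$components[["m_a"]] else NA_integer_,
      ns = {
        lens <- as.integer(sub("^ns_(\\d+)bp$", "\\1", names(pred$lifetime)))
        as.integer(lens - cfg$footprint + 1L)
      })
    data.frame(kind = cfg$kind, length_a = cfg$length_a,
               length_b = cfg$length_b, branch = names(pred$lifetime),
               m = m, lifetime_s = unname(pred$lifetime))
  })
  do.call(rbind, rows)
}
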