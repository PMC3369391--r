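# Dosage regimens and the zero-order absorption input G(t).
#
# Controlled-release lithium carbonate is modelled as zero-order absorption:
# a dose of m_D mg releases m_D * (mEq Li per mg) of lithium into the GI tract
# at a constant rate over its absorption window, G(t) = m_D * li_per_mg / dt.
# Peak serum levels with the controlled-release formulation occur 4-12 h after
# dosing; the default window of 240 min takes the lower ("worst-case") end.

#' Define a daily dosage regimen
#'
#' A regimen is a repeating cycle (default 24 h) of oral doses given at fixed
#' offsets within the cycle. When `offsets_min` is omitted the doses are
#' spaced evenly over the cycle (12 h apart for 2 doses, 8 h for 3, 6 h for
#' 4), the convention used for multi-dose regimens throughout.
#'
#' @param doses_mg Numeric vector of dose masses, mg of lithium carbonate;
#'   at least one dose, each `>= 0`.
#' @param offsets_min Administration times within the cycle, minutes from the
#'   cycle start; defaults to even spacing. Must satisfy
#'   `0 <= offset < cycle_length_min`.
#' @param cycle_length_min Cycle length in minutes (default 1440 = 24 h).
#' @param duration_min Absorption window length per dose, minutes; recycled
#'   across doses. Default 240 min (4 h zero-order release).
#' @param label Display name; defaults to the doses joined by `/`.
#' @return An object of class `li_regimen`.
#' @examples
#' li_regimen(c(450, 900))          # 450 mg morning, 900 mg evening
#' li_regimen(rep(400, 3))          # 400 mg every 8 h
#' @export
li_regimen <- function(doses_mg, offsets_min = NULL, cycle_length_min = 1440,
                       duration_min = 240, label = NULL) {
  if (!is.numeric(doses_mg) || length(doses_mg) < 1L || any(doses_mg < 0) ||
      any(!is.finite(doses_mg))) {
    stop("a regimen needs at least one dose with mass >= 0 mg", call. = FALSE)
  }
  n <- length(doses_mg)
  if (is.null(offsets_min)) {
    offsets_min <- cycle_length_min * (seq_len(n) - 1L) / n
  }
  if (length(offsets_min) != n) {
    stop("offsets_min must match doses_mg in length", call. = FALSE)
  }
  if (any(offsets_min < 0) || any(offsets_min >= cycle_length_min)) {
    stop("dose offsets must lie in [0, cycle_length_min)", call. = FALSE)
  }
  duration_min <- rep_len(duration_min, n)
  if (any(duration_min <= 0)) {
    stop("absorption duration must be > 0", call. = FALSE)
  }
  if (is.null(label)) label <- paste(doses_mg, collapse = "/")
  structure(list(doses_mg = as.numeric(doses_mg),
                 offsets_min = as.numeric(offsets_min),
                 cycle_length_min = as.numeric(cycle_length_min),
                 duration_min = as.numeric(duration_min),
                 label = label),
            class = "li_regimen")
}

# preset definitions; offsets NULL = evenly spaced
.presets <- function() {
  list(
    "450/900"         = list(d = c(450, 900), label = "450/900 (pathological reference)"),
    "900/900"         = list(d = c(900, 900)),
    "700/700"         = list(d = c(700, 700)),
    "1000/300"        = list(d = c(1000, 300)),
    "300/300"         = list(d = c(300, 300)),
    "600/600"         = list(d = c(600, 600)),
    "300/300/500"     = list(d = c(300, 300, 500)),
    "400/400/400"     = list(d = rep(400, 3)),
    "300/300/300/300" = list(d = rep(300, 4)),
    # one dose on a 30-day cycle: effectively non-repeating, so multi-day
    # simulations of single-dose kinetics see exactly one administration
    "single-900"      = list(d = 900, o = 0, cyc = 43200,
                             label = "single 900 mg dose"),
    "none"            = list(d = 0, o = 0, label = "no drug")
  )
}

#' Named regimen presets
#'
#' Every regimen studied in the screening analysis is available by name:
#' the pathological reference `"450/900"` (450 mg then 900 mg 12 h later),
#' the standard `"900/900"`, the eliminated candidates `"700/700"` and
#' `"1000/300"` (1000 mg first, 300 mg 12 h later), the reduced-risk set
#' `"300/300"`, `"600/600"`, `"300/300/500"`, `"400/400/400"`,
#' `"300/300/300/300"` (all evenly spaced), plus `"single-900"` (one dose,
#' for single-dose kinetics) and `"none"` (zero drug).
#'
#' @param name Preset name; see [regimen_presets()] for the list.
#' @return An `li_regimen`.
#' @examples
#' regimen_preset("400/400/400")
#' @export
regimen_preset <- function(name) {
  p <- .presets()[[name]]
  if (is.null(p)) {
    stop("unknown regimen preset '", name, "'; available: ",
         paste(regimen_presets(), collapse = ", "), call. = FALSE)
  }
  li_regimen(p$d, offsets_min = p$o, cycle_length_min = p$cyc %||% 1440,
             label = p$label %||% name)
}

#' @rdname regimen_preset
#' @export
regimen_presets <- function() names(.presets())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand a regimen into dose events over several cycles
#'
#' @param regimen An [li_regimen()].
#' @param n_cycles Number of complete cycles to expand (`>= 1`).
#' @return A data frame with one row per dose event: `start_min`, `mass_mg`,
#'   `duration_min`.
#' @examples
#' expand_regimen(regimen_preset("450/900"), n_cycles = 2)
#' @export
expand_regimen <- function(regimen, n_cycles = 1L) {
  stopifnot(inherits(regimen, "li_regimen"))
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1) {
    stop("n_cycles must be >= 1", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  starts <- as.vector(outer(regimen$offsets_min,
                            (seq_len(n_cycles) - 1L) * regimen$cycle_length_min,
                            `+`))
  data.frame(start_min = starts,
             mass_mg = rep(regimen$doses_mg, n_cycles),
             duration_min = rep(regimen$duration_min, n_cycles))
}

#' Build the zero-order absorption input G(t)
#'
#' Constructs the piecewise-constant lithium absorption rate: each dose event
#' contributes `mass_mg * li_per_mg / duration_min` (mEq/min) on its window
#' `[start, start + duration)`; overlapping windows sum; the rate is zero
#' outside all windows. The integral of the rate over the full schedule
#' equals the total administered lithium in mEq.
#'
#' @param events Data frame of dose events as from [expand_regimen()].
#' @param li_per_mg Lithium content, mEq per mg of drug.
#' @return An object of class `li_absorption` holding the rate function, its
#'   breakpoints (window edges), and the total dose.
#' @export
absorption_profile <- function(events, li_per_mg) {
  stopifnot(is.data.frame(events),
            all(c("start_min", "mass_mg", "duration_min") %in% names(events)))
  if (nrow(events) > 0L &&
      (any(events$mass_mg < 0) || any(events$duration_min <= 0))) {
    stop("dose events need mass >= 0 and duration > 0", call. = FALSE)
  }
  rates <- if (nrow(events)) events$mass_mg * li_per_mg / events$duration_min
           else numeric()
  starts <- events$start_min
  ends <- events$start_min + events$duration_min
  structure(list(starts = starts, ends = ends, rates = rates,
                 breakpoints = sort(unique(c(starts, ends))),
                 total_meq = sum(events$mass_mg) * li_per_mg),
            class = "li_absorption")
}

#' Evaluate an absorption profile
#'
#' @param profile An [absorption_profile()].
#' @param t Time(s), minutes; vectorized.
#' @return Absorption rate G(t), mEq/min.
#' @export
absorption_rate <- function(profile, t) {
  stopifnot(inherits(profile, "li_absorption"))
  if (length(profile$rates) == 0L) return(numeric(length(t)))
  vapply(t, function(tt) {
    sum(profile$rates[profile$starts <= tt & tt < profile$ends])
  }, numeric(1))
}

#' Total lithium delivered per cycle
#'
#' @param regimen An [li_regimen()].
#' @param li_per_mg Lithium content, mEq per mg of drug.
#' @return mEq of lithium administered over one complete cycle (e.g. 36 mEq
#'   for 450/900 mg at 8/300 mEq/mg).
#' @export
cycle_dose_meq <- function(regimen, li_per_mg) {
  stopifnot(inherits(regimen, "li_regimen"))
  sum(regimen$doses_mg) * li_per_mg
}

#' Read / write a regimen configuration file
#'
#' YAML with keys `doses_mg`, and optionally `offsets_min`, `cycle_length_min`,
#' `duration_min`, `label`.
#'
#' @param path YAML file path.
#' @return `read_regimen()`: an `li_regimen`; `write_regimen()`: `path`,
#'   invisibly.
#' @export
read_regimen <- function(path) {
  x <- yaml::read_yaml(path)
  li_regimen(unlist(x$doses_mg),
             offsets_min = if (!is.null(x$offsets_min)) unlist(x$offsets_min),
             cycle_length_min = x$cycle_length_min %||% 1440,
             duration_min = unlist(x$duration_min %||% 240),
             label = x$label)
}

#' @rdname read_regimen
#' @param regimen An `li_regimen` to serialize.
#' @export
write_regimen <- function(regimen, path) {
  yaml::write_yaml(list(doses_mg = regimen$doses_mg,
                        offsets_min = regimen$offsets_min,
                        cycle_length_min = regimen$cycle_length_min,
                        duration_min = regimen$duration_min,
                        label = regimen$label),
                   path, precision = 17L)
  invisible(path)
}

#' @export
print.li_regimen <- function(x, ...) {
  cat(sprintf("Regimen '%s': %s mg at %s min (cycle %g min, absorption %s min)\n",
              x$label, paste(x$doses_mg, collapse = "/"),
              paste(x$offsets_min, collapse = "/"), x$cycle_length_min,
              paste(unique(x$duration_min), collapse = "/")))
  invisible(x)
}
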