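# Regimen screening against the pathological reference exposure.
#
# The 450/900 mg regimen is documented to have caused birth defects; its
# terminal-cycle fetal peak and average define not-to-exceed levels. A
# candidate regimen is eliminated if its terminal fetal peak or average
# exceeds the corresponding reference level. Because the model is linear and
# the fetal partition ratio scales candidate and reference identically, the
# classification does not depend on the (uncertain) fetal partition value.

.TIE_REL <- 1e-9

#' Derive the pathological reference exposure levels
#'
#' Runs the reference regimen (default the documented pathological
#' 450 mg / 900 mg schedule) to its terminal profile under the given
#' physiology and extracts the fetal peak and average. References are always
#' recomputed from the supplied parameter set — never cached — so physiology
#' overrides (including the fetal partition ratio) propagate consistently to
#' both sides of every comparison.
#'
#' @param params A validated [li_physiology()].
#' @param regimen Reference [li_regimen()]; default `regimen_preset("450/900")`.
#' @param ... Passed to [find_terminal_cycle()].
#' @return An object of class `li_reference`: list with `max_fetal_peak`,
#'   `max_fetal_average` (mEq/L), `provenance` (regimen label) and `summary`
#'   (the full [find_terminal_cycle()] result).
#' @export
derive_reference <- function(params, regimen = regimen_preset("450/900"),
                             ...) {
  cs <- find_terminal_cycle(params, regimen, ...)
  if (!attr(cs, "converged")) {
    stop("reference regimen '", regimen$label,
         "' did not reach a terminal profile; raise max_cycles", call. = FALSE)
  }
  fet <- cs[cs$compartment == "fetus", ]
  structure(list(max_fetal_peak = fet$peak, max_fetal_average = fet$average,
                 provenance = regimen$label, summary = cs),
            class = "li_reference")
}

# classify one (peak, average) pair against the reference
.classify <- function(peak, average, reference) {
  near <- function(v, r) abs(v - r) <= .TIE_REL * abs(r)
  over <- function(v, r) !near(v, r) && v > r
  over_p <- over(peak, reference$max_fetal_peak)
  over_a <- over(average, reference$max_fetal_average)
  if (over_p && over_a) return("eliminated_both")
  if (over_p) return("eliminated_peak")
  if (over_a) return("eliminated_average")
  if (near(peak, reference$max_fetal_peak) ||
      near(average, reference$max_fetal_average)) {
    return("at_reference")  # ties are conservatively not acceptable
  }
  "acceptable"
}

#' Screen a candidate regimen against the reference levels
#'
#' Classifies a regimen by strict comparison of its terminal-cycle fetal peak
#' and average against the reference: `acceptable` (both strictly below),
#' `eliminated_peak` / `eliminated_average` / `eliminated_both` (exceeding the
#' corresponding level), or `at_reference` (within 1e-9 relative of a level —
#' conservatively treated as not acceptable).
#'
#' @param params A validated [li_physiology()]; must be the set the reference
#'   was derived with.
#' @param regimen Candidate [li_regimen()].
#' @param reference An [derive_reference()] result.
#' @param ... Passed to [find_terminal_cycle()].
#' @return An object of class `li_screening`: one-row data frame with
#'   `regimen`, `fetal_peak`, `fetal_average`, `brain_average`
#'   (informational; mEq/L), `classification`, `margin_peak` and
#'   `margin_average` (reference minus value).
#' @export
screen_regimen <- function(params, regimen, reference, ...) {
  stopifnot(inherits(reference, "li_reference"))
  cs <- find_terminal_cycle(params, regimen, ...)
  if (!attr(cs, "converged")) {
    stop("regimen '", regimen$label,
         "' did not reach a terminal profile; raise max_cycles", call. = FALSE)
  }
  fet <- cs[cs$compartment == "fetus", ]
  br <- cs[cs$compartment == "brain", ]
  structure(data.frame(
    regimen = regimen$label,
    fetal_peak = fet$peak,
    fetal_average = fet$average,
    brain_average = br$average,
    classification = .classify(fet$peak, fet$average, reference),
    margin_peak = reference$max_fetal_peak - fet$peak,
    margin_average = reference$max_fetal_average - fet$average),
    class = c("li_screening", "data.frame"),
    reference = reference$provenance)
}

#' Screen and rank a set of candidate regimens
#'
#' Screens every regimen against the (freshly derived, unless supplied)
#' reference and returns a ranked table: acceptable regimens first, then by
#' fetal average descending — the ordering used when searching for the
#' maximum acceptable regimen.
#'
#' @param params A validated [li_physiology()].
#' @param regimens A list of [li_regimen()] objects and/or preset names.
#' @param reference Optional precomputed [derive_reference()] result.
#' @param ... Passed to [find_terminal_cycle()].
#' @return An `li_screening` data frame with one row per regimen.
#' @examples
#' \donttest{
#' compare_regimens(default_physiology(),
#'                  list("400/400/400", "700/700", "300/300"))
#' }
#' @export
compare_regimens <- function(params, regimens, reference = NULL, ...) {
  if (length(regimens) == 0L) {
    stop("at least one regimen is required", call. = FALSE)
  }
  regimens <- lapply(regimens, function(r) {
    if (inherits(r, "li_regimen")) r else regimen_preset(r)
  })
  if (is.null(reference)) reference <- derive_reference(params, ...)
  rows <- lapply(regimens, function(r) {
    screen_regimen(params, r, reference, ...)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$classification != "acceptable", -out$fetal_average)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("li_screening", "data.frame"),
            reference = reference$provenance)
}

#' @export
print.li_screening <- function(x, ...) {
  cat(sprintf("Regimen screening vs reference '%s' (fetal levels, mEq/L)\n",
              attr(x, "reference")))
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}
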