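# Coupled mass balances of the eight-compartment model.
#
# Each tissue obeys the flow-limited balance
#   dC_i/dt = Q_i (C_P - C_i/R_i) / V_i
# with three exceptions: the uterus exchanges with both plasma and fetus, the
# fetus exchanges only with the uterus (placental blood passes through the
# uterus; fetal renal clearance is neglected in the first trimester), the
# kidney carries the elimination term kk*C_K/R_K, and the GI tract receives
# the oral absorption input G(t). Plasma collects the venous return of the
# six directly perfused tissues minus the total arterial outflow. The system
# is linear in the state; G(t) enters as the only forcing.

#' Coefficient matrix of the lithium mass-balance system
#'
#' Builds the 8x8 matrix `A` such that the compartment concentrations
#' (mEq/mL, state order `plasma, brain, thyroid, bone, gi_tract, kidney,
#' uterus, fetus`) evolve as `dC/dt = A C + g(t)`, where `g(t)` is zero
#' except for the GI element `G(t)/V_G`.
#'
#' @param params A validated [li_physiology()] parameter set.
#' @return Numeric matrix with dimnames in canonical state order.
#' @export
system_matrix <- function(params) {
  findings <- validate_physiology(params)
  if (nrow(findings) > 0L) {
    stop("invalid physiology:\n",
         paste0("  - ", findings$message, collapse = "\n"), call. = FALSE)
  }
  V <- .volumes(params)
  Q <- .flows(params)
  R <- .partitions(params)
  kk <- params$renal_clearance
  A <- matrix(0, 8, 8, dimnames = list(.state_names, .state_names))

  # brain, thyroid, bone, gi_tract, kidney: plain perfusion exchange
  for (i in c("brain", "thyroid", "bone", "gi_tract", "kidney")) {
    A[i, "plasma"] <- Q[i] / V[i]
    A[i, i] <- -Q[i] / (R[i] * V[i])
  }
  # renal elimination kk * C_K / R_K
  A["kidney", "kidney"] <- A["kidney", "kidney"] - kk / (R["kidney"] * V["kidney"])

  # uterus: inflow from plasma (Q_U) and from the fetus (Q_F at C_F/R_F);
  # outflow at C_U/R_U towards both plasma and fetus
  A["uterus", "plasma"] <- Q["uterus"] / V["uterus"]
  A["uterus", "uterus"] <- -(Q["uterus"] + Q["fetus"]) / (R["uterus"] * V["uterus"])
  A["uterus", "fetus"]  <- Q["fetus"] / (R["fetus"] * V["uterus"])

  # fetus: exchanges only with the uterus
  A["fetus", "uterus"] <- Q["fetus"] / (R["uterus"] * V["fetus"])
  A["fetus", "fetus"]  <- -Q["fetus"] / (R["fetus"] * V["fetus"])

  # plasma: venous return from the six directly perfused tissues minus the
  # total arterial outflow (the fetus has no direct plasma connection)
  direct <- c("brain", "thyroid", "bone", "gi_tract", "kidney", "uterus")
  for (i in direct) A["plasma", i] <- Q[i] / (R[i] * V["plasma"])
  A["plasma", "plasma"] <- -sum(Q[direct]) / V["plasma"]
  A
}

#' Build the ODE right-hand side
#'
#' Returns a derivative function in the form expected by [deSolve::lsoda()]:
#' `function(t, state, parms)` yielding `list(A %*% state + g(t))`, with the
#' absorption input entering the GI tract as `G(t)/V_G`.
#'
#' @param params A validated [li_physiology()].
#' @param absorption An [absorption_profile()] (may be empty: no dosing).
#' @return A function `(t, state, parms) -> list(dstate)`.
#' @export
build_rhs <- function(params, absorption) {
  stopifnot(inherits(absorption, "li_absorption"))
  A <- system_matrix(params)
  v_gi <- params$compartments$gi_tract$volume
  gi <- match("gi_tract", .state_names)
  function(t, state, parms) {
    d <- as.vector(A %*% state)
    d[gi] <- d[gi] + absorption_rate(absorption, t) / v_gi
    list(d)
  }
}

#' Total lithium amount in the body
#'
#' Sums `V_i * C_i` over plasma and all tissue compartments. Along any
#' trajectory this quantity changes only through absorption and renal
#' elimination: `d/dt total = G(t) - kk * C_K / R_K`.
#'
#' @param state Named (or canonically ordered) concentration vector, mEq/mL.
#' @param params An [li_physiology()].
#' @return Amount in mEq.
#' @export
total_body_amount <- function(state, params) {
  V <- .volumes(params)
  if (!is.null(names(state))) state <- state[.state_names]
  sum(V * as.numeric(state))
}

#' Whole-body plasma clearance implied by the kidney compartment
#'
#' At steady state the kidney's flow balance gives an effective plasma
#' clearance of `kk * Q_K / (Q_K + kk)` mL/min: lithium is presented to the
#' kidney at perfusion rate Q_K and a fraction `kk / (Q_K + kk)` of it is
#' excreted. With the default parameters this is 20*1240/1260 = 19.68 mL/min.
#'
#' @param params An [li_physiology()].
#' @return Effective clearance, mL/min.
#' @export
effective_clearance <- function(params) {
  kk <- params$renal_clearance
  qk <- params$compartments$kidney$flow
  kk * qk / (qk + kk)
}
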