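# Compartment parameterization of the maternal-fetal lithium PBPK model.
#
# The model is flow-limited: blood leaving a tissue is assumed to be in
# diffusion equilibrium with it, so each compartment is characterized by its
# volume V_i (mL), the plasma flow it receives Q_i (mL/min), and a
# tissue-to-plasma equilibrium distribution ratio R_i (blood exits compartment
# i at concentration C_i/R_i). Internal units are fixed at {mEq, mL, min}.

# canonical state ordering used everywhere (plasma first, then tissues)
.state_names <- c("plasma", "brain", "thyroid", "bone", "gi_tract",
                  "kidney", "uterus", "fetus")
.tissue_names <- .state_names[-1]

#' Define a single organ/tissue compartment
#'
#' A compartment is one lumped organ or tissue region with anatomically
#' meaningful volume, perfusion rate and lithium partition ratio.
#'
#' @param name Compartment identifier (e.g. `"brain"`).
#' @param volume Tissue volume, mL.
#' @param flow Plasma flow delivered to the compartment, mL/min.
#' @param partition Tissue-to-plasma equilibrium distribution ratio
#'   (dimensionless); blood leaves the compartment at concentration
#'   `C_i / partition`.
#' @return An object of class `li_compartment`.
#' @examples
#' li_compartment("brain", volume = 1450, flow = 700, partition = 1.5)
#' @export
li_compartment <- function(name, volume, flow, partition) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (v in c(volume = volume, flow = flow, partition = partition)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("compartment '", name,
           "': volume, flow and partition must be finite and > 0",
           call. = FALSE)
    }
  }
  structure(list(name = name, volume = as.numeric(volume),
                 flow = as.numeric(flow), partition = as.numeric(partition)),
            class = "li_compartment")
}

#' Assemble a full physiology parameter set
#'
#' @param compartments Named list of [li_compartment()] objects; exactly the
#'   seven tissue compartments `brain, thyroid, bone, gi_tract, kidney,
#'   uterus, fetus` must be present (the fetus exchanges lithium only through
#'   the uterus; see [build_rhs()]).
#' @param plasma_volume Plasma (central) compartment volume, mL.
#' @param renal_clearance Kidney clearance parameter `kk`, mL/min; lithium is
#'   eliminated at rate `kk * C_K / R_K`.
#' @param li_per_mg Lithium content of the drug, mEq per mg of lithium
#'   carbonate (a 300 mg tablet contains 8 mEq, hence the default 8/300).
#' @return An object of class `li_physiology`.
#' @seealso [default_physiology()], [validate_physiology()]
#' @export
li_physiology <- function(compartments, plasma_volume, renal_clearance,
                          li_per_mg = 8 / 300) {
  obj <- structure(list(compartments = compartments,
                        plasma_volume = as.numeric(plasma_volume),
                        renal_clearance = as.numeric(renal_clearance),
                        li_per_mg = as.numeric(li_per_mg)),
                   class = "li_physiology")
  findings <- validate_physiology(obj)
  if (nrow(findings) > 0L) {
    stop("invalid physiology:\n",
         paste0("  - ", findings$message, collapse = "\n"), call. = FALSE)
  }
  obj
}

#' Reference physiology of a pregnant woman with a first-trimester fetus
#'
#' Returns the packaged default parameter set: compartment volumes, plasma
#' flows, lithium partition ratios, plasma volume 5200 mL, renal clearance
#' 20 mL/min and drug conversion factor 8/300 mEq/mg. Bone volume is derived
#' from 8 kg bone mass at density 1.1 g/mL (see [bone_volume()]); the fetal
#' partition ratio defaults to 0.8 and is an ordinary overridable parameter —
#' fetal concentrations scale linearly with it, so screening conclusions do
#' not depend on its value.
#'
#' @param fetal_partition Tissue-to-plasma ratio for the fetal compartment.
#' @return An `li_physiology` object.
#' @examples
#' phys <- default_physiology()
#' phys$compartments$brain$flow      # 700 mL/min
#' phys$renal_clearance              # 20 mL/min
#' @export
default_physiology <- function(fetal_partition = 0.8) {
  comps <- list(
    brain    = li_compartment("brain",    volume = 1450, flow = 700,  partition = 1.5),
    thyroid  = li_compartment("thyroid",  volume = 13,   flow = 60,   partition = 1.5),
    bone     = li_compartment("bone",     volume = bone_volume(8, 1.1),
                              flow = 272, partition = 1.5),
    gi_tract = li_compartment("gi_tract", volume = 1650, flow = 1100, partition = 1),
    kidney   = li_compartment("kidney",   volume = 280,  flow = 1240, partition = 1),
    uterus   = li_compartment("uterus",   volume = 1000, flow = 475,  partition = 0.4),
    fetus    = li_compartment("fetus",    volume = 150,  flow = 300,
                              partition = fetal_partition)
  )
  li_physiology(comps, plasma_volume = 5200, renal_clearance = 20,
                li_per_mg = 8 / 300)
}

#' Bone compartment volume from bone mass and density
#'
#' @param mass_kg Bone mass, kg.
#' @param density_g_per_ml Bone density, g/mL.
#' @return Volume in mL, rounded to the nearest mL (8 kg at 1.1 g/mL gives
#'   7273 mL, the default bone compartment volume).
#' @export
bone_volume <- function(mass_kg, density_g_per_ml) {
  if (!is.numeric(mass_kg) || mass_kg <= 0 ||
      !is.numeric(density_g_per_ml) || density_g_per_ml <= 0) {
    stop("bone mass and density must be > 0", call. = FALSE)
  }
  round(1000 * mass_kg / density_g_per_ml)
}

#' Validate a physiology parameter set
#'
#' Checks every structural invariant of the model — the seven named tissue
#' compartments are present (the fetus is reachable only via the uterus, so
#' both must exist), volumes/flows/partitions are positive, renal clearance is
#' non-negative and the drug conversion factor is positive — and reports
#' violations as structured findings rather than raising, so callers (and the
#' command line) can print them.
#'
#' @param params An `li_physiology`-shaped object.
#' @return A data frame with columns `field` and `message`; zero rows means
#'   the parameter set is valid.
#' @export
validate_physiology <- function(params) {
  findings <- list()
  add <- function(field, message) {
    findings[[length(findings) + 1L]] <<- data.frame(field = field,
                                                     message = message)
  }
  comps <- params$compartments
  missing <- setdiff(.tissue_names, names(comps))
  extra <- setdiff(names(comps), .tissue_names)
  for (m in missing) {
    msg <- paste0("compartment '", m, "' is missing")
    if (m %in% c("uterus", "fetus")) {
      msg <- paste0(msg, " (the fetus exchanges lithium only through the ",
                    "uterus, so both compartments are required)")
    }
    add(m, msg)
  }
  for (e in extra) add(e, paste0("unknown compartment '", e, "'"))
  for (nm in intersect(.tissue_names, names(comps))) {
    cc <- comps[[nm]]
    for (fld in c("volume", "flow", "partition")) {
      v <- cc[[fld]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
        add(paste0(nm, ".", fld), paste0(nm, ": ", fld, " must be > 0"))
      }
    }
  }
  if (!is.numeric(params$plasma_volume) || !is.finite(params$plasma_volume) ||
      params$plasma_volume <= 0) {
    add("plasma_volume", "plasma_volume must be > 0")
  }
  if (!is.numeric(params$renal_clearance) ||
      !is.finite(params$renal_clearance) || params$renal_clearance < 0) {
    add("renal_clearance", "renal_clearance must be >= 0")
  }
  if (!is.numeric(params$li_per_mg) || !is.finite(params$li_per_mg) ||
      params$li_per_mg <= 0) {
    add("li_per_mg", "li_per_mg must be > 0")
  }
  if (length(findings) == 0L) {
    data.frame(field = character(), message = character())
  } else {
    do.call(rbind, findings)
  }
}

# named parameter vectors in canonical state order (plasma first);
# partitions/flows for plasma are 1/NA by convention
.volumes <- function(params) {
  c(plasma = params$plasma_volume,
    vapply(params$compartments[.tissue_names], `[[`, numeric(1), "volume"))
}
.flows <- function(params) {
  vapply(params$compartments[.tissue_names], `[[`, numeric(1), "flow")
}
.partitions <- function(params) {
  vapply(params$compartments[.tissue_names], `[[`, numeric(1), "partition")
}

#' Read a physiology configuration file
#'
#' The configuration is a YAML document with top-level keys `plasma_volume`,
#' `renal_clearance`, `li_per_mg` and a `compartments` section holding one
#' `{volume, flow, partition}` block per tissue. A packaged file encoding the
#' default parameter set ships under
#' `system.file("extdata", "physiology_default.yaml", package = "lipbpk")`.
#'
#' @param path Path to a YAML physiology file.
#' @return An `li_physiology` object.
#' @seealso [write_physiology()]
#' @export
read_physiology <- function(path) {
  x <- yaml::read_yaml(path)
  comps <- lapply(names(x$compartments), function(nm) {
    cc <- x$compartments[[nm]]
    li_compartment(nm, cc$volume, cc$flow, cc$partition)
  })
  names(comps) <- names(x$compartments)
  li_physiology(comps[.tissue_names],
                plasma_volume = x$plasma_volume,
                renal_clearance = x$renal_clearance,
                li_per_mg = x$li_per_mg)
}

#' Write a physiology configuration file
#'
#' Inverse of [read_physiology()]; numeric values are written with enough
#' digits that a round trip reproduces the parameter set exactly.
#'
#' @param params An `li_physiology` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_physiology <- function(params, path) {
  x <- list(
    plasma_volume = params$plasma_volume,
    renal_clearance = params$renal_clearance,
    li_per_mg = params$li_per_mg,
    compartments = lapply(params$compartments[.tissue_names], function(cc) {
      list(volume = cc$volume, flow = cc$flow, partition = cc$partition)
    })
  )
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @export
print.li_physiology <- function(x, ...) {
  cat("Maternal-fetal lithium PBPK physiology\n")
  cat(sprintf("  plasma volume: %g mL   renal clearance (kk): %g mL/min   drug factor: %.6g mEq/mg\n",
              x$plasma_volume, x$renal_clearance, x$li_per_mg))
  df <- data.frame(
    volume_mL = vapply(x$compartments, `[[`, numeric(1), "volume"),
    flow_mL_min = vapply(x$compartments, `[[`, numeric(1), "flow"),
    partition = vapply(x$compartments, `[[`, numeric(1), "partition")
  )
  print(df, ...)
  invisible(x)
}
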