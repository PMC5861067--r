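# Model configuration: geometry, fluid properties, boundary conditions, and
# the dimensionless screening numbers that justify the quasi-steady laminar
# treatment. All internal computation is in SI base units (m, s, kg, Pa,
# m^3/s, W); conversion to the reporting units (um, nL/s, kPa, nW) happens
# only at I/O boundaries.

#' Straight-tube geometry
#'
#' A straight circular tube segment of the feeding pathway (feeding canal,
#' pharynx, or esophagus).
#'
#' @param length_m Tube length in metres.
#' @param diameter_m Internal diameter in metres.
#' @return An object of class `mozpump_tube`.
#' @export
tube_geometry <- function(length_m, diameter_m) {
  check_positive(length_m = length_m, diameter_m = diameter_m)
  structure(list(length_m = length_m, diameter_m = diameter_m),
            class = "mozpump_tube")
}

#' Pharyngeal/esophageal valve parameters
#'
#' The pharyngeal valve is modelled as a section of the pharynx of length
#' `constricted_length_m` that narrows to `constricted_diameter_m` the
#' instant backflow occurs. The esophageal valve is modelled as a finite
#' multiplicative penalty on the esophageal impedance under backflow
#' (default 1e6), which approximates a no-backflow condition while keeping
#' the linear solve well-posed.
#'
#' @param constricted_length_m Length of the constricting section, metres.
#' @param constricted_diameter_m Diameter of the constricted section, metres.
#' @param esophageal_backflow_factor Impedance multiplier applied to the
#'   esophagus under backflow; must be >= 1.
#' @return An object of class `mozpump_valve`.
#' @export
valve_geometry <- function(constricted_length_m = 20e-6,
                           constricted_diameter_m = 5e-6,
                           esophageal_backflow_factor = 1e6) {
  check_positive(constricted_length_m = constricted_length_m,
                 constricted_diameter_m = constricted_diameter_m)
  if (!is.numeric(esophageal_backflow_factor) ||
      length(esophageal_backflow_factor) != 1L ||
      esophageal_backflow_factor < 1) {
    stop("`esophageal_backflow_factor` must be a single number >= 1",
         call. = FALSE)
  }
  structure(list(constricted_length_m = constricted_length_m,
                 constricted_diameter_m = constricted_diameter_m,
                 esophageal_backflow_factor = esophageal_backflow_factor),
            class = "mozpump_valve")
}

#' Pump geometry
#'
#' Each head pump is a prolate spheroid of fixed length (major axis
#' `length_m = 2 b`) whose height (minor axis `H = 2 a`) oscillates between
#' a resting minimum and a mode-dependent maximum.
#'
#' @param length_m Pump length (2b), metres.
#' @param h_min_m Resting pump height, metres.
#' @param h_max_continuous_m Maximum height in the continuous drinking mode,
#'   metres.
#' @param h_max_burst_m Maximum height in the burst drinking mode, metres.
#' @return An object of class `mozpump_pump`.
#' @export
pump_geometry <- function(length_m, h_min_m, h_max_continuous_m,
                          h_max_burst_m) {
  check_positive(length_m = length_m, h_min_m = h_min_m,
                 h_max_continuous_m = h_max_continuous_m,
                 h_max_burst_m = h_max_burst_m)
  if (!(h_min_m <= h_max_continuous_m && h_max_continuous_m <= h_max_burst_m)) {
    stop("pump heights must satisfy h_min <= h_max_continuous <= h_max_burst",
         call. = FALSE)
  }
  structure(list(length_m = length_m, h_min_m = h_min_m,
                 h_max_continuous_m = h_max_continuous_m,
                 h_max_burst_m = h_max_burst_m),
            class = "mozpump_pump")
}

#' Feeding-solution fluid properties
#'
#' @param density_kg_m3 Density, kg/m^3.
#' @param viscosity_pa_s Dynamic viscosity, Pa s.
#' @param surface_tension_n_m Surface tension against air, N/m.
#' @return An object of class `mozpump_fluid`.
#' @export
fluid_properties <- function(density_kg_m3 = 1100,
                             viscosity_pa_s = 3.0e-3,
                             surface_tension_n_m = 0.077) {
  check_positive(density_kg_m3 = density_kg_m3,
                 viscosity_pa_s = viscosity_pa_s,
                 surface_tension_n_m = surface_tension_n_m)
  structure(list(density_kg_m3 = density_kg_m3,
                 viscosity_pa_s = viscosity_pa_s,
                 surface_tension_n_m = surface_tension_n_m),
            class = "mozpump_fluid")
}

#' Pressure boundary conditions
#'
#' Pressures are gauge pressures relative to atmospheric, so the default
#' (everything atmospheric, zero gut backpressure) is all zeros. The gut
#' backpressure is `dp_gut_pa = p_gut_pa - p_food_pa`.
#'
#' @param p_food_pa Pressure of the food at the proboscis inlet, Pa (gauge).
#' @param p_gut_pa Pressure in the gut at the esophagus exit, Pa (gauge).
#' @param p_hemo_pa Hemolymph pressure surrounding the pumps, Pa (gauge).
#' @param p_atm_pa Atmospheric reference, Pa (gauge; normally 0).
#' @return An object of class `mozpump_boundaries`.
#' @export
boundary_conditions <- function(p_food_pa = 0, p_gut_pa = 0,
                                p_hemo_pa = 0, p_atm_pa = 0) {
  for (nm in c("p_food_pa", "p_gut_pa", "p_hemo_pa", "p_atm_pa")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  structure(list(p_food_pa = p_food_pa, p_gut_pa = p_gut_pa,
                 p_hemo_pa = p_hemo_pa, p_atm_pa = p_atm_pa,
                 dp_gut_pa = p_gut_pa - p_food_pa),
            class = "mozpump_boundaries")
}

#' Assemble a full system configuration
#'
#' @param feeding_canal,pharynx,esophagus [tube_geometry()] objects.
#' @param valve A [valve_geometry()] object.
#' @param cibarial,pharyngeal [pump_geometry()] objects.
#' @param fluid A [fluid_properties()] object.
#' @param boundaries A [boundary_conditions()] object.
#' @return An object of class `mozpump_config`.
#' @seealso [default_config()] for the reference parameterization.
#' @export
system_config <- function(feeding_canal, pharynx, esophagus, valve,
                          cibarial, pharyngeal,
                          fluid = fluid_properties(),
                          boundaries = boundary_conditions()) {
  stopifnot(inherits(feeding_canal, "mozpump_tube"),
            inherits(pharynx, "mozpump_tube"),
            inherits(esophagus, "mozpump_tube"),
            inherits(valve, "mozpump_valve"),
            inherits(cibarial, "mozpump_pump"),
            inherits(pharyngeal, "mozpump_pump"),
            inherits(fluid, "mozpump_fluid"),
            inherits(boundaries, "mozpump_boundaries"))
  if (valve$constricted_length_m > pharynx$length_m) {
    stop("valve constricted length exceeds pharynx length", call. = FALSE)
  }
  if (valve$constricted_diameter_m > pharynx$diameter_m) {
    stop("valve constricted diameter exceeds pharynx diameter", call. = FALSE)
  }
  structure(list(feeding_canal = feeding_canal, pharynx = pharynx,
                 esophagus = esophagus, valve = valve,
                 cibarial = cibarial, pharyngeal = pharyngeal,
                 fluid = fluid, boundaries = boundaries),
            class = "mozpump_config")
}

#' Reference mosquito configuration
#'
#' The measured morphology of the *Aedes* feeding system and the measured
#' properties of the sugar/iodine feeding solution: feeding canal 1560 x 25
#' um, pharynx 200 x 25 um with a 20 x 5 um valve constriction, esophagus
#' 100 x 50 um; cibarial pump 232 um long with heights 38/50/63 um
#' (rest/continuous max/burst max); pharyngeal pump 326 um long with heights
#' 44/50/256 um; density 1100 kg/m^3, viscosity 3.0 mPa s, surface tension
#' 0.077 N/m; all boundary pressures atmospheric (zero gut backpressure).
#'
#' @return An object of class `mozpump_config`.
#' @export
default_config <- function() {
  system_config(
    feeding_canal = tube_geometry(length_m = 1560e-6, diameter_m = 25e-6),
    pharynx       = tube_geometry(length_m = 200e-6,  diameter_m = 25e-6),
    esophagus     = tube_geometry(length_m = 100e-6,  diameter_m = 50e-6),
    valve         = valve_geometry(constricted_length_m = 20e-6,
                                   constricted_diameter_m = 5e-6,
                                   esophageal_backflow_factor = 1e6),
    cibarial      = pump_geometry(length_m = 232e-6, h_min_m = 38e-6,
                                  h_max_continuous_m = 50e-6,
                                  h_max_burst_m = 63e-6),
    pharyngeal    = pump_geometry(length_m = 326e-6, h_min_m = 44e-6,
                                  h_max_continuous_m = 50e-6,
                                  h_max_burst_m = 256e-6),
    fluid         = fluid_properties(density_kg_m3 = 1100,
                                     viscosity_pa_s = 3.0e-3,
                                     surface_tension_n_m = 0.077),
    boundaries    = boundary_conditions()
  )
}

#' Hagen-Poiseuille impedance of a straight circular tube
#'
#' `kappa = 128 mu L / (pi D^4)`: the proportionality constant between
#' pressure drop and volumetric flow rate for steady, laminar, fully
#' developed flow.
#'
#' @param length_m Tube length, metres.
#' @param diameter_m Tube diameter, metres.
#' @param viscosity_pa_s Dynamic viscosity, Pa s.
#' @return Impedance in Pa s/m^3.
#' @export
tube_impedance <- function(length_m, diameter_m, viscosity_pa_s) {
  check_positive(length_m = length_m, diameter_m = diameter_m,
                 viscosity_pa_s = viscosity_pa_s)
  128 * viscosity_pa_s * length_m / (pi * diameter_m^4)
}

#' Reynolds number for tube flow
#'
#' @param density_kg_m3 Fluid density, kg/m^3.
#' @param velocity_m_s Characteristic mean velocity, m/s.
#' @param diameter_m Tube diameter, metres.
#' @param viscosity_pa_s Dynamic viscosity, Pa s.
#' @return Dimensionless Reynolds number `rho U D / mu`.
#' @export
reynolds_number <- function(density_kg_m3, velocity_m_s, diameter_m,
                            viscosity_pa_s) {
  check_positive(density_kg_m3 = density_kg_m3, diameter_m = diameter_m,
                 viscosity_pa_s = viscosity_pa_s)
  if (!is.numeric(velocity_m_s) || any(velocity_m_s < 0)) {
    stop("`velocity_m_s` must be non-negative", call. = FALSE)
  }
  density_kg_m3 * velocity_m_s * diameter_m / viscosity_pa_s
}

#' Womersley number for pulsatile tube flow
#'
#' `alpha = sqrt(rho D^2 / (mu T))`; values much below 1 mean the flow
#' tracks the driving kinematics quasi-steadily.
#'
#' @param density_kg_m3 Fluid density, kg/m^3.
#' @param diameter_m Tube diameter, metres.
#' @param viscosity_pa_s Dynamic viscosity, Pa s.
#' @param period_s Period of the pulsatile driving, seconds.
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(density_kg_m3, diameter_m, viscosity_pa_s,
                             period_s) {
  check_positive(density_kg_m3 = density_kg_m3, diameter_m = diameter_m,
                 viscosity_pa_s = viscosity_pa_s, period_s = period_s)
  sqrt(density_kg_m3 * diameter_m^2 / (viscosity_pa_s * period_s))
}

#' Laminar entrance (development) length
#'
#' `l_e ~ 0.6 Re D`; where this is small compared with the tube length,
#' flow-development corrections to the impedance can be neglected.
#'
#' @param reynolds Reynolds number (>= 0).
#' @param diameter_m Tube diameter, metres.
#' @return Entrance length, metres.
#' @export
entrance_length <- function(reynolds, diameter_m) {
  if (!is.numeric(reynolds) || any(reynolds < 0)) {
    stop("`reynolds` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(diameter_m) || any(diameter_m < 0)) {
    stop("`diameter_m` must be non-negative", call. = FALSE)
  }
  0.6 * reynolds * diameter_m
}

#' Dimensionless screening report
#'
#' Computes, for each tube in a configuration, the Reynolds number,
#' Womersley number, and entrance length at a stated characteristic
#' velocity and driving period. Used to check that the laminar,
#' quasi-steady model assumptions hold for a given parameterization.
#'
#' @param config A [system_config()] object.
#' @param velocity_m_s Characteristic mean velocity in the feeding canal,
#'   m/s (default 0.01, i.e. 1 cm/s). Velocities in the other tubes follow
#'   from continuity at the same volumetric flow (scaled by the inverse
#'   square of the diameter ratio).
#' @param period_s Driving period, seconds (default: continuous-mode period
#'   of [default_timing()]).
#' @return A data frame with one row per tube: `tube`, `reynolds`,
#'   `womersley`, `entrance_length_m`, plus the velocity and period used.
#' @export
dimensionless_report <- function(config, velocity_m_s = 0.01,
                                 period_s = default_timing()$t_c_s) {
  stopifnot(inherits(config, "mozpump_config"))
  tubes <- list(feeding_canal = config$feeding_canal,
                pharynx = config$pharynx,
                esophagus = config$esophagus)
  rho <- config$fluid$density_kg_m3
  mu <- config$fluid$viscosity_pa_s
  d_ref <- config$feeding_canal$diameter_m
  out <- do.call(rbind, lapply(names(tubes), function(nm) {
    d <- tubes[[nm]]$diameter_m
    u <- velocity_m_s * (d_ref / d)^2
    re <- reynolds_number(rho, u, d, mu)
    data.frame(tube = nm,
               reynolds = re,
               womersley = womersley_number(rho, d, mu, period_s),
               entrance_length_m = entrance_length(re, d),
               velocity_m_s = u,
               period_s = period_s,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# ---- config serialization ---------------------------------------------------

#' Write a configuration (and optional timing) to JSON
#'
#' @param config A [system_config()] object.
#' @param path Output file path.
#' @param timing Optional [mode_timing()] object stored alongside the
#'   geometry.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path, timing = NULL) {
  stopifnot(inherits(config, "mozpump_config"))
  doc <- lapply(unclass(config), function(x) unclass(x))
  if (!is.null(timing)) {
    stopifnot(inherits(timing, "mozpump_timing"))
    doc$timing <- unclass(timing)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a configuration from JSON
#'
#' Strict reader: every expected field must be present and no unknown
#' fields are tolerated, so that typos in parameter names cannot silently
#' fall back to defaults.
#'
#' @param path JSON file written by [write_config()] (or hand-authored in
#'   the same schema).
#' @return A [system_config()] object. If the file carries a `timing`
#'   block, it is attached as attribute `"timing"`.
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expected <- c("feeding_canal", "pharynx", "esophagus", "valve",
                "cibarial", "pharyngeal", "fluid", "boundaries")
  extra <- setdiff(names(doc), c(expected, "timing"))
  if (length(extra) > 0) {
    stop("unknown top-level config fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(expected, names(doc))
  if (length(missing) > 0) {
    stop("missing config fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  take <- function(block, fields, where) {
    extra <- setdiff(names(block), fields)
    if (length(extra) > 0) {
      stop(sprintf("unknown fields in '%s': %s", where,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    miss <- setdiff(fields, names(block))
    if (length(miss) > 0) {
      stop(sprintf("missing fields in '%s': %s", where,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    lapply(block[fields], as.numeric)  # JSON integers -> double
  }
  tube <- function(b, w) {
    f <- take(b, c("length_m", "diameter_m"), w)
    tube_geometry(f$length_m, f$diameter_m)
  }
  pump <- function(b, w) {
    f <- take(b, c("length_m", "h_min_m", "h_max_continuous_m",
                   "h_max_burst_m"), w)
    pump_geometry(f$length_m, f$h_min_m, f$h_max_continuous_m,
                  f$h_max_burst_m)
  }
  vf <- take(doc$valve, c("constricted_length_m", "constricted_diameter_m",
                          "esophageal_backflow_factor"), "valve")
  ff <- take(doc$fluid, c("density_kg_m3", "viscosity_pa_s",
                          "surface_tension_n_m"), "fluid")
  bf <- take(doc$boundaries, c("p_food_pa", "p_gut_pa", "p_hemo_pa",
                               "p_atm_pa", "dp_gut_pa"), "boundaries")
  if (abs(bf$dp_gut_pa - (bf$p_gut_pa - bf$p_food_pa)) > 1e-12) {
    stop("boundaries: dp_gut_pa inconsistent with p_gut_pa - p_food_pa",
         call. = FALSE)
  }
  cfg <- system_config(
    feeding_canal = tube(doc$feeding_canal, "feeding_canal"),
    pharynx = tube(doc$pharynx, "pharynx"),
    esophagus = tube(doc$esophagus, "esophagus"),
    valve = valve_geometry(vf$constricted_length_m, vf$constricted_diameter_m,
                           vf$esophageal_backflow_factor),
    cibarial = pump(doc$cibarial, "cibarial"),
    pharyngeal = pump(doc$pharyngeal, "pharyngeal"),
    fluid = fluid_properties(ff$density_kg_m3, ff$viscosity_pa_s,
                             ff$surface_tension_n_m),
    boundaries = boundary_conditions(bf$p_food_pa, bf$p_gut_pa,
                                     bf$p_hemo_pa, bf$p_atm_pa)
  )
  if (!is.null(doc$timing)) {
    tf <- take(doc$timing, c("t_c_s", "tau_cp_c_s", "tau_pp_c_s", "t_b_s",
                             "t_s_cp_s", "t_e_cp_s", "t_s_pp_s", "t_e_pp_s"),
               "timing")
    attr(cfg, "timing") <- do.call(mode_timing, tf)
  }
  cfg
}

#' @export
print.mozpump_config <- function(x, ...) {
  um <- function(v) sprintf("%.4g um", v * 1e6)
  cat("<mozpump_config>\n")
  cat(sprintf("  feeding canal: L = %s, D = %s\n",
              um(x$feeding_canal$length_m), um(x$feeding_canal$diameter_m)))
  cat(sprintf("  pharynx:       L = %s, D = %s (valve %s x %s)\n",
              um(x$pharynx$length_m), um(x$pharynx$diameter_m),
              um(x$valve$constricted_length_m),
              um(x$valve$constricted_diameter_m)))
  cat(sprintf("  esophagus:     L = %s, D = %s\n",
              um(x$esophagus$length_m), um(x$esophagus$diameter_m)))
  for (p in c("cibarial", "pharyngeal")) {
    g <- x[[p]]
    cat(sprintf("  %-10s pump: L = %s, H = %s / %s / %s (rest/cont/burst)\n",
                p, um(g$length_m), um(g$h_min_m), um(g$h_max_continuous_m),
                um(g$h_max_burst_m)))
  }
  cat(sprintf("  fluid: rho = %g kg/m3, mu = %g mPa s, sigma = %g N/m\n",
              x$fluid$density_kg_m3, x$fluid$viscosity_pa_s * 1e3,
              x$fluid$surface_tension_n_m))
  cat(sprintf("  boundaries (gauge Pa): food %g, gut %g, hemo %g (dp_gut %g)\n",
              x$boundaries$p_food_pa, x$boundaries$p_gut_pa,
              x$boundaries$p_hemo_pa, x$boundaries$dp_gut_pa))
  invisible(x)
}

# internal: validate strictly positive scalars, named for error messages
check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive finite number", nm),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
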