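#' Numeric model parameters shared by all simulators
#'
#' Collects every tunable biophysical constant in one validated object. Units
#' are stated per field; internal computation is in M, s, um and cells/mL.
#'
#' @param constants [binding_constants()] for the two BiTE arms.
#' @param bite_mw BiTE molar mass, g/mol; used only for ng/mL <-> M conversion.
#' @param diffusion_um2_s effector-cell Brownian diffusion coefficient, um^2/s.
#'   Default 0.03 corresponds to Stokes-Einstein thermal diffusion of an
#'   ~11-13 um suspension cell in culture medium at 37 C.
#' @param radius_E_um,radius_T_um effector / target cell radii, um.
#' @param round_s duration of one encounter round, s.
#' @param spatial_coefficients named unitless multipliers of the encounter rate
#'   per encountering-entity class: `free` (single effector, reference 1),
#'   `size2` (two-cell synapse), `size3` (three-cell synapse). Defaults > 1 for
#'   entities reflect the larger encounter radius of a multi-cell cluster;
#'   the mobility asymmetry between recruiting a mobile effector and an
#'   immotile target is handled separately by the round loop.
#' @param contact_area_um2 area of the transient cell-cell contact patch, um^2.
#' @param contact_duration_s length-2 range of the uniform contact-duration
#'   draw, s.
#' @param confinement_nm confinement length of the single-step 3D->2D rate
#'   conversion, nm.
#' @param alpha adhesion sensitivity coefficient (per bond); the one manually
#'   calibrated parameter, fitted by [calibrate_alpha()] against co-incubation
#'   engagement data.
#' @param cd3_fmax maximal downregulatable fraction of surface CD3.
#' @param cd3_k_min first-order approach rate of CD3 downregulation, 1/min
#'   (0.06/min places the plateau at about one hour).
#' @param cd3_khalf half-saturation of the downregulation drive in
#'   CD3-BiTE complexes per cell.
#' @param cd19_internalization_min CD19 internalization rate constant, 1/min,
#'   applied to the bound-complex pool in the base model only.
#' @param is_duration_min lifetime of a synapse before detachment in the
#'   serial-engagement (in vitro / in vivo) models, min.
#' @param allocation `"proportional"` (deterministic per-cell occupancy) or
#'   `"binomial"` (sampled) allocation of binary complexes to cells.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(constants = binding_constants(),
                       bite_mw = 54000,
                       diffusion_um2_s = 0.03,
                       radius_E_um = 5.5,
                       radius_T_um = 6.0,
                       round_s = 60,
                       spatial_coefficients = c(free = 1, size2 = 1.35, size3 = 1.5),
                       contact_area_um2 = 3,
                       contact_duration_s = c(0.1, 5),
                       confinement_nm = 10,
                       alpha = 0.00316,
                       cd3_fmax = 0.7,
                       cd3_k_min = 0.06,
                       cd3_khalf = 500,
                       cd19_internalization_min = 0.002,
                       is_duration_min = 150,
                       allocation = c("proportional", "binomial")) {
  allocation <- match.arg(allocation)
  stopifnot(inherits(constants, "binding_constants"))
  num <- c(bite_mw = bite_mw, diffusion_um2_s = diffusion_um2_s,
           radius_E_um = radius_E_um, radius_T_um = radius_T_um,
           round_s = round_s, contact_area_um2 = contact_area_um2,
           confinement_nm = confinement_nm, alpha = alpha,
           cd3_k_min = cd3_k_min, cd3_khalf = cd3_khalf,
           is_duration_min = is_duration_min)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("sim_params: ", paste(names(num)[!is.finite(num) | num <= 0],
                               collapse = ", "), " must be positive")
  }
  if (cd3_fmax < 0 || cd3_fmax > 1) stop("sim_params: cd3_fmax must be in [0,1]")
  if (cd19_internalization_min < 0) {
    stop("sim_params: cd19_internalization_min must be >= 0")
  }
  if (length(contact_duration_s) != 2 || contact_duration_s[1] <= 0 ||
      diff(contact_duration_s) < 0) {
    stop("sim_params: contact_duration_s must be an increasing positive range")
  }
  req <- c("free", "size2", "size3")
  if (!all(req %in% names(spatial_coefficients))) {
    stop("sim_params: spatial_coefficients needs entries ",
         paste(req, collapse = ", "))
  }
  if (any(spatial_coefficients <= 0)) {
    stop("sim_params: spatial coefficients must be positive")
  }
  structure(list(constants = constants, bite_mw = bite_mw,
                 diffusion_um2_s = diffusion_um2_s,
                 radius_E_um = radius_E_um, radius_T_um = radius_T_um,
                 round_s = round_s,
                 spatial_coefficients = spatial_coefficients,
                 contact_area_um2 = contact_area_um2,
                 contact_duration_s = contact_duration_s,
                 confinement_nm = confinement_nm, alpha = alpha,
                 cd3_fmax = cd3_fmax, cd3_k_min = cd3_k_min,
                 cd3_khalf = cd3_khalf,
                 cd19_internalization_min = cd19_internalization_min,
                 is_duration_min = is_duration_min,
                 allocation = allocation),
            class = "sim_params")
}

#' Per-cell antigen expression specification
#'
#' Log-normal per-cell receptor counts, the flow-cytometry convention for
#' surface-marker heterogeneity. `mean` is the arithmetic mean of the
#' distribution; `dispersion` is the log-space standard deviation.
#'
#' @param mean mean receptors per cell (> 0).
#' @param dispersion log-space SD (>= 0); 0 gives identical cells.
#' @param label optional expression-level tag, e.g. "L", "M", "H".
#' @return an object of class `expression_spec`.
#' @export
expression_spec <- function(mean, dispersion = 0.3, label = NA_character_) {
  if (!is.finite(mean) || mean <= 0) {
    stop("expression_spec: mean must be positive")
  }
  if (!is.finite(dispersion) || dispersion < 0) {
    stop("expression_spec: dispersion must be >= 0")
  }
  structure(list(mean = mean, dispersion = dispersion, label = label),
            class = "expression_spec")
}

# Default sorted-subpopulation means (receptors/cell). CD19 medium is the
# measured Raji value; the rest are package defaults for the sorted gates.
CD3_LEVELS <- c(L = 5e4, M = 1e5, H = 2e5)
CD19_LEVELS <- c(L = 3e4, M = 1.45e5, H = 3e5)

resolve_level <- function(x, table, what) {
  if (is.character(x)) {
    if (!x %in% names(table)) {
      stop(sprintf("%s level must be one of %s", what,
                   paste(names(table), collapse = "/")))
    }
    unname(table[x])
  } else {
    if (!is.numeric(x) || x <= 0) stop(what, " must be a level tag or > 0")
    x
  }
}

#' Configuration for a base-model run (<= 1 h)
#'
#' @param total_density_per_ml total (effector + target) cell density,
#'   cells/mL.
#' @param et_ratio effector:target number ratio.
#' @param cd3,cd19 expression level tag ("L"/"M"/"H") or a numeric mean
#'   receptors/cell.
#' @param dispersion log-space SD of per-cell expression.
#' @param bite_ngml BiTE concentration, ng/mL.
#' @param duration_min incubation duration, minutes (<= 60; longer horizons
#'   belong to the in vitro model).
#' @param scaled_volume_ul simulated subvolume, uL; densities (not agent
#'   counts) drive all probabilities, the volume only sets Monte-Carlo
#'   granularity.
#' @param replicates number of seeded replicate runs.
#' @param seed integer RNG seed.
#' @param params a [sim_params()] object.
#' @return an object of class `base_config`.
#' @export
base_config <- function(total_density_per_ml = 2e6, et_ratio = 1,
                        cd3 = "L", cd19 = "M", dispersion = 0.3,
                        bite_ngml = 100, duration_min = 60,
                        scaled_volume_ul = 0.1, replicates = 10,
                        seed = 1, params = sim_params()) {
  if (total_density_per_ml < 0) stop("total_density_per_ml must be >= 0")
  if (et_ratio <= 0) stop("et_ratio must be > 0")
  if (bite_ngml < 0) stop("bite_ngml must be >= 0")
  if (duration_min <= 0) stop("duration_min must be > 0")
  if (duration_min > 60) {
    stop("base model is restricted to <= 60 min; use the in vitro model")
  }
  if (scaled_volume_ul <= 0) stop("scaled_volume_ul must be > 0")
  if (replicates < 1) stop("replicates must be >= 1")
  stopifnot(inherits(params, "sim_params"))
  cd3_mean <- resolve_level(cd3, CD3_LEVELS, "cd3")
  cd19_mean <- resolve_level(cd19, CD19_LEVELS, "cd19")
  structure(list(
    total_density_per_ml = total_density_per_ml, et_ratio = et_ratio,
    effector_density_per_ml = total_density_per_ml * et_ratio / (1 + et_ratio),
    target_density_per_ml = total_density_per_ml / (1 + et_ratio),
    cd3_spec = expression_spec(cd3_mean, dispersion,
                               if (is.character(cd3)) cd3 else NA_character_),
    cd19_spec = expression_spec(cd19_mean, dispersion,
                                if (is.character(cd19)) cd19 else NA_character_),
    bite_ngml = bite_ngml, duration_min = duration_min,
    scaled_volume_ul = scaled_volume_ul, replicates = replicates,
    seed = as.integer(seed), params = params), class = "base_config")
}

#' Configuration for an in vitro serial-engagement run (<= 72 h)
#'
#' Same scenario fields as [base_config()] plus the long-horizon controls.
#'
#' @inheritParams base_config
#' @param duration_h incubation duration in hours (<= 72).
#' @param snapshot_times_h times (h) at which survivor CD19 distributions are
#'   summarised.
#' @return an object of class `invitro_config`.
#' @export
invitro_config <- function(total_density_per_ml = 2e6, et_ratio = 1,
                           cd3 = "L", cd19 = "M", dispersion = 0.3,
                           bite_ngml = 0.65, duration_h = 72,
                           snapshot_times_h = c(0, 24, 48, 72),
                           scaled_volume_ul = 0.1, replicates = 3,
                           seed = 1, params = sim_params()) {
  if (duration_h <= 0 || duration_h > 72) {
    stop("invitro duration_h must be in (0, 72]")
  }
  base <- base_config(total_density_per_ml, et_ratio, cd3, cd19, dispersion,
                      bite_ngml, duration_min = 60,
                      scaled_volume_ul = scaled_volume_ul,
                      replicates = replicates, seed = seed, params = params)
  base$duration_min <- NULL
  base$duration_h <- duration_h
  base$snapshot_times_h <- sort(unique(pmin(snapshot_times_h, duration_h)))
  class(base) <- "invitro_config"
  base
}

#' The 12 co-incubation preset conditions
#'
#' Ready-to-run [base_config()] objects for the standard 60-min co-incubation
#' panel: conditions 1-6 at 100 ng/mL and 7-12 as the same scenarios at
#' 20 ng/mL. "2X" means 2e6 total cells/mL.
#'
#' @param replicates,seed,params passed to each config.
#' @return named list of 12 `base_config` objects.
#' @export
preset_conditions <- function(replicates = 10, seed = 1, params = sim_params()) {
  scen <- list(
    list(total = 2e6, et = 1,    cd3 = "L", cd19 = "M"),
    list(total = 4e6, et = 1,    cd3 = "L", cd19 = "M"),
    list(total = 2e6, et = 1,    cd3 = "H", cd19 = "M"),
    list(total = 2e6, et = 1,    cd3 = "L", cd19 = "L"),
    list(total = 4e6, et = 6,    cd3 = "L", cd19 = "M"),
    list(total = 4e6, et = 0.17, cd3 = "L", cd19 = "M"))
  out <- list()
  for (dose in c(100, 20)) {
    for (i in seq_along(scen)) {
      s <- scen[[i]]
      idx <- if (dose == 100) i else i + 6
      out[[paste0("condition_", idx)]] <-
        base_config(s$total, s$et, s$cd3, s$cd19, bite_ngml = dose,
                    replicates = replicates, seed = seed, params = params)
    }
  }
  out
}

#' Load and validate a run configuration from a YAML file
#'
#' The file must contain a `model` field (`base`, `invitro`, `invivo` or
#' `regimens`); remaining keys are matched against the corresponding
#' constructor arguments, with unknown keys rejected by name. Nested `params`
#' and `constants` blocks override [sim_params()] / [binding_constants()]
#' defaults.
#'
#' @param path path to a YAML file.
#' @return a validated config object of the class matching `model`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$model)) stop("load_config: missing required field 'model'")
  model <- match.arg(raw$model, c("base", "invitro", "invivo", "regimens"))
  raw$model <- NULL

  params_args <- raw$params
  raw$params <- NULL
  params <- do.call_checked(sim_params_from_list, list(x = params_args),
                            "params")

  ctor <- switch(model,
                 base = base_config,
                 invitro = invitro_config,
                 invivo = invivo_config,
                 regimens = invivo_config)
  known <- names(formals(ctor))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("load_config: unknown field(s): ", paste(unknown, collapse = ", "))
  }
  raw$params <- params
  cfg <- do.call(ctor, raw)
  attr(cfg, "model") <- model
  cfg
}

# Build sim_params from a plain list (YAML), rejecting unknown keys.
sim_params_from_list <- function(x) {
  if (is.null(x)) return(sim_params())
  const_args <- x$constants
  x$constants <- NULL
  known <- setdiff(names(formals(sim_params)), "constants")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(const_args)) {
    cknown <- names(formals(binding_constants))
    cunknown <- setdiff(names(const_args), cknown)
    if (length(cunknown) > 0) {
      stop("unknown constants field(s): ", paste(cunknown, collapse = ", "))
    }
    x$constants <- do.call(binding_constants, const_args)
  }
  if (!is.null(x$spatial_coefficients)) {
    x$spatial_coefficients <- unlist(x$spatial_coefficients)
  }
  if (!is.null(x$contact_duration_s)) {
    x$contact_duration_s <- unlist(x$contact_duration_s)
  }
  do.call(sim_params, x)
}

do.call_checked <- function(f, args, field) {
  tryCatch(do.call(f, args),
           error = function(e) stop("load_config: in '", field, "': ",
                                    conditionMessage(e), call. = FALSE))
}
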