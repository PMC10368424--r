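#' Generate a heterogeneous cell population
#'
#' Draws per-cell surface antigen totals (CD3 for effectors, CD19 for targets)
#' from the log-normal distribution described by an [expression_spec()]. The
#' log-normal is parameterised so that the arithmetic mean equals `spec$mean`.
#'
#' @param n number of cells (>= 0).
#' @param role `"effector"` or `"target"`.
#' @param spec an [expression_spec()].
#' @param seed optional integer seed; the draw is reproducible given the seed.
#' @param id_offset first cell id minus one.
#' @return a data.frame of cell agents with columns `id`, `role`,
#'   `antigen_total`, `free_antigen`, `binary_complex`, `baseline_total`,
#'   `cd3_lost`, `state`, `entity`, `organ`.
#' @export
generate_population <- function(n, role = c("effector", "target"), spec,
                                seed = NULL, id_offset = 0) {
  role <- match.arg(role)
  stopifnot(inherits(spec, "expression_spec"))
  if (n < 0) stop("generate_population: n must be >= 0")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  totals <- if (n == 0) {
    numeric(0)
  } else if (spec$dispersion == 0) {
    rep(spec$mean, n)
  } else {
    meanlog <- log(spec$mean) - spec$dispersion^2 / 2
    stats::rlnorm(n, meanlog = meanlog, sdlog = spec$dispersion)
  }
  data.frame(id = id_offset + seq_len(n),
             role = rep(role, n),
             antigen_total = totals,
             free_antigen = totals,
             binary_complex = rep(0, n),
             baseline_total = totals,
             cd3_lost = rep(0, n),
             state = rep("free", n),
             entity = rep(NA_integer_, n),
             organ = rep(NA_character_, n),
             stringsAsFactors = FALSE)
}

#' Allocate bulk binary complexes to individual cells
#'
#' Distributes the bulk equilibrium binary complexes over cells: each cell's
#' bound count is its antigen total times the bulk occupancy fraction
#' (`AY/A_tot` for effectors, `YB/B_tot` for targets). With
#' `allocation = "binomial"` the bound count is instead drawn binomially at
#' that occupancy, cell by cell.
#'
#' @param cells a cell data.frame from [generate_population()].
#' @param eq an `equilibrium_state` from [solve_equilibrium()].
#' @param allocation `"proportional"` or `"binomial"`.
#' @return `cells` with `free_antigen` / `binary_complex` updated.
#' @export
allocate_binary_complexes <- function(cells, eq,
                                      allocation = c("proportional", "binomial")) {
  allocation <- match.arg(allocation)
  stopifnot(inherits(eq, "equilibrium_state"))
  occ_A <- if (eq$A_tot > 0) eq$AY / eq$A_tot else 0
  occ_B <- if (eq$B_tot > 0) eq$YB / eq$B_tot else 0
  if (occ_A < -1e-12 || occ_A > 1 + 1e-12 || occ_B < -1e-12 || occ_B > 1 + 1e-12) {
    stop("allocate_binary_complexes: occupancy fraction outside [0, 1]")
  }
  occ <- ifelse(cells$role == "effector", occ_A, occ_B)
  occ <- pmin(pmax(occ, 0), 1)
  bound <- if (allocation == "proportional") {
    cells$antigen_total * occ
  } else {
    stats::rbinom(nrow(cells), size = round(cells$antigen_total), prob = occ)
  }
  cells$binary_complex <- bound
  cells$free_antigen <- cells$antigen_total - bound
  cells
}

#' CD3 downregulation on engaged effector cells
#'
#' Surface CD3 is lost at a rate driven by the per-cell abundance of
#' CD3-BiTE binary complexes. The drive saturates with complex abundance,
#' `occ = AY' / (K + AY')`, and the loss approaches its asymptote
#' `fmax * occ * baseline` with first-order rate `k` so that the trajectory
#' plateaus by about one hour. Loss is applied proportionally to the free and
#' bound CD3 pools; counts never go negative. The update is exact for a
#' constant complex level, so coarse (60 s) and fine stepping agree.
#'
#' @param cells effector cell data.frame rows.
#' @param dt_s time step, s (> 0).
#' @param params a [sim_params()] object.
#' @return updated cells.
#' @export
update_cd3_downregulation <- function(cells, dt_s, params = sim_params()) {
  if (dt_s <= 0) stop("update_cd3_downregulation: dt must be > 0")
  if (any(cells$role != "effector")) {
    stop("update_cd3_downregulation: effector cells only")
  }
  occ <- cells$binary_complex / (params$cd3_khalf + cells$binary_complex)
  loss_target <- params$cd3_fmax * occ * cells$baseline_total
  step <- (pmax(loss_target - cells$cd3_lost, 0)) *
    (1 - exp(-params$cd3_k_min * dt_s / 60))
  lost <- cells$cd3_lost + step
  scale <- ifelse(cells$antigen_total > 0,
                  pmax(cells$baseline_total - lost, 0) / cells$antigen_total, 1)
  scale <- pmin(scale, 1)
  cells$cd3_lost <- lost
  cells$antigen_total <- cells$antigen_total * scale
  cells$free_antigen <- cells$free_antigen * scale
  cells$binary_complex <- cells$binary_complex * scale
  cells
}

#' CD19 internalization of bound complexes
#'
#' First-order decay of the CD19-BiTE bound pool at the fixed rate constant
#' 0.002/min (base-model context only; ignored by the longer-horizon models).
#'
#' @param cells target cell data.frame rows.
#' @param dt_min time step, minutes (>= 0).
#' @param rate_min rate constant, 1/min.
#' @return updated cells.
#' @export
update_cd19_internalization <- function(cells, dt_min, rate_min = 0.002) {
  if (dt_min < 0) stop("update_cd19_internalization: dt must be >= 0")
  if (any(cells$role != "target")) {
    stop("update_cd19_internalization: target cells only")
  }
  f <- exp(-rate_min * dt_min)
  internalized <- cells$binary_complex * (1 - f)
  cells$binary_complex <- cells$binary_complex * f
  cells$antigen_total <- cells$antigen_total - internalized
  cells
}
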