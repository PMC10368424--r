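#' Per-round cell-cell encounter probability
#'
#' Probability that one mobile entity meets at least one immotile target cell
#' within a round. The encounter rate kernel is the Smoluchowski
#' diffusion-limited rate for an absorbing sphere of radius `R = r_E + r_T`,
#' time-averaged over the round to include the transient term that applies
#' when positions re-randomise each round (cells that fail to adhere diffuse
#' away):
#' `kbar = 4*pi*D*R * (1 + 2*R/sqrt(pi*D*dt))`, giving
#' `P = 1 - exp(-s * kbar * C * dt)` with `s` the class-specific spatial
#' coefficient and `C` the target entity density.
#'
#' @param target_density_per_ml density of target entities, per mL.
#' @param params a [sim_params()] object.
#' @param entity_class `"free"` (single effector, spatial coefficient 1 by
#'   convention), `"size2"` or `"size3"` for engaged entities.
#' @param dt_s round duration, s (default `params$round_s`).
#' @return probability in `[0, 1]`.
#' @export
encounter_probability <- function(target_density_per_ml, params = sim_params(),
                                  entity_class = "free",
                                  dt_s = params$round_s) {
  if (any(target_density_per_ml < 0)) {
    stop("encounter_probability: density must be >= 0")
  }
  if (!entity_class %in% names(params$spatial_coefficients)) {
    stop("encounter_probability: unknown entity class '", entity_class, "'")
  }
  s <- unname(params$spatial_coefficients[entity_class])
  kbar <- smoluchowski_rate(params, dt_s)
  C <- target_density_per_ml / 1e12  # cells/mL -> cells/um^3
  p <- -expm1(-s * kbar * C * dt_s)
  pmin(pmax(p, 0), 1)
}

# Time-averaged diffusion-limited encounter rate, um^3/s.
smoluchowski_rate <- function(params, dt_s) {
  D <- params$diffusion_um2_s
  R <- params$radius_E_um + params$radius_T_um
  4 * pi * D * R * (1 + 2 * R / sqrt(pi * D * dt_s))
}

#' Derive 2D membrane rate constants from 3D solution constants
#'
#' Single-step model: the volumetric on-rate is confined to a reaction zone of
#' thickness `confinement_nm` at the membrane apposition, so
#' `kon2D = kon3D / (N_A * h)` after unit conversion, in
#' (molecules/um^2)^-1 s^-1; off-rates are unchanged. The 2D affinity thus
#' scales as the 3D affinity divided by the confinement length.
#'
#' @param constants3d a [binding_constants()] object.
#' @param confinement_nm confinement length in nm (> 0).
#' @return an object of class `twod_constants` with fields `kon2d_A`,
#'   `kon2d_B` ((molecules/um^2)^-1 s^-1), `koff2d_A`, `koff2d_B` (1/s) and
#'   `confinement_nm`.
#' @export
derive_2d_constants <- function(constants3d, confinement_nm = 10) {
  stopifnot(inherits(constants3d, "binding_constants"))
  if (confinement_nm <= 0) {
    stop("derive_2d_constants: confinement length must be > 0")
  }
  h_um <- confinement_nm * 1e-3
  vol_factor <- 1e15 / AVOGADRO  # 1/(M s) -> um^3/(molecule s)
  structure(list(kon2d_A = constants3d$kon_A * vol_factor / h_um,
                 kon2d_B = constants3d$kon_B * vol_factor / h_um,
                 koff2d_A = constants3d$koff_A,
                 koff2d_B = constants3d$koff_B,
                 confinement_nm = confinement_nm),
            class = "twod_constants")
}

#' Describe one transient cell-cell contact
#'
#' Converts the two cells' surface counts to per-area densities on the contact
#' patch (counts spread over each cell's full surface) and records the contact
#' geometry and duration.
#'
#' @param effector,target single-row cell data.frames (from the population
#'   module) for the two parties.
#' @param duration_s contact duration, s; must lie in
#'   `params$contact_duration_s`.
#' @param params a [sim_params()] object.
#' @return an object of class `contact_event` with per-area densities
#'   (molecules/um^2), `contact_area` (um^2) and `duration` (s).
#' @export
contact_event <- function(effector, target, duration_s, params = sim_params()) {
  rng <- params$contact_duration_s
  if (duration_s < rng[1] || duration_s > rng[2]) {
    stop("contact_event: duration outside configured range")
  }
  area_E <- 4 * pi * params$radius_E_um^2
  area_T <- 4 * pi * params$radius_T_um^2
  structure(list(rho_A = effector$free_antigen / area_E,
                 rho_AY = effector$binary_complex / area_E,
                 rho_B = target$free_antigen / area_T,
                 rho_YB = target$binary_complex / area_T,
                 contact_area = params$contact_area_um2,
                 duration = duration_s),
            class = "contact_event")
}

#' Ternary bonds formed during a contact
#'
#' Integrates the mean-field kinetics of membrane ternary-complex (AYB)
#' formation on the contact patch over the contact duration, from N(0) = 0:
#' production through the two channels `A + YB -> AYB` and `AY + B -> AYB`
#' at the 2D on-rates, dissociation of either arm at the 2D off-rates
#' (returning the constituents to their pools), with explicit depletion of all
#' four reactant pools. The bond count is therefore bounded by the lesser
#' side's available binding partners on the patch.
#'
#' @param contact a [contact_event()].
#' @param k2d a [derive_2d_constants()] object.
#' @return scalar bond count (AYB on the patch) at the end of the contact.
#' @export
simulate_bond_formation <- function(contact, k2d) {
  stopifnot(inherits(contact, "contact_event"), inherits(k2d, "twod_constants"))
  n <- bond_counts(contact$rho_A * contact$contact_area,
                   contact$rho_AY * contact$contact_area,
                   contact$rho_B * contact$contact_area,
                   contact$rho_YB * contact$contact_area,
                   contact$duration, k2d, contact$contact_area)
  if (!is.finite(n) || n < -1e-9) {
    stop(sprintf(paste0("simulate_bond_formation: integration failure ",
                        "(rho_A=%.3g rho_AY=%.3g rho_B=%.3g rho_YB=%.3g ",
                        "dur=%.3g)"),
                 contact$rho_A, contact$rho_AY, contact$rho_B, contact$rho_YB,
                 contact$duration))
  }
  max(n, 0)
}

# Vectorised RK4 integration of the 5-species patch kinetics, in molecule
# counts on the patch. All arguments except k2d/area may be vectors.
bond_counts <- function(nA0, nAY0, nB0, nYB0, dur, k2d, area) {
  m <- max(length(nA0), length(dur))
  nA <- rep_len(pmax(nA0, 0), m); nAY <- rep_len(pmax(nAY0, 0), m)
  nB <- rep_len(pmax(nB0, 0), m); nYB <- rep_len(pmax(nYB0, 0), m)
  dur <- rep_len(dur, m)
  N <- numeric(m)
  ka <- k2d$kon2d_A / area
  kb <- k2d$kon2d_B / area
  # time scale of the fastest production channel sets the step
  rate0 <- pmax(ka * nA * nYB, kb * nAY * nB, k2d$koff2d_A + k2d$koff2d_B, 1)
  pool <- pmax(pmin(nA + nAY, nB + nYB), 1)
  dt_needed <- pmin(0.05, 0.2 * pool / rate0)
  nstep <- pmin(pmax(ceiling(max(dur) / min(dt_needed)), 25L), 4000L)
  h <- dur / nstep
  deriv <- function(nA, nAY, nB, nYB, N) {
    p1 <- ka * pmax(nA, 0) * pmax(nYB, 0)
    p2 <- kb * pmax(nAY, 0) * pmax(nB, 0)
    dA <- k2d$koff2d_A * N
    dB <- k2d$koff2d_B * N
    list(dN = p1 + p2 - dA - dB,
         dnA = -p1 + dA, dnYB = -p1 + dA,
         dnAY = -p2 + dB, dnB = -p2 + dB)
  }
  for (i in seq_len(nstep)) {
    k1 <- deriv(nA, nAY, nB, nYB, N)
    k2 <- deriv(nA + h / 2 * k1$dnA, nAY + h / 2 * k1$dnAY,
                nB + h / 2 * k1$dnB, nYB + h / 2 * k1$dnYB, N + h / 2 * k1$dN)
    k3 <- deriv(nA + h / 2 * k2$dnA, nAY + h / 2 * k2$dnAY,
                nB + h / 2 * k2$dnB, nYB + h / 2 * k2$dnYB, N + h / 2 * k2$dN)
    k4 <- deriv(nA + h * k3$dnA, nAY + h * k3$dnAY,
                nB + h * k3$dnB, nYB + h * k3$dnYB, N + h * k3$dN)
    wsum <- function(f) (k1[[f]] + 2 * k2[[f]] + 2 * k3[[f]] + k4[[f]]) / 6
    nA <- pmax(nA + h * wsum("dnA"), 0)
    nAY <- pmax(nAY + h * wsum("dnAY"), 0)
    nB <- pmax(nB + h * wsum("dnB"), 0)
    nYB <- pmax(nYB + h * wsum("dnYB"), 0)
    N <- pmax(N + h * wsum("dN"), 0)
  }
  pmin(N, pmin(nA0 + nAY0, nB0 + nYB0))
}

#' Adhesion probability from the ternary bond count
#'
#' Small-system adhesion-frequency form `P_a = 1 - exp(-alpha * N)`: strictly
#' increasing in the bond count, saturating at 1. `alpha` is the adhesion
#' sensitivity coefficient, the single calibrated parameter of the model.
#'
#' @param bond_count ternary bonds formed during the contact (>= 0).
#' @param alpha sensitivity coefficient (> 0).
#' @return probability in `[0, 1]`.
#' @export
adhesion_probability <- function(bond_count, alpha) {
  if (any(bond_count < 0)) stop("adhesion_probability: bond_count must be >= 0")
  if (any(alpha <= 0)) stop("adhesion_probability: alpha must be > 0")
  -expm1(-alpha * bond_count)
}

# Vectorised contact -> adhesion probability for the engine: surface counts of
# the two parties, one sampled duration per contact.
contact_adhesion_prob <- function(eff_free, eff_bound, tgt_free, tgt_bound,
                                  durations, params, k2d) {
  area_E <- 4 * pi * params$radius_E_um^2
  area_T <- 4 * pi * params$radius_T_um^2
  ac <- params$contact_area_um2
  n <- bond_counts(eff_free / area_E * ac, eff_bound / area_E * ac,
                   tgt_free / area_T * ac, tgt_bound / area_T * ac,
                   durations, k2d, ac)
  adhesion_probability(pmax(n, 0), params$alpha)
}
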