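#' Organ compartment system
#'
#' Named body compartments with volumes, B- and T-cell partition fractions
#' (the "partition repertoire"), and per-organ BiTE exposure scaling. The
#' blood compartment is a trafficking route only and can never host synapse
#' formation; this is enforced structurally. Default volumes and partition
#' fractions are package defaults assembled from standard human lymphocyte
#' distribution data (about 2% of lymphocytes in blood; lymph nodes and
#' spleen effector-rich; bone marrow effector-poor) and are fully
#' configurable.
#'
#' @param compartments data.frame with columns `organ`, `volume_ml`,
#'   `b_fraction`, `t_fraction`, `exposure`, `forms_is`.
#' @return validated data.frame of class `organ_system`.
#' @export
organ_system <- function(compartments = NULL) {
  if (is.null(compartments)) {
    compartments <- data.frame(
      organ = c("blood", "bone_marrow", "lymph_nodes", "spleen", "lung",
                "gut", "remainder"),
      volume_ml = c(5000, 1750, 200, 225, 1000, 1500, 20000),
      b_fraction = c(0.02, 0.18, 0.40, 0.25, 0.05, 0.06, 0.04),
      t_fraction = c(0.02, 0.04, 0.40, 0.25, 0.10, 0.10, 0.09),
      exposure = rep(1, 7),
      forms_is = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE)
  }
  req <- c("organ", "volume_ml", "b_fraction", "t_fraction", "exposure",
           "forms_is")
  if (!all(req %in% names(compartments))) {
    stop("organ_system: compartments need columns ", paste(req, collapse = ", "))
  }
  if (!"blood" %in% compartments$organ) {
    stop("organ_system: a 'blood' compartment is required")
  }
  if (abs(sum(compartments$b_fraction) - 1) > 1e-9 ||
      abs(sum(compartments$t_fraction) - 1) > 1e-9) {
    stop("organ_system: partition fractions must sum to 1")
  }
  if (any(compartments$volume_ml <= 0)) {
    stop("organ_system: volumes must be positive")
  }
  if (compartments$forms_is[compartments$organ == "blood"]) {
    stop("organ_system: the blood compartment cannot form synapses")
  }
  class(compartments) <- c("organ_system", "data.frame")
  compartments
}

#' Distribute total cell counts over organ compartments
#'
#' @param total_count total cells in the system.
#' @param organs an [organ_system()].
#' @param type `"b"` or `"t"` — which partition repertoire to use.
#' @return data.frame: `organ`, `count`, `density_per_ml`.
#' @export
partition_cells <- function(total_count, organs, type = c("b", "t")) {
  type <- match.arg(type)
  organs <- organ_system(organs)
  frac <- if (type == "b") organs$b_fraction else organs$t_fraction
  count <- total_count * frac
  data.frame(organ = organs$organ, count = count,
             density_per_ml = count / organs$volume_ml,
             stringsAsFactors = FALSE)
}

#' Dosing regimen presets
#'
#' Piecewise-constant continuous-infusion schedules over a treatment course.
#' The high level mirrors the approved step-up schedule (starting dose in the
#' first week of cycle 1 only, then the full dose); medium and low are reduced
#' levels. Scheme 1 infuses weeks 1-4 of each 6-week cycle; scheme 2 infuses
#' weeks 1-3, giving a lower total dose. Numeric values are editable package
#' presets, not transcriptions.
#'
#' @param level `"high"`, `"medium"` or `"low"`.
#' @param scheme 1 or 2.
#' @param n_weeks course length in weeks.
#' @return object of class `dose_regimen` with `weekly_ug_day` (length
#'   `n_weeks`) and `total_dose_ug`.
#' @export
dose_regimen <- function(level = c("high", "medium", "low"), scheme = 1,
                         n_weeks = 22) {
  level <- match.arg(level)
  if (!scheme %in% c(1, 2)) stop("dose_regimen: scheme must be 1 or 2")
  doses <- switch(level,
                  high = c(start = 9, full = 28),
                  medium = c(start = 9, full = 15),
                  low = c(start = 5, full = 5))
  on_weeks <- if (scheme == 1) 4 else 3
  weekly <- numeric(n_weeks)
  for (w in seq_len(n_weeks)) {
    in_cycle <- (w - 1) %% 6 + 1
    weekly[w] <- if (in_cycle <= on_weeks) unname(doses["full"]) else 0
  }
  if (n_weeks >= 1 && weekly[1] > 0) weekly[1] <- unname(doses["start"])
  structure(list(level = level, scheme = scheme, n_weeks = n_weeks,
                 weekly_ug_day = weekly,
                 total_dose_ug = sum(weekly) * 7),
            class = "dose_regimen")
}

# Plasma concentration (ng/mL) at hour t under continuous infusion:
# steady state = infusion rate / clearance.
regimen_concentration <- function(regimen, t_h, clearance_l_h) {
  w <- pmin(floor(t_h / 168) + 1, regimen$n_weeks)
  rate <- regimen$weekly_ug_day[w]          # ug/day
  rate / (clearance_l_h * 24)               # ug/L == ng/mL
}

#' Patient profile for in vivo simulation
#'
#' @param baseline_b_per_ul baseline blood B-cell density, cells/uL.
#' @param growth_per_day B-cell net growth rate, 1/day (0.071 fast, 0.0071
#'   slow).
#' @param t_b_ratio baseline T:B cell number ratio.
#' @param cd19_mean mean CD19 receptors per B cell (3e4 high, 1e4 low).
#' @param cd19_dispersion log-space SD of per-cell CD19.
#' @param t_multiplier function of time (h) returning a multiplier on the
#'   baseline T-cell numbers; T-cell dynamics are exogenous inputs.
#' @param cd3_per_tcell CD3 receptors per T cell.
#' @return object of class `patient_profile`.
#' @export
patient_profile <- function(baseline_b_per_ul = 200, growth_per_day = 0.0071,
                            t_b_ratio = 1, cd19_mean = 3e4,
                            cd19_dispersion = 0.5,
                            t_multiplier = function(t_h) 1,
                            cd3_per_tcell = 1e5) {
  if (baseline_b_per_ul <= 0) stop("patient_profile: baseline must be > 0")
  if (growth_per_day < 0) stop("patient_profile: growth rate must be >= 0")
  if (t_b_ratio <= 0) stop("patient_profile: t_b_ratio must be > 0")
  structure(list(baseline_b_per_ul = baseline_b_per_ul,
                 growth_per_day = growth_per_day, t_b_ratio = t_b_ratio,
                 cd19_mean = cd19_mean, cd19_dispersion = cd19_dispersion,
                 t_multiplier = t_multiplier, cd3_per_tcell = cd3_per_tcell),
            class = "patient_profile")
}

#' Simulation controls for the in vivo model
#'
#' @param duration_weeks simulated treatment duration, weeks.
#' @param n_agents number of B-cell agents carrying the population (each
#'   agent represents an equal, exponentially growing number of real cells).
#' @param clearance_l_h BiTE clearance, L/h (default 1.8 so that 28 ug/day
#'   gives ~0.65 ng/mL at steady state).
#' @param regimen_level,regimen_scheme defaults used when [run_invivo()] is
#'   not handed an explicit regimen.
#' @param record_every_h output sampling interval, h.
#' @inheritParams base_config
#' @return object of class `invivo_config`.
#' @export
invivo_config <- function(duration_weeks = 2, n_agents = 2000,
                          clearance_l_h = 1.8, regimen_level = "high",
                          regimen_scheme = 1, record_every_h = 24,
                          replicates = 1, seed = 1, params = sim_params()) {
  if (duration_weeks <= 0) stop("duration_weeks must be > 0")
  if (n_agents < 10) stop("n_agents must be >= 10")
  if (clearance_l_h <= 0) stop("clearance_l_h must be > 0")
  structure(list(duration_weeks = duration_weeks, n_agents = n_agents,
                 clearance_l_h = clearance_l_h,
                 regimen_level = regimen_level,
                 regimen_scheme = regimen_scheme,
                 record_every_h = record_every_h,
                 replicates = replicates, seed = as.integer(seed),
                 params = params),
            class = "invivo_config")
}

# Minimal in vivo state used by the trafficking/turnover operations and the
# main loop: B-cell agents (organ, cd19, state) plus the global agent weight.
invivo_state <- function(agents, weight, organs) {
  list(agents = agents, weight = weight, organs = organ_system(organs))
}

#' Hourly B-cell trafficking through the blood
#'
#' Each free B-cell agent leaves its organ with probability
#' `rate_per_h * dt_h`, passes through the blood, and is reassigned to a
#' compartment multinomially by the B-cell partition repertoire. Trafficking
#' alone conserves the total B-cell count exactly.
#'
#' @param state an in vivo state (list with `agents`, `weight`, `organs`).
#' @param dt_h time step in whole hours.
#' @param rate_per_h trafficking rate to blood (default 4.17%/h).
#' @return updated state.
#' @export
traffic_b_cells <- function(state, dt_h = 1, rate_per_h = 0.0417) {
  if (dt_h != round(dt_h) || dt_h < 1) {
    stop("traffic_b_cells: dt must be whole hours")
  }
  agents <- state$agents
  for (i in seq_len(dt_h)) {
    mov <- which(agents$state == "free" &
                   stats::runif(nrow(agents)) < rate_per_h)
    if (length(mov) > 0) {
      agents$organ[mov] <- state$organs$organ[
        sample.int(nrow(state$organs), length(mov), replace = TRUE,
                   prob = state$organs$b_fraction)]
    }
  }
  state$agents <- agents
  state
}

#' B-cell turnover
#'
#' Exponential growth at the profile rate, identical in every organ. Growth
#' scales the per-agent weight, so daughters inherit their parent's CD19
#' expression exactly and pure growth leaves the survivor CD19 distribution
#' unchanged: evolution in this model is selection, not mutation.
#'
#' @param state an in vivo state.
#' @param profile a [patient_profile()].
#' @param dt_h time step, h.
#' @return updated state with `weight` scaled by `exp(growth * dt/24)`.
#' @export
b_cell_turnover <- function(state, profile, dt_h = 1) {
  state$weight <- state$weight * exp(profile$growth_per_day * dt_h / 24)
  state
}

# Adhesion probability for B cells of given CD19 against the organ's T cells,
# evaluated on a (log CD19 x contact duration) grid and interpolated
# bilinearly per agent. occA/occB are the organ-hour equilibrium occupancies.
pa_lookup <- function(cd19, durations, occA, occB, cd3, params, k2d) {
  lo <- min(cd19); hi <- max(cd19)
  rng <- params$contact_duration_s
  if (hi / max(lo, 1) < 1.001) {
    return(contact_adhesion_prob(rep(cd3 * (1 - occA), length(cd19)),
                                 rep(cd3 * occA, length(cd19)),
                                 cd19 * (1 - occB), cd19 * occB,
                                 durations, params, k2d))
  }
  gx <- exp(seq(log(max(lo, 1)), log(hi), length.out = 12))
  gy <- seq(rng[1], rng[2], length.out = 6)
  grid <- expand.grid(x = gx, y = gy)
  pa <- contact_adhesion_prob(rep(cd3 * (1 - occA), nrow(grid)),
                              rep(cd3 * occA, nrow(grid)),
                              grid$x * (1 - occB), grid$x * occB,
                              grid$y, params, k2d)
  m <- matrix(pa, nrow = length(gx))
  ix <- pmin(pmax(findInterval(cd19, gx), 1), length(gx) - 1)
  iy <- pmin(pmax(findInterval(durations, gy), 1), length(gy) - 1)
  fx <- (log(cd19) - log(gx[ix])) / (log(gx[ix + 1]) - log(gx[ix]))
  fy <- (durations - gy[iy]) / (gy[iy + 1] - gy[iy])
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  m[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    m[cbind(ix + 1, iy)] * fx * (1 - fy) +
    m[cbind(ix, iy + 1)] * (1 - fx) * fy +
    m[cbind(ix + 1, iy + 1)] * fx * fy
}

#' Run the in vivo model
#'
#' Hourly loop over organ compartments: the infusion schedule sets each
#' organ's BiTE concentration (steady-state plasma level times the organ
#' exposure scaling); within each synapse-forming organ the soluble-phase
#' equilibrium is re-solved from current T/B antigen totals and every free
#' B-cell agent runs its 60 one-minute encounter rounds against the organ's
#' free T-cell density, with adhesion computed from its own CD19 expression;
#' engaged B cells are lysed 150 min later, releasing their T cells; B cells
#' then traffic through the blood and grow exponentially. T-cell dynamics are
#' exogenous (baseline T:B ratio plus an optional time-varying multiplier);
#' the blood compartment never forms synapses.
#'
#' @param organs an [organ_system()].
#' @param regimen a [dose_regimen()]; default built from the config's
#'   `regimen_level` / `regimen_scheme`.
#' @param profile a [patient_profile()].
#' @param config an [invivo_config()].
#' @return object of class `bite_invivo_sim`: `blood_b` (sampled time course
#'   of blood B density and survivor CD19), `organ_lysis` (per-organ baseline,
#'   lysed cells, share of all lysis, fractional lysis), `evolution`,
#'   `totals` (baseline, final, log10 kill), `regimen`, `profile`, `config`.
#' @export
run_invivo <- function(organs = organ_system(), regimen = NULL,
                       profile = patient_profile(),
                       config = invivo_config()) {
  stopifnot(inherits(config, "invivo_config"))
  organs <- organ_system(organs)
  if (is.null(regimen)) {
    regimen <- dose_regimen(config$regimen_level, config$regimen_scheme,
                            n_weeks = max(config$duration_weeks, 1))
  }
  params <- config$params
  k2d <- derive_2d_constants(params$constants, params$confinement_nm)
  set.seed(derive_seed(config$seed, 1))

  blood <- which(organs$organ == "blood")
  total_B0 <- profile$baseline_b_per_ul * 1000 * organs$volume_ml[blood] /
    organs$b_fraction[blood]
  n <- config$n_agents
  w0 <- total_B0 / n
  meanlog <- log(profile$cd19_mean) - profile$cd19_dispersion^2 / 2
  agents <- data.frame(
    id = seq_len(n),
    organ = organs$organ[sample.int(nrow(organs), n, replace = TRUE,
                                    prob = organs$b_fraction)],
    cd19 = stats::rlnorm(n, meanlog, profile$cd19_dispersion),
    state = rep("free", n),
    release_h = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  st <- invivo_state(agents, w0, organs)

  total_T0 <- total_B0 * profile$t_b_ratio
  T_count <- total_T0 * organs$t_fraction
  busy_T <- stats::setNames(numeric(nrow(organs)), organs$organ)
  baseline_w <- stats::setNames(
    vapply(organs$organ, function(o) sum(st$agents$organ == o), 1) * w0,
    organs$organ)
  lysed_w <- stats::setNames(numeric(nrow(organs)), organs$organ)

  n_hours <- round(config$duration_weeks * 168)
  rng <- params$contact_duration_s
  rec <- list()
  record <- function(t_h) {
    alive <- st$agents$state != "lysed"
    data.frame(time_h = t_h,
               b_per_ul = sum(alive) * st$weight *
                 organs$b_fraction[blood] / organs$volume_ml[blood] / 1000,
               total_b = sum(alive) * st$weight,
               mean_cd19 = if (any(alive)) mean(st$agents$cd19[alive])
                           else NA_real_)
  }
  rec[[1]] <- record(0)

  for (t in seq_len(n_hours)) {
    # lysis of expired synapses
    due <- which(st$agents$state == "engaged" & st$agents$release_h <= t)
    if (length(due) > 0) {
      for (o in unique(st$agents$organ[due])) {
        k <- sum(st$agents$organ[due] == o)
        lysed_w[o] <- lysed_w[o] + k * st$weight
        busy_T[o] <- max(busy_T[o] - k * st$weight, 0)
      }
      st$agents$state[due] <- "lysed"
    }
    conc <- regimen_concentration(regimen, t - 1, config$clearance_l_h)
    mult <- profile$t_multiplier(t)
    if (conc > 0) {
      for (oi in which(organs$forms_is)) {
        o <- organs$organ[oi]
        in_o <- which(st$agents$organ == o & st$agents$state == "free")
        if (length(in_o) == 0) next
        vol <- organs$volume_ml[oi]
        T_tot <- T_count[oi] * mult
        free_T <- max(T_tot - busy_T[o], 0)
        if (free_T <= 0) next
        alive_o <- which(st$agents$organ == o & st$agents$state != "lysed")
        A_tot <- T_tot * profile$cd3_per_tcell / vol * 1000 / AVOGADRO
        B_tot <- sum(st$agents$cd19[alive_o]) * st$weight / vol * 1000 /
          AVOGADRO
        Y_tot <- ngml_to_molar(conc * organs$exposure[oi], params$bite_mw)
        eq <- solve_equilibrium(params$constants, A_tot, B_tot, Y_tot)
        occA <- if (A_tot > 0) eq$AY / A_tot else 0
        occB <- if (B_tot > 0) eq$YB / B_tot else 0
        Pe <- encounter_probability(free_T / vol, params, "free")
        dur <- stats::runif(length(in_o), rng[1], rng[2])
        pa <- pa_lookup(st$agents$cd19[in_o], dur, occA, occB,
                        profile$cd3_per_tcell, params, k2d)
        p_hour <- 1 - (1 - Pe * pa)^(3600 / params$round_s)
        # cap expected engagements by available free T cells
        exp_cells <- sum(p_hour) * st$weight
        if (exp_cells > free_T) p_hour <- p_hour * free_T / exp_cells
        hit <- in_o[stats::runif(length(in_o)) < p_hour]
        max_hits <- floor(free_T / st$weight)
        if (length(hit) > max_hits) hit <- resample(hit, max_hits)
        if (length(hit) > 0) {
          st$agents$state[hit] <- "engaged"
          st$agents$release_h[hit] <- t + params$is_duration_min / 60
          busy_T[o] <- busy_T[o] + length(hit) * st$weight
        }
      }
    }
    st <- traffic_b_cells(st, 1)
    st <- b_cell_turnover(st, profile, 1)
    if (t %% config$record_every_h == 0 || t == n_hours) {
      rec[[length(rec) + 1]] <- record(t)
    }
  }

  blood_b <- do.call(rbind, rec)
  alive_end_w <- vapply(organs$organ, function(o)
    sum(st$agents$organ == o & st$agents$state != "lysed"), 1) * st$weight
  organ_lysis <- data.frame(
    organ = organs$organ,
    baseline_b = unname(baseline_w[organs$organ]),
    lysed = unname(lysed_w[organs$organ]),
    share_of_lysed_pct = if (sum(lysed_w) > 0)
      100 * unname(lysed_w[organs$organ]) / sum(lysed_w) else NA_real_,
    baseline_share_pct = 100 * unname(baseline_w[organs$organ]) /
      sum(baseline_w),
    lysis_fraction = unname(lysed_w[organs$organ]) /
      pmax(unname(lysed_w[organs$organ]) + unname(alive_end_w), 1e-300),
    stringsAsFactors = FALSE)
  alive <- st$agents$state != "lysed"
  totals <- c(baseline = total_B0,
              final = sum(alive) * st$weight,
              kill_log10 = log10(total_B0 / max(sum(alive) * st$weight,
                                                1e-300)))
  structure(list(blood_b = blood_b, organ_lysis = organ_lysis,
                 evolution = blood_b[, c("time_h", "mean_cd19")],
                 totals = totals, regimen = regimen, profile = profile,
                 organs = organs, config = config),
            class = "bite_invivo_sim")
}

#' Rank dosing regimens lexicographically
#'
#' Orders simulated treatment courses by (1) B-cell killing efficacy (log10
#' reduction of the systemic B-cell burden), (2) CD19 evolution (final
#' survivor-mean CD19 relative to baseline; higher = less antigen escape),
#' and (3) total administered dose (lower is better), with configurable
#' equivalence tolerances at the first two tiers. All bundles must share the
#' same patient scenario.
#'
#' @param bundles list of `bite_invivo_sim` objects (>= 2).
#' @param tol_kill_log10 equivalence band on the efficacy tier.
#' @param tol_cd19 relative equivalence band on the CD19 tier.
#' @return data.frame ranked best-first with the three tier metrics.
#' @export
rank_regimens <- function(bundles, tol_kill_log10 = 0.3, tol_cd19 = 0.05) {
  if (length(bundles) < 2) stop("rank_regimens: need at least two bundles")
  key <- function(b) paste(b$profile$baseline_b_per_ul,
                           b$profile$growth_per_day, b$profile$t_b_ratio,
                           b$profile$cd19_mean)
  if (length(unique(vapply(bundles, key, ""))) != 1) {
    stop("rank_regimens: bundles were run on different scenarios")
  }
  met <- data.frame(
    regimen = vapply(bundles, function(b)
      paste0(b$regimen$level, "/scheme", b$regimen$scheme), ""),
    kill_log10 = vapply(bundles, function(b) unname(b$totals["kill_log10"]),
                        1),
    final_cd19_ratio = vapply(bundles, function(b) {
      ev <- b$evolution
      utils::tail(ev$mean_cd19, 1) / ev$mean_cd19[1]
    }, 1),
    total_dose_ug = vapply(bundles, function(b) b$regimen$total_dose_ug, 1))
  better <- function(i, j) {
    dk <- met$kill_log10[i] - met$kill_log10[j]
    if (abs(dk) > tol_kill_log10) return(dk > 0)
    dc <- (met$final_cd19_ratio[i] - met$final_cd19_ratio[j]) /
      max(met$final_cd19_ratio[j], 1e-12)
    if (abs(dc) > tol_cd19) return(dc > 0)
    met$total_dose_ug[i] < met$total_dose_ug[j]
  }
  ord <- seq_len(nrow(met))
  for (a in seq_along(ord)) {
    for (b in seq_along(ord)) {
      if (b > a && better(ord[b], ord[a])) {
        tmp <- ord[a]; ord[a] <- ord[b]; ord[b] <- tmp
      }
    }
  }
  out <- met[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
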