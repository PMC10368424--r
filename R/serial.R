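#' Run the in vitro serial-engagement model (<= 72 h)
#'
#' Extends the base-model round loop with synapse detachment: every entity
#' dissolves `is_duration_min` (default 150 min) after formation, its target
#' members are lysed and recorded, and its effector members return to the free
#' pool for further engagement. The binary-complex equilibrium is recalibrated
#' hourly from the surviving cells' antigen totals; CD19 internalization is
#' off at this time scale and CD3 downregulation is frozen after the first
#' hour. BiTE concentration is held constant.
#'
#' @param config an [invitro_config()].
#' @return an object of class `bite_invitro_sim` with components
#'   `lysis` (per replicate and hour: cumulative target lysis fraction and
#'   effector engagement), `kills` (one row per lysed target: id, CD19 at
#'   death, time, entity label), `evolution` (survivor CD19 snapshots),
#'   `summary` (replicate mean/SE of final lysis), and `config`.
#' @export
run_invitro <- function(config) {
  stopifnot(inherits(config, "invitro_config"))
  params <- config$params
  n_rounds <- ceiling(config$duration_h * 3600 / params$round_s)
  is_dur_s <- params$is_duration_min * 60
  lysis <- list(); kills <- list(); evo <- list()
  for (r in seq_len(config$replicates)) {
    set.seed(derive_seed(config$seed, r))
    st <- init_state(config)
    tgt_idx <- which(st$agents$role == "target")
    initial <- data.frame(id = st$agents$id[tgt_idx],
                          cd19 = st$agents$antigen_total[tgt_idx])
    n_t <- length(tgt_idx)
    krec <- list()
    hour_rows <- matrix(0, config$duration_h + 1, 3)
    hour_rows[1, ] <- c(0, 0, 0)
    for (i in seq_len(n_rounds)) {
      # detachment of expired entities (checked at round start)
      exp_ids <- which(st$entities$active &
                         st$clock - st$entities$formed_at >= is_dur_s)
      if (length(exp_ids) > 0) {
        for (k in exp_ids) {
          members <- which(st$agents$entity == st$entities$id[k] &
                             st$agents$state == "engaged")
          t_m <- members[st$agents$role[members] == "target"]
          e_m <- members[st$agents$role[members] == "effector"]
          krec[[length(krec) + 1]] <- data.frame(
            target_id = st$agents$id[t_m],
            cd19_at_death = st$agents$antigen_total[t_m],
            time_h = st$clock / 3600,
            label = st$entities$label[k])
          st$agents$state[t_m] <- "lysed"
          st$agents$entity[t_m] <- NA_integer_
          st$agents$state[e_m] <- "free"
          st$agents$entity[e_m] <- NA_integer_
          st$entities$active[k] <- FALSE
        }
      }
      # hourly re-equilibration against surviving antigen totals
      if (st$clock > 0 && st$clock %% 3600 == 0) {
        st$eq <- bulk_equilibrium(st$agents, st$volume_ml, config$bite_ngml,
                                  params)
        alive <- which(st$agents$state != "lysed")
        upd <- allocate_binary_complexes(st$agents[alive, , drop = FALSE],
                                         st$eq, params$allocation)
        st$agents$binary_complex[alive] <- upd$binary_complex
        st$agents$free_antigen[alive] <- upd$free_antigen
      }
      st <- step_round(st, downreg = st$clock < 3600, internalization = FALSE)
      if (st$clock %% 3600 == 0) {
        h <- st$clock / 3600
        lysed <- sum(st$agents$state == "lysed" & st$agents$role == "target")
        fr <- engaged_fractions(st$agents)
        hour_rows[h + 1, ] <- c(h, lysed / max(n_t, 1), fr["effector"])
      }
    }
    kr <- if (length(krec) > 0) do.call(rbind, krec) else
      data.frame(target_id = integer(0), cd19_at_death = numeric(0),
                 time_h = numeric(0), label = character(0))
    lysis[[r]] <- data.frame(replicate = r, time_h = hour_rows[, 1],
                             lysis_fraction = hour_rows[, 2],
                             effector_engaged = hour_rows[, 3])
    kills[[r]] <- cbind(replicate = if (nrow(kr) > 0) r else integer(0), kr)
    ev <- evolution_summary(kr, initial, config$snapshot_times_h)
    evo[[r]] <- cbind(replicate = r, ev)
  }
  lysis <- do.call(rbind, lysis)
  kills <- do.call(rbind, kills)
  final <- lysis$lysis_fraction[lysis$time_h == config$duration_h]
  structure(list(lysis = lysis, kills = kills,
                 evolution = do.call(rbind, evo),
                 summary = c(mean = mean(final),
                             se = stats::sd(final) / sqrt(length(final))),
                 config = config),
            class = "bite_invitro_sim")
}

#' Survivor CD19 snapshots from kill records
#'
#' Reconstructs the surviving target population at each requested time by
#' removing targets killed up to that time from the initial population, and
#' summarises its CD19 distribution. Under any positive killing pressure the
#' survivor mean is non-increasing in cumulative lysis because low-CD19 cells
#' are preferentially spared.
#'
#' @param kills data.frame with columns `target_id`, `time_h` (and typically
#'   `cd19_at_death`); may have zero rows.
#' @param initial data.frame of the initial target population: `id`, `cd19`.
#' @param times_h snapshot times in hours.
#' @return data.frame: `time_h`, `survivors`, `lysed`, `mean_cd19`,
#'   `q10`, `q50`, `q90`.
#' @export
evolution_summary <- function(kills, initial, times_h = c(0, 24, 48, 72)) {
  rows <- lapply(times_h, function(tt) {
    dead <- kills$target_id[kills$time_h <= tt]
    surv <- initial$cd19[!initial$id %in% dead]
    data.frame(time_h = tt, survivors = length(surv), lysed = length(dead),
               mean_cd19 = if (length(surv) > 0) mean(surv) else NA_real_,
               q10 = if (length(surv) > 0)
                 unname(stats::quantile(surv, 0.1)) else NA_real_,
               q50 = if (length(surv) > 0)
                 unname(stats::quantile(surv, 0.5)) else NA_real_,
               q90 = if (length(surv) > 0)
                 unname(stats::quantile(surv, 0.9)) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Target lysis over a grid of effector and target densities
#'
#' Runs the in vitro model at every combination of the two density grids and
#' reports the final lysis percentage, optionally annotated with named
#' organ-typical (effector, target) density pairs.
#'
#' @param effector_density_grid,target_density_grid positive densities,
#'   cells/mL.
#' @param config an [invitro_config()] supplying everything else.
#' @param organ_densities optional data.frame with columns `organ`,
#'   `effector_per_ml`, `target_per_ml` used as overlay markers.
#' @return an object of class `bite_lysis_grid`: list with `lysis_pct` matrix
#'   (rows = effector densities), the two grids, and `organs`.
#' @export
organ_grid_lysis <- function(effector_density_grid, target_density_grid,
                             config, organ_densities = NULL) {
  if (any(effector_density_grid < 0) || any(target_density_grid <= 0)) {
    stop("organ_grid_lysis: density grids must be positive")
  }
  m <- matrix(NA_real_, length(effector_density_grid),
              length(target_density_grid),
              dimnames = list(paste0("E_", signif(effector_density_grid, 3)),
                              paste0("T_", signif(target_density_grid, 3))))
  for (i in seq_along(effector_density_grid)) {
    for (j in seq_along(target_density_grid)) {
      e <- effector_density_grid[i]; t <- target_density_grid[j]
      if (e == 0) { m[i, j] <- 0; next }
      cfg <- config
      cfg$total_density_per_ml <- e + t
      cfg$et_ratio <- e / t
      cfg$effector_density_per_ml <- e
      cfg$target_density_per_ml <- t
      res <- run_invitro(cfg)
      m[i, j] <- 100 * unname(res$summary["mean"])
    }
  }
  structure(list(lysis_pct = m,
                 effector_density_grid = effector_density_grid,
                 target_density_grid = target_density_grid,
                 organs = organ_densities),
            class = "bite_lysis_grid")
}
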