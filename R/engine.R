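# sample() semantics without the scalar-x surprise
resample <- function(x, n = length(x), replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

#' Classify a synapse entity by composition
#'
#' Entities grow from a typical ET synapse by single-cell accretion up to four
#' cells; the six reachable compositions map to the standard labels.
#'
#' @param e_count,t_count effector / target members.
#' @param join_order optional character vector of member roles in join order;
#'   if given it must be consistent with the counts and start E, T.
#' @return one of `"ET"`, `"ETE"`, `"ETT"`, `"ETET"`, `"ETEE"`, `"ETTT"`.
#' @export
classify_entity <- function(e_count, t_count, join_order = NULL) {
  if (!is.null(join_order)) {
    if (sum(join_order == "effector") != e_count ||
        sum(join_order == "target") != t_count ||
        !identical(join_order[1:2], c("effector", "target"))) {
      stop("classify_entity: join order inconsistent with composition")
    }
  }
  key <- paste(e_count, t_count, sep = ",")
  lab <- switch(key,
                "1,1" = "ET", "2,1" = "ETE", "1,2" = "ETT",
                "2,2" = "ETET", "3,1" = "ETEE", "1,3" = "ETTT", NULL)
  if (is.null(lab)) {
    stop("classify_entity: composition (", key,
         ") not reachable by single-cell accretion from ET")
  }
  lab
}

# Initialise a simulation state for one replicate. Bulk equilibrium is solved
# from the realised per-cell antigen totals so that allocated complexes close
# exactly against the bulk.
init_state <- function(config) {
  params <- config$params
  vol_ml <- config$scaled_volume_ul * 1e-3
  nE <- round(config$effector_density_per_ml * vol_ml)
  nT <- round(config$target_density_per_ml * vol_ml)
  eff <- generate_population(nE, "effector", config$cd3_spec)
  tgt <- generate_population(nT, "target", config$cd19_spec, id_offset = nE)
  agents <- rbind(eff, tgt)
  eq <- bulk_equilibrium(agents, vol_ml, config$bite_ngml, params)
  agents <- allocate_binary_complexes(agents, eq, params$allocation)
  list(clock = 0,
       agents = agents,
       entities = data.frame(id = integer(0), e = integer(0), t = integer(0),
                             label = character(0), formed_at = numeric(0),
                             active = logical(0), stringsAsFactors = FALSE),
       volume_ml = vol_ml,
       eq = eq,
       params = params,
       k2d = derive_2d_constants(params$constants, params$confinement_nm),
       next_entity = 1L)
}

# Solve the soluble-phase equilibrium for the current (non-lysed) population.
bulk_equilibrium <- function(agents, vol_ml, bite_ngml, params) {
  alive <- agents$state != "lysed"
  is_e <- alive & agents$role == "effector"
  is_t <- alive & agents$role == "target"
  A_tot <- sum(agents$antigen_total[is_e]) / vol_ml * 1000 / AVOGADRO
  B_tot <- sum(agents$antigen_total[is_t]) / vol_ml * 1000 / AVOGADRO
  Y_tot <- ngml_to_molar(bite_ngml, params$bite_mw)
  solve_equilibrium(params$constants, A_tot, B_tot, Y_tot)
}

#' Advance the simulation by one encounter round
#'
#' Executes one round (default 60 s) of the base-model loop: (1) encounter
#' probabilities are recomputed from current free-entity densities; (2) every
#' free effector gets one encounter chance against the free targets, and on
#' encounter a contact is drawn (surface counts of the specific pair, uniform
#' contact duration) and accepted with the adhesion probability -- failures
#' remain free; (3) every 2-3-cell entity existing at the start of the round
#' may recruit one free cell, chosen effector vs target in proportion to the
#' free pools, with the spatial coefficient of its size class and the standard
#' adhesion test against a random exposed member; (4) receptor updates
#' (CD3 downregulation, CD19 internalization) are applied.
#'
#' @param state simulation state from the internal initialiser.
#' @param downreg,internalization logical switches for the step-4 updates.
#' @return updated state with `clock` advanced by one round.
#' @export
step_round <- function(state, downreg = TRUE, internalization = TRUE) {
  params <- state$params
  dt <- params$round_s
  agents <- state$agents
  ents <- state$entities
  vol <- state$volume_ml
  rng <- params$contact_duration_s

  open_ents <- which(ents$active & (ents$e + ents$t) < 4L)

  # --- step 2: free effector vs free target pairing -------------------------
  freeE <- which(agents$role == "effector" & agents$state == "free")
  freeT <- which(agents$role == "target" & agents$state == "free")
  if (length(freeE) > 0 && length(freeT) > 0) {
    Pe <- encounter_probability(length(freeT) / vol, params, "free", dt)
    enc <- freeE[stats::runif(length(freeE)) < Pe]
    if (length(enc) > 0) {
      # shuffled-order priority: each encountering effector claims a distinct
      # free target; surplus effectors have futile rounds
      enc <- resample(enc)
      n_pair <- min(length(enc), length(freeT))
      enc <- enc[seq_len(n_pair)]
      tgt <- resample(freeT, n_pair)
      dur <- stats::runif(length(enc), rng[1], rng[2])
      pa <- contact_adhesion_prob(agents$free_antigen[enc],
                                  agents$binary_complex[enc],
                                  agents$free_antigen[tgt],
                                  agents$binary_complex[tgt],
                                  dur, params, state$k2d)
      adh <- stats::runif(length(enc)) < pa
      for (i in seq_along(enc)) {
        if (!adh[i]) next
        ti <- tgt[i]
        if (agents$state[ti] != "free") next  # taken earlier this round
        eid <- state$next_entity
        state$next_entity <- eid + 1L
        ents <- rbind(ents, data.frame(id = eid, e = 1L, t = 1L, label = "ET",
                                       formed_at = state$clock, active = TRUE,
                                       stringsAsFactors = FALSE))
        agents$state[c(enc[i], ti)] <- "engaged"
        agents$entity[c(enc[i], ti)] <- eid
      }
    }
  }

  # --- step 3: recruitment by pre-existing entities -------------------------
  if (length(open_ents) > 0) {
    freeE <- which(agents$role == "effector" & agents$state == "free")
    freeT <- which(agents$role == "target" & agents$state == "free")
    nfree <- length(freeE) + length(freeT)
    if (nfree > 0) {
      for (k in resample(open_ents)) {
        nE_f <- sum(agents$state[freeE] == "free")
        freeE <- freeE[agents$state[freeE] == "free"]
        freeT <- freeT[agents$state[freeT] == "free"]
        nfree <- length(freeE) + length(freeT)
        if (nfree == 0) break
        cls <- if (ents$e[k] + ents$t[k] == 2L) "size2" else "size3"
        # free effectors are themselves mobile: that channel runs at the
        # relative diffusion (~2D), immotile free targets at D
        w_e <- 2 * length(freeE)
        w_t <- length(freeT)
        Pe <- encounter_probability((w_e + w_t) / vol, params, cls, dt)
        if (stats::runif(1) >= Pe) next
        pick_e <- stats::runif(1) < w_e / (w_e + w_t)
        cand <- if (pick_e) resample(freeE, 1) else resample(freeT, 1)
        members <- which(agents$entity == ents$id[k] &
                           agents$state == "engaged")
        exposed_role <- if (pick_e) "target" else "effector"
        exposed <- resample(members[agents$role[members] == exposed_role], 1)
        dur <- stats::runif(1, rng[1], rng[2])
        eff_i <- if (pick_e) cand else exposed
        tgt_i <- if (pick_e) exposed else cand
        pa <- contact_adhesion_prob(agents$free_antigen[eff_i],
                                    agents$binary_complex[eff_i],
                                    agents$free_antigen[tgt_i],
                                    agents$binary_complex[tgt_i],
                                    dur, params, state$k2d)
        if (stats::runif(1) < pa) {
          if (pick_e) ents$e[k] <- ents$e[k] + 1L else ents$t[k] <- ents$t[k] + 1L
          ents$label[k] <- classify_entity(ents$e[k], ents$t[k])
          agents$state[cand] <- "engaged"
          agents$entity[cand] <- ents$id[k]
        }
      }
    }
  }

  # --- step 4: receptor updates --------------------------------------------
  is_e <- which(agents$role == "effector" & agents$state != "lysed")
  if (downreg && length(is_e) > 0) {
    upd <- update_cd3_downregulation(agents[is_e, , drop = FALSE], dt, params)
    agents$antigen_total[is_e] <- upd$antigen_total
    agents$free_antigen[is_e] <- upd$free_antigen
    agents$binary_complex[is_e] <- upd$binary_complex
    agents$cd3_lost[is_e] <- upd$cd3_lost
  }
  is_t <- which(agents$role == "target" & agents$state != "lysed")
  if (internalization && length(is_t) > 0) {
    upd <- update_cd19_internalization(agents[is_t, , drop = FALSE], dt / 60,
                                       params$cd19_internalization_min)
    agents$antigen_total[is_t] <- upd$antigen_total
    agents$binary_complex[is_t] <- upd$binary_complex
  }

  check_state_invariants(agents, ents)
  state$agents <- agents
  state$entities <- ents
  state$clock <- state$clock + dt
  state
}

check_state_invariants <- function(agents, ents) {
  eng <- agents$state == "engaged"
  if (any(eng & is.na(agents$entity))) {
    stop("state invariant violated: engaged agent without entity")
  }
  if (nrow(ents) > 0) {
    sizes <- ents$e + ents$t
    if (any(sizes > 4L) || any(sizes < 2L)) {
      stop("state invariant violated: entity size outside 2..4")
    }
    counts <- table(factor(agents$entity[!is.na(agents$entity) &
                                           agents$state != "lysed"],
                           levels = ents$id[ents$active]))
    if (any(counts != sizes[ents$active][match(names(counts),
                                               ents$id[ents$active])])) {
      stop("state invariant violated: membership/tally mismatch")
    }
  }
  invisible(TRUE)
}

engaged_fractions <- function(agents) {
  e <- agents$role == "effector"
  t <- agents$role == "target"
  c(effector = if (any(e)) mean(agents$state[e] != "free") else 0,
    target = if (any(t)) mean(agents$state[t] != "free") else 0)
}

#' Run the base model (<= 1 h of IS formation)
#'
#' Replicated round-based agent simulation of immunological synapse formation
#' in a scaled co-incubation subvolume. Returns per-round engagement time
#' series, the final synapse-entity table, and replicate-averaged summaries.
#'
#' @param config a [base_config()].
#' @return an object of class `bite_base_sim` with components
#'   `timeseries` (per replicate and time: engaged fractions),
#'   `summary` (mean and SE over replicates per timepoint),
#'   `entities` (pooled final entity table with replicate column),
#'   `variants` (per-replicate [summarize_variants()] output), and `config`.
#' @export
run_base <- function(config) {
  stopifnot(inherits(config, "base_config"))
  n_rounds <- ceiling(config$duration_min * 60 / config$params$round_s)
  ts <- list(); ent <- list(); var <- list()
  for (r in seq_len(config$replicates)) {
    set.seed(derive_seed(config$seed, r))
    st <- init_state(config)
    rows <- matrix(0, n_rounds + 1, 3)
    rows[1, ] <- c(0, engaged_fractions(st$agents))
    for (i in seq_len(n_rounds)) {
      st <- step_round(st)
      rows[i + 1, ] <- c(st$clock / 60, engaged_fractions(st$agents))
    }
    ts[[r]] <- data.frame(replicate = r, time_min = rows[, 1],
                          effector_engaged = rows[, 2],
                          target_engaged = rows[, 3])
    if (nrow(st$entities) > 0) {
      ent[[r]] <- cbind(replicate = r, st$entities)
    }
    var[[r]] <- summarize_variants(st)
  }
  ts <- do.call(rbind, ts)
  entities <- if (length(ent) > 0) do.call(rbind, ent) else
    data.frame(replicate = integer(0), id = integer(0), e = integer(0),
               t = integer(0), label = character(0), formed_at = numeric(0),
               active = logical(0))
  agg <- stats::aggregate(cbind(effector_engaged, target_engaged) ~ time_min,
                          data = ts, FUN = mean)
  sem <- stats::aggregate(cbind(effector_engaged, target_engaged) ~ time_min,
                          data = ts,
                          FUN = function(x) stats::sd(x) / sqrt(length(x)))
  names(sem)[-1] <- paste0(names(sem)[-1], "_se")
  structure(list(timeseries = ts, summary = merge(agg, sem, by = "time_min"),
                 entities = entities, variants = var, config = config),
            class = "bite_base_sim")
}

derive_seed <- function(seed, replicate, stream = 0L) {
  (as.integer(seed) * 1009L + as.integer(replicate) * 7919L +
     as.integer(stream) * 104729L) %% 2147483587L
}

#' Summarise synapse-variant composition
#'
#' The E:T ratio statistics follow the co-incubation-sample convention: for
#' each sample (replicate) the ratio of effector to target cells engaged in
#' synapses is computed in aggregate — over all synapses and over variants
#' only — and the median is taken across samples. If no `replicate` column is
#' present the entity table is treated as one sample.
#'
#' @param state a simulation state, a `bite_base_sim`, or an entity
#'   data.frame with columns `e`, `t`, `label` (optionally `replicate`).
#' @return list with `n_entities`, `variant_fraction` (share of all synapses
#'   with > 2 cells), `composition` (shares of the five variant labels among
#'   variants, summing to 1), `median_et_all`, `median_et_variants`.
#' @export
summarize_variants <- function(state) {
  ents <- if (is.data.frame(state)) state
          else if (inherits(state, "bite_base_sim")) state$entities
          else state$entities
  if (is.null(ents) || nrow(ents) == 0) {
    return(list(n_entities = 0L, variant_fraction = NA_real_,
                composition = stats::setNames(rep(NA_real_, 5),
                                              c("ETE", "ETT", "ETET", "ETEE",
                                                "ETTT")),
                median_et_all = NA_real_, median_et_variants = NA_real_))
  }
  is_var <- ents$label != "ET"
  comp <- table(factor(ents$label[is_var],
                       levels = c("ETE", "ETT", "ETET", "ETEE", "ETTT")))
  comp <- if (sum(comp) > 0) comp / sum(comp) else comp * NA_real_
  grp <- if ("replicate" %in% names(ents)) ents$replicate else
    rep(1L, nrow(ents))
  ratio_by <- function(keep) {
    r <- vapply(split(ents[keep, , drop = FALSE], grp[keep]),
                function(d) sum(d$e) / sum(d$t), 1)
    if (length(r) > 0) stats::median(r) else NA_real_
  }
  list(n_entities = nrow(ents),
       variant_fraction = mean(is_var),
       composition = c(unclass(comp)),
       median_et_all = ratio_by(rep(TRUE, nrow(ents))),
       median_et_variants = if (any(is_var)) ratio_by(is_var) else NA_real_)
}
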