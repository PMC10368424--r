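# Independent oracles used by the test suite. These deliberately avoid the
# package's own solver paths: the equilibrium oracle is a damped fixed-point
# iteration, the encounter oracle is a brute-force Brownian random walk among
# absorbing spheres, and the bond oracle is a Gillespie stochastic simulation
# of the patch reaction scheme.

# Fixed-point solution of the two-competing-ligand equilibrium:
# iterate Y <- Y_tot / (1 + A_free/KD_A + B_free/KD_B) with the free antigen
# levels updated from conservation, damped for stability.
fixed_point_equilibrium <- function(KD_A, KD_B, A_tot, B_tot, Y_tot,
                                    tol = 1e-14, max_iter = 100000) {
  Y <- Y_tot / 2
  for (i in seq_len(max_iter)) {
    A_free <- A_tot / (1 + Y / KD_A)
    B_free <- B_tot / (1 + Y / KD_B)
    Y_new <- Y_tot / (1 + A_free / KD_A + B_free / KD_B)
    Y_next <- 0.5 * Y + 0.5 * Y_new
    if (abs(Y_next - Y) <= tol * max(Y_tot, 1e-300)) {
      Y <- Y_next
      break
    }
    Y <- Y_next
  }
  A_free <- A_tot / (1 + Y / KD_A)
  B_free <- B_tot / (1 + Y / KD_B)
  list(Y_free = Y, A_free = A_free, B_free = B_free,
       AY = A_free * Y / KD_A, YB = B_free * Y / KD_B)
}

# Closed-form single-ligand equilibrium (quadratic) for B + Y <-> YB.
single_ligand_yb <- function(KD, B_tot, Y_tot) {
  s <- B_tot + Y_tot + KD
  (s - sqrt(s^2 - 4 * B_tot * Y_tot)) / 2
}

# Brownian-walk encounter oracle: point walkers diffusing with coefficient D
# in a periodic box containing one immotile absorbing sphere of radius R at
# the box centre (density 1/L^3). Returns the fraction absorbed within t_max.
brownian_hit_fraction <- function(n_walkers, D, R, L, t_max, dt) {
  sigma <- sqrt(2 * D * dt)
  pos <- matrix(stats::runif(3 * n_walkers, 0, L), ncol = 3)
  centre <- L / 2
  d2 <- rowSums((pos - centre)^2)
  while (any(d2 < R^2)) {       # do not start inside the sphere
    inside <- d2 < R^2
    pos[inside, ] <- matrix(stats::runif(3 * sum(inside), 0, L), ncol = 3)
    d2 <- rowSums((pos - centre)^2)
  }
  n0 <- n_walkers
  absorbed <- 0L
  steps <- ceiling(t_max / dt)
  for (s in seq_len(steps)) {
    n <- nrow(pos)
    if (n == 0) break
    pos <- pos + matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3)
    pos <- pos %% L
    d2 <- (pos[, 1] - centre)^2 + (pos[, 2] - centre)^2 +
      (pos[, 3] - centre)^2
    hit <- d2 < R^2
    absorbed <- absorbed + sum(hit)
    pos <- pos[!hit, , drop = FALSE]
  }
  c(fraction = absorbed / n0,
    se = sqrt(absorbed / n0 * (1 - absorbed / n0) / n0))
}

# Gillespie simulation of the contact-patch scheme, in molecule counts:
#   A + YB -> AYB  (rate konA/area per pair)
#   AY + B -> AYB  (rate konB/area per pair)
#   AYB -> A + YB  (koffA)
#   AYB -> AY + B  (koffB)
# Returns the bond count N at time t_end for one realisation.
gillespie_bonds_once <- function(nA, nAY, nB, nYB, konA, konB, koffA, koffB,
                                 area, t_end) {
  t <- 0
  N <- 0L
  ka <- konA / area
  kb <- konB / area
  repeat {
    a1 <- ka * nA * nYB
    a2 <- kb * nAY * nB
    a3 <- koffA * N
    a4 <- koffB * N
    a0 <- a1 + a2 + a3 + a4
    if (a0 <= 0) break
    t <- t + stats::rexp(1, a0)
    if (t > t_end) break
    u <- stats::runif(1) * a0
    if (u < a1) {
      nA <- nA - 1L; nYB <- nYB - 1L; N <- N + 1L
    } else if (u < a1 + a2) {
      nAY <- nAY - 1L; nB <- nB - 1L; N <- N + 1L
    } else if (u < a1 + a2 + a3) {
      nA <- nA + 1L; nYB <- nYB + 1L; N <- N - 1L
    } else {
      nAY <- nAY + 1L; nB <- nB + 1L; N <- N - 1L
    }
  }
  N
}

gillespie_bonds_mean <- function(n_runs, ...) {
  draws <- vapply(seq_len(n_runs), function(i) gillespie_bonds_once(...), 1)
  c(mean = mean(draws), se = stats::sd(draws) / sqrt(n_runs))
}

# Final engagement percent of a base run (column helper used across tests).
final_engagement_pct <- function(res) {
  fin <- res$summary[nrow(res$summary), ]
  c(eff = 100 * fin$effector_engaged, se = 100 * fin$effector_engaged_se,
    tgt = 100 * fin$target_engaged)
}
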