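#' Binding rate constants for a bispecific ligand against two antigens
#'
#' Bundles 3D association/dissociation rate constants for the two arms of a
#' bispecific T cell engager: arm A binds CD3 on effector cells, arm B binds
#' CD19 on target cells. Equilibrium constants KD are always derived from the
#' rates, never stored independently.
#'
#' @param kon_A,kon_B on-rates, 1/(M*s).
#' @param koff_A,koff_B off-rates, 1/s.
#' @return an object of class `binding_constants` with derived `KD_A`, `KD_B`.
#' @export
binding_constants <- function(kon_A = 1e5, koff_A = 2.6e-2,
                              kon_B = 1e5, koff_B = 1.49e-4) {
  vals <- c(kon_A = kon_A, koff_A = koff_A, kon_B = kon_B, koff_B = koff_B)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("binding_constants: all rates must be positive and finite")
  }
  structure(list(kon_A = kon_A, koff_A = koff_A,
                 kon_B = kon_B, koff_B = koff_B,
                 KD_A = koff_A / kon_A, KD_B = koff_B / kon_B),
            class = "binding_constants")
}

#' @export
print.binding_constants <- function(x, ...) {
  cat("BiTE binding constants (3D)\n")
  cat(sprintf("  CD3 arm : kon %.3g /M/s, koff %.3g /s, KD %.3g M\n",
              x$kon_A, x$koff_A, x$KD_A))
  cat(sprintf("  CD19 arm: kon %.3g /M/s, koff %.3g /s, KD %.3g M\n",
              x$kon_B, x$koff_B, x$KD_B))
  invisible(x)
}

#' Solve the soluble-phase binding equilibrium of one ligand vs two antigens
#'
#' Mass-action equilibrium of a bispecific ligand Y binding two competing
#' antigens A (CD3) and B (CD19) in solution: A + Y <-> AY with KD_A and
#' B + Y <-> YB with KD_B. Conservation of A, B and Y reduces the system to a
#' single monotone equation in free ligand,
#' `Y + A_tot*Y/(KD_A + Y) + B_tot*Y/(KD_B + Y) = Y_tot`,
#' whose unique physical root on `[0, Y_tot]` is bracketed and polished by
#' Newton iteration. Ternary complexes do not form in solution; they are a
#' membrane-restricted species handled by the contact module.
#'
#' @param constants a [binding_constants()] object.
#' @param A_tot,B_tot,Y_tot total molar concentrations (>= 0).
#' @param tol relative conservation tolerance (default 1e-12 for the polish;
#'   results are validated to 1e-9).
#' @return an object of class `equilibrium_state`: list with totals and the
#'   equilibrium concentrations `A_free`, `B_free`, `Y_free`, `AY`, `YB`.
#' @export
solve_equilibrium <- function(constants, A_tot, B_tot, Y_tot, tol = 1e-12) {
  stopifnot(inherits(constants, "binding_constants"))
  if (any(c(A_tot, B_tot, Y_tot) < 0)) {
    stop("solve_equilibrium: total concentrations must be non-negative")
  }
  KD_A <- constants$KD_A
  KD_B <- constants$KD_B

  if (Y_tot == 0) {
    Y <- 0
  } else if (A_tot == 0 && B_tot == 0) {
    Y <- Y_tot
  } else {
    f <- function(y) {
      y * (1 + A_tot / (KD_A + y) + B_tot / (KD_B + y)) - Y_tot
    }
    # f(0) = -Y_tot < 0, f(Y_tot) >= 0: root is bracketed
    Y <- stats::uniroot(f, interval = c(0, Y_tot),
                        tol = .Machine$double.eps^0.75)$root
    # Newton polish on the same residual
    fp <- function(y) {
      1 + A_tot * KD_A / (KD_A + y)^2 + B_tot * KD_B / (KD_B + y)^2
    }
    for (i in seq_len(50)) {
      step <- f(Y) / fp(Y)
      Ynew <- Y - step
      if (Ynew < 0 || Ynew > Y_tot) break
      Y <- Ynew
      if (abs(step) <= tol * max(Y_tot, .Machine$double.xmin)) break
    }
    if (Y < 0 || Y > Y_tot || !is.finite(Y)) {
      stop("solve_equilibrium: no physical root in [0, Y_tot]")
    }
  }

  A_free <- A_tot * KD_A / (KD_A + Y)
  B_free <- B_tot * KD_B / (KD_B + Y)
  AY <- A_tot * Y / (KD_A + Y)
  YB <- B_tot * Y / (KD_B + Y)

  out <- structure(list(A_tot = A_tot, B_tot = B_tot, Y_tot = Y_tot,
                        A_free = A_free, B_free = B_free, Y_free = Y,
                        AY = AY, YB = YB),
                   class = "equilibrium_state")
  check_equilibrium(out, constants, tol = 1e-9)
  out
}

# Validate conservation and mass-action residuals of an equilibrium state.
check_equilibrium <- function(eq, constants, tol = 1e-9) {
  sc <- function(x) max(x, .Machine$double.xmin)
  if (abs(eq$A_free + eq$AY - eq$A_tot) > tol * sc(eq$A_tot) ||
      abs(eq$B_free + eq$YB - eq$B_tot) > tol * sc(eq$B_tot) ||
      abs(eq$Y_free + eq$AY + eq$YB - eq$Y_tot) > tol * sc(eq$Y_tot)) {
    stop("solve_equilibrium: conservation violated beyond tolerance")
  }
  if (abs(eq$AY - eq$A_free * eq$Y_free / constants$KD_A) > tol * sc(eq$Y_tot) ||
      abs(eq$YB - eq$B_free * eq$Y_free / constants$KD_B) > tol * sc(eq$Y_tot)) {
    stop("solve_equilibrium: mass-action residual beyond tolerance")
  }
  invisible(TRUE)
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Binding equilibrium (mol/L)\n")
  cat(sprintf("  A: total %.3g, free %.3g, AY %.3g\n", x$A_tot, x$A_free, x$AY))
  cat(sprintf("  B: total %.3g, free %.3g, YB %.3g\n", x$B_tot, x$B_free, x$YB))
  cat(sprintf("  Y: total %.3g, free %.3g\n", x$Y_tot, x$Y_free))
  invisible(x)
}

#' Binary-complex occupancy over a grid of ligand concentrations
#'
#' Solves the competing-ligand equilibrium for each total BiTE concentration on
#' an ascending grid and reports, per row, the binary complexes and a
#' crosslinking-potential proxy
#' `occA*(1 - occB) + occB*(1 - occA)` (occupied arm meeting an available
#' co-partner on the opposing membrane). Over a sufficiently wide grid the
#' proxy is bell-shaped: at high ligand both antigens are occupied by separate
#' ligand molecules and crosslinking collapses.
#'
#' @inheritParams solve_equilibrium
#' @param Y_grid ascending vector of total ligand concentrations (mol/L).
#' @return data.frame with columns `Y_tot`, `A_free`, `B_free`, `Y_free`,
#'   `AY`, `YB`, `crosslink_potential`.
#' @export
occupancy_curve <- function(constants, A_tot, B_tot, Y_grid) {
  if (length(Y_grid) == 0) stop("occupancy_curve: Y_grid must be nonempty")
  if (is.unsorted(Y_grid, strictly = FALSE)) {
    stop("occupancy_curve: Y_grid must be ascending")
  }
  rows <- lapply(Y_grid, function(y) {
    eq <- solve_equilibrium(constants, A_tot, B_tot, y)
    occA <- if (A_tot > 0) eq$AY / A_tot else 0
    occB <- if (B_tot > 0) eq$YB / B_tot else 0
    data.frame(Y_tot = y, A_free = eq$A_free, B_free = eq$B_free,
               Y_free = eq$Y_free, AY = eq$AY, YB = eq$YB,
               crosslink_potential = occA * (1 - occB) + occB * (1 - occA))
  })
  do.call(rbind, rows)
}
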