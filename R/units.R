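#' @keywords internal
AVOGADRO <- 6.02214076e23

#' Convert per-cell receptor counts to a molar concentration
#'
#' Treats membrane receptors as well-mixed solutes in the co-incubation volume,
#' the convention used to feed the soluble-phase binding equilibrium from
#' cell-level inputs.
#'
#' @param receptors_per_cell mean receptor copies per cell (>= 0).
#' @param cell_density_per_ml cell density in cells per mL (>= 0).
#' @return concentration in mol/L.
#' @examples
#' counts_to_molar(1.45e5, 1e6) # medium CD19 at 1e6 cells/mL
#' @export
counts_to_molar <- function(receptors_per_cell, cell_density_per_ml) {
  if (any(receptors_per_cell < 0) || any(cell_density_per_ml < 0)) {
    stop("counts_to_molar: inputs must be non-negative")
  }
  # molecules/mL -> molecules/L -> mol/L
  receptors_per_cell * cell_density_per_ml * 1000 / AVOGADRO
}

#' Convert a BiTE mass concentration to molar
#'
#' @param ngml concentration in ng/mL (ng/mL == ug/L).
#' @param mw molar mass in g/mol (default 54 kDa, blinatumomab).
#' @return concentration in mol/L.
#' @export
ngml_to_molar <- function(ngml, mw = 54000) {
  if (any(ngml < 0)) stop("ngml_to_molar: concentration must be non-negative")
  ngml * 1e-6 / mw
}

#' @rdname ngml_to_molar
#' @param molar concentration in mol/L.
#' @export
molar_to_ngml <- function(molar, mw = 54000) {
  molar * mw / 1e-6
}
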