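#' Element parameter table
#'
#' Per-element constants used throughout descriptor and field computation:
#' Bondi van der Waals radii (Angstrom), covalent radii (Angstrom), Sanderson
#' electronegativities (dimensionless), valence electron counts, atomic
#' numbers, default Lennard-Jones well depths (kcal/mol) and coarse atomic
#' hydrophobicity increments (dimensionless, carbon-positive convention).
#'
#' The table covers H, C, N, O, S, P and the halogens; requesting an element
#' outside it is an error so that silent zero-parameter atoms cannot occur.
#'
#' @return A data.frame keyed by element symbol.
#' @examples
#' atomParameterTable()["C", "vdw"]
#' @export
atomParameterTable <- function() {
  tab <- data.frame(
    element = c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
    Z       = c(1, 6, 7, 8, 16, 15, 9, 17, 35, 53),
    Zv      = c(1, 4, 5, 6, 6, 5, 7, 7, 7, 7),
    vdw     = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98),
    covalent = c(0.32, 0.76, 0.71, 0.66, 1.05, 1.07, 0.57, 1.02, 1.20, 1.39),
    sanderson = c(2.592, 2.746, 3.194, 3.654, 2.957, 2.515, 4.000, 3.475,
                  3.219, 2.778),
    lj_eps  = c(0.0157, 0.1094, 0.1700, 0.2100, 0.2500, 0.2000, 0.0610,
                0.2650, 0.3200, 0.4000),
    hydrophobicity = c(0.12, 0.36, -0.60, -0.40, 0.26, -0.50, 0.22, 0.49,
                       0.62, 0.80),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$element
  tab
}

# Standard valences used for implicit hydrogen assignment; multiple entries
# for hypervalent elements, smallest valence >= bond-order sum wins.
.standard_valences <- list(
  H = 1, C = 4, N = 3, O = 2, S = c(2, 4, 6), P = c(3, 5),
  F = 1, Cl = 1, Br = 1, I = 1
)

# Gasteiger-Marsili electronegativity polynomial chi(q) = a + b q + c q^2,
# keyed by element and hybridisation (sp3/sp2/sp; halogens and H single-row).
.gasteiger_params <- list(
  H  = list(sp3 = c(7.17, 6.24, -0.56)),
  C  = list(sp3 = c(7.98, 9.18, 1.88),
            sp2 = c(8.79, 9.32, 1.51),
            sp  = c(10.39, 9.45, 0.73)),
  N  = list(sp3 = c(11.54, 10.82, 1.36),
            sp2 = c(12.87, 11.15, 0.85),
            sp  = c(15.68, 11.70, -0.27)),
  O  = list(sp3 = c(14.18, 12.92, 1.39),
            sp2 = c(17.07, 13.79, 0.47)),
  S  = list(sp3 = c(10.14, 9.13, 1.38)),
  P  = list(sp3 = c(8.90, 8.24, 0.96)),
  F  = list(sp3 = c(14.66, 13.85, 2.31)),
  Cl = list(sp3 = c(11.00, 9.69, 1.35)),
  Br = list(sp3 = c(10.08, 8.47, 1.16)),
  I  = list(sp3 = c(9.90, 7.96, 0.96))
)

.elementParam <- function(elements, column, context = "parameter lookup") {
  tab <- atomParameterTable()
  missing <- setdiff(unique(elements), rownames(tab))
  if (length(missing) > 0L) {
    stop(sprintf("no %s parameters for element(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab[elements, column]
}
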