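#' Physical constants and unit conversions
#'
#' All internal energies are kcal/mol, lengths nm, times ps.  Harmonic umbrella
#' force constants follow GROMACS convention (kJ/mol/nm^2) at the user surface
#' and are converted once, via [kJToKcal()], on entry.
#'
#' @format `kBoltzmannKcal` is the Boltzmann constant in kcal/(mol K).
#' @export
kBoltzmannKcal <- 0.0019872041

# kcal <-> kJ conversion; 4.184 exactly (thermochemical calorie)
.kJPerKcal <- 4.184

#' Convert kJ/mol quantities to kcal/mol
#'
#' @param x numeric, energy (kJ/mol) or force constant (kJ/mol/nm^2).
#' @return numeric in kcal units.
#' @examples
#' kJToKcal(4.184) # 1
#' @export
kJToKcal <- function(x) x / .kJPerKcal

#' @rdname kJToKcal
#' @export
kcalToKJ <- function(x) x * .kJPerKcal

#' Thermal energy kT in kcal/mol
#'
#' @param temperature kelvin.
#' @return kT in kcal/mol.
#' @examples
#' kT(323)
#' @export
kT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  kBoltzmannKcal * temperature
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
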