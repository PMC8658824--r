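#' Physical constants used in Arrhenius and Eyring calculations
#'
#' Returns the fixed physical constants the package uses throughout:
#' the gas constant in kcal units (so all activation parameters come out in
#' kcal/mol), the Boltzmann constant and the Planck constant (SI, 2019
#' redefinition values).
#'
#' @return A named list with elements `R_kcal` (kcal mol^-1 K^-1), `kB` (J/K)
#'   and `h` (J s).
#' @examples
#' thermo_constants()$R_kcal
#' @export
thermo_constants <- function() {
  list(
    R_kcal = 1.9872e-3,    # kcal mol^-1 K^-1
    kB     = 1.380649e-23, # J K^-1
    h      = 6.62607015e-34 # J s
  )
}

# internal shorthand; immutable by convention
.const <- list(
  R_kcal = 1.9872e-3,
  kB     = 1.380649e-23,
  h      = 6.62607015e-34
)
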