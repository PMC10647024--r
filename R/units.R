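#' Unit conversion constants
#'
#' The package works in Angstrom and kcal/mol throughout; atomic units
#' (Hartree, Bohr) appear only at the convergence test of the geometry
#' optimizer, which mirrors the Gaussian convergence quartet. These are the
#' two conversion constants used at that boundary.
#'
#' @format Named numeric constants:
#' \describe{
#'   \item{HARTREE_KCAL}{kcal/mol per Hartree, 627.509474.}
#'   \item{BOHR_ANGSTROM}{Angstrom per Bohr, 0.529177210903 (CODATA 2018).}
#' }
#' @name units
#' @keywords internal
NULL

HARTREE_KCAL  <- 627.509474
BOHR_ANGSTROM <- 0.529177210903

# kcal/mol/Angstrom -> Hartree/Bohr
force_kcal_to_au <- function(f) f * BOHR_ANGSTROM / HARTREE_KCAL

# Angstrom -> Bohr
length_ang_to_au <- function(x) x / BOHR_ANGSTROM
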