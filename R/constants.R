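#' Physical constants and scoring-function defaults
#'
#' Default parameter set used throughout the scoring function. All defaults
#' are overridable in the individual functions; this object centralises them
#' so a whole run can be reconfigured at once.
#'
#' @details
#' \describe{
#'   \item{\code{gas_constant}}{1.986 cal/(mol K). This value, rather than the
#'     CODATA 1.9872, reproduces the reference IC50-to-free-energy conversions
#'     to better than 0.001 kcal/mol.}
#'   \item{\code{temperature}}{310 K (physiological), the temperature at which
#'     IC50 values are converted to free energies.}
#'   \item{\code{gamma}}{5.0 cal/(mol A^2), the surface-tension coefficient of
#'     the nonpolar solvation term.}
#'   \item{\code{b}}{0.86 kcal/mol, the intercept of the nonpolar solvation
#'     term.}
#'   \item{\code{probe_radius}}{1.4 A, the water-probe radius used for solvent
#'     accessible surface area.}
#'   \item{\code{rot_bond_penalty}}{1 kcal/mol per rotatable bond, the
#'     conformational entropy penalty.}
#'   \item{\code{hartree_to_kcal}}{627.5095 kcal/mol per Hartree.}
#' }
#'
#' @return \code{scoringConstants()} returns a named list of the defaults,
#'   with any supplied overrides applied.
#' @param ... named overrides, e.g. \code{temperature = 298}.
#' @examples
#' scoringConstants()$gamma
#' scoringConstants(temperature = 298)$temperature
#' @export
scoringConstants <- function(...) {
  defaults <- list(
    gas_constant     = 1.986e-3,   # kcal/(mol K)
    temperature      = 310,        # K
    gamma            = 5.0,        # cal/(mol A^2)
    b                = 0.86,       # kcal/mol
    probe_radius     = 1.4,        # A
    rot_bond_penalty = 1.0,        # kcal/mol per bond
    hartree_to_kcal  = 627.5095
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0L)
    stop("unknown constant(s): ", paste(bad, collapse = ", "))
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("constant '", nm, "' must be a single positive number")
    defaults[[nm]] <- v
  }
  defaults
}

.HARTREE_KCAL <- 627.5095
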