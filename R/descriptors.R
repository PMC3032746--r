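#' Convert an IC50 to a binding free energy
#'
#' Maps a half-maximal inhibitory concentration to an apparent binding free
#' energy via \eqn{\Delta G = RT \ln(\mathrm{IC50})} with the IC50 expressed
#' in mol/L, at physiological temperature by default. Sub-molar potencies
#' give negative free energies; 1 M maps to exactly zero. The gas constant
#' default (1.986 cal/(mol K)) matches the convention of the bundled CDK2
#' reference values.
#'
#' @param ic50 IC50 in micromolar (vectorised, > 0).
#' @param temperature K.
#' @param gasConstant kcal/(mol K).
#' @return free energy, kcal/mol.
#' @examples
#' dgFromIc50(185)    # approx -5.29
#' dgFromIc50(1e6)    # 1 M -> 0
#' @export
dgFromIc50 <- function(ic50, temperature = 310,
                       gasConstant = 1.986e-3) {
  if (any(!is.finite(ic50) | ic50 <= 0))
    stop("IC50 must be positive and finite", call. = FALSE)
  gasConstant * temperature * log(ic50 * 1e-6)
}

#' Invert the free-energy / IC50 relation
#'
#' Exact inverse of [dgFromIc50()].
#'
#' @param dg free energy, kcal/mol.
#' @inheritParams dgFromIc50
#' @return IC50 in micromolar.
#' @examples
#' ic50FromDg(dgFromIc50(185))  # 185
#' @export
ic50FromDg <- function(dg, temperature = 310, gasConstant = 1.986e-3) {
  stopifnot(all(is.finite(dg)))
  exp(dg / (gasConstant * temperature)) * 1e6
}

#' Count rotatable bonds
#'
#' A bond is rotatable when it is a single bond, not in a ring, not
#' terminal (both end atoms are bonded to at least two heavy atoms), and —
#' unless \code{includeAmides} — not an amide C-N bond (a C-N single bond
#' whose carbon bears a double-bonded oxygen). Hydrogens are ignored
#' throughout; this is the standard medicinal-chemistry convention used to
#' assess the conformational entropy a ligand loses on binding.
#'
#' @param mol a \linkS4class{Molecule}.
#' @param includeAmides count amide C-N bonds as rotatable?
#' @return integer count.
#' @examples
#' rotatableBondCount(makeSyntheticMolecule("linear_alkane", n = 4))  # 1
#' rotatableBondCount(makeSyntheticMolecule("ring", n = 6))           # 0
#' @export
rotatableBondCount <- function(mol, includeAmides = FALSE) {
  at <- atoms(mol)
  bd <- bonds(mol)
  if (nrow(bd) == 0L) return(0L)
  heavy <- at$element != "H"
  # heavy-atom degree, counting only bonds between two heavy atoms
  hb <- bd[heavy[bd$a] & heavy[bd$b], , drop = FALSE]
  deg <- tabulate(c(hb$a, hb$b), nbins = nrow(at))
  is_amide <- function(a, b) {
    ends <- c(a, b)
    cidx <- ends[at$element[ends] == "C"]
    nidx <- ends[at$element[ends] == "N"]
    if (length(cidx) != 1L || length(nidx) != 1L) return(FALSE)
    # carbonyl: the carbon double-bonded to an oxygen
    co <- bd$order == 2L &
      ((bd$a == cidx & at$element[bd$b] == "O") |
       (bd$b == cidx & at$element[bd$a] == "O"))
    any(co)
  }
  rot <- vapply(seq_len(nrow(bd)), function(k) {
    a <- bd$a[k]; b <- bd$b[k]
    if (bd$order[k] != 1L || bd$in_ring[k]) return(FALSE)
    if (!heavy[a] || !heavy[b]) return(FALSE)
    if (deg[a] < 2L || deg[b] < 2L) return(FALSE)
    if (!includeAmides && is_amide(a, b)) return(FALSE)
    TRUE
  }, logical(1))
  sum(rot)
}

#' Rotatable-bond conformational entropy penalty
#'
#' The entropy term of the scoring function: a fixed penalty per rotatable
#' bond (default 1 kcal/mol), charging the ligand for the torsional freedom
#' it loses when bound.
#'
#' @param nRot rotatable-bond count (>= 0).
#' @param penalty kcal/mol per bond.
#' @return entropy term \eqn{T\Delta S}, kcal/mol.
#' @examples
#' entropyTerm(6)
#' @export
entropyTerm <- function(nRot, penalty = 1.0) {
  if (any(nRot < 0)) stop("rotatable-bond count must be >= 0", call. = FALSE)
  nRot * penalty
}

#' Nonpolar solvation free energy from SASA
#'
#' The linear surface-area model \eqn{\Delta G_{np} = \gamma\,SASA + b}
#' with the surface-tension coefficient in cal/(mol A^2) (converted to kcal
#' internally) and the intercept in kcal/mol.
#'
#' @param sasa solvent accessible surface area, A^2 (>= 0).
#' @param gamma cal/(mol A^2).
#' @param b kcal/mol.
#' @return kcal/mol.
#' @examples
#' nonpolarSolvation(100)  # 0.5 + 0.86
#' @export
nonpolarSolvation <- function(sasa, gamma = 5.0, b = 0.86) {
  if (any(!is.finite(sasa) | sasa < 0))
    stop("SASA must be non-negative", call. = FALSE)
  gamma * 1e-3 * sasa + b
}

#' Total solvation free energy
#'
#' \eqn{\Delta G_{solv} = \Delta G_{psolv} + \Delta G_{npsolv}}: the polar
#' (Poisson-Boltzmann, supplied externally) and nonpolar (surface-area)
#' contributions.
#'
#' @param polar,nonpolar kcal/mol.
#' @return kcal/mol.
#' @export
solvationTerm <- function(polar, nonpolar) {
  stopifnot(all(is.finite(polar)), all(is.finite(nonpolar)))
  polar + nonpolar
}

#' Net solvation change on binding
#'
#' The thermodynamic-cycle combination
#' \eqn{\Delta G_{solv}^{complex} - \Delta G_{solv}^{receptor} -
#' \Delta G_{solv}^{ligand}}: the solvation the complex gains minus what
#' the separated species give up.
#'
#' @param complexSolv,receptorSolv,ligandSolv kcal/mol.
#' @return kcal/mol.
#' @export
bindingSolvation <- function(complexSolv, receptorSolv, ligandSolv) {
  stopifnot(is.finite(complexSolv), is.finite(receptorSolv),
            is.finite(ligandSolv))
  complexSolv - receptorSolv - ligandSolv
}

#' Assemble the four scoring-function descriptors
#'
#' Packs the gas-phase FMO enthalpy, the polar solvation input, the
#' nonpolar solvation term and the entropy penalty (computed from the
#' rotatable-bond count) into the named descriptor vector the PLS model
#' consumes.
#'
#' @param dHgas sum of ligand-residue pair interaction energies, kcal/mol.
#' @param dGpsolv polar (Poisson-Boltzmann) solvation, kcal/mol.
#' @param dGnpsolv nonpolar (surface-area) solvation, kcal/mol.
#' @param nRot rotatable-bond count (>= 0).
#' @param penalty entropy penalty per bond, kcal/mol.
#' @return named numeric of length 4: \code{dH_gas}, \code{dG_psolv},
#'   \code{dG_npsolv}, \code{TdS}.
#' @examples
#' assembleDescriptors(-41.712, -8.756, -2.296, 0)
#' @export
assembleDescriptors <- function(dHgas, dGpsolv, dGnpsolv, nRot,
                                penalty = 1.0) {
  stopifnot(is.finite(dHgas), is.finite(dGpsolv), is.finite(dGnpsolv))
  c(dH_gas = dHgas, dG_psolv = dGpsolv, dG_npsolv = dGnpsolv,
    TdS = entropyTerm(nRot, penalty))
}

#' Unscaled thermodynamic-cycle binding free energy
#'
#' The naive physical sum
#' \eqn{\Delta G = \Delta H_{gas} - T\Delta S + \Delta G_{psolv} +
#' \Delta G_{npsolv}}, taking the two solvation descriptors as net
#' binding-state changes. With quantum-chemical enthalpies this absolute
#' estimate is far too favourable (tens of kcal/mol) — the observation that
#' motivates rescaling the four terms through a PLS model instead of using
#' the raw cycle.
#'
#' @param v named descriptor vector from [assembleDescriptors()] (or any
#'   numeric with those four names).
#' @return kcal/mol.
#' @examples
#' physicalBindingEstimate(assembleDescriptors(-41.712, -8.756, -2.296, 0))
#' @export
physicalBindingEstimate <- function(v) {
  need <- c("dH_gas", "dG_psolv", "dG_npsolv", "TdS")
  if (!all(need %in% names(v)))
    stop("descriptor vector must have names ",
         paste(need, collapse = ", "), call. = FALSE)
  stopifnot(all(is.finite(v[need])))
  unname(v["dH_gas"] - v["TdS"] + v["dG_psolv"] + v["dG_npsolv"])
}
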