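## Accessors and show methods. Slot access from user code should go through
## these.

#' @describeIn PDBStructure-class Atom table accessor.
#' @param x,object An object.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @export
setMethod("atoms", "PDBStructure", function(x) x@atoms)
#' @export
setMethod("atoms", "QMCluster", function(x) x@atoms)
#' @export
setMethod("atoms", "HisConfiguration", function(x) x@atoms)

#' Number of atoms
#' @param x A structure-like object.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @export
setMethod("nAtoms", "PDBStructure", function(x) nrow(x@atoms))
#' @export
setMethod("nAtoms", "QMCluster", function(x) nrow(x@atoms))
#' @export
setMethod("nAtoms", "HisConfiguration", function(x) nrow(x@atoms))

#' Unit-cell record of a structure (empty list when absent)
#' @param x A [PDBStructure-class].
#' @export
crystal <- function(x) x@crystal

#' Per-atom freeze flags
#' @param x A [QMCluster-class] or [HisConfiguration-class].
#' @export
setGeneric("isFrozen", function(x) standardGeneric("isFrozen"))
#' @export
setMethod("isFrozen", "QMCluster", function(x) x@frozen)
#' @export
setMethod("isFrozen", "HisConfiguration", function(x) x@frozen)

#' Net formal charge of a cluster
#' @param x A [QMCluster-class].
#' @export
netCharge <- function(x) x@netCharge

#' Cap-atom bookkeeping of a cluster
#' @param x A [QMCluster-class].
#' @export
capAtoms <- function(x) x@caps

#' Selection mask (TRUE on target-histidine atoms)
#' @param x A [QMCluster-class].
#' @export
selectionMask <- function(x) x@selection

#' Calibration fit coefficients, RMS error and record count
#' @param x A [CalibrationFit-class].
#' @export
pkaIntercept <- function(x) x@a
#' @rdname pkaIntercept
#' @export
pkaSlope <- function(x) x@b
#' @rdname pkaIntercept
#' @export
rmsError <- function(x) x@rmsPka

#' Proton reference free energy (kcal/mol)
#' @param x A [ProtonReference-class].
#' @export
gProton <- function(x) x@gProton

#' Final protonation call of a report
#' @param x A [DecisionReport-class].
#' @export
decisionCall <- function(x) x@call

#' Per-configuration rows of a report
#' @param x A [DecisionReport-class].
#' @export
reportRows <- function(x) x@rows

#' Labels within the significance threshold of the winning configuration
#' @param x A [DecisionReport-class].
#' @export
ambiguousWith <- function(x) x@ambiguousWith

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  cat("PDBStructure with", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resseq, a$icode))), "residues",
      if (length(object@crystal)) "(CRYST1 present)" else "", "\n")
})

setMethod("show", "QMCluster", function(object) {
  cat("QMCluster:", nrow(object@atoms), "atoms (",
      sum(object@selection), "selection,", nrow(object@caps), "caps,",
      sum(object@frozen), "frozen ), net charge",
      object@netCharge, "\n")
})

setMethod("show", "HisConfiguration", function(object) {
  cat("HisConfiguration:", object@label, "-", nrow(object@atoms), "atoms,",
      object@nRingProtons, "ring proton(s)\n")
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf("CalibrationFit (%s, n=%d): pKa = %.4f + %.5f * dG, rms %.4f\n",
              object@siteFilter, object@n, object@a, object@b,
              object@rmsPka))
})

setMethod("show", "ProtonReference", function(object) {
  cat(sprintf("ProtonReference: G(H+) = %.4f kcal/mol at pH %.2f\n",
              object@gProton, object@pH))
})

setMethod("show", "QMResult", function(object) {
  cat(sprintf("QMResult: E = %.4f kcal/mol, %s after %d cycle(s)\n",
              object@finalEnergy,
              if (object@converged) "converged" else "NOT converged",
              object@nCycles))
})

setMethod("show", "DecisionReport", function(object) {
  cat(formatReport(object), sep = "\n")
})
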