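## Central S4 classes. Atom tables are plain data.frames with a fixed column
## set; the classes wrap them with validity checks and provenance.

.ATOM_COLS <- c("serial", "name", "altloc", "resname", "chain", "resseq",
                "icode", "x", "y", "z", "occupancy", "bfactor", "element",
                "segid")

.emptyAtoms <- function() {
  data.frame(serial = integer(), name = character(), altloc = character(),
             resname = character(), chain = character(), resseq = integer(),
             icode = character(), x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), bfactor = numeric(),
             element = character(), segid = character(),
             stringsAsFactors = FALSE)
}

.checkAtoms <- function(atoms) {
  miss <- setdiff(.ATOM_COLS, names(atoms))
  if (length(miss))
    return(paste("atoms table missing columns:", paste(miss, collapse = ", ")))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(xyz)))
    return("non-finite atomic coordinates")
  TRUE
}

#' PDBStructure: a parsed atomic model
#'
#' Holds every ATOM/HETATM record of a PDB file in file order, plus the
#' CRYST1 unit-cell record when present (pass-through only; no crystal
#' arithmetic is done in the core).
#'
#' @slot atoms data.frame of atom records (serial, name, altloc, resname,
#'   chain, resseq, icode, x, y, z, occupancy, bfactor, element, segid).
#' @slot crystal list with elements `a`, `b`, `c`, `alpha`, `beta`, `gamma`,
#'   `sgroup`, or empty when the file has no CRYST1 record.
#' @seealso [readPDB()], [findHistidines()]
#' @export
setClass("PDBStructure",
         representation(atoms = "data.frame", crystal = "list"),
         prototype(atoms = .emptyAtoms(), crystal = list()),
         validity = function(object) .checkAtoms(object@atoms))

#' HisSite: one histidine residue eligible for protonation assignment
#'
#' A site is accepted only when all six side-chain heavy atoms
#' (CB, CG, ND1, CD2, CE1, NE2) are present.
#'
#' @slot chain,resseq,icode Residue identity (1-based PDB numbering).
#' @slot atomIndices Named integer vector mapping canonical histidine atom
#'   names to row indices of the parent structure's atom table.
#' @export
setClass("HisSite",
         representation(chain = "character", resseq = "integer",
                        icode = "character", atomIndices = "integer"),
         validity = function(object) {
           need <- c("CB", "CG", "ND1", "CD2", "CE1", "NE2")
           miss <- setdiff(need, names(object@atomIndices))
           if (length(miss))
             return(paste("histidine site missing heavy atoms:",
                          paste(miss, collapse = ", ")))
           TRUE
         })

#' QMCluster: the excised quantum-chemistry micro-model
#'
#' All entities with at least one atom within the buffer distance of the
#' target histidine, copied out of the parent structure, with per-atom freeze
#' flags, capping hydrogens on severed peptide bonds, and a provenance map
#' back to the parent.
#'
#' @slot atoms Atom table (parent copies first, then added hydrogens).
#' @slot frozen Logical per atom; frozen atoms never move during minimization.
#' @slot selection Logical per atom; TRUE exactly on target-histidine atoms.
#' @slot caps data.frame describing added hydrogens: `index` (row in atoms),
#'   `bondedTo` (row in atoms), `severedParent` (row in the parent structure
#'   for peptide caps, NA for built water hydrogens), `kind`
#'   ("peptide" or "water").
#' @slot netCharge Integer sum of formal charges of the included entities,
#'   with the target histidine counted doubly protonated (+1).
#' @slot parentIndex Integer per atom: row in the parent structure
#'   (NA for added hydrogens).
#' @export
setClass("QMCluster",
         representation(atoms = "data.frame", frozen = "logical",
                        selection = "logical", caps = "data.frame",
                        netCharge = "integer", parentIndex = "integer"),
         validity = function(object) {
           ok <- .checkAtoms(object@atoms)
           if (!isTRUE(ok)) return(ok)
           n <- nrow(object@atoms)
           if (length(object@frozen) != n || length(object@selection) != n ||
               length(object@parentIndex) != n)
             return("frozen/selection/parentIndex length must match atoms")
           pi <- object@parentIndex[!is.na(object@parentIndex)]
           if (anyDuplicated(pi))
             return("parentIndex must be injective over non-cap atoms")
           TRUE
         })

#' TorsionRestraint: harmonic planar restraint on the ring torsion
#'
#' Anchors the imidazole ring plane to the main chain during minimization via
#' the CA-CB-CG-ND1 torsion; the target is always the value measured on the
#' starting geometry of the configuration being minimized.
#'
#' @slot atomNames Four atom names defining the torsion.
#' @slot target Target angle, degrees.
#' @slot weight Harmonic weight, kcal mol^-1 deg^-2.
#' @slot enabled Logical.
#' @export
setClass("TorsionRestraint",
         representation(atomNames = "character", target = "numeric",
                        weight = "numeric", enabled = "logical"),
         prototype(atomNames = c("CA", "CB", "CG", "ND1"), target = 0,
                   weight = 50 * (pi / 180)^2, enabled = TRUE),
         validity = function(object) {
           if (length(object@atomNames) != 4L)
             return("a torsion restraint needs exactly 4 atom names")
           if (object@weight < 0) return("restraint weight must be >= 0")
           TRUE
         })

#' HisConfiguration: one of the six protonation/flip states
#'
#' @slot state One of "HD1^HE2", "HD1", "HE2".
#' @slot flipped Logical; TRUE for the three ring-flipped states.
#' @slot nRingProtons 2 for "HD1^HE2", else 1.
#' @slot atoms Cluster atom table for this configuration (ring nitrogen
#'   protons built, ring flipped when requested).
#' @slot frozen Logical per atom (inherited from the cluster; built protons
#'   are free).
#' @slot selection Logical per atom; TRUE on target-histidine atoms.
#' @slot restraint A [TorsionRestraint-class].
#' @slot label Display string, e.g. "HD1 only flipped".
#' @export
setClass("HisConfiguration",
         representation(state = "character", flipped = "logical",
                        nRingProtons = "integer", atoms = "data.frame",
                        frozen = "logical", selection = "logical",
                        restraint = "TorsionRestraint",
                        label = "character"),
         validity = function(object) {
           if (!object@state %in% c("HD1^HE2", "HD1", "HE2"))
             return("state must be HD1^HE2, HD1 or HE2")
           want <- if (object@state == "HD1^HE2") 2L else 1L
           if (object@nRingProtons != want)
             return("nRingProtons inconsistent with protonation state")
           TRUE
         })

#' CalibrationFit: the fitted linear pKa model
#'
#' pKa = a + b * (G(A-) - G(HA)), fitted by ordinary least squares (which
#' minimizes the RMS error in pKa). The RMS error uses the residual
#' degrees-of-freedom denominator (n - 2).
#'
#' @slot a Intercept (dimensionless).
#' @slot b Slope (mol kcal^-1), always positive for the bundled data.
#' @slot rmsPka RMS error of the fit in pKa units.
#' @slot n Number of records fitted.
#' @slot siteFilter "all", "N" or "O".
#' @seealso [fitPkaModel()], [printedPrecision()], [protonFreeEnergy()]
#' @export
setClass("CalibrationFit",
         representation(a = "numeric", b = "numeric", rmsPka = "numeric",
                        n = "integer", siteFilter = "character"),
         validity = function(object) {
           if (object@b <= 0) return("slope b must be positive")
           TRUE
         })

#' ProtonReference: effective free energy of a solvated proton
#'
#' g_proton = (pH - a) / b from a calibration fit; used to compare
#' configurations differing in proton count.
#'
#' @slot gProton kcal mol^-1.
#' @slot pH Dimensionless (default 7.4).
#' @slot fit The source [CalibrationFit-class].
#' @export
setClass("ProtonReference",
         representation(gProton = "numeric", pH = "numeric",
                        fit = "CalibrationFit"),
         validity = function(object) {
           g <- (object@pH - object@fit@a) / object@fit@b
           if (abs(g - object@gProton) > 1e-9)
             return("gProton inconsistent with source fit")
           TRUE
         })

#' QMJob: a single minimization request
#'
#' @slot configuration The [HisConfiguration-class] to minimize.
#' @slot cluster The parent [QMCluster-class].
#' @slot method QM method tag (default "PM6-D3H4").
#' @slot solventEps Relative static permittivity of the implicit solvent
#'   (default 78.4, approximating water).
#' @slot charge Total cluster charge for this configuration.
#' @slot maxCycles Maximum minimization cycles.
#' @slot backend "surrogate" or "mopac".
#' @export
setClass("QMJob",
         representation(configuration = "HisConfiguration",
                        cluster = "QMCluster", method = "character",
                        solventEps = "numeric", charge = "integer",
                        maxCycles = "integer", backend = "character"),
         prototype(method = "PM6-D3H4", solventEps = 78.4,
                   maxCycles = 200L, backend = "surrogate"),
         validity = function(object) {
           if (!object@backend %in% c("surrogate", "mopac"))
             return("backend must be 'surrogate' or 'mopac'")
           TRUE
         })

#' QMResult: outcome of a minimization
#'
#' @slot finalEnergy Heat of formation, kcal mol^-1.
#' @slot finalCoords n x 3 matrix of final coordinates; frozen atoms are
#'   bit-identical to their input coordinates.
#' @slot converged Logical.
#' @slot nCycles Cycles used.
#' @slot trace Energy after each accepted cycle (non-increasing for the
#'   surrogate backend).
#' @slot log Backend log text.
#' @export
setClass("QMResult",
         representation(finalEnergy = "numeric", finalCoords = "matrix",
                        converged = "logical", nCycles = "integer",
                        trace = "numeric", log = "character"))

#' DecisionReport: the six-configuration comparison and final call
#'
#' @slot site list(chain, resseq, icode).
#' @slot rows data.frame with one row per configuration: label, state,
#'   flipped, energy (proton-corrected, kcal mol^-1), deltaE, nHBonds, rmsd,
#'   rotamer, converged.
#' @slot call Protonation state of the winning row.
#' @slot flipped Whether the winning row is ring-flipped.
#' @slot ambiguousWith Labels of non-winning rows within the significance
#'   threshold of the minimum.
#' @slot threshold Significance threshold, kcal mol^-1.
#' @slot pH pH used for the proton reference.
#' @slot original list(label, rotamer) describing the input model.
#' @export
setClass("DecisionReport",
         representation(site = "list", rows = "data.frame", call = "character",
                        flipped = "logical", ambiguousWith = "character",
                        threshold = "numeric", pH = "numeric",
                        original = "list"),
         validity = function(object) {
           r <- object@rows
           conv <- r[r$converged, , drop = FALSE]
           if (nrow(conv)) {
             if (min(conv$deltaE) < 0) return("deltaE must be >= 0")
             if (sum(conv$deltaE == 0) < 1L)
               return("one converged row must sit at deltaE = 0")
           }
           TRUE
         })
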