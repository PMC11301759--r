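## The six protonation/flip configurations of the imidazole ring: proton
## construction, the 180-degree coordinate-swap flip, and the planar torsion
## restraint attached to each configuration.

.N_H <- 1.01   # ring N-H bond length, Angstrom
.C_H <- 1.08   # ring C-H bond length, Angstrom

#' Place a ring proton on a trigonal nitrogen (or carbon)
#'
#' The hydrogen is placed at `length` from the central atom, in the plane of
#' the two ring neighbors, along the external bisector of the
#' neighbor1-N-neighbor2 angle.
#'
#' @param n 3-vector: the protonated atom.
#' @param nb1,nb2 3-vectors: its two ring neighbors.
#' @param length Bond length in Angstrom (default 1.01 for N-H).
#' @return 3-vector hydrogen position.
#' @export
placeRingProton <- function(n, nb1, nb2, length = .N_H) {
  u <- .vunit(nb1 - n)
  v <- .vunit(nb2 - n)
  bis <- u + v
  if (.vnorm(bis) < 1e-9 || .vnorm(.vcross(u, v)) < 1e-9)
    stop("degenerate geometry: collinear neighbors for proton placement")
  n - length * .vunit(bis)
}

#' Flip an imidazole ring by 180 degrees
#'
#' Implemented as the coordinate swap ND1<->CD2 and CE1<->NE2; CB and CG are
#' untouched. This preserves the experimentally observed ring-atom positions
#' exactly (for ideal rings it coincides with a chi2 rotation by 180
#' degrees). Ring protons must be rebuilt afterwards on the new nitrogen
#' positions.
#'
#' @param atoms Atom table containing the histidine.
#' @param hisRows Integer rows of the histidine residue within `atoms`.
#' @return The atom table with swapped ring coordinates.
#' @export
flipRing <- function(atoms, hisRows) {
  nm <- atoms$name[hisRows]
  swap <- function(a, b) {
    i <- hisRows[match(a, nm)]
    j <- hisRows[match(b, nm)]
    if (is.na(i) || is.na(j)) stop("ring atom missing for flip: ", a, "/", b)
    tmp <- atoms[i, c("x", "y", "z")]
    atoms[i, c("x", "y", "z")] <<- atoms[j, c("x", "y", "z")]
    atoms[j, c("x", "y", "z")] <<- tmp
    invisible(NULL)
  }
  swap("ND1", "CD2")
  swap("CE1", "NE2")
  atoms
}

.hisXYZ <- function(atoms, hisRows, name) {
  i <- hisRows[match(name, atoms$name[hisRows])]
  if (is.na(i)) stop("histidine atom not found: ", name)
  as.numeric(atoms[i, c("x", "y", "z")])
}

## ring neighbor map for proton construction
.RING_NB <- list(ND1 = c("CG", "CE1"), NE2 = c("CD2", "CE1"),
                 CE1 = c("ND1", "NE2"), CD2 = c("CG", "NE2"))

.buildRingH <- function(atoms, hisRows, center, hname, len) {
  nb <- .RING_NB[[center]]
  h <- placeRingProton(.hisXYZ(atoms, hisRows, center),
                       .hisXYZ(atoms, hisRows, nb[1]),
                       .hisXYZ(atoms, hisRows, nb[2]), len)
  i <- hisRows[match(center, atoms$name[hisRows])]
  .appendAtom(atoms, i, hname, "H", h, segid = "")
}

.STATE_TABLE <- data.frame(
  state = rep(c("HD1^HE2", "HD1", "HE2"), 2),
  flipped = rep(c(FALSE, TRUE), each = 3),
  stringsAsFactors = FALSE)
.STATE_TABLE$label <- paste0(
  sub("\\^", ", ", .STATE_TABLE$state),
  ifelse(.STATE_TABLE$state == "HD1^HE2", "", " only"),
  ifelse(.STATE_TABLE$flipped, " flipped", ""))

#' Enumerate the six protonation/flip configurations
#'
#' Produces, in canonical order, HD1^HE2, HD1, HE2, then the same three
#' states with the ring flipped. Any ring nitrogen protons present on input
#' are discarded and rebuilt so that all six configurations start from
#' identical heavy-atom geometry; the ring carbon hydrogens HE1 and HD2 are
#' always present. Each configuration carries a [TorsionRestraint-class] on
#' CA-CB-CG-ND1 whose target is the torsion measured on that configuration's
#' starting geometry.
#'
#' @param cluster A capped, freeze-flagged [QMCluster-class].
#' @param restraintWeight Harmonic weight in kcal mol^-1 rad^-2 (default 50;
#'   stored per-degree internally).
#' @param restrain Logical; set FALSE to disable the planar restraint.
#' @return List of six [HisConfiguration-class] objects.
#' @export
enumerateConfigurations <- function(cluster, restraintWeight = 50,
                                    restrain = TRUE) {
  base <- cluster@atoms
  hisRows0 <- which(cluster@selection)
  ## discard existing ring N protons of the target histidine
  drop <- hisRows0[base$name[hisRows0] %in% c("HD1", "HE2")]
  if (length(drop)) {
    keep <- setdiff(seq_len(nrow(base)), drop)
    base <- base[keep, , drop = FALSE]
    rownames(base) <- NULL
    frozen0 <- cluster@frozen[keep]
    sel0 <- cluster@selection[keep]
  } else {
    frozen0 <- cluster@frozen
    sel0 <- cluster@selection
  }
  hisRows <- which(sel0)
  ## ensure ring carbon hydrogens exist
  for (ch in c("CE1", "CD2")) {
    hname <- if (ch == "CE1") "HE1" else "HD2"
    if (!hname %in% base$name[hisRows]) {
      base <- .buildRingH(base, hisRows, ch, hname, .C_H)
      frozen0 <- c(frozen0, FALSE)
      sel0 <- c(sel0, TRUE)
      hisRows <- which(sel0)
    }
  }
  wDeg <- restraintWeight * (pi / 180)^2
  out <- vector("list", 6L)
  for (i in seq_len(6L)) {
    st <- .STATE_TABLE$state[i]
    fl <- .STATE_TABLE$flipped[i]
    a <- base
    if (fl) a <- flipRing(a, hisRows)
    sel <- sel0
    froz <- frozen0
    protons <- c(if (st %in% c("HD1^HE2", "HD1")) "ND1",
                 if (st %in% c("HD1^HE2", "HE2")) "NE2")
    for (p in protons) {
      hname <- if (p == "ND1") "HD1" else "HE2"
      a <- .buildRingH(a, which(sel), p, hname, .N_H)
      froz <- c(froz, FALSE)
      sel <- c(sel, TRUE)
    }
    target <- dihedralAngle(.hisXYZ(a, which(sel), "CA"),
                            .hisXYZ(a, which(sel), "CB"),
                            .hisXYZ(a, which(sel), "CG"),
                            .hisXYZ(a, which(sel), "ND1"))
    restraint <- methods::new("TorsionRestraint",
                              atomNames = c("CA", "CB", "CG", "ND1"),
                              target = target, weight = wDeg,
                              enabled = restrain)
    out[[i]] <- methods::new("HisConfiguration", state = st, flipped = fl,
                             nRingProtons = length(protons),
                             atoms = a, frozen = froz, selection = sel,
                             restraint = restraint,
                             label = .STATE_TABLE$label[i])
  }
  out
}

## chi angles of the target histidine within a configuration/cluster table
.hisChi <- function(atoms, hisRows) {
  c(chi1 = dihedralAngle(.hisXYZ(atoms, hisRows, "N"),
                         .hisXYZ(atoms, hisRows, "CA"),
                         .hisXYZ(atoms, hisRows, "CB"),
                         .hisXYZ(atoms, hisRows, "CG")),
    chi2 = dihedralAngle(.hisXYZ(atoms, hisRows, "CA"),
                         .hisXYZ(atoms, hisRows, "CB"),
                         .hisXYZ(atoms, hisRows, "CG"),
                         .hisXYZ(atoms, hisRows, "ND1")))
}
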