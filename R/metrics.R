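## Per-configuration quality metrics: hydrogen-bond count, RMSD from the
## starting geometry, and rotamer label.

#' Hydrogen-bond geometric criteria
#'
#' Conventional values, configurable so users can match other validation
#' tools: donor-acceptor distance <= 3.5 A, hydrogen-acceptor distance
#' <= 2.5 A, donor-hydrogen-acceptor angle >= 120 degrees.
#'
#' @param maxDA,maxHA Distances in Angstrom.
#' @param minAngle Degrees.
#' @return List of class "HBondCriteria".
#' @export
hbondCriteria <- function(maxDA = 3.5, maxHA = 2.5, minAngle = 120) {
  stopifnot(maxDA > 0, maxHA > 0, minAngle > 0, maxHA < maxDA)
  structure(list(maxDA = maxDA, maxHA = maxHA, minAngle = minAngle),
            class = "HBondCriteria")
}

## donor (D, H) pairs and acceptor indices from element/connectivity:
## N/O/S with a bonded H donate through that H; O and S always accept;
## N accepts only when it carries no hydrogen (a protonated ring nitrogen
## is a donor, an unprotonated one an acceptor).
.donorsAcceptors <- function(atoms) {
  el <- atoms$element
  xyz <- .coordsOf(atoms)
  hIdx <- which(el == "H")
  heavy <- which(el != "H")
  donors <- matrix(integer(), 0, 2)
  hasH <- rep(FALSE, nrow(atoms))
  if (length(hIdx) && length(heavy)) {
    d <- .crossDist(xyz[hIdx, , drop = FALSE], xyz[heavy, , drop = FALSE])
    for (k in seq_along(hIdx)) {
      j <- heavy[which.min(d[k, ])]
      if (min(d[k, ]) < 1.25) {
        hasH[j] <- TRUE
        if (el[j] %in% c("N", "O", "S"))
          donors <- rbind(donors, c(j, hIdx[k]))
      }
    }
  }
  acceptors <- which(el %in% c("O", "S") | (el == "N" & !hasH))
  list(donors = donors, acceptors = acceptors)
}

#' Count hydrogen bonds in an atom set
#'
#' Counts unique (H, acceptor) pairs satisfying all three criteria; each
#' hydrogen counts at most once (its best-angle qualifying acceptor wins).
#' Pairs where the acceptor is the donor itself or covalently bonded to it
#' are excluded.
#'
#' @param atoms Atom table (or [QMCluster-class]/[HisConfiguration-class]).
#' @param criteria From [hbondCriteria()].
#' @param involve Optional logical mask over atoms; when given, only bonds
#'   whose hydrogen or acceptor lies in the mask are counted (used to
#'   restrict the count to atoms free during minimization).
#' @return Integer count with attribute `"pairs"` (data.frame of D, H, A
#'   indices).
#' @export
countHBonds <- function(atoms, criteria = hbondCriteria(), involve = NULL) {
  if (methods::is(atoms, "QMCluster") || methods::is(atoms, "HisConfiguration"))
    atoms <- atoms(atoms)
  da <- .donorsAcceptors(atoms)
  xyz <- .coordsOf(atoms)
  found <- data.frame(D = integer(), H = integer(), A = integer(),
                      angle = numeric())
  for (r in seq_len(nrow(da$donors))) {
    dAtom <- da$donors[r, 1]
    h <- da$donors[r, 2]
    best <- NULL
    for (acc in da$acceptors) {
      if (acc == dAtom) next
      rDA <- .vnorm(xyz[acc, ] - xyz[dAtom, ])
      if (rDA <= 1.8) next          # covalently bonded to the donor
      rHA <- .vnorm(xyz[acc, ] - xyz[h, ])
      if (rDA > criteria$maxDA || rHA > criteria$maxHA) next
      ang <- bondAngle(xyz[dAtom, ], xyz[h, ], xyz[acc, ])
      if (ang < criteria$minAngle) next
      if (!is.null(involve) && !(involve[h] || involve[acc] || involve[dAtom]))
        next
      if (is.null(best) || ang > best$angle)
        best <- data.frame(D = dAtom, H = h, A = acc, angle = ang)
    }
    if (!is.null(best)) found <- rbind(found, best)
  }
  structure(nrow(found), pairs = found)
}

.CHI1_BINS <- c(p = 60, t = 180, m = -60)

#' Classify a side-chain rotamer from chi1/chi2
#'
#' chi1 is binned to p (+60), t (180) or m (-60) by nearest center mod 360;
#' the label is the bin letter followed by chi2 rounded to the nearest 10
#' degrees. When chi1 deviates more than 40 degrees from every bin center
#' the label is "OUTLIER". This nearest-bin scheme is a sanity label, not a
#' full rotamer-library lookup.
#'
#' @param chi1,chi2 Degrees in (-180, 180].
#' @return Label string, e.g. "m90", "m-70", "OUTLIER".
#' @export
classifyRotamer <- function(chi1, chi2) {
  dev <- abs(.wrapAngle(chi1 - .CHI1_BINS))
  if (min(dev) > 40) return("OUTLIER")
  bin <- names(.CHI1_BINS)[which.min(dev)]
  c2 <- .wrapAngle(round(.wrapAngle(chi2) / 10) * 10)
  paste0(bin, c2)
}

#' Score a minimized configuration
#'
#' Assembles the per-configuration metrics: hydrogen-bond count over the
#' final geometry (restricted to bonds involving at least one atom that was
#' free during minimization), RMSD of the target histidine from its starting
#' geometry (name-based pairing over atoms present in both states, so built
#' protons are excluded), and the rotamer label from the final chi1/chi2.
#'
#' @param before Atom table of the input-model histidine (heavy atoms).
#' @param config The minimized [HisConfiguration-class].
#' @param finalCoords n x 3 matrix from the [QMResult-class].
#' @param criteria From [hbondCriteria()].
#' @param converged Logical from the minimization result.
#' @return List: nHBonds, rmsdStart, rotamer, converged.
#' @export
scoreConfiguration <- function(before, config, finalCoords,
                               criteria = hbondCriteria(),
                               converged = TRUE) {
  a <- config@atoms
  a$x <- finalCoords[, 1]; a$y <- finalCoords[, 2]; a$z <- finalCoords[, 3]
  nhb <- countHBonds(a, criteria, involve = !config@frozen | config@selection)
  sel <- which(config@selection)
  common <- intersect(before$name, a$name[sel])
  rmsd <- coordinateRMSD(before[before$name %in% common, , drop = FALSE],
                         a[sel[a$name[sel] %in% common], , drop = FALSE])
  chi <- .hisChi(a, sel)
  list(nHBonds = as.integer(nhb), rmsdStart = rmsd,
       rotamer = classifyRotamer(chi["chi1"], chi["chi2"]),
       converged = converged)
}
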