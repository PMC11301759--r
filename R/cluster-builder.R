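## Cluster extraction: whole-entity selection within a buffer distance,
## hydrogen capping of severed peptide bonds, solvent protonation and freeze
## flags.

.FORMAL_CHARGE <- c(ASP = -1L, GLU = -1L, LYS = 1L, ARG = 1L)
.METAL_CHARGE <- c(ZN = 2L, MG = 2L, CA = 2L, MN = 2L, FE = 2L, CU = 2L,
                   NI = 2L, CO = 2L, "NA" = 1L, K = 1L)
.WATER_NAMES <- c("HOH", "WAT", "H2O")

.residueCharge <- function(resname, isTarget) {
  if (isTarget) return(1L)  # doubly protonated reference state
  if (resname %in% names(.FORMAL_CHARGE)) return(.FORMAL_CHARGE[[resname]])
  if (resname %in% names(.METAL_CHARGE)) return(.METAL_CHARGE[[resname]])
  0L
}

.fracMatrix <- function(cr) {
  al <- .rad(cr$alpha); be <- .rad(cr$beta); ga <- .rad(cr$gamma)
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
            2 * cos(al) * cos(be) * cos(ga))
  ## orthogonalization matrix, then invert
  m <- matrix(c(cr$a, cr$b * cos(ga), cr$c * cos(be),
                0, cr$b * sin(ga),
                cr$c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
                0, 0, cr$c * v / sin(ga)), 3, 3, byrow = TRUE)
  solve(m)
}

#' Select the quantum-chemistry cluster around a histidine
#'
#' Any residue/entity with at least one atom within `buffer` Angstrom of at
#' least one target-histidine atom is included whole; the target histidine is
#' always included. The net formal charge of the included entities is
#' computed with the target histidine in its doubly protonated (+1) reference
#' state. Freeze flags are initialized all-free; see [assignFreezeFlags()].
#'
#' Crystal-symmetry neighbor expansion is not performed; when the structure
#' carries a unit cell and the histidine lies within `buffer + 5` Angstrom of
#' a cell boundary, a warning flags possible missing symmetry contacts.
#'
#' @param s A [PDBStructure-class].
#' @param site A [HisSite-class] belonging to `s`.
#' @param buffer Buffer distance in Angstrom (default 3.5).
#' @return A [QMCluster-class].
#' @seealso [capCluster()], [assignFreezeFlags()]
#' @export
selectCluster <- function(s, site, buffer = 3.5) {
  stopifnot(buffer > 0)
  a <- atoms(s)
  if (any(site@atomIndices > nrow(a)) ||
      !all(a$name[site@atomIndices] == names(site@atomIndices)))
    stop("site does not belong to this structure")
  selIdx <- unname(site@atomIndices)
  key <- .resKey(a)
  selKey <- key[selIdx[1]]
  d <- .crossDist(.coordsOf(a), .coordsOf(a[selIdx, , drop = FALSE]))
  nearAtom <- apply(d <= buffer, 1L, any)
  inclKeys <- unique(c(selKey, key[nearAtom]))
  keep <- which(key %in% inclKeys)
  atoms <- a[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  sel <- key[keep] == selKey
  charge <- 0L
  for (k in unique(key[keep])) {
    rn <- a$resname[key == k][1]
    charge <- charge + .residueCharge(rn, k == selKey)
  }
  if (length(s@crystal)) {
    f <- .fracMatrix(s@crystal)
    fr <- f %*% colMeans(.coordsOf(a[selIdx, , drop = FALSE]))
    lens <- c(s@crystal$a, s@crystal$b, s@crystal$c)
    margin <- pmin(abs(fr %% 1), abs(1 - fr %% 1)) * lens
    if (any(margin < buffer + 5))
      warning("target histidine lies within ", round(buffer + 5, 1),
              " A of a unit-cell boundary; symmetry-mate contacts are NOT ",
              "included in the cluster")
  }
  methods::new("QMCluster", atoms = atoms,
               frozen = rep(FALSE, nrow(atoms)), selection = sel,
               caps = .emptyCaps(), netCharge = as.integer(charge),
               parentIndex = keep)
}

.emptyCaps <- function()
  data.frame(index = integer(), bondedTo = integer(),
             severedParent = integer(), kind = character(),
             stringsAsFactors = FALSE)

.appendAtom <- function(atoms, ref, name, element, xyz, segid = "CAP") {
  row <- atoms[ref, , drop = FALSE]
  row$serial <- max(atoms$serial) + 1L
  row$name <- name
  row$element <- element
  row$altloc <- " "
  row$x <- xyz[1]; row$y <- xyz[2]; row$z <- xyz[3]
  row$occupancy <- 1; row$bfactor <- 0
  row$segid <- segid
  rbind(atoms, row)
}

#' Cap severed bonds and protonate solvent
#'
#' Each severed backbone peptide bond (an N-C bond between an included and an
#' excluded residue) is replaced by a hydrogen on the included atom, placed
#' exactly along the severed bond vector at the standard length (N-H 1.01,
#' C-H 1.09 Angstrom). Waters missing hydrogens receive two hydrogens at
#' 0.96 Angstrom with an H-O-H angle of 104.5 degrees, the first pointing at
#' the nearest acceptor within 3.5 Angstrom when one exists (hydrogens are
#' free during minimization, so the initial orientation only affects
#' convergence).
#'
#' @param cluster A [QMCluster-class] from [selectCluster()].
#' @param s The parent [PDBStructure-class] (needed to locate the excluded
#'   bonding partners of severed bonds).
#' @return The cluster with cap atoms appended and recorded in `capAtoms()`.
#' @export
capCluster <- function(cluster, s) {
  a <- cluster@atoms
  pa <- atoms(s)
  caps <- .emptyCaps()
  inside <- rep(FALSE, nrow(pa))
  inside[cluster@parentIndex[!is.na(cluster@parentIndex)]] <- TRUE

  ## severed peptide bonds: included backbone C or N bonded (< 1.8 A) to an
  ## excluded backbone N or C of a neighboring residue
  bb <- which(a$name %in% c("N", "C") & a$element %in% c("N", "C"))
  for (i in bb) {
    partnerName <- if (a$name[i] == "C") "N" else "C"
    cand <- which(!inside & pa$name == partnerName &
                  pa$chain == a$chain[i] &
                  abs(pa$resseq - a$resseq[i]) == 1L)
    if (!length(cand)) next
    dd <- .crossDist(.coordsOf(pa[cand, , drop = FALSE]),
                     matrix(as.numeric(a[i, c("x", "y", "z")]), 1))[, 1]
    hit <- cand[dd < 1.8]
    for (j in hit) {
      v <- .vunit(as.numeric(pa[j, c("x", "y", "z")]) -
                  as.numeric(a[i, c("x", "y", "z")]))
      len <- if (a$element[i] == "N") 1.01 else 1.09
      h <- as.numeric(a[i, c("x", "y", "z")]) + len * v
      a <- .appendAtom(a, i, "HCP", "H", h)
      caps <- rbind(caps, data.frame(index = nrow(a), bondedTo = i,
                                     severedParent = j, kind = "peptide",
                                     stringsAsFactors = FALSE))
    }
  }

  ## waters missing hydrogens
  key <- .resKey(a)
  for (k in unique(key[a$resname %in% .WATER_NAMES])) {
    rows <- which(key == k)
    o <- rows[a$element[rows] == "O"][1]
    nH <- sum(a$element[rows] == "H")
    if (is.na(o) || nH >= 2L) next
    oxy <- as.numeric(a[o, c("x", "y", "z")])
    heavy <- which(a$element %in% c("N", "O", "S"))
    heavy <- setdiff(heavy, rows)
    dir1 <- c(1, 0, 0)
    if (length(heavy)) {
      dd <- .crossDist(.coordsOf(a[heavy, , drop = FALSE]), matrix(oxy, 1))[, 1]
      if (min(dd) <= 3.5)
        dir1 <- .vunit(as.numeric(a[heavy[which.min(dd)], c("x", "y", "z")]) - oxy)
    }
    ## second H: rotate dir1 by 104.5 deg about an axis perpendicular to it
    perp <- .vcross(dir1, c(0, 0, 1))
    if (.vnorm(perp) < 1e-6) perp <- .vcross(dir1, c(0, 1, 0))
    perp <- .vunit(perp)
    th <- .rad(104.5)
    dir2 <- cos(th) * dir1 + sin(th) * perp
    hNames <- c("H1", "H2")[seq_len(2L - nH)]
    dirs <- list(dir1, dir2)[seq_len(2L - nH)]
    for (m in seq_along(hNames)) {
      a <- .appendAtom(a, o, hNames[m], "H", oxy + 0.96 * dirs[[m]])
      caps <- rbind(caps, data.frame(index = nrow(a), bondedTo = o,
                                     severedParent = NA_integer_,
                                     kind = "water", stringsAsFactors = FALSE))
    }
  }

  extra <- nrow(a) - nrow(cluster@atoms)
  methods::new("QMCluster", atoms = a,
               frozen = c(cluster@frozen, rep(FALSE, extra)),
               selection = c(cluster@selection, rep(FALSE, extra)),
               caps = caps, netCharge = cluster@netCharge,
               parentIndex = c(cluster@parentIndex, rep(NA_integer_, extra)))
}

#' Assign freeze flags to a capped cluster
#'
#' Default policy: environment heavy atoms are frozen; every hydrogen, every
#' cap and the target-histidine atoms are free — except the histidine
#' main-chain-to-CG stem (CA, CB, CG), which stays frozen so that the
#' experimentally determined ring anchor is preserved. With `policy =
#' "all-frozen"` every atom is frozen and minimization degenerates to a
#' single-point energy.
#'
#' @param cluster A capped [QMCluster-class].
#' @param policy "default" or "all-frozen".
#' @return The cluster with `isFrozen()` populated.
#' @export
assignFreezeFlags <- function(cluster, policy = c("default", "all-frozen")) {
  policy <- match.arg(policy)
  a <- cluster@atoms
  if (policy == "all-frozen") {
    cluster@frozen <- rep(TRUE, nrow(a))
    return(cluster)
  }
  frozen <- rep(TRUE, nrow(a))
  frozen[a$element == "H"] <- FALSE
  frozen[cluster@selection] <- FALSE
  if (nrow(cluster@caps)) frozen[cluster@caps$index] <- FALSE
  stem <- cluster@selection & a$name %in% c("CA", "CB", "CG")
  frozen[stem] <- TRUE
  cluster@frozen <- frozen
  cluster
}
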