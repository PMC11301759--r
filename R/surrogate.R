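## Deterministic surrogate energy model and minimizer. Its purpose is the
## mechanics of the pipeline — ordering of configurations, restraint and
## freeze-flag behavior — with fixed shipped constants, not chemical
## accuracy. Energies are reported on a heat-of-formation-like scale: every
## hydrogen carries a constant formation term equal to the general-purpose
## aqueous proton reference, so that the proton-count correction applied
## downstream cancels exactly for a non-interacting proton and energy
## differences between protonation states reflect interactions only.

.COV_RADIUS <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                 Zn = 1.22, Mg = 1.41, Fe = 1.32, Mn = 1.39, Cu = 1.32,
                 Ni = 1.24, Co = 1.26, Na = 1.66, K = 2.03, Cl = 1.02)

## ideal bond lengths by element pair (fallback: sum of covalent radii)
.BOND_R0 <- c("H-N" = 1.01, "H-O" = 0.96, "C-H" = 1.09, "C-C" = 1.52,
              "C-N" = 1.37, "C-O" = 1.30, "C-S" = 1.80, "N-N" = 1.35,
              "O-S" = 1.45)
.KBOND <- 400    # kcal mol^-1 A^-2
.KANGLE <- 80    # kcal mol^-1 rad^-2

## Lennard-Jones Rmin/2 (A) and epsilon (kcal/mol) by element
.LJ_RMIN2 <- c(H = 1.10, C = 1.90, N = 1.80, O = 1.70, S = 2.00,
               Zn = 1.10, Mg = 1.15, Fe = 1.10, Mn = 1.15, Cu = 1.10,
               Ni = 1.10, Co = 1.10, Na = 1.35, K = 1.75, Cl = 2.05)
.LJ_EPS <- c(H = 0.02, C = 0.08, N = 0.17, O = 0.15, S = 0.25,
             Zn = 0.25, Mg = 0.02, Fe = 0.25, Mn = 0.25, Cu = 0.25,
             Ni = 0.25, Co = 0.25, Na = 0.03, K = 0.03, Cl = 0.15)

.COULOMB_K <- 332.0637   # kcal A / e^2
.HB_R0 <- 1.90           # H...A distance of the hydrogen-bond well, A
.HB_EPS <- 3.0           # well depth, kcal/mol
## per-hydrogen formation term: removing a proton lowers the raw heat by
## the aqueous proton reference (-94.51 kcal/mol), as with real heats of
## formation, so the downstream proton-count correction cancels exactly
## for a non-interacting proton
.MU_H <- 94.51

#' Build the surrogate force-field topology of a configuration
#'
#' Bonds are inferred from interatomic distances against covalent radii;
#' angles are every bonded triple. Bond reference lengths come from a small
#' ideal-value table; angle reference values are taken from the starting
#' geometry (the surrogate's job is to hold the input geometry together, not
#' to re-derive it). Partial charges and Lennard-Jones parameters come from
#' fixed per-element tables with context tweaks for hydrogens.
#'
#' @param atoms Atom table of the configuration.
#' @return A list used by [surrogateEnergy()]: bond/angle index matrices and
#'   reference values, nonbonded pair list with charges and LJ parameters,
#'   donor-hydrogen/acceptor indices.
#' @export
buildTopology <- function(atoms) {
  n <- nrow(atoms)
  el <- atoms$element
  xyz <- .coordsOf(atoms)
  rc <- .COV_RADIUS[el]
  rc[is.na(rc)] <- 1.3
  d <- .crossDist(xyz, xyz)
  cut <- 1.3 * outer(rc, rc, "+")
  bmat <- d < cut & upper.tri(d)
  bmat[el == "H", el == "H"] <- FALSE  # no H-H bonds
  bonds <- which(bmat, arr.ind = TRUE)
  ## H bonded only to its single nearest heavy atom
  if (nrow(bonds)) {
    isH <- el[bonds[, 1]] == "H" | el[bonds[, 2]] == "H"
    hidx <- ifelse(el[bonds[, 1]] == "H", bonds[, 1], bonds[, 2])
    keep <- rep(TRUE, nrow(bonds))
    for (h in unique(hidx[isH])) {
      rows <- which(isH & hidx == h)
      if (length(rows) > 1L) {
        dd <- d[cbind(bonds[rows, 1], bonds[rows, 2])]
        keep[rows[-which.min(dd)]] <- FALSE
      }
    }
    bonds <- bonds[keep, , drop = FALSE]
  }
  pair <- function(i, j) {
    k <- paste(pmin(el[i], el[j]), pmax(el[i], el[j]), sep = "-")
    r0 <- .BOND_R0[k]
    ifelse(is.na(r0), rc[i] + rc[j], r0)
  }
  bondR0 <- if (nrow(bonds)) pair(bonds[, 1], bonds[, 2]) else numeric()

  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  angles <- matrix(integer(), 0, 3)
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(nb, 2L)
      angles <- rbind(angles, cbind(cmb[1, ], j, cmb[2, ]))
    }
  }
  angle0 <- if (nrow(angles)) apply(angles, 1L, function(tr)
    bondAngle(xyz[tr[1], ], xyz[tr[2], ], xyz[tr[3], ])) else numeric()

  ## partial charges
  q <- numeric(n)
  q[el == "N"] <- -0.50
  q[el == "O"] <- -0.60
  q[el == "S"] <- -0.25
  metal <- el %in% c("Zn", "Mg", "Fe", "Mn", "Cu", "Ni", "Co")
  q[metal] <- 2
  q[el %in% c("Na", "K")] <- 1
  q[el == "Cl"] <- -1
  heavyOf <- rep(NA_integer_, n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    if (el[i] == "H") heavyOf[i] <- j
    if (el[j] == "H") heavyOf[j] <- i
  }
  hs <- which(el == "H" & !is.na(heavyOf))
  q[hs] <- c(N = 0.40, O = 0.42, C = 0.09, S = 0.15)[el[heavyOf[hs]]]
  q[is.na(q)] <- 0
  cpol <- el == "C" & vapply(adj, function(nb) any(el[nb] %in% c("N", "O")),
                             TRUE)
  q[cpol] <- 0.15

  ## nonbonded exclusions: 1-2 and 1-3
  excl <- matrix(FALSE, n, n)
  excl[bonds] <- TRUE
  if (nrow(angles)) excl[angles[, c(1, 3), drop = FALSE]] <- TRUE
  excl <- excl | t(excl)
  nb <- which(upper.tri(d) & !excl, arr.ind = TRUE)

  rmin2 <- .LJ_RMIN2[el]; rmin2[is.na(rmin2)] <- 1.5
  eps <- .LJ_EPS[el]; eps[is.na(eps)] <- 0.1
  ## polar hydrogens get a near-zero radius (as in standard force fields)
  ## so Lennard-Jones repulsion does not mask hydrogen bonding
  polarH <- el == "H" & !is.na(heavyOf) & el[heavyOf] %in% c("N", "O", "S")
  rmin2[polarH] <- 0.4
  eps[polarH] <- 0.01

  ## donor hydrogens and acceptors for the explicit hydrogen-bond well;
  ## candidate (H, acceptor) pairs precomputed as index vectors
  donH <- which(el == "H" & !is.na(heavyOf) &
                el[heavyOf] %in% c("N", "O", "S"))
  hasH <- vapply(seq_len(n), function(i) any(el[adj[[i]]] == "H"), TRUE)
  acc <- which((el %in% c("O", "S")) | (el == "N" & !hasH))
  hb <- expand.grid(h = donH, a = acc)
  if (nrow(hb)) {
    hb$d <- heavyOf[hb$h]
    hb <- hb[hb$a != hb$d & hb$a != hb$h, , drop = FALSE]
  } else hb$d <- integer()

  list(n = n, elements = el, bonds = bonds, bondR0 = bondR0,
       angles = angles, angle0 = angle0, nb = nb,
       q = q, rmin2 = rmin2, eps = eps,
       donorH = donH, donorOf = heavyOf, acceptors = acc,
       hbH = hb$h, hbA = hb$a, hbD = hb$d,
       nH = sum(el == "H"))
}

#' Surrogate energy of a configuration
#'
#' E = harmonic bonds + harmonic angles + optional torsion restraint +
#' Lennard-Jones + Coulomb with a distance-dependent dielectric (eps = 4r) +
#' an angular 10-12 hydrogen-bond well for D-H...A triples + a constant
#' formation term per hydrogen. Deterministic and invariant under rigid-body
#' motion.
#'
#' @param coords n x 3 coordinate matrix.
#' @param topology From [buildTopology()].
#' @param restraint Optional [TorsionRestraint-class]; `restraintIdx` gives
#'   the four atom rows it acts on.
#' @param restraintIdx Integer 4-vector, required when `restraint` is given
#'   and enabled.
#' @return Energy in kcal mol^-1.
#' @export
surrogateEnergy <- function(coords, topology, restraint = NULL,
                            restraintIdx = NULL) {
  tp <- topology
  E <- tp$nH * .MU_H
  if (nrow(tp$bonds)) {
    dv <- coords[tp$bonds[, 1], , drop = FALSE] -
      coords[tp$bonds[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    E <- E + sum(.KBOND * (r - tp$bondR0)^2)
  }
  if (nrow(tp$angles)) {
    u <- coords[tp$angles[, 1], , drop = FALSE] -
      coords[tp$angles[, 2], , drop = FALSE]
    v <- coords[tp$angles[, 3], , drop = FALSE] -
      coords[tp$angles[, 2], , drop = FALSE]
    cosd <- rowSums(u * v) / (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
    th <- acos(pmax(-1, pmin(1, cosd)))
    E <- E + sum(.KANGLE * (th - .rad(tp$angle0))^2)
  }
  if (!is.null(restraint) && restraint@enabled) {
    ang <- dihedralAngle(coords[restraintIdx[1], ], coords[restraintIdx[2], ],
                         coords[restraintIdx[3], ], coords[restraintIdx[4], ])
    E <- E + restraint@weight * .wrapAngle(ang - restraint@target)^2
  }
  if (nrow(tp$nb)) {
    i <- tp$nb[, 1]; j <- tp$nb[, 2]
    dv <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    r2 <- rowSums(dv * dv)
    r <- sqrt(r2)
    rm <- tp$rmin2[i] + tp$rmin2[j]
    e <- sqrt(tp$eps[i] * tp$eps[j])
    s6 <- (rm / r)^6
    E <- E + sum(e * (s6 * s6 - 2 * s6))
    E <- E + sum(.COULOMB_K * tp$q[i] * tp$q[j] / (4 * r2))
  }
  ## hydrogen-bond wells (vectorized over precomputed candidate pairs)
  if (length(tp$hbH)) {
    ha <- coords[tp$hbA, , drop = FALSE] - coords[tp$hbH, , drop = FALSE]
    r <- sqrt(rowSums(ha * ha))
    ok <- r <= 3.5 & r > 1e-6
    if (any(ok)) {
      hd <- coords[tp$hbD[ok], , drop = FALSE] -
        coords[tp$hbH[ok], , drop = FALSE]
      rhd <- sqrt(rowSums(hd * hd))
      ## cosDHA = -cos(D-H-A): +1 at a linear hydrogen bond, 0 at 90 degrees
      cosDHA <- -rowSums(hd * ha[ok, , drop = FALSE]) / (rhd * r[ok])
      cosDHA <- pmax(-1, pmin(1, cosDHA))
      ## wells only for D-H...A angles past 90 degrees, scaled by cos^2 of
      ## the deviation from linearity
      lin <- cosDHA > 0
      if (any(lin)) {
        s <- .HB_R0 / r[ok][lin]
        well <- .HB_EPS * (5 * s^12 - 6 * s^10)
        E <- E + sum(well * cosDHA[lin]^2)
      }
    }
  }
  E
}

#' Minimize a configuration with the surrogate backend
#'
#' Free-atom coordinates are optimized by cycles of L-BFGS-B with a central
#' finite-difference gradient; frozen atoms are never touched (they are
#' excluded from the parameter vector, so their coordinates are bit-for-bit
#' identical on output). The energy after each accepted cycle is recorded in
#' the result's `trace` and is non-increasing. Convergence: maximum gradient
#' component below `gtol` (kcal mol^-1 A^-1) or energy change below 1e-7
#' between cycles.
#'
#' @param job A [QMJob-class] with backend "surrogate".
#' @param gtol Gradient tolerance (default 1e-4).
#' @return A [QMResult-class].
#' @export
surrogateMinimize <- function(job, gtol = 1e-4) {
  cfg <- job@configuration
  a <- cfg@atoms
  tp <- buildTopology(a)
  coords <- .coordsOf(a)
  free <- !cfg@frozen
  ## restraint atoms are the target histidine's
  sel <- which(cfg@selection)
  ridx <- sel[match(cfg@restraint@atomNames, a$name[sel])]
  efun <- function(par) {
    cc <- coords
    cc[free, ] <- matrix(par, ncol = 3)
    surrogateEnergy(cc, tp, cfg@restraint, ridx)
  }
  gfun <- function(par) {
    g <- numeric(length(par))
    h <- 1e-5
    for (k in seq_along(par)) {
      pp <- par; pp[k] <- par[k] + h
      pm <- par; pm[k] <- par[k] - h
      g[k] <- (efun(pp) - efun(pm)) / (2 * h)
    }
    g
  }
  par <- as.numeric(coords[free, ])
  e0 <- efun(par)
  trace <- e0
  ncyc <- 0L
  converged <- FALSE
  if (!length(par)) {
    converged <- TRUE   # nothing to move: single-point energy
  } else {
    repeat {
      ncyc <- ncyc + 1L
      ePrev <- trace[length(trace)]
      opt <- stats::optim(par, efun, gfun, method = "L-BFGS-B",
                          control = list(maxit = 60, factr = 1e4))
      if (opt$value <= ePrev) par <- opt$par   # accept only improvements
      eNew <- min(opt$value, ePrev)
      trace <- c(trace, eNew)
      g <- gfun(par)
      if (max(abs(g)) < gtol || abs(ePrev - eNew) < 1e-7) {
        converged <- TRUE
        break
      }
      if (ncyc >= job@maxCycles) break
    }
  }
  final <- coords
  if (length(par)) final[free, ] <- matrix(par, ncol = 3)
  eF <- efun(par)
  methods::new("QMResult", finalEnergy = eF, finalCoords = final,
               converged = converged, nCycles = ncyc, trace = trace,
               log = sprintf("surrogate: %d cycle(s), E %.6f -> %.6f",
                             ncyc, e0, eF))
}
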