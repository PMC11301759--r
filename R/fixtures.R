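## Deterministic synthetic micro-environments: a capped histidine dipeptide
## built from an internal-coordinate table, placeable interaction partners
## (waters, carbonyl acceptors, ammonia donors, clash atoms), canned MOPAC
## output for the parser, and synthetic pKa datasets for calibration
## studies. Everything is a deterministic function of its spec; these stand
## in for crystal-structure environments and are labelled synthetic
## throughout.

## internal-coordinate table (Angstrom / degrees): standard ideal amino-acid
## geometry; shipped constants so tests are stable
.ICT <- list(
  C_N = 1.329, N_CA = 1.458, CA_C = 1.525, C_O = 1.231, CA_CB = 1.530,
  CB_CG = 1.497, CG_ND1 = 1.378, ND1_CE1 = 1.321, CE1_NE2 = 1.321,
  NE2_CD2 = 1.373, CD2_CG = 1.354,
  ang_CA_C_N = 116.2, ang_C_N_CA = 121.7, ang_N_CA_C = 111.0,
  ang_CA_C_O = 120.8, ang_N_CA_CB = 110.4, ang_CA_CB_CG = 113.8,
  ## ring angles nudged (< 1 degree each) from library ideals so the
  ## five-membered ring closes on the tabulated CD2-CG length exactly
  ang_CB_CG_ND1 = 122.7, ang_CG_ND1_CE1 = 108.70, ang_ND1_CE1_NE2 = 110.26,
  ang_CE1_NE2_CD2 = 106.61)

#' Specification of a synthetic histidine micro-environment
#'
#' @param chi1,chi2 Side-chain torsions in degrees (defaults -60, 90: the
#'   common m90 rotamer).
#' @param phi,psi Backbone torsions (default extended, -120/140).
#' @param flankN,flankC Number of extra glycine residues before/after the
#'   histidine (default 0); useful for exercising backbone-cut capping.
#' @param partners List of partner placements, each a list with elements
#'   `target` (histidine atom name), `distance` (A), `role` ("acceptor",
#'   "donor" or "clash") and optional `kind` ("carbonyl", "ammonia",
#'   "water", "atom").
#' @param seed Integer seed for coordinate jitter.
#' @param jitterSigma Gaussian jitter on heavy-atom coordinates, A
#'   (default 0).
#' @return List of class "FixtureSpec".
#' @export
fixtureSpec <- function(chi1 = -60, chi2 = 90, phi = -120, psi = 140,
                        flankN = 0L, flankC = 0L, partners = list(),
                        seed = 1L, jitterSigma = 0) {
  structure(list(chi1 = chi1, chi2 = chi2, phi = phi, psi = psi,
                 flankN = as.integer(flankN), flankC = as.integer(flankC),
                 partners = partners, seed = as.integer(seed),
                 jitterSigma = jitterSigma),
            class = "FixtureSpec")
}

.mkAtom <- function(serial, name, element, resname, resseq, xyz,
                    chain = "A") {
  data.frame(serial = as.integer(serial), name = name, altloc = " ",
             resname = resname, chain = chain, resseq = as.integer(resseq),
             icode = " ", x = xyz[1], y = xyz[2], z = xyz[3],
             occupancy = 1, bfactor = 10, element = element, segid = "",
             stringsAsFactors = FALSE)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Build a synthetic histidine dipeptide structure
#'
#' An Ace-(Gly)n-His-(Gly)m-Nme fragment with canonical bond lengths and
#' angles from the built-in internal-coordinate table, the requested
#' chi1/chi2, exactly planar imidazole ring (to machine precision before
#' jitter), and any requested interaction partners placed via
#' [placePartner()]. Deterministic for a fixed spec, including the seeded
#' jitter.
#'
#' @param spec A [fixtureSpec()].
#' @return A [PDBStructure-class].
#' @export
buildHisDipeptide <- function(spec = fixtureSpec()) {
  ic <- .ICT
  nres <- 2L + spec$flankN + spec$flankC + 1L   # ACE + flanks + HIS + NME
  hisPos <- 2L + spec$flankN
  atoms <- NULL
  add <- function(name, element, resname, resseq, xyz) {
    atoms <<- rbind(atoms, .mkAtom(if (is.null(atoms)) 1L else
      max(atoms$serial) + 1L, name, element, resname, resseq, xyz))
    xyz
  }
  ## ACE: CH3-C(=O)-
  ch3 <- add("CH3", "C", "ACE", 1L, c(0, 0, 0))
  cPrev <- add("C", "C", "ACE", 1L, c(ic$CA_C, 0, 0))
  o <- .placeAtom(c(0, 1, 0), ch3, cPrev, ic$C_O, ic$ang_CA_C_O, 90)
  add("O", "O", "ACE", 1L, o)
  caPrev <- ch3
  nPrev <- NULL
  resseq <- 1L
  for (k in seq_len(nres - 2L)) {
    resseq <- resseq + 1L
    isHis <- resseq == hisPos + 0L
    rn <- if (isHis) "HIS" else "GLY"
    n <- add("N", "N", rn, resseq,
             .placeAtom(o, caPrev, cPrev, ic$C_N, ic$ang_CA_C_N, 180))
    ca <- add("CA", "C", rn, resseq,
              .placeAtom(caPrev, cPrev, n, ic$N_CA, ic$ang_C_N_CA, 180))
    cc <- add("C", "C", rn, resseq,
              .placeAtom(cPrev, n, ca, ic$CA_C, ic$ang_N_CA_C, spec$phi))
    o <- add("O", "O", rn, resseq,
             .placeAtom(n, ca, cc, ic$C_O, ic$ang_CA_C_O, spec$psi + 180))
    if (isHis) {
      cb <- add("CB", "C", rn, resseq,
                .placeAtom(cPrev, n, ca, ic$CA_CB, ic$ang_N_CA_CB,
                           spec$phi - 122.6))
      cg <- add("CG", "C", rn, resseq,
                .placeAtom(n, ca, cb, ic$CB_CG, ic$ang_CA_CB_CG, spec$chi1))
      nd1 <- add("ND1", "N", rn, resseq,
                 .placeAtom(ca, cb, cg, ic$CG_ND1, ic$ang_CB_CG_ND1,
                            spec$chi2))
      ce1 <- add("CE1", "C", rn, resseq,
                 .placeAtom(cb, cg, nd1, ic$ND1_CE1, ic$ang_CG_ND1_CE1, 180))
      ne2 <- add("NE2", "N", rn, resseq,
                 .placeAtom(cg, nd1, ce1, ic$CE1_NE2, ic$ang_ND1_CE1_NE2, 0))
      add("CD2", "C", rn, resseq,
          .placeAtom(nd1, ce1, ne2, ic$NE2_CD2, ic$ang_CE1_NE2_CD2, 0))
    }
    cPrevOld <- cPrev
    caPrev <- ca; cPrev <- cc
    nPrev <- n
  }
  ## NME cap
  resseq <- resseq + 1L
  n <- add("N", "N", "NME", resseq,
           .placeAtom(o, caPrev, cPrev, ic$C_N, ic$ang_CA_C_N, 180))
  add("CH3", "C", "NME", resseq,
      .placeAtom(caPrev, cPrev, n, ic$N_CA, ic$ang_C_N_CA, 180))

  if (spec$jitterSigma > 0) {
    atoms[, c("x", "y", "z")] <- .withSeed(spec$seed,
      atoms[, c("x", "y", "z")] +
        matrix(stats::rnorm(3L * nrow(atoms), 0, spec$jitterSigma),
               ncol = 3))
  }
  rownames(atoms) <- NULL
  s <- methods::new("PDBStructure", atoms = atoms, crystal = list())
  for (p in spec$partners)
    s <- placePartner(s, target = p$target, distance = p$distance,
                      role = p$role,
                      kind = if (is.null(p$kind)) "auto" else p$kind)
  s
}

## in-plane interaction direction of a histidine ring atom: the external
## bisector of its two ring neighbors (where a proton or lone pair points)
.interactionVector <- function(atoms, hisRows, target) {
  nb <- .RING_NB[[target]]
  if (is.null(nb)) stop("no interaction vector defined for atom ", target)
  n <- .hisXYZ(atoms, hisRows, target)
  u <- .vunit(.hisXYZ(atoms, hisRows, nb[1]) - n)
  v <- .vunit(.hisXYZ(atoms, hisRows, nb[2]) - n)
  -.vunit(u + v)
}

#' Place an interaction partner against a histidine ring atom
#'
#' The partner is placed at `distance` Angstrom from the target atom along
#' its ideal in-plane interaction vector (the direction a ring proton or
#' lone pair points). Partner kinds: a carbonyl probe (C=O; acceptor only),
#' an ammonia molecule (donor only: one N-H aimed at the target), a water
#' (donor or acceptor orientation), or a bare carbon atom (pure
#' steric clash). By default the kind follows the role.
#'
#' @param s A [PDBStructure-class] containing a histidine.
#' @param target Ring atom name ("ND1", "NE2", "CE1", "CD2").
#' @param distance Angstrom from the target heavy atom.
#' @param role "acceptor", "donor" or "clash".
#' @param kind "auto" (default), "carbonyl", "ammonia", "water" or "atom".
#' @return The structure with the partner appended.
#' @export
placePartner <- function(s, target = "ND1", distance = 2.9,
                         role = c("acceptor", "donor", "clash"),
                         kind = "auto") {
  role <- match.arg(role)
  if (kind == "auto")
    kind <- switch(role, acceptor = "carbonyl", donor = "ammonia",
                   clash = "atom")
  a <- atoms(s)
  sites <- findHistidines(s)
  if (!length(sites)) stop("no histidine in structure")
  hisRows <- unname(sites[[1]]@atomIndices)
  tpos <- .hisXYZ(a, hisRows, target)
  u <- .interactionVector(a, hisRows, target)
  base <- tpos + distance * u
  if (min(.crossDist(.coordsOf(a), matrix(base, 1))) < 1.5)
    stop("placement error: position within 1.5 A of an existing atom")
  ## any vector perpendicular to u
  perp <- .vcross(u, c(0, 0, 1))
  if (.vnorm(perp) < 1e-6) perp <- .vcross(u, c(0, 1, 0))
  perp <- .vunit(perp)
  resseq <- max(a$resseq) + 1L
  serial <- max(a$serial)
  newRows <- switch(kind,
    carbonyl = {
      rbind(.mkAtom(serial + 1L, "O", "O", "CBO", resseq, base),
            .mkAtom(serial + 2L, "C", "C", "CBO", resseq, base + 1.23 * u))
    },
    ammonia = {
      h1 <- base - 1.01 * u
      th <- .rad(109.5)
      d2 <- cos(th) * (-u) + sin(th) * perp
      d3 <- cos(th) * (-u) - sin(th) * perp
      rbind(.mkAtom(serial + 1L, "N", "N", "NH3", resseq, base),
            .mkAtom(serial + 2L, "H1", "H", "NH3", resseq, h1),
            .mkAtom(serial + 3L, "H2", "H", "NH3", resseq, base + 1.01 * d2),
            .mkAtom(serial + 4L, "H3", "H", "NH3", resseq, base + 1.01 * d3))
    },
    water = {
      hdir1 <- if (role == "donor") -u else
        .vunit(cos(.rad(125)) * (-u) + sin(.rad(125)) * perp)
      th <- .rad(104.5)
      hdir2 <- cos(th) * hdir1 +
        sin(th) * .vunit(perp - sum(perp * hdir1) * hdir1)
      rbind(.mkAtom(serial + 1L, "O", "O", "HOH", resseq, base),
            .mkAtom(serial + 2L, "H1", "H", "HOH", resseq,
                    base + 0.96 * hdir1),
            .mkAtom(serial + 3L, "H2", "H", "HOH", resseq,
                    base + 0.96 * hdir2))
    },
    atom = .mkAtom(serial + 1L, "C", "C", "CLS", resseq, base),
    stop("unknown partner kind: ", kind))
  out <- rbind(a, newRows)
  rownames(out) <- NULL
  methods::new("PDBStructure", atoms = out, crystal = s@crystal)
}

#' Named fixture presets
#'
#' "donor-at-ND1": ammonia donating into ND1 (favours the HE2 tautomer);
#' "acceptor-at-NE2": carbonyl accepting from an NE2 proton (favours
#' HE2-containing states); "acceptor-at-ND1": carbonyl accepting from an
#' HD1 proton; "metal-clash": bare clash atom against ND1; "bare": the
#' dipeptide alone.
#'
#' @param name Preset name.
#' @return A [PDBStructure-class].
#' @export
fixturePreset <- function(name = c("bare", "donor-at-ND1", "acceptor-at-ND1",
                                   "acceptor-at-NE2", "metal-clash")) {
  name <- match.arg(name)
  partners <- switch(name,
    "bare" = list(),
    "donor-at-ND1" = list(list(target = "ND1", distance = 3.0,
                               role = "donor")),
    "acceptor-at-ND1" = list(list(target = "ND1", distance = 2.9,
                                  role = "acceptor")),
    "acceptor-at-NE2" = list(list(target = "NE2", distance = 2.9,
                                  role = "acceptor")),
    "metal-clash" = list(list(target = "ND1", distance = 2.4,
                              role = "clash")))
  buildHisDipeptide(fixtureSpec(partners = partners))
}

#' Generate a syntactically valid MOPAC output text
#'
#' Embeds the given heat of formation and final coordinates so that
#' [parseMopacOutput()] round-trips them (coordinates at 1e-4 A format
#' precision).
#'
#' @param energy kcal/mol.
#' @param coords n x 3 matrix.
#' @param elements Character vector of element symbols (default "C").
#' @param done Include the normal-termination marker (default TRUE).
#' @return Single text string.
#' @export
cannedMopacOutput <- function(energy, coords,
                              elements = rep("C", nrow(coords)),
                              done = TRUE) {
  lines <- c(" *  MOPAC output (synthetic fixture)",
             "",
             sprintf(" FINAL HEAT OF FORMATION = %17.5f KCAL/MOL", energy),
             "",
             "          CARTESIAN COORDINATES",
             "",
             sprintf("  %4d  %-2s %12.4f %12.4f %12.4f",
                     seq_len(nrow(coords)), toupper(elements),
                     coords[, 1], coords[, 2], coords[, 3]),
             "")
  if (done) lines <- c(lines, " == MOPAC DONE ==")
  paste(lines, collapse = "\n")
}

#' Simulate a synthetic pKa calibration dataset
#'
#' Draws heat-of-formation differences uniformly over the reference range
#' and generates pKa values from a known linear model with Gaussian noise;
#' used for parameter-recovery studies of the calibration fit.
#'
#' @param n Records (default 20).
#' @param a,b True model parameters.
#' @param sigma Gaussian noise on pKa (default 1.5).
#' @param dGRange Range of dG values, kcal/mol.
#' @param seed Integer seed.
#' @return data.frame usable by [fitPkaModel()].
#' @export
simulatePkaRecords <- function(n = 20L, a = 42.18, b = 0.368, sigma = 1.5,
                               dGRange = c(-112.3, -76.06), seed = 1L) {
  .withSeed(seed, {
    dG <- stats::runif(n, dGRange[1], dGRange[2])
    data.frame(solute = sprintf("synthetic%02d", seq_len(n)),
               pka_exp = a + b * dG + stats::rnorm(n, 0, sigma),
               dG = dG,
               site_class = rep_len(c("N", "O"), n),
               stringsAsFactors = FALSE)
  })
}
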