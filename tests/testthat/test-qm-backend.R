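test_that("MOPAC input decks carry method, solvent, charge and freeze flags", {
  cl <- makeCluster(fixturePreset("bare"))
  cfgs <- enumerateConfigurations(cl)
  job <- qmJob(cfgs[[2]], cl)            # HD1 only: net charge 1 - 1 = 0
  txt <- writeMopacInput(job)
  expect_match(txt, "PM6-D3H4")
  expect_match(txt, "EPS=78.4", fixed = TRUE)
  expect_match(txt, "CHARGE=0", fixed = TRUE)
  lines <- strsplit(txt, "\n")[[1]]
  atomLines <- lines[-(1:3)]
  frozen <- cfgs[[2]]@frozen
  expect_length(atomLines, length(frozen))
  hasFree <- grepl(" 1 ", atomLines, fixed = TRUE)
  expect_identical(hasFree, !frozen)

  # doubly protonated carries the full +1; charge propagates to the keyword
  jobP <- qmJob(cfgs[[1]], cl)
  expect_equal(jobP@charge, 1L)
  expect_match(writeMopacInput(jobP), "CHARGE=1", fixed = TRUE)
  jobN <- methods::initialize(jobP, charge = -1L)
  expect_match(writeMopacInput(jobN), "CHARGE=-1", fixed = TRUE)
  expect_error(writeMopacInput(methods::initialize(job, method = "B3LYP")),
               "unsupported")
})

test_that("canned MOPAC output round-trips energy, coordinates and status", {
  set.seed(21)
  co <- matrix(rnorm(9, sd = 5), 3)
  txt <- cannedMopacOutput(-1019.6, co, c("N", "C", "H"))
  res <- parseMopacOutput(txt)
  expect_equal(res@finalEnergy, -1019.6)
  expect_equal(nrow(res@finalCoords), 3L)
  expect_lt(max(abs(res@finalCoords - co)), 1e-4)
  expect_true(res@converged)
  # truncated output is a parse error; missing DONE marker flags non-converged
  expect_error(parseMopacOutput("some truncated text"), "parse error")
  resBad <- parseMopacOutput(cannedMopacOutput(-1.5, co, done = FALSE))
  expect_false(resBad@converged)
})

test_that("surrogate energy has Lennard-Jones shape and hydrogen-bond wells", {
  two <- function(r) {
    a <- data.frame(serial = 1:2, name = c("C1", "C2"), altloc = " ",
                    resname = "CLS", chain = "A", resseq = 1:2, icode = " ",
                    x = c(0, r), y = 0, z = 0, occupancy = 1, bfactor = 0,
                    element = "C", segid = "")
    surrogateEnergy(as.matrix(a[, c("x", "y", "z")]), buildTopology(a))
  }
  rmin <- 3.8   # twice the carbon Rmin/2
  expect_lt(two(rmin), two(0.8 * rmin))
  expect_lt(two(rmin), two(3 * rmin))

  nho <- function(angleDHA) {
    th <- (180 - angleDHA) * pi / 180
    hpos <- c(1.01, 0, 0)
    apos <- hpos + 1.9 * c(cos(th), sin(th), 0)
    a <- data.frame(serial = 1:4, name = c("N", "H1", "O", "C"),
                    altloc = " ", resname = c("AMN", "AMN", "CBO", "CBO"),
                    chain = "A", resseq = c(1L, 1L, 2L, 2L), icode = " ",
                    x = c(0, hpos[1], apos[1], apos[1] + 1.23),
                    y = c(0, hpos[2], apos[2], apos[2]), z = 0,
                    occupancy = 1, bfactor = 0,
                    element = c("N", "H", "O", "C"), segid = "")
    surrogateEnergy(as.matrix(a[, c("x", "y", "z")]), buildTopology(a))
  }
  expect_lt(nho(180), nho(90))
})

test_that("surrogate energy is rigid-motion invariant and deterministic", {
  cl <- makeCluster(fixturePreset("acceptor-at-ND1"))
  cfg <- enumerateConfigurations(cl)[[1]]
  a <- atoms(cfg)
  tp <- buildTopology(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  e1 <- surrogateEnergy(xyz, tp)
  expect_identical(e1, surrogateEnergy(xyz, tp))  # bit-for-bit deterministic
  th <- 0.7
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  expect_equal(surrogateEnergy(xyz %*% t(R) + 2.5, tp), e1, tolerance = 1e-9)
})

test_that("all-frozen minimization is a single-point energy", {
  s <- fixturePreset("bare")
  site <- findHistidines(s)[[1]]
  cl <- assignFreezeFlags(capCluster(selectCluster(s, site), s),
                          policy = "all-frozen")
  cfg <- enumerateConfigurations(cl)[[3]]
  cfg@frozen[] <- TRUE   # include the built proton: no degrees of freedom
  res <- surrogateMinimize(qmJob(cfg, cl))
  expect_true(res@converged)
  expect_equal(res@nCycles, 0L)
  expect_identical(res@finalCoords, as.matrix(atoms(cfg)[, c("x", "y", "z")]),
                   ignore_attr = TRUE)
})

test_that("minimization restores a displaced proton and conserves frozen atoms", {
  cl <- makeCluster(fixturePreset("bare"))
  cfg <- enumerateConfigurations(cl)[[2]]
  a <- atoms(cfg)
  sel <- which(cfg@selection)
  hIdx <- sel[match("HD1", a$name[sel])]
  nIdx <- sel[match("ND1", a$name[sel])]
  nPos <- as.numeric(a[nIdx, c("x", "y", "z")])
  hPos <- as.numeric(a[hIdx, c("x", "y", "z")])
  u <- (hPos - nPos) / sqrt(sum((hPos - nPos)^2))
  a[hIdx, c("x", "y", "z")] <- nPos + (1.01 + 0.2) * u   # 0.2 A too long
  cfg@atoms <- a
  res <- surrogateMinimize(qmJob(cfg, cl))
  expect_true(res@converged)
  bond <- sqrt(sum((res@finalCoords[hIdx, ] - res@finalCoords[nIdx, ])^2))
  expect_lt(abs(bond - 1.01), 0.01)
  # frozen atoms bit-for-bit identical
  expect_identical(res@finalCoords[cfg@frozen, ],
                   as.matrix(atoms(cfg)[cfg@frozen, c("x", "y", "z")]),
                   ignore_attr = TRUE)
  # accepted-cycle energies are non-increasing and end at or below the start
  expect_true(all(diff(res@trace) <= 0))
  expect_lte(res@finalEnergy, res@trace[1])
})

test_that("the planar restraint holds the ring torsion against a clash", {
  cl <- makeCluster(fixturePreset("metal-clash"))
  finalTorsion <- function(restrain) {
    cfg <- enumerateConfigurations(cl, restrain = restrain)[[2]]
    res <- surrogateMinimize(qmJob(cfg, cl))
    a <- atoms(cfg)
    sel <- which(cfg@selection)
    cc <- res@finalCoords
    xyz <- function(n) cc[sel[match(n, a$name[sel])], ]
    dev <- dihedralAngle(xyz("CA"), xyz("CB"), xyz("CG"), xyz("ND1")) -
      cfg@restraint@target
    abs(((dev + 180) %% 360) - 180)
  }
  devOn <- finalTorsion(TRUE)
  devOff <- finalTorsion(FALSE)
  expect_lt(devOn, 5)
  expect_gt(devOff, devOn)
})

test_that("an adapter round trip recovers atom count, flags and charge", {
  cl <- makeCluster(fixturePreset("bare"))
  cfg <- enumerateConfigurations(cl)[[3]]
  job <- qmJob(cfg, cl)
  txt <- writeMopacInput(job)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(length(lines) - 3L, nAtoms(cfg))
  # echo the geometry through a canned output and re-parse
  out <- parseMopacOutput(cannedMopacOutput(-7.25,
                                            as.matrix(atoms(cfg)[, c("x", "y", "z")]),
                                            atoms(cfg)$element))
  expect_equal(nrow(out@finalCoords), nAtoms(cfg))
  expect_match(regmatches(lines[1], regexpr("CHARGE=-?[0-9]+", lines[1])),
               paste0("CHARGE=", job@charge), fixed = TRUE)
})
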