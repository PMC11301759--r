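clusterFor <- function(preset = "bare") makeCluster(fixturePreset(preset))

test_that("exactly six canonical configurations with proton counts 2,1,1,2,1,1", {
  cl <- clusterFor()
  cfgs <- enumerateConfigurations(cl)
  expect_length(cfgs, 6L)
  expect_identical(vapply(cfgs, function(c) c@state, ""),
                   rep(c("HD1^HE2", "HD1", "HE2"), 2))
  expect_identical(vapply(cfgs, function(c) c@flipped, TRUE),
                   rep(c(FALSE, TRUE), each = 3))
  expect_identical(vapply(cfgs, function(c) c@nRingProtons, 1L),
                   c(2L, 1L, 1L, 2L, 1L, 1L))
  # non-redundant: distinct (state, flip) pairs
  expect_equal(anyDuplicated(vapply(cfgs, function(c)
    paste(c@state, c@flipped), "")), 0L)
  # atom counts: base + number of ring protons
  n <- vapply(cfgs, nAtoms, 1L)
  expect_identical(n - min(n), c(1L, 0L, 0L, 1L, 0L, 0L))
})

test_that("unflipped states share heavy atoms; flips swap ring coordinates", {
  cl <- clusterFor()
  cfgs <- enumerateConfigurations(cl)
  heavy <- function(cfg) {
    a <- atoms(cfg)
    a[a$element != "H", c("name", "x", "y", "z")]
  }
  expect_equal(heavy(cfgs[[1]]), heavy(cfgs[[2]]), ignore_attr = TRUE)
  expect_equal(heavy(cfgs[[2]]), heavy(cfgs[[3]]), ignore_attr = TRUE)
  # ND1 of the flipped state sits on CD2 of the unflipped, and vice versa
  a1 <- atoms(cfgs[[1]])
  a4 <- atoms(cfgs[[4]])
  expect_equal(hisXYZ(a4, "ND1"), hisXYZ(a1, "CD2"), tolerance = 1e-12)
  expect_equal(hisXYZ(a4, "CD2"), hisXYZ(a1, "ND1"), tolerance = 1e-12)
  expect_equal(hisXYZ(a4, "CE1"), hisXYZ(a1, "NE2"), tolerance = 1e-12)
  # CB and CG untouched
  expect_equal(hisXYZ(a4, "CG"), hisXYZ(a1, "CG"), tolerance = 1e-12)
  expect_equal(hisXYZ(a4, "CB"), hisXYZ(a1, "CB"), tolerance = 1e-12)
})

test_that("the ring flip is an involution and rotates chi2 by 180 degrees", {
  s <- buildHisDipeptide(fixtureSpec())
  a <- atoms(s)
  hisRows <- which(a$resname == "HIS")
  once <- flipRing(a, hisRows)
  twice <- flipRing(once, hisRows)
  expect_equal(twice[, c("x", "y", "z")], a[, c("x", "y", "z")],
               tolerance = 1e-12, ignore_attr = TRUE)
  chi2 <- function(at) dihedralAngle(hisXYZ(at, "CA"), hisXYZ(at, "CB"),
                                     hisXYZ(at, "CG"), hisXYZ(at, "ND1"))
  d <- (chi2(once) - chi2(a)) %% 360
  expect_equal(min(d, 360 - d), 180, tolerance = 0.5)
})

test_that("ring protons are built at 1.01 A in-plane along the external bisector", {
  # symmetric case: external bisector forced onto -x
  h <- placeRingProton(c(0, 0, 0), c(1, 0.5, 0), c(1, -0.5, 0))
  expect_equal(h, c(-1.01, 0, 0), tolerance = 1e-9)
  expect_error(placeRingProton(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
  set.seed(3)
  for (k in 1:10) {
    n <- rnorm(3); n1 <- n + rnorm(3); n2 <- n + rnorm(3)
    hh <- placeRingProton(n, n1, n2)
    expect_equal(sqrt(sum((hh - n)^2)), 1.01, tolerance = 1e-6)
    # coplanar with the two neighbors
    expect_equal(abs(dihedralAngle(n1, n2, n, hh)), 180, tolerance = 1e-3)
  }
})

test_that("proton placement is rotation/translation equivariant", {
  set.seed(5)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  t <- c(3, -2, 7)
  for (k in 1:5) {
    n <- rnorm(3); n1 <- n + rnorm(3); n2 <- n + rnorm(3)
    h <- placeRingProton(n, n1, n2)
    h2 <- placeRingProton(as.numeric(R %*% n + t), as.numeric(R %*% n1 + t),
                          as.numeric(R %*% n2 + t))
    expect_equal(h2, as.numeric(R %*% h + t), tolerance = 1e-9)
  }
})

test_that("configurations are planar with correct N-H geometry and restraints", {
  cl <- clusterFor()
  cfgs <- enumerateConfigurations(cl)
  for (cfg in cfgs) {
    a <- atoms(cfg)
    sel <- which(cfg@selection)
    ring <- sel[a$name[sel] %in% c("CG", "ND1", "CD2", "CE1", "NE2")]
    m <- as.matrix(a[ring, c("x", "y", "z")])
    sv <- svd(sweep(m, 2, colMeans(m)))
    expect_lt(sv$d[3], 0.02)  # coplanar ring
    for (p in c("HD1", "HE2")) {
      i <- sel[match(p, a$name[sel])]
      if (is.na(i)) next
      nAtom <- sel[match(if (p == "HD1") "ND1" else "NE2", a$name[sel])]
      expect_equal(sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) -
                             as.numeric(a[nAtom, c("x", "y", "z")]))^2)),
                   1.01, tolerance = 1e-3)
    }
    # restraint target equals the measured starting torsion
    sel <- which(cfg@selection)
    tor <- dihedralAngle(hisXYZ(a, "CA"), hisXYZ(a, "CB"),
                         hisXYZ(a, "CG"), hisXYZ(a, "ND1"))
    expect_equal(cfg@restraint@target, tor, tolerance = 1e-9)
    expect_identical(cfg@restraint@atomNames, c("CA", "CB", "CG", "ND1"))
  }
})

test_that("input ring protons are discarded so all states share heavy geometry", {
  s <- fixturePreset("bare")
  # give the input model an HE2 proton
  a <- atoms(s)
  hisRows <- which(a$resname == "HIS")
  ne2 <- hisXYZ(a, "NE2")
  cd2 <- hisXYZ(a, "CD2")
  ce1 <- hisXYZ(a, "CE1")
  h <- placeRingProton(ne2, cd2, ce1)
  a <- rbind(a, data.frame(serial = max(a$serial) + 1L, name = "HE2",
                           altloc = " ", resname = "HIS", chain = "A",
                           resseq = a$resseq[hisRows[1]], icode = " ",
                           x = h[1], y = h[2], z = h[3], occupancy = 1,
                           bfactor = 0, element = "H", segid = ""))
  rownames(a) <- NULL
  s2 <- new("PDBStructure", atoms = a, crystal = list())
  cl <- makeCluster(s2)
  cfgs <- enumerateConfigurations(cl)
  # the HD1-only state must not inherit the input HE2 proton
  expect_false("HE2" %in% atoms(cfgs[[2]])$name[cfgs[[2]]@selection])
  expect_identical(vapply(cfgs, function(c) c@nRingProtons, 1L),
                   c(2L, 1L, 1L, 2L, 1L, 1L))
})
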