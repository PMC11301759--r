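test_that("buffer selection includes and excludes whole entities by distance", {
  s <- buildHisDipeptide(fixtureSpec())
  site <- findHistidines(s)[[1]]
  a <- atoms(s)
  ne2 <- hisXYZ(a, "NE2")
  # water oxygen 3.0 A from NE2: included at buffer 3.5
  w1 <- rbind(a, data.frame(serial = max(a$serial) + 1L, name = "O",
                            altloc = " ", resname = "HOH", chain = "A",
                            resseq = 90L, icode = " ", x = ne2[1] + 3.0,
                            y = ne2[2], z = ne2[3], occupancy = 1,
                            bfactor = 0, element = "O", segid = ""))
  rownames(w1) <- NULL
  s1 <- new("PDBStructure", atoms = w1, crystal = list())
  cl1 <- selectCluster(s1, findHistidines(s1)[[1]], 3.5)
  expect_true("HOH" %in% atoms(cl1)$resname)

  # water 4.0+ A from every histidine atom: excluded
  hisA <- a[a$resname == "HIS", c("x", "y", "z")]
  far <- ne2 + c(6, 0, 0)
  stopifnot(min(sqrt(rowSums((t(t(hisA) - far))^2))) > 4)
  w2 <- w1
  w2[nrow(w2), c("x", "y", "z")] <- far
  s2 <- new("PDBStructure", atoms = w2, crystal = list())
  cl2 <- selectCluster(s2, findHistidines(s2)[[1]], 3.5)
  expect_false("HOH" %in% atoms(cl2)$resname)

  # selection mask marks exactly the target histidine
  expect_setequal(atoms(cl1)$resname[selectionMask(cl1)], "HIS")
})

test_that("included entity set equals a brute-force all-pairs scan", {
  set.seed(11)
  s <- buildHisDipeptide(fixtureSpec())
  a <- atoms(s)
  # scatter 12 waters at varied distances
  ne2 <- hisXYZ(a, "NE2")
  for (k in 1:12) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    pos <- ne2 + runif(1, 2.5, 8) * u
    a <- rbind(a, data.frame(serial = max(a$serial) + 1L, name = "O",
                             altloc = " ", resname = "HOH", chain = "A",
                             resseq = 100L + k, icode = " ", x = pos[1],
                             y = pos[2], z = pos[3], occupancy = 1,
                             bfactor = 0, element = "O", segid = ""))
  }
  rownames(a) <- NULL
  s <- new("PDBStructure", atoms = a, crystal = list())
  site <- findHistidines(s)[[1]]
  for (buffer in c(3.0, 3.5, 4.5)) {
    cl <- selectCluster(s, site, buffer)
    got <- sort(unique(atoms(cl)$resseq[atoms(cl)$resname == "HOH"]))
    # oracle: O(N^2) scan over all (atom, selection-atom) pairs
    selXYZ <- as.matrix(a[site@atomIndices, c("x", "y", "z")])
    want <- integer()
    for (r in unique(a$resseq[a$resname == "HOH"])) {
      rx <- as.matrix(a[a$resseq == r & a$resname == "HOH",
                        c("x", "y", "z")])
      dmin <- min(apply(selXYZ, 1, function(p)
        sqrt(rowSums((rx - matrix(p, nrow(rx), 3, byrow = TRUE))^2))))
      if (dmin <= buffer) want <- c(want, r)
    }
    expect_identical(got, sort(want))
  }
})

test_that("enlarging the buffer never removes an included entity", {
  s <- fixturePreset("acceptor-at-ND1")
  site <- findHistidines(s)[[1]]
  prev <- character()
  for (buffer in c(2, 3, 3.5, 5, 8)) {
    cl <- selectCluster(s, site, buffer)
    keys <- unique(paste(atoms(cl)$resname, atoms(cl)$resseq))
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("severed peptide bonds are capped on the bond line at standard lengths", {
  s <- buildHisDipeptide(fixtureSpec(flankN = 1, flankC = 1))
  site <- findHistidines(s)[[1]]
  cl0 <- selectCluster(s, site, 3.5)
  # flanking glycines included whole, terminal caps excluded: two cuts
  expect_setequal(unique(atoms(cl0)$resname), c("GLY", "HIS"))
  cl <- capCluster(cl0, s)
  caps <- capAtoms(cl)
  expect_equal(sum(caps$kind == "peptide"), 2L)
  a <- atoms(cl)
  pa <- atoms(s)
  for (i in which(caps$kind == "peptide")) {
    h <- as.numeric(a[caps$index[i], c("x", "y", "z")])
    b <- as.numeric(a[caps$bondedTo[i], c("x", "y", "z")])
    p <- as.numeric(pa[caps$severedParent[i], c("x", "y", "z")])
    len <- sqrt(sum((h - b)^2))
    expect_equal(len, if (a$element[caps$bondedTo[i]] == "N") 1.01 else 1.09,
                 tolerance = 1e-9)
    # cap sits on the severed-bond line to 1e-6 A
    u <- (p - b) / sqrt(sum((p - b)^2))
    v <- h - b
    expect_lt(sqrt(sum((v - sum(v * u) * u)^2)), 1e-6)
  }
  expect_identical(a$segid[caps$index], rep("CAP", nrow(caps)))
  # atom count bookkeeping and injective provenance
  expect_equal(nAtoms(cl), nAtoms(cl0) + nrow(caps))
  pidx <- cl@parentIndex[!is.na(cl@parentIndex)]
  expect_false(anyDuplicated(pidx) > 0)
})

test_that("bare waters get two hydrogens at 0.96 A and 104.5 degrees", {
  s <- buildHisDipeptide(fixtureSpec())
  a <- atoms(s)
  ne2 <- hisXYZ(a, "NE2")
  a <- rbind(a, data.frame(serial = max(a$serial) + 1L, name = "O",
                           altloc = " ", resname = "HOH", chain = "A",
                           resseq = 50L, icode = " ", x = ne2[1] + 2.8,
                           y = ne2[2], z = ne2[3], occupancy = 1, bfactor = 0,
                           element = "O", segid = ""))
  rownames(a) <- NULL
  s <- new("PDBStructure", atoms = a, crystal = list())
  cl <- capCluster(selectCluster(s, findHistidines(s)[[1]], 3.5), s)
  caps <- capAtoms(cl)
  wcaps <- caps[caps$kind == "water", ]
  expect_equal(nrow(wcaps), 2L)
  ca <- atoms(cl)
  o <- as.numeric(ca[wcaps$bondedTo[1], c("x", "y", "z")])
  h1 <- as.numeric(ca[wcaps$index[1], c("x", "y", "z")])
  h2 <- as.numeric(ca[wcaps$index[2], c("x", "y", "z")])
  expect_equal(sqrt(sum((h1 - o)^2)), 0.96, tolerance = 1e-9)
  expect_equal(sqrt(sum((h2 - o)^2)), 0.96, tolerance = 1e-9)
  expect_equal(bondAngle(h1, o, h2), 104.5, tolerance = 0.1)
})

test_that("freeze policy frees hydrogens, caps and ring but keeps stem frozen", {
  s <- fixturePreset("acceptor-at-ND1")
  cl <- makeCluster(s)
  a <- atoms(cl)
  frozen <- isFrozen(cl)
  sel <- selectionMask(cl)
  # environment heavy atoms frozen
  expect_true(all(frozen[!sel & a$element != "H" &
                         !seq_len(nrow(a)) %in% capAtoms(cl)$index]))
  # all hydrogens free
  expect_false(any(frozen[a$element == "H"]))
  # histidine stem CA-CB-CG frozen, ring atoms free
  expect_true(all(frozen[sel & a$name %in% c("CA", "CB", "CG")]))
  expect_false(any(frozen[sel & a$name %in% c("ND1", "CD2", "CE1", "NE2")]))
  # degenerate all-frozen policy
  clF <- assignFreezeFlags(cl, policy = "all-frozen")
  expect_true(all(isFrozen(clF)))
})

test_that("net charge sums textbook formal charges with a +1 target histidine", {
  s <- buildHisDipeptide(fixtureSpec())
  site <- findHistidines(s)[[1]]
  expect_equal(netCharge(selectCluster(s, site, 3.5)), 1L)
  # add a zinc within the buffer: +2
  a <- atoms(s)
  nd1 <- hisXYZ(a, "ND1")
  a <- rbind(a, data.frame(serial = max(a$serial) + 1L, name = "ZN",
                           altloc = " ", resname = "ZN", chain = "A",
                           resseq = 60L, icode = " ", x = nd1[1] + 2.2,
                           y = nd1[2] + 1.5, z = nd1[3], occupancy = 1,
                           bfactor = 0, element = "Zn", segid = ""))
  rownames(a) <- NULL
  s2 <- new("PDBStructure", atoms = a, crystal = list())
  expect_equal(netCharge(selectCluster(s2, findHistidines(s2)[[1]], 3.5)), 3L)
})

test_that("a histidine near the unit-cell boundary triggers a symmetry warning", {
  s <- buildHisDipeptide(fixtureSpec())
  s@crystal <- list(a = 100, b = 100, c = 100, alpha = 90, beta = 90,
                    gamma = 90, sgroup = "P 1")
  site <- findHistidines(s)[[1]]
  # fixture sits near the origin, well within buffer+5 of the cell edge
  expect_warning(selectCluster(s, site, 3.5), "symmetry")
})
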