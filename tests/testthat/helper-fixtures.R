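# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except the bundled calibration table.

hisXYZ <- function(atoms, name, resname = "HIS") {
  i <- which(atoms$name == name & atoms$resname == resname)[1]
  as.numeric(atoms[i, c("x", "y", "z")])
}

# a capped, freeze-flagged cluster around the fixture histidine
makeCluster <- function(s, buffer = 3.5) {
  site <- findHistidines(s)[[1]]
  assignFreezeFlags(capCluster(selectCluster(s, site, buffer), s))
}

# minimal hand-written PDB content
minimalPDB <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdbLine <- function(serial, name, resname, chain, resseq, x, y, z,
                    element, record = "ATOM") {
  sprintf("%-6s%5d %-4s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resname, chain, resseq, x, y, z,
          toupper(element))
}

# brute-force O(N^2) hydrogen-bond scan, independent of countHBonds()
bruteForceHBonds <- function(atoms, criteria) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- atoms$element
  # donors: every H within 1.25 A of an N/O/S heavy atom
  donors <- list()
  hasH <- rep(FALSE, nrow(atoms))
  for (h in which(el == "H")) {
    dd <- sqrt(colSums((t(xyz) - xyz[h, ])^2))
    dd[el == "H"] <- Inf
    j <- which.min(dd)
    if (dd[j] < 1.25) {
      hasH[j] <- TRUE
      if (el[j] %in% c("N", "O", "S"))
        donors[[length(donors) + 1]] <- c(D = j, H = h)
    }
  }
  acceptors <- which(el %in% c("O", "S") | (el == "N" & !hasH))
  count <- 0L
  for (d in donors) {
    hits <- data.frame(A = integer(), ang = numeric())
    for (a in acceptors) {
      if (a == d["D"]) next
      rDA <- sqrt(sum((xyz[a, ] - xyz[d["D"], ])^2))
      if (rDA <= 1.8 || rDA > criteria$maxDA) next
      rHA <- sqrt(sum((xyz[a, ] - xyz[d["H"], ])^2))
      if (rHA > criteria$maxHA) next
      u <- xyz[d["D"], ] - xyz[d["H"], ]
      v <- xyz[a, ] - xyz[d["H"], ]
      ang <- acos(max(-1, min(1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (ang < criteria$minAngle) next
      hits <- rbind(hits, data.frame(A = a, ang = ang))
    }
    if (nrow(hits)) count <- count + 1L  # each H counts at most once
  }
  count
}

# random micro-cluster of water-like and amine-like fragments
randomMicroCluster <- function(n = 6, seed = 1) {
  set.seed(seed)
  rows <- NULL
  serial <- 0L
  for (k in seq_len(n)) {
    cen <- runif(3, 0, 8)
    kind <- sample(c("HOH", "AMN", "CBO"), 1)
    add <- function(name, el, xyz) {
      serial <<- serial + 1L
      rows <<- rbind(rows, data.frame(
        serial = serial, name = name, altloc = " ", resname = kind,
        chain = "A", resseq = k, icode = " ", x = xyz[1], y = xyz[2],
        z = xyz[3], occupancy = 1, bfactor = 0, element = el, segid = "",
        stringsAsFactors = FALSE))
    }
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    if (kind == "HOH") {
      add("O", "O", cen)
      add("H1", "H", cen + 0.96 * u)
      add("H2", "H", cen + 0.96 * (cos(1.82) * u + sin(1.82) * v))
    } else if (kind == "AMN") {
      add("N", "N", cen)
      add("H1", "H", cen + 1.01 * u)
    } else {
      add("O", "O", cen)
      add("C", "C", cen + 1.23 * u)
    }
  }
  rows
}
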