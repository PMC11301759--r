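## PDB input/output and histidine location. Parsing and writing of the
## fixed-width format are delegated to bio3d; this layer normalizes elements,
## applies the single-conformer altloc policy and extracts the CRYST1 record.

.normElement <- function(el, name) {
  el <- toupper(trimws(el))
  guess <- function(nm) {
    nm <- gsub("[0-9']", "", trimws(nm))
    two <- toupper(substr(nm, 1, 2))
    if (two %in% c("ZN", "MG", "FE", "MN", "CU", "NI", "CO", "NA", "CL",
                   "BR", "SE", "CA")) two else toupper(substr(nm, 1, 1))
  }
  el[el == "" | is.na(el)] <- vapply(name[el == "" | is.na(el)], guess, "")
  paste0(substr(el, 1, 1), tolower(substr(el, 2, 10)))
}

.scanCryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(list())
  f <- cl[1]
  list(a = as.numeric(substr(f, 7, 15)), b = as.numeric(substr(f, 16, 24)),
       c = as.numeric(substr(f, 25, 33)), alpha = as.numeric(substr(f, 34, 40)),
       beta = as.numeric(substr(f, 41, 47)), gamma = as.numeric(substr(f, 48, 54)),
       sgroup = trimws(substr(f, 56, 66)))
}

#' Read a PDB file
#'
#' Reads all ATOM/HETATM records in file order. Only the blank or "A"
#' alternate-conformer records are kept (a warning reports dropped altlocs):
#' the method operates on a single conformer. Elements are normalized to
#' standard symbols ("ZN" -> "Zn").
#'
#' @param path Path to a PDB file.
#' @return A [PDBStructure-class].
#' @seealso [writePDB()], [findHistidines()]
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty structure: no ATOM/HETATM records in ", path)
  bad <- which(rec & nchar(lines) < 54)
  if (!length(bad)) {
    xs <- suppressWarnings(as.numeric(substr(lines[rec], 31, 38)))
    ys <- suppressWarnings(as.numeric(substr(lines[rec], 39, 46)))
    zs <- suppressWarnings(as.numeric(substr(lines[rec], 47, 54)))
    badc <- which(is.na(xs) | is.na(ys) | is.na(zs))
    if (length(badc)) bad <- which(rec)[badc]
  }
  if (length(bad))
    stop("malformed ATOM/HETATM record at line ", bad[1], " of ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  a <- pdb$atom
  altloc <- ifelse(is.na(a$alt) | a$alt == "", " ", a$alt)
  keep <- altloc %in% c(" ", "A")
  if (any(!keep))
    warning("dropped ", sum(!keep), " alternate-conformer atom(s) (altloc ",
            paste(sort(unique(altloc[!keep])), collapse = ","),
            "); only ' '/'A' kept")
  a <- a[keep, , drop = FALSE]
  altloc <- altloc[keep]
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    altloc = altloc,
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain) | a$chain == "", " ", a$chain),
    resseq = as.integer(a$resno),
    icode = ifelse(is.na(a$insert) | a$insert == "", " ", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    bfactor = ifelse(is.na(a$b), 0, a$b),
    element = .normElement(a$elesy, trimws(a$elety)),
    segid = ifelse(is.na(a$segid) | a$segid == "", "", a$segid),
    stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  methods::new("PDBStructure", atoms = atoms, crystal = .scanCryst1(lines))
}

#' Write a structure (or cluster) to a PDB file
#'
#' Emits standard 80-column ATOM/HETATM records; cluster cap atoms carry the
#' segment id "CAP" so they can be distinguished on inspection.
#'
#' @param x A [PDBStructure-class] or [QMCluster-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  a <- atoms(x)
  ions <- c("HOH", "WAT", "ZN", "MG", "CA", "NA", "K", "CL", "FE", "MN",
            "CU", "NI", "CO")
  type <- ifelse(a$resname %in% ions, "HETATM", "ATOM")
  bio3d::write.pdb(file = path,
                   type = type,
                   xyz = as.numeric(t(.coordsOf(a))),
                   resno = a$resseq, resid = a$resname,
                   eleno = a$serial, elety = a$name,
                   chain = ifelse(a$chain == " ", "", a$chain),
                   insert = ifelse(a$icode == " ", "", a$icode),
                   alt = ifelse(a$altloc == " ", "", a$altloc),
                   o = a$occupancy, b = a$bfactor,
                   segid = a$segid, elesy = toupper(a$element))
  invisible(path)
}

.HIS_RING <- c("CB", "CG", "ND1", "CD2", "CE1", "NE2")
.HIS_NAMES <- c("HIS", "HID", "HIE", "HIP")

#' Locate histidine residues in a structure
#'
#' Returns one [HisSite-class] per histidine having all six side-chain heavy
#' atoms (CB, CG, ND1, CD2, CE1, NE2). Incomplete histidines are reported in
#' the `"rejected"` attribute of the result (a data.frame with the missing
#' atom names), never silently dropped.
#'
#' @param s A [PDBStructure-class].
#' @return List of [HisSite-class] objects with attribute `rejected`.
#' @export
findHistidines <- function(s) {
  a <- atoms(s)
  idx <- which(a$resname %in% .HIS_NAMES)
  sites <- list()
  rejected <- data.frame(chain = character(), resseq = integer(),
                         icode = character(), missing = character(),
                         stringsAsFactors = FALSE)
  if (length(idx)) {
    key <- paste(a$chain[idx], a$resseq[idx], a$icode[idx], sep = "|")
    for (k in unique(key)) {
      rows <- idx[key == k]
      map <- structure(rows, names = a$name[rows])
      miss <- setdiff(.HIS_RING, names(map))
      if (length(miss)) {
        rejected <- rbind(rejected, data.frame(
          chain = a$chain[rows[1]], resseq = a$resseq[rows[1]],
          icode = a$icode[rows[1]], missing = paste(miss, collapse = ","),
          stringsAsFactors = FALSE))
      } else {
        sites[[length(sites) + 1L]] <- methods::new(
          "HisSite", chain = a$chain[rows[1]],
          resseq = a$resseq[rows[1]], icode = a$icode[rows[1]],
          atomIndices = map)
      }
    }
  }
  attr(sites, "rejected") <- rejected
  sites
}

#' Select one histidine site by residue identity
#'
#' @param s A [PDBStructure-class].
#' @param chain Chain id.
#' @param resseq Residue number.
#' @param icode Insertion code (default blank).
#' @return A [HisSite-class].
#' @export
hisSite <- function(s, chain, resseq, icode = " ") {
  sites <- findHistidines(s)
  for (st in sites)
    if (st@chain == chain && st@resseq == resseq && st@icode == icode)
      return(st)
  stop("no complete histidine at ", chain, ":", resseq,
       if (icode != " ") paste0(":", icode) else "")
}

## residue key helper used across modules
.resKey <- function(a) paste(a$chain, a$resseq, a$icode, sep = "|")
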