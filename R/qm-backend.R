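## Energy/minimization backend contract: job construction, the MOPAC
## PM6-D3H4/COSMO adapter (input writer, output parser, subprocess driver)
## and dispatch to the surrogate when no QM engine is installed. The QM
## engine itself is always external; it is never re-implemented here.

.SUPPORTED_METHODS <- c("PM6-D3H4", "PM6", "PM7")

#' Construct a minimization job
#'
#' The total charge is the cluster net charge (computed for the doubly
#' protonated reference state) minus the configuration's proton deficiency.
#'
#' @param configuration A [HisConfiguration-class].
#' @param cluster The parent [QMCluster-class].
#' @param method QM method tag (default "PM6-D3H4").
#' @param solventEps Implicit-solvent relative permittivity (default 78.4).
#' @param maxCycles Cycle limit (default 200).
#' @param backend "surrogate" or "mopac".
#' @return A [QMJob-class].
#' @export
qmJob <- function(configuration, cluster, method = "PM6-D3H4",
                  solventEps = 78.4, maxCycles = 200L,
                  backend = c("surrogate", "mopac")) {
  backend <- match.arg(backend)
  charge <- cluster@netCharge - (2L - configuration@nRingProtons)
  methods::new("QMJob", configuration = configuration, cluster = cluster,
               method = method, solventEps = solventEps,
               charge = as.integer(charge), maxCycles = as.integer(maxCycles),
               backend = backend)
}

#' Write a MOPAC input deck for a job
#'
#' Keyword line carries the method token, `EPS=` (COSMO permittivity) and
#' `CHARGE=`; the Cartesian block uses per-coordinate optimization flags
#' (1 = free, 0 = frozen).
#'
#' @param job A [QMJob-class].
#' @return Input text as a single string.
#' @export
writeMopacInput <- function(job) {
  if (!job@method %in% .SUPPORTED_METHODS)
    stop("unsupported QM method tag: ", job@method)
  cfg <- job@configuration
  a <- cfg@atoms
  flag <- ifelse(cfg@frozen, 0L, 1L)
  kw <- sprintf("%s EPS=%g CHARGE=%d GEO-OK", job@method, job@solventEps,
                job@charge)
  lines <- c(kw,
             sprintf("qmflip cluster: %s", cfg@label),
             "",
             sprintf(" %-2s %12.5f %d %12.5f %d %12.5f %d",
                     toupper(a$element), a$x, flag, a$y, flag, a$z, flag))
  paste(lines, collapse = "\n")
}

#' Parse a MOPAC output text
#'
#' Extracts the final heat of formation (kcal/mol), the last Cartesian
#' coordinate block and the normal-termination marker.
#'
#' @param text Output text (single string or character vector of lines).
#' @return A [QMResult-class]; abnormal termination yields
#'   `converged = FALSE` with the log attached, a missing heat-of-formation
#'   line is a parse error.
#' @export
parseMopacOutput <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  hofLine <- grep("FINAL HEAT OF FORMATION", lines, value = TRUE)
  if (!length(hofLine))
    stop("parse error: no FINAL HEAT OF FORMATION line in MOPAC output")
  m <- regmatches(hofLine[1],
                  regexpr("=\\s*(-?[0-9]+\\.?[0-9]*)\\s*KCAL/MOL", hofLine[1]))
  energy <- as.numeric(gsub("[^0-9.-]", "", sub("KCAL/MOL", "", m)))
  if (!length(energy) || is.na(energy))
    stop("parse error: malformed heat-of-formation line")
  blk <- grep("CARTESIAN COORDINATES", lines)
  coords <- matrix(numeric(), 0, 3)
  if (length(blk)) {
    start <- blk[length(blk)] + 2L
    rows <- list()
    i <- start
    while (i <= length(lines)) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 5L || is.na(suppressWarnings(as.integer(f[1])))) break
      rows[[length(rows) + 1L]] <- as.numeric(f[3:5])
      i <- i + 1L
    }
    if (length(rows)) coords <- do.call(rbind, rows)
  }
  converged <- any(grepl("== MOPAC DONE ==|SCF FIELD WAS ACHIEVED", lines))
  methods::new("QMResult", finalEnergy = energy, finalCoords = coords,
               converged = converged, nCycles = NA_integer_,
               trace = energy, log = paste(lines, collapse = "\n"))
}

#' Is a MOPAC executable available?
#'
#' @param exec Executable name or path (default: `mopac` on the PATH).
#' @return TRUE/FALSE.
#' @export
mopacAvailable <- function(exec = Sys.getenv("QMFLIP_MOPAC", "mopac")) {
  nzchar(Sys.which(exec))
}

.runMopac <- function(job, exec = Sys.getenv("QMFLIP_MOPAC", "mopac")) {
  dir <- tempfile("mopac")
  dir.create(dir)
  inp <- file.path(dir, "job.mop")
  writeLines(writeMopacInput(job), inp)
  status <- system2(Sys.which(exec), inp, stdout = TRUE, stderr = TRUE)
  outFile <- file.path(dir, "job.out")
  if (!file.exists(outFile))
    stop("MOPAC produced no output file; log:\n",
         paste(status, collapse = "\n"))
  res <- parseMopacOutput(readLines(outFile, warn = FALSE))
  ## frozen atoms are restored bit-for-bit from the input: MOPAC echoes
  ## them at format precision only
  cfg <- job@configuration
  cc <- res@finalCoords
  if (nrow(cc) == nrow(cfg@atoms)) cc[cfg@frozen, ] <- .coordsOf(cfg@atoms)[cfg@frozen, ]
  methods::initialize(res, finalCoords = cc)
}

#' Minimize a job with its configured backend
#'
#' Dispatches to [surrogateMinimize()] or the MOPAC adapter. When the job
#' requests MOPAC but no executable is found, the surrogate is used and a
#' loud warning is emitted, so the pipeline always runs.
#'
#' @param job A [QMJob-class].
#' @param ... Passed to the backend.
#' @return A [QMResult-class]. Non-convergence is reported in the result,
#'   not raised as an error.
#' @export
minimizeJob <- function(job, ...) {
  if (job@backend == "mopac") {
    if (mopacAvailable()) return(.runMopac(job))
    warning("MOPAC executable not found; falling back to the surrogate ",
            "energy backend")
  }
  surrogateMinimize(job, ...)
}
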