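## Orchestration: run the six configurations, apply the proton-corrected
## energy comparison and the significance threshold, assemble the report.

.CANONICAL <- c("HD1^HE2", "HD1", "HE2", "HD1^HE2 flipped", "HD1 flipped",
                "HE2 flipped")

#' Rank protonation states from comparable energies
#'
#' Given per-configuration proton-corrected energies, computes delta-E
#' against the minimum, the winning configuration (ties break by canonical
#' state order: HD1^HE2, HD1, HE2, then the flipped states) and the
#' ambiguity set — every non-winning configuration within the significance
#' threshold of the minimum.
#'
#' @param labels Configuration labels.
#' @param energies Comparable energies, kcal/mol (NA for failed runs).
#' @param threshold Significance threshold, kcal/mol.
#' @param states Optional state codes parallel to `labels` (for canonical
#'   tie-breaking); derived from labels when omitted.
#' @param flipped Optional logical parallel to `labels`.
#' @return List: deltaE (numeric, NA where energy was NA), winner (index),
#'   call, flipped, ambiguousWith (labels).
#' @export
rankConfigurations <- function(labels, energies, threshold,
                               states = NULL, flipped = NULL) {
  stopifnot(length(labels) == length(energies))
  if (is.null(states))
    states <- ifelse(grepl("HD1, HE2", labels), "HD1^HE2",
                     ifelse(grepl("HD1", labels), "HD1", "HE2"))
  if (is.null(flipped)) flipped <- grepl("flipped", labels)
  ok <- !is.na(energies)
  if (!any(ok)) stop("no converged configuration to rank")
  eMin <- min(energies[ok])
  deltaE <- energies - eMin
  cand <- which(ok & deltaE == 0)
  canon <- match(paste0(states, ifelse(flipped, " flipped", "")), .CANONICAL)
  winner <- cand[order(canon[cand])][1]
  amb <- which(ok & deltaE < threshold)
  amb <- setdiff(amb, winner)
  list(deltaE = deltaE, winner = winner, call = states[winner],
       flipped = flipped[winner],
       ambiguousWith = labels[amb])
}

.originalState <- function(s, site) {
  a <- atoms(s)
  nm <- a$name[site@atomIndices]
  hd1 <- "HD1" %in% nm
  he2 <- "HE2" %in% nm
  if (hd1 && he2) "HD1^HE2" else if (hd1) "HD1" else if (he2) "HE2"
  else "unknown"
}

#' Run the quantum-mechanical flipping procedure on one histidine
#'
#' Builds the cluster once (selection, capping, freeze flags), enumerates
#' the six protonation/flip configurations, minimizes each in the frozen
#' environment, corrects energies for proton count against the doubly
#' protonated reference, and ranks the states with the calibrated
#' significance threshold plus hydrogen-bond, RMSD and rotamer metrics.
#'
#' @param s A [PDBStructure-class].
#' @param site A [HisSite-class] (see [findHistidines()], [hisSite()]).
#' @param buffer Buffer distance, Angstrom (default 3.5).
#' @param pH pH of the proton reference (default 7.4).
#' @param backend "surrogate" or "mopac".
#' @param restrain Keep the planar torsion restraint on (default TRUE).
#' @param restraintWeight kcal mol^-1 rad^-2 (default 50).
#' @param criteria Hydrogen-bond criteria, [hbondCriteria()].
#' @param fit Calibration fit used for the proton reference and threshold;
#'   defaults to the bundled-table fit at quoted precision, which reproduces
#'   the published constants (G(H+) = -94.51 kcal/mol, threshold 4.81).
#' @param maxCycles Minimization cycle limit per configuration.
#' @return A [DecisionReport-class]. Non-converged configurations are
#'   reported and excluded from the minimum; if all six fail an error is
#'   raised.
#' @export
runQMF <- function(s, site, buffer = 3.5, pH = 7.4,
                   backend = c("surrogate", "mopac"), restrain = TRUE,
                   restraintWeight = 50, criteria = hbondCriteria(),
                   fit = printedPrecision(fitPkaModel()),
                   maxCycles = 200L) {
  backend <- match.arg(backend)
  cluster <- selectCluster(s, site, buffer)
  cluster <- capCluster(cluster, s)
  cluster <- assignFreezeFlags(cluster)
  configs <- enumerateConfigurations(cluster,
                                     restraintWeight = restraintWeight,
                                     restrain = restrain)
  ref <- protonFreeEnergy(fit, pH)
  threshold <- energyThreshold(fit)

  rows <- NULL
  for (cfg in configs) {
    job <- qmJob(cfg, cluster, backend = backend, maxCycles = maxCycles)
    res <- minimizeJob(job)
    eCorr <- comparableEnergy(res@finalEnergy, 2L - cfg@nRingProtons, ref)
    ## RMSD is measured against this configuration's own starting geometry
    ## (for flipped states: the post-swap coordinates the minimization
    ## starts from), over the histidine heavy atoms
    before <- atoms(cfg)[cfg@selection & atoms(cfg)$element != "H", ,
                         drop = FALSE]
    met <- scoreConfiguration(before, cfg, res@finalCoords, criteria,
                              res@converged)
    rows <- rbind(rows, data.frame(
      label = cfg@label, state = cfg@state, flipped = cfg@flipped,
      energy = eCorr, nHBonds = met$nHBonds, rmsd = met$rmsdStart,
      rotamer = met$rotamer, converged = res@converged,
      rawEnergy = res@finalEnergy, stringsAsFactors = FALSE))
  }
  if (!any(rows$converged)) stop("all six configurations failed to converge")
  eRank <- ifelse(rows$converged, rows$energy, NA_real_)
  rk <- rankConfigurations(rows$label, eRank, threshold,
                           states = rows$state, flipped = rows$flipped)
  rows$deltaE <- rk$deltaE
  rows <- rows[, c("label", "state", "flipped", "energy", "deltaE",
                   "nHBonds", "rmsd", "rotamer", "converged", "rawEnergy")]
  chi0 <- .hisChi(atoms(s), unname(site@atomIndices))
  methods::new("DecisionReport",
               site = list(chain = site@chain, resseq = site@resseq,
                           icode = site@icode),
               rows = rows, call = rk$call, flipped = rk$flipped,
               ambiguousWith = rk$ambiguousWith, threshold = threshold,
               pH = pH,
               original = list(label = .originalState(s, site),
                               rotamer = classifyRotamer(chi0["chi1"],
                                                         chi0["chi2"])))
}

#' Format a decision report as a fixed-column text table
#'
#' First line: the original configuration and rotamer; then one line per
#' configuration with energy (1 decimal), delta-E, hydrogen bonds, RMSD
#' (2 decimals) and rotamer. Non-converged rows are flagged with "!"; an
#' ambiguity footnote lists states within the threshold of the winner.
#'
#' @param r A [DecisionReport-class].
#' @return Character vector of lines.
#' @export
formatReport <- function(r) {
  rows <- r@rows
  hdr <- sprintf("%-20s %10s %8s %7s %7s %8s", "Configuration",
                 "Energy", "dE", "H-bonds", "RMSD", "Rotamer")
  out <- c(sprintf("His %s %s%s  (pH %.1f, threshold %.2f kcal/mol)",
                   r@site$resseq, r@site$chain,
                   if (r@site$icode != " ") r@site$icode else "", r@pH,
                   r@threshold),
           hdr,
           sprintf("%-20s %10s %8s %7s %7s %8s",
                   paste0("0 ", r@original$label), "", "", "", "",
                   r@original$rotamer))
  for (i in seq_len(nrow(rows))) {
    flag <- if (rows$converged[i]) " " else "!"
    out <- c(out, sprintf("%-20s %10.1f %8.1f %7d %7.2f %8s%s",
                          paste0(i, " ", rows$label[i]), rows$energy[i],
                          rows$deltaE[i], rows$nHBonds[i], rows$rmsd[i],
                          rows$rotamer[i], flag))
  }
  out <- c(out, sprintf("Call: %s%s", r@call,
                        if (r@flipped) " (flipped)" else ""))
  if (length(r@ambiguousWith))
    out <- c(out, paste("Ambiguous with:",
                        paste(r@ambiguousWith, collapse = "; ")))
  out
}

#' Run every histidine in a structure
#'
#' Processes each complete histidine independently. With `iterate = TRUE`
#' the sites are re-run in increasing energy-gap order, the environment is
#' updated with each call (the chosen configuration's histidine coordinates
#' and ring protons replace the input residue), and sweeps repeat until the
#' assignments are stable or `maxSweeps` is reached; every change is
#' messaged.
#'
#' @param s A [PDBStructure-class].
#' @param sites List of [HisSite-class]; defaults to [findHistidines()].
#' @param iterate Environment-updating mode (default FALSE).
#' @param maxSweeps Sweep limit for `iterate` (default 3).
#' @param ... Passed to [runQMF()].
#' @return Named list of [DecisionReport-class], one per site.
#' @export
runQMFAll <- function(s, sites = findHistidines(s), iterate = FALSE,
                      maxSweeps = 3L, ...) {
  nameOf <- function(st) paste0(st@chain, ":", st@resseq,
                                ifelse(st@icode == " ", "", st@icode))
  reports <- lapply(sites, function(st) runQMF(s, st, ...))
  names(reports) <- vapply(sites, nameOf, "")
  if (!iterate || length(sites) < 2L) return(reports)
  for (sweep in seq_len(maxSweeps)) {
    gaps <- vapply(reports, function(r) {
      e <- r@rows$energy[r@rows$converged]
      if (length(e) > 1L) diff(sort(e))[1] else Inf
    }, 0)
    changed <- FALSE
    for (k in order(gaps)) {
      st <- sites[[k]]
      s <- .applyCall(s, st, reports[[k]])
      newRep <- runQMF(s, hisSite(s, st@chain, st@resseq, st@icode), ...)
      if (newRep@call != reports[[k]]@call ||
          newRep@flipped != reports[[k]]@flipped) {
        message("iterate: ", nameOf(st), " changed to ", newRep@call,
                if (newRep@flipped) " (flipped)" else "")
        changed <- TRUE
      }
      reports[[k]] <- newRep
    }
    if (!changed) break
  }
  reports
}

## write the called configuration's histidine atoms (with ring protons)
## back into the parent structure
.applyCall <- function(s, site, report) {
  a <- atoms(s)
  win <- which(report@rows$label == report@rows$label[report@rows$deltaE == 0][1])
  ## rebuild the winning configuration geometry on the parent residue
  rows <- unname(site@atomIndices)
  keep <- a$name[rows] %in% c("HD1", "HE2")
  if (any(keep)) a <- a[-rows[keep], , drop = FALSE]
  sites2 <- findHistidines(methods::new("PDBStructure", atoms = a,
                                        crystal = s@crystal))
  st2 <- NULL
  for (x in sites2)
    if (x@chain == site@chain && x@resseq == site@resseq &&
        x@icode == site@icode) st2 <- x
  hisRows <- unname(st2@atomIndices)
  if (report@flipped) a <- flipRing(a, hisRows)
  state <- report@call
  for (p in c(if (state %in% c("HD1^HE2", "HD1")) "ND1",
              if (state %in% c("HD1^HE2", "HE2")) "NE2")) {
    hname <- if (p == "ND1") "HD1" else "HE2"
    a <- .buildRingH(a, hisRows, p, hname, .N_H)
    a$segid[nrow(a)] <- ""
  }
  rownames(a) <- NULL
  methods::new("PDBStructure", atoms = a, crystal = s@crystal)
}

#' Serialize a decision report to JSON
#'
#' Mirrors the report field-for-field, including raw backend energies.
#'
#' @param r A [DecisionReport-class].
#' @param path Optional output file.
#' @return JSON string (invisibly when `path` given).
#' @export
reportJSON <- function(r, path = NULL) {
  obj <- list(site = r@site, rows = r@rows, call = r@call,
              flipped = r@flipped, ambiguous_with = r@ambiguousWith,
              threshold = r@threshold, pH = r@pH, original = r@original)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
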