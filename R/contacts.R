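# Run-length helpers shared by residue-, lipid- and bond-level statistics.
# A presence episode of k consecutive frames contributes k frames (k*dt time);
# there are no half-frame end corrections.

# longest uninterrupted TRUE run; gaps of <= gapTolerance FALSE frames may be
# bridged (default 0: any absent frame breaks the run)
.longestRun <- function(x, gapTolerance = 0L) {
  r <- rle(as.logical(x))
  if (!any(r$values)) return(0L)
  if (gapTolerance > 0L) {
    # bridge short FALSE runs that sit between TRUE runs
    v <- r$values
    inner <- which(!v & r$lengths <= gapTolerance)
    inner <- inner[inner > 1 & inner < length(v)]
    v[inner] <- TRUE
    r <- rle(inverse.rle(list(lengths = r$lengths, values = v)))
  }
  max(r$lengths[r$values])
}

.runStats <- function(x, gapTolerance = 0L) {
  c(total = sum(x), longest = .longestRun(x, gapTolerance))
}

#' Lipid-residue contact tensor
#'
#' Computes the boolean presence tensor: lipid molecule m is "in contact" with
#' residue r in frame f when any atom of m (`whole_lipid` mode) or any
#' head-group atom of m (`headgroup_only` mode) lies within `cutoff` of any
#' atom of r under the minimum-image convention.
#'
#' @param traj a [Trajectory-class]
#' @param lipidSpecies species label of the lipids to track
#' @param proteinResidues residue ids to include (default: all protein
#'   residues)
#' @param cutoff contact cutoff, Angstrom (default 6, the customary
#'   coarse-grained contact distance)
#' @param mode `"whole_lipid"` or `"headgroup_only"`
#' @return a [ContactTensor-class]
#' @export
computeContactTensor <- function(traj, lipidSpecies, proteinResidues = NULL,
                                 cutoff = 6, mode = c("whole_lipid",
                                                      "headgroup_only")) {
  mode <- match.arg(mode)
  a <- atoms(traj)
  if (!lipidSpecies %in% a$species)
    stop("unknown species: ", lipidSpecies, " (available: ",
         paste(setdiff(unique(a$species), "PROT"), collapse = ", "), ")")
  lipRole <- if (mode == "headgroup_only") "lipid_head"
             else c("lipid_head", "lipid_tail")
  lipSel <- which(a$species == lipidSpecies & a$role %in% lipRole)
  protSel <- which(a$role == "protein")
  if (!is.null(proteinResidues))
    protSel <- protSel[a$resid[protSel] %in% proteinResidues]
  if (!length(protSel)) stop("no protein residues selected")
  mols <- sort(unique(a$molid[lipSel]))
  resids <- unique(a$resid[protSel])
  pres <- cpp_contact_tensor(
    traj@coords, traj@box,
    lipSel - 1L, match(a$molid[lipSel], mols) - 1L, length(mols),
    protSel - 1L, match(a$resid[protSel], resids) - 1L, length(resids),
    cutoff)
  dimnames(pres) <- list(NULL, as.character(mols), as.character(resids))
  new("ContactTensor", presence = pres, dt = traj@dt, mode = mode,
      cutoff = cutoff)
}

#' Number of lipids near the protein, per frame, with running average
#'
#' Counts, per frame, the distinct lipid molecules of a species with at least
#' one head-group atom within `cutoff` of any protein atom, optionally
#' restricted to one leaflet (assigned per frame), plus a centred moving
#' average over a time window.
#'
#' @param traj a [Trajectory-class]
#' @param lipidSpecies species label
#' @param cutoff contact cutoff, Angstrom
#' @param window running-average window, ns (must be >= dt)
#' @param leaflet `"both"`, `"outer"` or `"inner"`
#' @return data.frame with columns `time`, `count`, `runningAverage` (NA where
#'   the centred window is incomplete)
#' @export
countLipidsNearProtein <- function(traj, lipidSpecies, cutoff = 6,
                                   window = 500,
                                   leaflet = c("both", "outer", "inner")) {
  leaflet <- match.arg(leaflet)
  if (is.na(traj@dt)) stop("trajectory has undefined frame spacing")
  if (window < traj@dt) stop("window must be at least one frame spacing (dt)")
  a <- atoms(traj)
  if (!lipidSpecies %in% a$species) stop("unknown species: ", lipidSpecies)
  headSel <- which(a$species == lipidSpecies & a$role == "lipid_head")
  if (!length(headSel)) stop("no head-group atoms annotated for ", lipidSpecies)
  protSel <- which(a$role == "protein")
  mols <- sort(unique(a$molid[headSel]))
  pres <- cpp_contact_tensor(
    traj@coords, traj@box,
    headSel - 1L, match(a$molid[headSel], mols) - 1L, length(mols),
    protSel - 1L, rep(0L, length(protSel)), 1L, cutoff)
  inContact <- matrix(pres, nrow = dim(pres)[1])  # frames x lipids
  if (leaflet != "both") {
    allHeads <- which(a$role == "lipid_head")
    lab <- assignLeaflets(traj, makeSelection(traj@topology, allHeads,
                                              "headgroups"))
    inContact <- inContact & (lab[, as.character(mols), drop = FALSE] == leaflet)
  }
  count <- rowSums(inContact)
  w <- max(1L, round(window / traj@dt))
  ra <- as.numeric(stats::filter(count, rep(1 / w, w), sides = 2))
  data.frame(time = traj@time, count = count, runningAverage = ra)
}

#' Per-residue interaction statistics from a contact tensor
#'
#' For every residue, the total interaction time (time with at least one lipid
#' in contact, a union over lipids so simultaneous contacts are not double
#' counted) and the longest lifetime (the single longest uninterrupted contact
#' run over any one lipid). A per-lipid *sum* variant of the total is
#' available via `sumOverLipids = TRUE`.
#'
#' @param tensor a [ContactTensor-class]
#' @param gapTolerance frames of absence allowed inside a lifetime run
#'   (default 0: any absent frame breaks the run)
#' @param sumOverLipids count simultaneous contacts multiply in the total?
#' @return data.frame with columns `resid`, `totalTime`, `longestLifetime`
#'   (ns)
#' @export
residueStats <- function(tensor, gapTolerance = 0L, sumOverLipids = FALSE) {
  p <- tensor@presence
  d <- dim(p)
  resids <- dimnames(p)[[3]]
  total <- numeric(d[3])
  longest <- numeric(d[3])
  for (r in seq_len(d[3])) {
    slab <- p[, , r, drop = FALSE]
    dim(slab) <- d[1:2]
    total[r] <- if (sumOverLipids) sum(slab) * tensor@dt
                else sum(rowSums(slab) > 0) * tensor@dt
    m <- 0L
    for (l in seq_len(d[2]))
      m <- max(m, .longestRun(slab[, l], gapTolerance))
    longest[r] <- m * tensor@dt
  }
  data.frame(resid = as.integer(resids), totalTime = unname(total),
             longestLifetime = longest)
}

#' @rdname residueStats
#' @export
residueTotalInteractionTime <- function(tensor, sumOverLipids = FALSE) {
  s <- residueStats(tensor, sumOverLipids = sumOverLipids)
  stats::setNames(s$totalTime, s$resid)
}

#' @rdname residueStats
#' @export
residueLongestLifetime <- function(tensor, gapTolerance = 0L) {
  s <- residueStats(tensor, gapTolerance = gapTolerance)
  stats::setNames(s$longestLifetime, s$resid)
}

#' Average per-residue statistics across symmetric subunits
#'
#' Positional average: value at position i is the arithmetic mean over
#' subunits of the per-subunit value at position i (positions defined by the
#' order of each subunit's residue list in `subunitMap`). Results are reported
#' against the first subunit's residue numbering.
#'
#' @param stats data.frame from [residueStats()] (columns `resid` plus any
#'   numeric statistics)
#' @param subunitMap named list, subunit -> ordered residue ids (all equal
#'   length)
#' @return data.frame with the first subunit's `resid` and averaged statistics
#' @export
symmetryAverage <- function(stats, subunitMap) {
  n <- lengths(subunitMap)
  if (length(unique(n)) != 1)
    stop("subunits have unequal residue counts; cannot symmetry-average")
  cols <- setdiff(names(stats), "resid")
  pos <- lapply(subunitMap, function(r) match(r, stats$resid))
  if (any(is.na(unlist(pos))))
    stop("subunitMap refers to residues absent from the statistics table")
  out <- data.frame(resid = subunitMap[[1]])
  for (cl in cols) {
    m <- vapply(pos, function(ix) stats[[cl]][ix], numeric(n[1]))
    out[[cl]] <- rowMeans(m)
  }
  out
}

#' Tukey-fence classification of high-contact and stable-contact residues
#'
#' For each statistic independently, residues whose value lies strictly above
#' Q3 + 1.5 IQR over all residues are flagged: `highContact` from the total
#' interaction time and `stableContact` from the longest lifetime. Ties at
#' the fence are excluded (strict inequality). The quantile convention
#' defaults to linear interpolation between order statistics (R type 7) and is
#' recorded in the output.
#'
#' @param stats data.frame with columns `resid`, `totalTime`,
#'   `longestLifetime` (raw or symmetry-averaged)
#' @param quantileType R quantile `type`
#' @return list with `highContact` and `stableContact` residue-id vectors and
#'   a `fences` data.frame (statistic, q3, iqr, fence, quantileType)
#' @export
classifyContactResidues <- function(stats, quantileType = 7L) {
  if (nrow(stats) < 4)
    stop("at least 4 residues are required for quartile-based classification")
  one <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), type = quantileType, names = FALSE)
    iqr <- q[2] - q[1]
    c(q3 = q[2], iqr = iqr, fence = q[2] + 1.5 * iqr)
  }
  ft <- one(stats$totalTime)
  fl <- one(stats$longestLifetime)
  list(
    highContact = stats$resid[stats$totalTime > ft["fence"]],
    stableContact = stats$resid[stats$longestLifetime > fl["fence"]],
    fences = data.frame(
      statistic = c("totalTime", "longestLifetime"),
      q3 = c(ft["q3"], fl["q3"]), iqr = c(ft["iqr"], fl["iqr"]),
      fence = c(ft["fence"], fl["fence"]), quantileType = quantileType,
      row.names = NULL))
}

#' Export per-residue statistics as CSV
#'
#' @param stats data.frame from [residueStats()] or [symmetryAverage()]
#' @param traj the trajectory the statistics came from (for residue names and
#'   subunits)
#' @param path output CSV
#' @param averaged were the statistics symmetry-averaged?
#' @export
writeResidueStatsCSV <- function(stats, traj, path, averaged = FALSE) {
  a <- atoms(traj)
  i <- match(stats$resid, a$resid)
  out <- data.frame(residue_index = stats$resid,
                    residue_name = a$resname[i], subunit = a$chain[i],
                    total_time_ns = stats$totalTime,
                    longest_lifetime_ns = stats$longestLifetime,
                    averaged = averaged)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
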