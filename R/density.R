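# wrap coordinates into [0, L) per axis; accepts an n x 3 (x 1) slice
.wrapCoords <- function(xyz, box) {
  dim(xyz) <- c(length(xyz) / 3, 3)
  for (d in 1:3) xyz[, d] <- xyz[, d] - box[d] * floor(xyz[, d] / box[d])
  xyz
}

#' 3-D voxel occupancy grid
#'
#' Voxel occupancy is the fraction of frames in which at least one selected
#' atom falls inside the voxel (binary per frame per voxel, so an occupancy of
#' 0.03 means "present in 3% of all frames"). A count-weighted density mode
#' (`weighted = TRUE`) accumulates every atom-frame hit instead. Grids are
#' axis-aligned with the origin snapped to the box corner; voxel membership
#' uses half-open intervals [lo, hi).
#'
#' @param traj a [Trajectory-class]
#' @param selection a `Selection` of atoms to grid
#' @param resolution voxel edge length, Angstrom (default 1)
#' @param weighted accumulate atom counts instead of binary presence?
#' @return an [OccupancyGrid-class]
#' @export
occupancyGrid <- function(traj, selection, resolution = 1, weighted = FALSE) {
  if (resolution <= 0) stop("resolution must be positive")
  if (!length(selection)) stop("selection is empty")
  box <- traj@box[1, ]
  nd <- pmax(1L, as.integer(ceiling(box / resolution - 1e-9)))
  nf <- nFrames(traj)
  events <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- .wrapCoords(traj@coords[selection, , f, drop = FALSE], box)
    v <- floor(xyz / resolution)
    for (d in 1:3) v[, d] <- pmin(v[, d], nd[d] - 1L)
    lin <- 1L + v[, 1] + nd[1] * (v[, 2] + nd[2] * v[, 3])
    events[[f]] <- if (weighted) lin else unique(lin)
  }
  counts <- tabulate(unlist(events), nbins = prod(nd))
  dim(counts) <- nd
  new("OccupancyGrid", origin = c(0, 0, 0), spacing = resolution,
      counts = counts, occupancy = counts / nf, nFrames = as.integer(nf),
      weighted = weighted)
}

#' Threshold contour mask of an occupancy grid
#'
#' TRUE where voxel occupancy >= threshold; masks at higher thresholds are
#' nested inside masks at lower thresholds.
#'
#' @param grid an [OccupancyGrid-class]
#' @param threshold occupancy fraction in (0, 1)
#' @return logical array with the grid's dimensions
#' @export
thresholdContour <- function(grid, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  grid@occupancy >= threshold
}

#' Layered 2-D occupancy maps along the bilayer normal
#'
#' For each z layer, an x-y grid of occupancy fractions (binary per frame per
#' cell, as in [occupancyGrid()]) computed from the selected atoms whose z
#' falls in the layer [lo, hi). Summing per-layer counts over all layers
#' reproduces the counts of the full 3-D grid partitioned at the same layer
#' edges.
#'
#' @param traj a [Trajectory-class]
#' @param selection a `Selection` (typically lipid head groups)
#' @param zEdges increasing vector of layer edges, Angstrom (within the box)
#' @param resolution lateral cell size, Angstrom
#' @return list with `zEdges`, `counts` (list of x-y integer matrices),
#'   `occupancy` (counts / nFrames), `nFrames`, `resolution`
#' @export
layeredOccupancyMaps <- function(traj, selection, zEdges, resolution = 1) {
  if (length(zEdges) < 2) stop("zEdges must define at least one layer")
  if (any(diff(zEdges) <= 0)) stop("zEdges must be strictly increasing")
  box <- traj@box[1, ]
  if (min(zEdges) < 0 || max(zEdges) > box[3] + 1e-9)
    stop("z layers must lie within the box")
  nd <- pmax(1L, as.integer(ceiling(box[1:2] / resolution - 1e-9)))
  nl <- length(zEdges) - 1
  nf <- nFrames(traj)
  counts <- lapply(seq_len(nl), function(i) matrix(0L, nd[1], nd[2]))
  for (f in seq_len(nf)) {
    xyz <- .wrapCoords(traj@coords[selection, , f, drop = FALSE], box)
    lay <- findInterval(xyz[, 3], zEdges, rightmost.closed = FALSE)
    ok <- lay >= 1 & lay <= nl
    if (!any(ok)) next
    v <- floor(xyz[ok, 1:2, drop = FALSE] / resolution)
    v[, 1] <- pmin(v[, 1], nd[1] - 1L); v[, 2] <- pmin(v[, 2], nd[2] - 1L)
    key <- paste(lay[ok], v[, 1], v[, 2])
    first <- !duplicated(key)
    li <- lay[ok][first]
    cells <- 1L + v[first, 1, drop = FALSE] + nd[1] * v[first, 2, drop = FALSE]
    for (k in seq_along(li)) counts[[li[k]]][cells[k]] <-
        counts[[li[k]]][cells[k]] + 1L
  }
  list(zEdges = zEdges, counts = counts,
       occupancy = lapply(counts, function(m) m / nf),
       nFrames = nf, resolution = resolution)
}

#' Slab contact profile along the bilayer normal
#'
#' Counts (frame, head-group atom) contact events -- a head-group atom within
#' `shellCutoff` of any atom of the reference residues -- binned by the head
#' atom's z coordinate in slabs of `slab` Angstrom, separately for consecutive
#' time intervals. The per-interval profile totals equal the unbinned event
#' counts.
#'
#' @param traj a [Trajectory-class]
#' @param selection head-group `Selection` for one species
#' @param referenceResidues residue ids of the reference site
#' @param shellCutoff contact-shell radius, Angstrom (default 3)
#' @param slab slab thickness, Angstrom (default 0.5)
#' @param intervalNs interval length in ns (default: one interval spanning the
#'   whole trajectory)
#' @param label species/profile label recorded in the output
#' @return object of class `SlabProfile`: list with `edges`, `counts` (bins x
#'   intervals matrix), `intervals` (labels), `shellCutoff`, `slab`, `label`
#' @export
slabContactProfile <- function(traj, selection, referenceResidues,
                               shellCutoff = 3, slab = 0.5, intervalNs = NULL,
                               label = attr(selection, "label")) {
  if (shellCutoff <= 0) stop("shellCutoff must be positive")
  if (slab <= 0) stop("slab must be positive")
  a <- atoms(traj)
  ref <- which(a$role == "protein" & a$resid %in% referenceResidues)
  if (!length(ref)) stop("reference residues not found")
  box <- traj@box[1, ]
  nf <- nFrames(traj)
  pres <- cpp_contact_tensor(traj@coords, traj@box,
                             as.integer(selection) - 1L,
                             seq_along(selection) - 1L, length(selection),
                             ref - 1L, rep(0L, length(ref)), 1L, shellCutoff)
  hit <- matrix(pres, nrow = nf)  # frames x head atoms
  z <- traj@coords[selection, 3, , drop = FALSE]
  dim(z) <- c(length(selection), nf)
  z <- z - box[3] * floor(z / box[3])
  edges <- seq(0, box[3] + slab - 1e-9, by = slab)
  nbins <- length(edges) - 1
  if (is.null(intervalNs) || is.na(traj@dt)) {
    starts <- 1L; ends <- nf
  } else {
    per <- max(1L, round(intervalNs / traj@dt))
    starts <- seq(1L, nf, by = per)
    ends <- pmin(starts + per - 1L, nf)
  }
  counts <- matrix(0L, nbins, length(starts))
  for (k in seq_along(starts)) {
    fr <- starts[k]:ends[k]
    sub <- hit[fr, , drop = FALSE]
    if (!any(sub)) next
    zz <- t(z)[fr, , drop = FALSE][sub]
    bin <- pmin(findInterval(zz, edges), nbins)
    counts[, k] <- tabulate(bin, nbins = nbins)
  }
  structure(list(edges = edges, counts = counts,
                 intervals = sprintf("[%g,%g] ns",
                                     traj@time[starts], traj@time[ends]),
                 shellCutoff = shellCutoff, slab = slab, label = label),
            class = "SlabProfile")
}

#' Per-slab fold enrichment between two species profiles
#'
#' Ratio of per-bin contact counts A/B for identically binned profiles.
#' Bins with B = 0 and A > 0 are flagged `numerator_only` (no ratio);
#' bins with A = B = 0 are flagged `empty`.
#'
#' @param profileA,profileB `SlabProfile` objects on identical bins and
#'   intervals
#' @return data.frame with columns `zLo`, `zHi`, `interval`, `a`, `b`,
#'   `ratio`, `flag`
#' @export
foldEnrichment <- function(profileA, profileB) {
  if (!isTRUE(all.equal(profileA$edges, profileB$edges)) ||
      ncol(profileA$counts) != ncol(profileB$counts))
    stop("profiles must share binning and intervals")
  nb <- nrow(profileA$counts)
  out <- do.call(rbind, lapply(seq_len(ncol(profileA$counts)), function(k) {
    a <- profileA$counts[, k]; b <- profileB$counts[, k]
    data.frame(zLo = profileA$edges[-(nb + 1)], zHi = profileA$edges[-1],
               interval = profileA$intervals[k], a = a, b = b,
               ratio = ifelse(b > 0, a / b, NA_real_),
               flag = ifelse(b > 0, "ok",
                             ifelse(a > 0, "numerator_only", "empty")))
  }))
  rownames(out) <- NULL
  out
}

#' Lateral radial distribution function around the protein axis
#'
#' g(r) of selected atoms as a function of lateral (x-y) minimum-image
#' distance from the protein's centre-of-geometry axis, normalised by the
#' uniform-density expectation over annular areas within the periodic box, so
#' g(r) -> 1 for a uniform ideal gas. A 3-D minimum-distance-to-protein-
#' surface variant is available as `mode = "surface"` (normalised by spherical
#' shell volume); the mode is recorded in the output.
#'
#' @param traj a [Trajectory-class]
#' @param selection `Selection` of atoms (e.g. lipid head groups)
#' @param rBreaks increasing bin edges, Angstrom; edges beyond half the
#'   smaller lateral box length are truncated with a warning
#' @param mode `"axis"` (lateral, default) or `"surface"`
#' @param referenceSel protein reference `Selection` (default: all protein
#'   atoms)
#' @return data.frame with columns `r` (bin centres), `g`; attributes `mode`,
#'   `nSamples`
#' @export
lateralRDF <- function(traj, selection, rBreaks = seq(0, 50, by = 1),
                       mode = c("axis", "surface"), referenceSel = NULL) {
  mode <- match.arg(mode)
  a <- atoms(traj)
  if (is.null(referenceSel))
    referenceSel <- makeSelection(traj@topology, which(a$role == "protein"),
                                  "protein")
  if (!length(referenceSel)) stop("reference selection is empty")
  box <- traj@box[1, ]
  rmax <- min(box[1], box[2]) / 2
  if (max(rBreaks) > rmax + 1e-9) {
    warning("r bins beyond half the lateral box length truncated at ",
            signif(rmax, 4), " A")
    rBreaks <- c(rBreaks[rBreaks < rmax], rmax)
  }
  nf <- nFrames(traj)
  nbins <- length(rBreaks) - 1
  counts <- numeric(nbins)
  for (f in seq_len(nf)) {
    if (mode == "axis") {
      ctr <- colMeans(traj@coords[referenceSel, 1:2, f, drop = FALSE])
      d <- traj@coords[selection, 1:2, f, drop = FALSE]
      dim(d) <- c(length(selection), 2)
      d <- sweep(d, 2, ctr)
      d <- .miDisp(d, box[1:2])
      r <- sqrt(rowSums(d^2))
    } else {
      pairs <- expand.grid(i = as.integer(selection) - 1L,
                           j = as.integer(referenceSel) - 1L)
      dm <- cpp_dist_pairs(traj@coords[, , f, drop = FALSE],
                           traj@box[f, , drop = FALSE], pairs$i, pairs$j)
      dim(dm) <- c(length(selection), length(referenceSel))
      r <- apply(dm, 1, min)
    }
    bin <- findInterval(r, rBreaks, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nbins
    counts <- counts + tabulate(bin[ok], nbins = nbins)
  }
  nsamp <- length(selection) * nf
  if (mode == "axis") {
    areas <- pi * diff(rBreaks^2)
    expected <- nsamp * areas / (box[1] * box[2])
  } else {
    vols <- 4 / 3 * pi * diff(rBreaks^3)
    expected <- nsamp * vols / prod(box)
  }
  out <- data.frame(r = (rBreaks[-1] + rBreaks[-(nbins + 1)]) / 2,
                    g = counts / expected)
  attr(out, "mode") <- mode
  attr(out, "nSamples") <- nsamp
  out
}

#' Write an occupancy grid as an OpenDX scalar field
#'
#' @param grid an [OccupancyGrid-class]
#' @param path output .dx file
#' @export
writeOpenDX <- function(grid, path) {
  nd <- dim(grid@occupancy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", nd[1], nd[2], nd[3]),
    sprintf("origin %g %g %g", grid@origin[1] + grid@spacing / 2,
            grid@origin[2] + grid@spacing / 2, grid@origin[3] + grid@spacing / 2),
    sprintf("delta %g 0 0", grid@spacing),
    sprintf("delta 0 %g 0", grid@spacing),
    sprintf("delta 0 0 %g", grid@spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            nd[1], nd[2], nd[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(nd))), con)
  # OpenDX stores with the z index varying fastest
  vals <- as.vector(aperm(grid@occupancy, c(3, 2, 1)))
  idx <- seq(1, length(vals), by = 3)
  writeLines(vapply(idx, function(i)
    paste(signif(vals[i:min(i + 2, length(vals))], 6), collapse = " "),
    character(1)), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
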