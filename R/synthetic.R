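#' Specification of a planted binding site
#'
#' A site places one anchor residue per subunit at a fixed position along the
#' subunit; lipids of each species bind within `captureRadius` of an anchor
#' with per-frame probability `pOn[species]` and unbind with `kOff[species]`
#' (discrete-time Markov kinetics, geometric dwell times with mean
#' `1/kOff` frames).
#'
#' @param siteId site label
#' @param anchorPosition 1-based residue position within each subunit
#' @param captureRadius lateral capture radius, Angstrom
#' @param pOn named per-species binding probability per frame, each between 0
#'   and 1 (0 disables binding, giving a pure-diffusion bilayer)
#' @param kOff named per-species unbinding probability per frame, each between
#'   0 and 1 (0 pins a bound lipid permanently)
#' @return a list of class `SiteSpec`
#' @export
syntheticSiteSpec <- function(siteId, anchorPosition, captureRadius = 5,
                              pOn = c(LIN = 0.15, STE = 0.05),
                              kOff = c(LIN = 0.05, STE = 0.05)) {
  if (any(pOn < 0 | pOn > 1)) stop("pOn must lie in [0, 1]")
  if (any(kOff < 0 | kOff > 1)) stop("kOff must lie in [0, 1]")
  if (captureRadius <= 0) stop("captureRadius must be positive")
  structure(list(siteId = siteId, anchorPosition = as.integer(anchorPosition),
                 captureRadius = captureRadius, pOn = pOn, kOff = kOff),
            class = "SiteSpec")
}

#' Specification of the synthetic channel-bilayer system
#'
#' Defines a four-fold symmetric toy "channel" (one bead per pseudo-residue,
#' arranged on a ring at the membrane midplane inside a periodic box) plus a
#' population of three-bead lipids (charged head + two tail beads) that
#' diffuse laterally at leaflet height and bind planted sites with Markov
#' on/off kinetics. Free lipids ride at `leafletOffset` above/below the
#' midplane, far outside the contact cutoff of the midplane ring, so protein
#' contacts arise only through planted binding events and the planted anchors
#' are the exact ground truth for site-calling.
#'
#' Default kinetics give the two species a 3-fold affinity (pOn) ratio at
#' equal off-rate, mean dwell `1/kOff = 20` frames, and a lateral geometry
#' (7 A residue spacing, 2.5 A pin offset, 1.5 A pin height) under which a
#' bound lipid head sits 2.9 A from its anchor bead -- inside the 3 A contact
#' shell and the 4 A direct-contact cutoff -- while contacting no other
#' residue at the 6 A contact cutoff.
#'
#' @param nSubunits number of subunits (default 4)
#' @param residuesPerSubunit pseudo-residues per subunit
#' @param residueSpacing arc spacing between consecutive residue beads, A
#' @param box box lengths (Lx, Ly, Lz), A
#' @param nLipidsPerSpecies named counts per species
#' @param outerPerSpecies named counts of outer-leaflet lipids per species
#'   (only outer-leaflet lipids can reach the planted sites)
#' @param leafletOffset |z| of free lipid head groups above/below midplane, A
#' @param pinOffset lateral distance of a bound head from its anchor, A
#' @param pinZ height of a bound head above the midplane, A
#' @param diffusionSigma lateral random-walk step s.d. per frame, A
#' @param nFrames number of frames
#' @param dt frame spacing, ns
#' @param sites list of [syntheticSiteSpec()] objects
#' @param permanentBinder plant one permanently bound lipid (the first
#'   outer-leaflet lipid of the first species, pinned to the first site's
#'   subunit-A anchor for the whole run)?
#' @param seed integer RNG seed
#' @return a list of class `SyntheticSystemSpec`
#' @export
syntheticSystemSpec <- function(nSubunits = 4L, residuesPerSubunit = 20L,
                                residueSpacing = 7, box = c(200, 200, 60),
                                nLipidsPerSpecies = c(LIN = 12L, STE = 12L),
                                outerPerSpecies = c(LIN = 8L, STE = 8L),
                                leafletOffset = 17, pinOffset = 2.5,
                                pinZ = 1.5,
                                diffusionSigma = 3, nFrames = 20000L, dt = 0.5,
                                sites = list(
                                  syntheticSiteSpec("I", 5L),
                                  syntheticSiteSpec("II", 13L)),
                                permanentBinder = TRUE, seed = 42L) {
  spec <- list(nSubunits = as.integer(nSubunits),
               residuesPerSubunit = as.integer(residuesPerSubunit),
               residueSpacing = residueSpacing, box = box,
               nLipidsPerSpecies = nLipidsPerSpecies,
               outerPerSpecies = outerPerSpecies,
               leafletOffset = leafletOffset, pinOffset = pinOffset,
               pinZ = pinZ, diffusionSigma = diffusionSigma,
               nFrames = as.integer(nFrames), dt = dt, sites = sites,
               permanentBinder = permanentBinder, seed = as.integer(seed))
  if (spec$nSubunits < 1) stop("nSubunits must be >= 1")
  if (any(nLipidsPerSpecies <= 0) || spec$nFrames < 1)
    stop("all counts must be positive")
  if (any(outerPerSpecies > nLipidsPerSpecies))
    stop("outerPerSpecies cannot exceed nLipidsPerSpecies")
  pos <- vapply(sites, `[[`, 1L, "anchorPosition")
  if (any(pos > residuesPerSubunit))
    stop("anchorPosition exceeds residuesPerSubunit")
  if (length(unique(vapply(sites, `[[`, 1, "captureRadius"))) != 1)
    stop("all sites must share one captureRadius")
  class(spec) <- "SyntheticSystemSpec"
  # reject laterally overlapping capture zones (ambiguous site ownership)
  geo <- .toyGeometry(spec)
  if (nrow(geo$anchorXY) > 1) {
    dm <- as.matrix(stats::dist(geo$anchorXY))
    diag(dm) <- Inf
    rad <- geo$anchorCapture
    if (any(dm < outer(rad, rad, "+")))
      stop("capture radii of planted sites overlap; sites would be ambiguous")
  }
  spec
}

# Ring/anchor geometry shared by the generators (internal).
.toyGeometry <- function(spec) {
  nres <- spec$nSubunits * spec$residuesPerSubunit
  radius <- spec$residueSpacing * nres / (2 * pi)
  cx <- spec$box[1] / 2; cy <- spec$box[2] / 2; cz <- spec$box[3] / 2
  ang <- 2 * pi * (seq_len(nres) - 1) / nres
  beadXY <- cbind(cx + radius * cos(ang), cy + radius * sin(ang))
  anchorPos <- integer(0); anchorSite <- character(0); anchorCapture <- numeric(0)
  for (s in spec$sites) {
    gp <- (seq_len(spec$nSubunits) - 1) * spec$residuesPerSubunit +
      s$anchorPosition
    anchorPos <- c(anchorPos, gp)
    anchorSite <- c(anchorSite, rep(s$siteId, spec$nSubunits))
    anchorCapture <- c(anchorCapture, rep(s$captureRadius, spec$nSubunits))
  }
  anchorXY <- beadXY[anchorPos, , drop = FALSE]
  u <- cbind(anchorXY[, 1] - cx, anchorXY[, 2] - cy)
  u <- u / sqrt(rowSums(u^2))
  pinXY <- anchorXY + spec$pinOffset * u
  list(nres = nres, radius = radius, center = c(cx, cy, cz), beadXY = beadXY,
       anchorPos = anchorPos, anchorSite = anchorSite,
       anchorCapture = anchorCapture, anchorXY = anchorXY, pinXY = pinXY)
}

#' Annotation rules matching the synthetic system's naming
#'
#' Protein beads are named `BB` in residues `BB`; lipid head beads `Q0`
#' (charged head), tail beads `T1`/`T2`.
#' @param species lipid species labels
#' @export
toyAnnotationRules <- function(species = c("LIN", "STE")) {
  annotationRules(
    lipids = stats::setNames(lapply(species, function(s)
      list(resnames = s, headAtoms = "Q0")), species),
    proteinResnames = "BB")
}

#' Generate the four-fold symmetric toy channel
#'
#' One bead per pseudo-residue, `nSubunits` equal subunits arranged as
#' contiguous arcs of a ring centred in the box at the membrane midplane, so
#' that subunit k equals subunit 0 rotated by k*(360/nSubunits) degrees about
#' the channel axis.
#'
#' @param spec a [syntheticSystemSpec()]
#' @return list with elements `topology` ([Topology-class]), `coords`
#'   (natoms x 3 reference frame, protein beads only), `box`
#' @export
generateToyChannel <- function(spec) {
  g <- .toyGeometry(spec)
  nres <- g$nres
  chain <- rep(LETTERS[seq_len(spec$nSubunits)], each = spec$residuesPerSubunit)
  a <- data.frame(name = "BB", resid = seq_len(nres), resname = "BB",
                  chain = chain, molid = rep(seq_len(spec$nSubunits),
                                             each = spec$residuesPerSubunit),
                  species = "PROT", role = "protein", elem = "bead",
                  stringsAsFactors = FALSE)
  top <- new("Topology", atoms = a, bonds = matrix(integer(), 0, 2),
             speciesTable = stats::setNames(rep("PROT", spec$nSubunits),
                                            seq_len(spec$nSubunits)),
             subunitMap = split(a$resid, a$chain))
  coords <- cbind(g$beadXY, g$center[3])
  list(topology = top, coords = coords, box = spec$box)
}

#' Simulate the synthetic lipid trajectory with planted binding kinetics
#'
#' Lipids perform lateral periodic random walks at leaflet height; an
#' outer-leaflet lipid within a site's capture radius binds with probability
#' `pOn` per frame and is then held at a fixed pin offset from the anchor; a
#' bound lipid releases with probability `kOff` per frame and is emitted just
#' outside the capture zone. Fully reproducible given `spec$seed`.
#'
#' @param spec a [syntheticSystemSpec()]
#' @return list with elements `trajectory` ([Trajectory-class]) and `truth`
#'   (ground truth: planted site residues, per-frame bound-anchor matrix,
#'   per-species mean dwell `1/kOff` in frames, leaflet labels, the permanent
#'   binder's molecule id, anchor/pin geometry)
#' @export
simulateLipidTrajectory <- function(spec) {
  set.seed(spec$seed)
  g <- .toyGeometry(spec)
  chan <- generateToyChannel(spec)
  nprot <- nrow(chan$coords)
  speciesNames <- names(spec$nLipidsPerSpecies)
  nlip <- sum(spec$nLipidsPerSpecies)
  lipSpecies <- rep(speciesNames, spec$nLipidsPerSpecies)
  leaflet <- unlist(lapply(speciesNames, function(s) {
    n <- spec$nLipidsPerSpecies[[s]]
    rep(c("outer", "inner"), c(spec$outerPerSpecies[[s]],
                               n - spec$outerPerSpecies[[s]]))
  }))
  eligible <- leaflet == "outer"
  nanch <- nrow(g$anchorXY)
  pOn <- matrix(0, nlip, nanch)
  kOff <- matrix(0, nlip, nanch)
  for (l in seq_len(nlip)) {
    siteOf <- match(g$anchorSite, vapply(spec$sites, `[[`, "", "siteId"))
    pOn[l, ] <- vapply(spec$sites[siteOf], function(s)
      s$pOn[[lipSpecies[l]]], 1)
    kOff[l, ] <- vapply(spec$sites[siteOf], function(s)
      s$kOff[[lipSpecies[l]]], 1)
  }
  initBound <- integer(nlip)
  permanentLipid <- NA_integer_
  if (isTRUE(spec$permanentBinder)) {
    pl <- which(eligible)[1]
    initBound[pl] <- 1L
    kOff[pl, ] <- 0
    permanentLipid <- pl
  }
  head0 <- cbind(stats::runif(nlip, 0, spec$box[1]),
                 stats::runif(nlip, 0, spec$box[2]))
  sim <- cpp_simulate_walk(spec$nFrames, head0, spec$box[1:2], eligible,
                           spec$diffusionSigma, g$anchorXY, g$pinXY,
                           g$anchorCapture[1], g$anchorCapture[1] + 1,
                           pOn, kOff, initBound)
  # assemble topology: protein beads then 3 beads per lipid (Q0, T1, T2)
  protA <- chan$topology@atoms
  lipA <- data.frame(
    name = rep(c("Q0", "T1", "T2"), nlip),
    resid = rep(g$nres + seq_len(nlip), each = 3),
    resname = rep(lipSpecies, each = 3),
    chain = "X",
    molid = rep(spec$nSubunits + seq_len(nlip), each = 3),
    species = rep(lipSpecies, each = 3),
    role = rep(c("lipid_head", "lipid_tail", "lipid_tail"), nlip),
    elem = "bead", stringsAsFactors = FALSE)
  a <- rbind(protA, lipA)
  st <- c(chan$topology@speciesTable,
          stats::setNames(lipSpecies, spec$nSubunits + seq_len(nlip)))
  top <- new("Topology", atoms = a, bonds = matrix(integer(), 0, 2),
             speciesTable = st, subunitMap = chan$topology@subunitMap)
  nf <- spec$nFrames
  cz <- g$center[3]
  xyz <- array(0, dim = c(nrow(a), 3, nf))
  xyz[seq_len(nprot), 1, ] <- chan$coords[, 1]
  xyz[seq_len(nprot), 2, ] <- chan$coords[, 2]
  xyz[seq_len(nprot), 3, ] <- chan$coords[, 3]
  zsign <- ifelse(leaflet == "outer", 1, -1)
  for (l in seq_len(nlip)) {
    idx <- nprot + 3 * (l - 1) + 1:3
    bound <- sim$bound[, l] > 0
    zHead <- ifelse(bound, cz + spec$pinZ, cz + zsign[l] * spec$leafletOffset)
    for (k in 1:3) {
      xyz[idx[k], 1, ] <- sim$x[, l]
      xyz[idx[k], 2, ] <- sim$y[, l]
    }
    # tails point toward the midplane (or below the pinned head when bound)
    xyz[idx[1], 3, ] <- zHead
    xyz[idx[2], 3, ] <- zHead + ifelse(bound, -4, -zsign[l] * 4)
    xyz[idx[3], 3, ] <- zHead + ifelse(bound, -8, -zsign[l] * 8)
  }
  traj <- new("Trajectory", topology = top, coords = xyz,
              box = matrix(rep(spec$box, each = nf), nrow = nf),
              time = (seq_len(nf) - 1) * spec$dt, dt = spec$dt)
  siteResidues <- lapply(stats::setNames(spec$sites,
                                         vapply(spec$sites, `[[`, "", "siteId")),
                         function(s) as.integer(
                           (seq_len(spec$nSubunits) - 1) *
                             spec$residuesPerSubunit + s$anchorPosition))
  truth <- list(
    siteResidues = siteResidues,
    anchorResidues = sort(unlist(siteResidues, use.names = FALSE)),
    anchorResidOfIndex = g$anchorPos,
    anchorSite = g$anchorSite,
    anchorXY = g$anchorXY, pinXY = g$pinXY,
    captureRadius = g$anchorCapture[1],
    boundAnchor = sim$bound,
    lipidMolid = spec$nSubunits + seq_len(nlip),
    lipidSpecies = lipSpecies, leaflet = leaflet, eligible = eligible,
    permanentLipid = if (is.na(permanentLipid)) NA_integer_ else
      spec$nSubunits + permanentLipid,
    meanDwellFrames = vapply(spec$sites[[1]]$kOff, function(k) 1 / k, 1),
    pOn = spec$sites[[1]]$pOn, kOff = spec$sites[[1]]$kOff)
  list(trajectory = traj, truth = truth)
}

#' Completed bound-dwell episodes from the simulation ground truth
#'
#' Returns maximal uninterrupted bound runs per (lipid, anchor) that both
#' start and end strictly inside the trajectory (so their lengths are
#' unbiased draws from the geometric dwell distribution). The permanent
#' binder is excluded.
#'
#' @param truth the `truth` element of [simulateLipidTrajectory()]
#' @return data.frame with columns `lipid` (molecule id), `species`, `anchor`
#'   (residue id), `site`, `frames` (dwell length in frames)
#' @export
boundDwells <- function(truth) {
  b <- truth$boundAnchor
  out <- vector("list", ncol(b))
  nf <- nrow(b)
  for (l in seq_len(ncol(b))) {
    if (!is.na(truth$permanentLipid) &&
        truth$lipidMolid[l] == truth$permanentLipid) next
    r <- rle(b[, l])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values > 0 & starts > 1 & ends < nf
    if (!any(keep)) next
    out[[l]] <- data.frame(
      lipid = truth$lipidMolid[l], species = truth$lipidSpecies[l],
      anchor = truth$anchorResidOfIndex[r$values[keep]],
      site = truth$anchorSite[r$values[keep]],
      frames = r$lengths[keep])
  }
  do.call(rbind, out)
}

#' Synthetic conductance-voltage data from the Boltzmann model
#'
#' Forward model `G(V) = Gmin + (Gmax - Gmin) / (1 + exp((V50 - V) * s))`
#' plus additive Gaussian noise.
#'
#' @param voltages voltage grid, mV (nonempty)
#' @param gmin,gmax minimal and maximal conductance
#' @param v50 midpoint voltage, mV
#' @param slope slope factor s, 1/mV
#' @param noiseSd additive Gaussian noise s.d.
#' @param seed optional RNG seed
#' @return data.frame with columns `voltage`, `conductance`
#' @export
generateGVData <- function(voltages, gmin = 0, gmax = 1, v50 = -20,
                           slope = 0.1, noiseSd = 0, seed = NULL) {
  if (!length(voltages)) stop("voltage grid must be nonempty")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  g <- boltzmannModel(voltages, gmin, gmax, v50, slope)
  if (noiseSd > 0) g <- g + stats::rnorm(length(g), 0, noiseSd)
  data.frame(voltage = voltages, conductance = g)
}

#' Synthetic concentration-response data from the Hill model
#'
#' Forward model `dEffect([L]) = dEffectMax / (1 + (L50/[L])^|H|)` plus
#' additive Gaussian noise. `dEffectMax` may be negative (e.g. a
#' hyperpolarizing V50 shift); the magnitude of the effect grows and
#' saturates with concentration.
#'
#' @param conc ligand concentrations, must all be positive
#' @param effectMax maximal effect (sign carries the direction)
#' @param l50 concentration of half-maximal effect
#' @param hill Hill coefficient (its absolute value is used; the sign is a
#'   direction convention recorded by the fitting code)
#' @param noiseSd additive Gaussian noise s.d.
#' @param seed optional RNG seed
#' @return data.frame with columns `conc`, `effect`
#' @export
generateDoseResponse <- function(conc, effectMax = -25, l50 = 15, hill = 1,
                                 noiseSd = 0, seed = NULL) {
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  e <- hillModel(conc, effectMax, l50, hill)
  if (noiseSd > 0) e <- e + stats::rnorm(length(e), 0, noiseSd)
  data.frame(conc = conc, effect = e)
}

#' Synthetic exponential relaxation trace
#'
#' `I(t) = amplitude * exp(-t / tau) + offset` plus additive Gaussian noise.
#'
#' @param times time grid, s
#' @param amplitude,tau,offset exponential parameters (`tau` in s, > 0)
#' @param noiseSd additive Gaussian noise s.d.
#' @param seed optional RNG seed
#' @return data.frame with columns `time`, `current`
#' @export
generateExpTrace <- function(times, amplitude = 1, tau = 0.3, offset = 0,
                             noiseSd = 0, seed = NULL) {
  if (tau <= 0) stop("tau must be positive")
  if (!is.null(seed)) set.seed(seed)
  i <- amplitude * exp(-times / tau) + offset
  if (noiseSd > 0) i <- i + stats::rnorm(length(i), 0, noiseSd)
  data.frame(time = times, current = i)
}
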