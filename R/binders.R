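#' Per-lipid interaction statistics
#'
#' For each lipid molecule, the total time with at least one residue in
#' contact and the longest uninterrupted such run, from a contact tensor.
#'
#' @param tensor a [ContactTensor-class]
#' @param gapTolerance frames of absence allowed inside a lifetime run
#' @return data.frame with columns `molid`, `totalTime`, `longestLifetime` (ns)
#' @export
lipidInteractionStats <- function(tensor, gapTolerance = 0L) {
  p <- tensor@presence
  d <- dim(p)
  mols <- dimnames(p)[[2]]
  total <- numeric(d[2]); longest <- numeric(d[2])
  for (l in seq_len(d[2])) {
    slab <- p[, l, , drop = FALSE]
    dim(slab) <- d[c(1, 3)]
    anyRes <- rowSums(slab) > 0
    total[l] <- sum(anyRes) * tensor@dt
    longest[l] <- .longestRun(anyRes, gapTolerance) * tensor@dt
  }
  data.frame(molid = as.integer(mols), totalTime = total,
             longestLifetime = longest)
}

#' Upper-quartile (UQ) binders
#'
#' Lipids whose total interaction time lies in the upper quartile of all
#' lipids' totals, i.e. total time >= Q3 (inclusive: "in the upper quartile"
#' includes the boundary). The threshold and quantile convention are reported.
#'
#' @param stats data.frame from [lipidInteractionStats()]
#' @param quantileType R quantile `type` (7 = linear interpolation)
#' @return list with `uqBinders` (molecule ids) and `uqThreshold` (ns)
#' @export
identifyUQBinders <- function(stats, quantileType = 7L) {
  if (nrow(stats) < 4)
    stop("at least 4 lipids are required for upper-quartile selection")
  q3 <- stats::quantile(stats$totalTime, 0.75, type = quantileType,
                        names = FALSE)
  list(uqBinders = stats$molid[stats$totalTime >= q3], uqThreshold = q3,
       quantileType = quantileType)
}

#' Constant binders
#'
#' Lipids bound to the protein for the entire trajectory: longest lifetime
#' equal to the full duration (every frame in contact). A tolerance in frames
#' of absence is exposed for sensitivity analysis (default 0: literally every
#' frame).
#'
#' @param stats data.frame from [lipidInteractionStats()]
#' @param duration trajectory duration, ns (frame count x dt)
#' @param dt frame spacing, ns (needed when `maxMissingFrames > 0`)
#' @param maxMissingFrames frames of absence tolerated
#' @return list with `constantBinders` (molecule ids)
#' @export
identifyConstantBinders <- function(stats, duration, dt = NULL,
                                    maxMissingFrames = 0L) {
  slack <- if (maxMissingFrames > 0) {
    if (is.null(dt)) stop("dt is required when maxMissingFrames > 0")
    maxMissingFrames * dt
  } else 0
  list(constantBinders =
         stats$molid[stats$longestLifetime >= duration - slack - 1e-9])
}

#' Per-frame minimum heavy-atom distance between a residue and a lipid
#'
#' Minimum over all atom pairs (hydrogens excluded) under the minimum-image
#' convention, one value per frame.
#'
#' @param traj a [Trajectory-class]
#' @param resid residue id
#' @param molid lipid molecule id
#' @return numeric vector of length `nFrames(traj)`, Angstrom
#' @export
residueLipidMinDistance <- function(traj, resid, molid) {
  a <- atoms(traj)
  ri <- which(a$resid == resid & a$elem != "H")
  li <- which(a$molid == molid & a$elem != "H")
  if (!length(ri)) stop("residue not found (or has only hydrogens): ", resid)
  if (!length(li)) stop("lipid molecule not found: ", molid)
  cpp_min_dist_series(traj@coords, traj@box, ri - 1L, li - 1L)
}

#' Classify residues around a bound lipid as binder / proximal / none
#'
#' A residue is a *binder* when it makes direct contact with the lipid --
#' any heavy-atom pair within the hydrophobic cutoff (4.0 A), or a
#' hydrogen-bond / salt-bridge event -- in at least a fraction `theta` of
#' frames; it is *proximal* when it is within the contact cutoff (6 A) in at
#' least `theta` of frames without qualifying as a binder; otherwise *none*.
#' The persistence threshold is a declared package parameter (default 0.5),
#' always reported in the output.
#'
#' @param traj a [Trajectory-class]
#' @param molid the bound lipid's molecule id (normally a constant binder)
#' @param candidateResidues residue ids to classify
#' @param config an [analysisConfig()]
#' @param chemEvents optional logical matrix `nframes x nresidues` of
#'   hydrogen-bond/salt-bridge events per candidate residue (from
#'   `detectHBonds()`/`detectSaltBridges()`), OR-ed into the direct-contact
#'   criterion
#' @return data.frame with columns `resid`, `directFraction`,
#'   `proximalFraction`, `role`, `theta`
#' @export
classifyBinderResidues <- function(traj, molid, candidateResidues,
                                   config = analysisConfig(),
                                   chemEvents = NULL) {
  a <- atoms(traj)
  li <- which(a$molid == molid & a$elem != "H")
  if (!length(li)) stop("lipid molecule not found: ", molid)
  theta <- config$binderPersistence
  nf <- nFrames(traj)
  out <- data.frame(resid = candidateResidues, directFraction = NA_real_,
                    proximalFraction = NA_real_, role = "none",
                    theta = theta, stringsAsFactors = FALSE)
  for (k in seq_along(candidateResidues)) {
    ri <- which(a$resid == candidateResidues[k] & a$elem != "H")
    d <- cpp_min_dist_series(traj@coords, traj@box, ri - 1L, li - 1L)
    direct <- d <= config$hydrophobicCutoff
    if (!is.null(chemEvents)) direct <- direct | chemEvents[, k]
    near <- d <= config$contactCutoff
    out$directFraction[k] <- mean(direct)
    out$proximalFraction[k] <- mean(near)
    out$role[k] <- if (mean(direct) >= theta) "binder"
                   else if (mean(near) >= theta) "proximal" else "none"
  }
  out
}
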