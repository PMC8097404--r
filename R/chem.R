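#' Distance criteria for chemical interactions
#'
#' Cutoffs for hydrogen bonds (hydrogen-to-acceptor, default 3.5 A),
#' salt bridges (N-O, default 4.0 A) and hydrophobic contacts (C-C, default
#' 4.0 A). The hydrogen-bond criterion is purely distance based by default
#' (no angle term); a conventional donor-acceptor + angle mode can be enabled
#' with `hbondAngle`.
#'
#' @param hbond hydrogen-to-acceptor cutoff, Angstrom
#' @param saltbridge N-O cutoff, Angstrom
#' @param hydrophobic C-C cutoff, Angstrom
#' @param hbondAngle optional minimal donor-H...acceptor angle in degrees;
#'   `NULL` (default) disables the angle term
#' @param covalentCutoff heavy-atom-to-hydrogen distance used to identify a
#'   hydrogen's covalent partner when no bond list is available
#' @return a list of class `BondCriteria`
#' @export
bondCriteria <- function(hbond = 3.5, saltbridge = 4.0, hydrophobic = 4.0,
                         hbondAngle = NULL, covalentCutoff = 1.2) {
  if (any(c(hbond, saltbridge, hydrophobic, covalentCutoff) <= 0))
    stop("all cutoffs must be positive")
  structure(list(hbond = hbond, saltbridge = saltbridge,
                 hydrophobic = hydrophobic, hbondAngle = hbondAngle,
                 covalentCutoff = covalentCutoff), class = "BondCriteria")
}

# per-(pair, frame) boolean presence from a pair list and cutoff
.bondSeries <- function(traj, iIdx, jIdx, cutoff, type) {
  a <- atoms(traj)
  d <- cpp_dist_pairs(traj@coords, traj@box, iIdx - 1L, jIdx - 1L)
  pres <- d <= cutoff
  desc <- data.frame(i = iIdx, j = jIdx,
                     iName = paste0(a$resname[iIdx], a$resid[iIdx], ":",
                                    a$name[iIdx]),
                     jName = paste0(a$resname[jIdx], a$resid[jIdx], ":",
                                    a$name[jIdx]),
                     type = type, stringsAsFactors = FALSE)
  structure(list(presence = pres, pairs = desc, dt = traj@dt, type = type,
                 cutoff = cutoff, distances = d), class = "BondSeries")
}

# hydrogens of a selection together with their covalent heavy-atom partner
.donorHydrogens <- function(traj, donorSel, criteria) {
  a <- atoms(traj)
  hs <- donorSel[a$elem[donorSel] == "H"]
  if (!length(hs)) return(NULL)
  heavy <- which(a$elem %in% c("N", "O", "S"))
  out <- integer(0)
  bonds <- traj@topology@bonds
  for (h in hs) {
    partner <- NA_integer_
    if (nrow(bonds)) {
      hit <- c(bonds[bonds[, 1] == h, 2], bonds[bonds[, 2] == h, 1])
      hit <- hit[a$elem[hit] %in% c("N", "O", "S")]
      if (length(hit)) partner <- hit[1]
    }
    if (is.na(partner) && length(heavy)) {
      d <- cpp_dist_pairs(traj@coords[, , 1, drop = FALSE],
                          traj@box[1, , drop = FALSE],
                          rep(h - 1L, length(heavy)), heavy - 1L)
      if (min(d) <= criteria$covalentCutoff) partner <- heavy[which.min(d)]
    }
    if (!is.na(partner)) out <- c(out, h)
  }
  out
}

#' Detect hydrogen bonds
#'
#' A hydrogen bond is present in a frame when a donor hydrogen (a hydrogen
#' covalently bound to N, O or S, identified from the bond list or a
#' <= `covalentCutoff` heavy-atom heuristic) lies within the `hbond` cutoff of
#' an electronegative acceptor (N, O or S). Purely distance-based by default;
#' this matches the customary analysis of charged head-group contacts.
#'
#' @param traj a [Trajectory-class] (all-atom; coarse-grained systems without
#'   hydrogens raise an error)
#' @param donorSel `Selection` containing the donor hydrogens (heavy atoms in
#'   the selection are ignored)
#' @param acceptorSel `Selection` of acceptor candidates (non-N/O/S atoms are
#'   ignored)
#' @param criteria a [bondCriteria()]
#' @return a `BondSeries`: list with `presence` (frames x pairs logical),
#'   `pairs` (descriptors), `distances`, `dt`, `type`, `cutoff`
#' @export
detectHBonds <- function(traj, donorSel, acceptorSel,
                         criteria = bondCriteria()) {
  a <- atoms(traj)
  hs <- .donorHydrogens(traj, donorSel, criteria)
  if (is.null(hs) || !length(hs))
    stop("no identifiable donor hydrogens in the donor selection ",
         "(coarse-grained beads? use contact analysis instead)")
  acc <- acceptorSel[a$elem[acceptorSel] %in% c("N", "O", "S")]
  if (!length(acc)) stop("no N/O/S acceptors in the acceptor selection")
  grid <- expand.grid(h = hs, acc = acc)
  .bondSeries(traj, grid$h, grid$acc, criteria$hbond, "hbond")
}

#' Detect salt bridges
#'
#' Present in a frame when any basic nitrogen is within the `saltbridge`
#' cutoff of any acidic oxygen.
#'
#' @param traj a [Trajectory-class]
#' @param basicNitrogens `Selection` restricted to element class N
#' @param acidicOxygens `Selection` restricted to element class O
#' @param criteria a [bondCriteria()]
#' @return a `BondSeries`
#' @export
detectSaltBridges <- function(traj, basicNitrogens, acidicOxygens,
                              criteria = bondCriteria()) {
  a <- atoms(traj)
  if (!all(a$elem[basicNitrogens] == "N"))
    stop("basicNitrogens selection must contain only nitrogen atoms")
  if (!all(a$elem[acidicOxygens] == "O"))
    stop("acidicOxygens selection must contain only oxygen atoms")
  grid <- expand.grid(n = as.integer(basicNitrogens),
                      o = as.integer(acidicOxygens))
  .bondSeries(traj, grid$n, grid$o, criteria$saltbridge, "saltbridge")
}

#' Detect hydrophobic contacts
#'
#' Present in a frame when any carbon-carbon pair across the two selections is
#' within the `hydrophobic` cutoff.
#'
#' @param traj a [Trajectory-class]
#' @param carbonsA,carbonsB `Selection`s restricted to element class C
#' @param criteria a [bondCriteria()]
#' @return a `BondSeries`
#' @export
detectHydrophobicContacts <- function(traj, carbonsA, carbonsB,
                                      criteria = bondCriteria()) {
  a <- atoms(traj)
  if (!all(a$elem[carbonsA] == "C") || !all(a$elem[carbonsB] == "C"))
    stop("hydrophobic-contact selections must contain only carbon atoms")
  grid <- expand.grid(i = as.integer(carbonsA), j = as.integer(carbonsB))
  .bondSeries(traj, grid$i, grid$j, criteria$hydrophobic, "hydrophobic")
}

#' Total interaction time and longest lifetime of bond events
#'
#' Run-length statistics per pair descriptor (same frame-count convention as
#' the residue-level statistics), or for the union over all pairs with
#' `union = TRUE`.
#'
#' @param series a `BondSeries`
#' @param union aggregate all pairs into one presence series first?
#' @return data.frame with columns `pair`, `type`, `totalTime`,
#'   `longestLifetime` (ns; frame counts when `dt` is NA)
#' @export
bondTimeStats <- function(series, union = FALSE) {
  dt <- if (is.na(series$dt)) 1 else series$dt
  p <- series$presence
  if (union) {
    x <- rowSums(p) > 0
    st <- .runStats(x)
    return(data.frame(pair = "union", type = series$type,
                      totalTime = st["total"] * dt,
                      longestLifetime = st["longest"] * dt,
                      row.names = NULL))
  }
  st <- t(apply(p, 2, .runStats))
  data.frame(pair = paste(series$pairs$iName, series$pairs$jName, sep = "--"),
             type = series$type, totalTime = st[, "total"] * dt,
             longestLifetime = st[, "longest"] * dt, row.names = NULL)
}
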