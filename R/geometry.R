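#' Minimum-image distance in an orthorhombic box
#'
#' Euclidean distance between two points using the nearest periodic image
#' along each axis. Only orthorhombic boxes are supported.
#'
#' @param a,b numeric length-3 points, Angstrom
#' @param box numeric length-3 box lengths (Lx, Ly, Lz), all positive
#' @return distance in Angstrom; never exceeds half the box diagonal
#' @examples
#' minimumImageDistance(c(1, 1, 1), c(9, 1, 1), c(10, 10, 10))  # 2
#' @export
minimumImageDistance <- function(a, b, box) {
  if (any(box <= 0)) stop("box lengths must be positive")
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# Minimum-image displacement for matrices of row vectors (internal).
.miDisp <- function(d, box) {
  d - rep(box, each = nrow(d)) * round(d / rep(box, each = nrow(d)))
}

#' Map residue numbering between two construct conventions
#'
#' Converts residue numbers between the structure's numbering (x) and the
#' homologous human-construct numbering (h), which differ by a constant
#' offset (default +10, e.g. R218 <-> R228, K316 <-> K326).
#'
#' @param resid integer residue number(s)
#' @param direction `"x_to_h"` or `"h_to_x"`
#' @param offset integer offset added by `x_to_h`
#' @return integer residue number(s)
#' @export
mapResidueNumbering <- function(resid, direction = c("x_to_h", "h_to_x"),
                                offset = 10L) {
  direction <- match.arg(direction)
  if (direction == "x_to_h") resid + offset else resid - offset
}

#' Kabsch least-squares superposition (internal)
#'
#' Returns `mob` optimally rotated and translated onto `ref` (both n x 3).
#' @noRd
.kabsch <- function(mob, ref) {
  cm <- colMeans(mob)
  cr <- colMeans(ref)
  m <- sweep(mob, 2, cm)
  r <- sweep(ref, 2, cr)
  s <- svd(crossprod(m, r))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(m %*% t(rot), 2, cr, "+")
}

#' Make molecules whole across periodic boundaries
#'
#' Shifts atoms by integer multiples of the box lengths so that every bonded
#' pair is at its minimum-image separation (walks each molecule's bond graph
#' from its first atom). Requires a bond list; a no-op when none is present.
#'
#' @param traj a [Trajectory-class]
#' @return the trajectory with unwrapped molecules
#' @export
makeWhole <- function(traj) {
  bonds <- traj@topology@bonds
  if (nrow(bonds) == 0) return(traj)
  natoms <- nAtoms(traj)
  adj <- vector("list", natoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  xyz <- traj@coords
  for (f in seq_len(nFrames(traj))) {
    box <- traj@box[f, ]
    visited <- logical(natoms)
    for (root in seq_len(natoms)) {
      if (visited[root] || is.null(adj[[root]])) next
      queue <- root
      visited[root] <- TRUE
      while (length(queue)) {
        i <- queue[[1]]; queue <- queue[-1]
        for (j in adj[[i]]) {
          if (visited[j]) next
          d <- xyz[j, , f] - xyz[i, , f]
          shift <- -box * round(d / box)
          xyz[j, , f] <- xyz[j, , f] + shift
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  traj@coords <- xyz
  traj
}

#' Assign lipids to bilayer leaflets
#'
#' A lipid is labelled `"outer"` in a frame when the centroid z of its
#' head-group atoms lies above the membrane midplane (the mean z over all
#' selected head-group atoms in that frame), else `"inner"`.
#'
#' @param traj a [Trajectory-class]
#' @param headgroupSel a head-group `Selection` (see [selectAtoms()])
#' @return character matrix `nframes x nlipids` (dimnames: frame, molecule id)
#' @export
assignLeaflets <- function(traj, headgroupSel) {
  if (length(headgroupSel) == 0) stop("head-group selection is empty")
  a <- atoms(traj)
  mol <- a$molid[headgroupSel]
  mols <- sort(unique(mol))
  molf <- factor(mol, levels = mols)
  nf <- nFrames(traj)
  z <- traj@coords[headgroupSel, 3, , drop = FALSE]
  dim(z) <- c(length(headgroupSel), nf)
  mid <- colMeans(z)
  cz <- apply(z, 2, function(col) tapply(col, molf, mean))
  if (is.null(dim(cz))) cz <- matrix(cz, nrow = 1, dimnames = list(mols))
  lab <- ifelse(t(cz) > rep(mid, times = length(mols)), "outer", "inner")
  dim(lab) <- c(nf, length(mols))
  dimnames(lab) <- list(NULL, as.character(mols))
  if (all(lab == lab[1])) {
    warning("all lipids assigned to one leaflet (degenerate z distribution)")
  }
  lab
}
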