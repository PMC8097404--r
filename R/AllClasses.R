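#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib LipidSites, .registration = TRUE
NULL

.ROLES <- c("protein", "lipid_head", "lipid_tail", "other")
.ELEMS <- c("C", "N", "O", "S", "H", "bead", "other")

#' Annotated topology of a simulation system
#'
#' Holds one row per atom (name, residue, chain/subunit, molecule id, species
#' label, head/tail role, element class), an optional bond list, the
#' molecule-to-species table and the subunit map used for symmetry averaging.
#'
#' @slot atoms data.frame with columns `name`, `resid`, `resname`, `chain`,
#'   `molid`, `species`, `role`, `elem`; one row per atom, in file order.
#' @slot bonds two-column integer matrix of 1-based atom indices (may have 0
#'   rows).
#' @slot speciesTable named character vector, molecule id -> species label.
#' @slot subunitMap named list, subunit (chain) label -> ordered integer vector
#'   of residue ids belonging to that subunit.
#'
#' @export
setClass("Topology", representation(
  atoms = "data.frame",
  bonds = "matrix",
  speciesTable = "character",
  subunitMap = "list"
))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("name", "resid", "resname", "chain", "molid", "species", "role", "elem")
  msgs <- character()
  if (!all(need %in% names(a)))
    msgs <- c(msgs, paste("atoms is missing columns:",
                          paste(setdiff(need, names(a)), collapse = ", ")))
  else {
    if (!all(a$role %in% .ROLES))
      msgs <- c(msgs, "unknown role labels in atoms")
    if (!all(a$elem %in% .ELEMS))
      msgs <- c(msgs, "unknown element classes in atoms")
    lip <- a$role %in% c("lipid_head", "lipid_tail")
    if (any(lip)) {
      byMol <- tapply(a$role[lip], a$molid[lip], function(r) any(r == "lipid_head"))
      if (!all(byMol))
        msgs <- c(msgs, "every lipid molecule must have at least one lipid_head atom")
    }
    mols <- unique(a$molid)
    if (!all(as.character(mols) %in% names(object@speciesTable)))
      msgs <- c(msgs, "speciesTable does not cover every molecule id")
  }
  if (ncol(object@bonds) != 2)
    msgs <- c(msgs, "bonds must be a two-column matrix")
  if (length(object@subunitMap) > 1) {
    n <- lengths(object@subunitMap)
    if (length(unique(n)) != 1)
      msgs <- c(msgs, "all subunits in subunitMap must have equal residue counts")
  }
  if (length(msgs)) msgs else TRUE
})

#' Coordinate trajectory with an annotated topology
#'
#' Coordinates are stored in Angstrom in an `natoms x 3 x nframes` array with
#' per-frame orthorhombic box lengths; frame times are in nanoseconds with
#' uniform spacing `dt`.
#'
#' @slot topology a [Topology-class] object.
#' @slot coords numeric array, dim `c(natoms, 3, nframes)`, Angstrom.
#' @slot box numeric matrix `nframes x 3` of box lengths (Lx, Ly, Lz), Angstrom.
#' @slot time numeric vector of frame times, ns.
#' @slot dt frame spacing in ns (`NA` for a single frame).
#'
#' @export
setClass("Trajectory", representation(
  topology = "Topology",
  coords = "array",
  box = "matrix",
  time = "numeric",
  dt = "numeric"
))

setValidity("Trajectory", function(object) {
  msgs <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    msgs <- c(msgs, "coords must be an natoms x 3 x nframes array")
  else {
    if (d[1] != nrow(object@topology@atoms))
      msgs <- c(msgs, "coordinate count does not match atom count")
    if (d[3] < 1) msgs <- c(msgs, "trajectory must have at least one frame")
    if (nrow(object@box) != d[3] || ncol(object@box) != 3)
      msgs <- c(msgs, "box must be an nframes x 3 matrix")
    else if (any(object@box <= 0))
      msgs <- c(msgs, "box lengths must be positive")
    if (length(object@time) != d[3])
      msgs <- c(msgs, "time vector length must equal frame count")
    if (d[3] > 1) {
      dtv <- diff(object@time)
      if (any(dtv <= 0)) msgs <- c(msgs, "frame times must be strictly increasing")
      else if (!is.na(object@dt) &&
               any(abs(dtv - object@dt) > 1e-6 * object@dt))
        msgs <- c(msgs, "frame spacing is not uniform at tolerance 1e-6*dt")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Boolean lipid-residue contact tensor
#'
#' `presence[f, m, r]` is TRUE when lipid molecule `m` has at least one atom
#' (or head-group atom, in `headgroup_only` mode) within `cutoff` of any atom
#' of residue `r` in frame `f`, under the minimum-image convention.
#'
#' @slot presence logical array, dim `c(nframes, nlipids, nresidues)`, with
#'   lipid molecule ids and residue ids as dimnames.
#' @slot dt frame spacing, ns.
#' @slot mode `"whole_lipid"` or `"headgroup_only"`.
#' @slot cutoff contact cutoff, Angstrom.
#'
#' @export
setClass("ContactTensor", representation(
  presence = "array", dt = "numeric", mode = "character", cutoff = "numeric"
))

setValidity("ContactTensor", function(object) {
  msgs <- character()
  if (length(dim(object@presence)) != 3)
    msgs <- c(msgs, "presence must be a 3-d array (frames x lipids x residues)")
  if (!is.logical(object@presence))
    msgs <- c(msgs, "presence must be logical")
  if (object@cutoff <= 0) msgs <- c(msgs, "cutoff must be positive")
  if (!object@mode %in% c("whole_lipid", "headgroup_only"))
    msgs <- c(msgs, "mode must be 'whole_lipid' or 'headgroup_only'")
  if (length(msgs)) msgs else TRUE
})

#' Voxel occupancy grid
#'
#' Per-voxel fraction of frames in which at least one selected atom fell in
#' the voxel (binary per frame per voxel); a count-weighted density mode is
#' available from [occupancyGrid()].
#'
#' @slot origin grid origin (box corner), Angstrom.
#' @slot spacing voxel edge length, Angstrom.
#' @slot counts integer array of per-voxel frame counts (or atom-frame counts
#'   in weighted mode).
#' @slot occupancy numeric array, `counts / nFrames`.
#' @slot nFrames number of frames used.
#' @slot weighted logical; TRUE when counts are atom-weighted.
#'
#' @export
setClass("OccupancyGrid", representation(
  origin = "numeric", spacing = "numeric", counts = "array",
  occupancy = "array", nFrames = "integer", weighted = "logical"
))

setValidity("OccupancyGrid", function(object) {
  msgs <- character()
  if (object@spacing <= 0) msgs <- c(msgs, "spacing must be positive")
  if (!object@weighted) {
    if (any(object@counts > object@nFrames))
      msgs <- c(msgs, "voxel counts cannot exceed frame count")
    if (any(object@occupancy < 0 | object@occupancy > 1))
      msgs <- c(msgs, "occupancies must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Clustering result
#'
#' @slot labels integer vector, pose -> cluster id (0 marks Jarvis-Patrick
#'   singletons collected in the "unclustered" bin).
#' @slot representatives named integer vector, cluster id -> pose index.
#' @slot populations named numeric vector of cluster fractions, sorted
#'   descending, including an `"unclustered"` bin when singletons exist; sums
#'   to 1.
#' @slot algorithm character, `"gromos"` or `"jarvis_patrick"`.
#' @slot parameters named list of the parameters used.
#'
#' @export
setClass("ClusterResult", representation(
  labels = "integer", representatives = "integer", populations = "numeric",
  algorithm = "character", parameters = "list"
))

setValidity("ClusterResult", function(object) {
  msgs <- character()
  if (length(object@populations) &&
      abs(sum(object@populations) - 1) > 1e-8)
    msgs <- c(msgs, "cluster populations must sum to 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat("Topology:", nrow(a), "atoms,", length(unique(a$resid)), "residues,",
      length(unique(a$molid)), "molecules\n")
  cat("  species:", paste(sort(unique(a$species)), collapse = ", "), "\n")
  if (length(object@subunitMap))
    cat("  subunits:", paste(names(object@subunitMap), collapse = ", "),
        sprintf("(%d residues each)\n", length(object@subunitMap[[1]])))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d atoms, %d frames, dt = %s ns\n",
              d[1], d[3], format(object@dt)))
  cat(sprintf("  box (frame 1): %.1f x %.1f x %.1f A\n",
              object@box[1, 1], object@box[1, 2], object@box[1, 3]))
})

setMethod("show", "ContactTensor", function(object) {
  d <- dim(object@presence)
  cat(sprintf("ContactTensor: %d frames x %d lipids x %d residues (%s, cutoff %.1f A)\n",
              d[1], d[2], d[3], object@mode, object@cutoff))
  cat(sprintf("  contact density: %.3f\n", mean(object@presence)))
})

setMethod("show", "OccupancyGrid", function(object) {
  cat(sprintf("OccupancyGrid: %s voxels, spacing %.2f A, %d frames%s\n",
              paste(dim(object@counts), collapse = " x "), object@spacing,
              object@nFrames, if (object@weighted) " (atom-weighted)" else ""))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult (%s): %d poses, %d clusters\n", object@algorithm,
              length(object@labels),
              length(setdiff(unique(object@labels), 0L))))
  print(round(object@populations, 3))
})

#' @rdname Trajectory-class
#' @param x,object a `Trajectory` (or `Topology` where noted)
#' @export
nFrames <- function(x) dim(x@coords)[3]

#' @rdname Trajectory-class
#' @export
nAtoms <- function(x) {
  if (is(x, "Trajectory")) nrow(x@topology@atoms) else nrow(x@atoms)
}

#' @rdname Trajectory-class
#' @export
topology <- function(x) x@topology

#' @rdname Trajectory-class
#' @export
atoms <- function(x) {
  if (is(x, "Trajectory")) x@topology@atoms else x@atoms
}

#' @rdname Trajectory-class
#' @export
coords <- function(x) x@coords

#' @rdname Trajectory-class
#' @export
boxLengths <- function(x) x@box

#' @rdname Trajectory-class
#' @export
frameTimes <- function(x) x@time

#' Trajectory duration in ns (frame count times spacing)
#'
#' Each frame contributes one full `dt`, matching the run-length convention
#' used by the interaction-time statistics.
#' @param x a `Trajectory` or `ContactTensor`
#' @export
duration <- function(x) {
  if (is(x, "ContactTensor")) dim(x@presence)[1] * x@dt
  else nFrames(x) * x@dt
}

#' Subset of atoms by label
#'
#' A `Selection` is a labelled, duplicate-free, ordered vector of 1-based atom
#' indices bound to a topology.
#'
#' @param top a [Topology-class]
#' @param indices integer atom indices (1-based)
#' @param label selection label
#' @return an integer vector of class `Selection` with a `label` attribute
#' @export
makeSelection <- function(top, indices, label = "selection") {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must not contain duplicates")
  if (length(indices) && (min(indices) < 1 || max(indices) > nAtoms(top)))
    stop("selection indices out of range for this topology")
  structure(indices, label = label, class = "Selection")
}

#' Select atoms by attribute predicates
#'
#' @param top a [Topology-class]
#' @param species,role,elem,resid,chain,name optional filters; atoms matching
#'   all supplied filters are selected
#' @param label selection label
#' @return a `Selection`
#' @export
selectAtoms <- function(top, species = NULL, role = NULL, elem = NULL,
                        resid = NULL, chain = NULL, name = NULL,
                        label = "selection") {
  a <- top@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(species)) keep <- keep & a$species %in% species
  if (!is.null(role)) keep <- keep & a$role %in% role
  if (!is.null(elem)) keep <- keep & a$elem %in% elem
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(name)) keep <- keep & a$name %in% name
  makeSelection(top, which(keep), label)
}
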