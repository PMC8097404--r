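#' Pairwise pose RMSD matrix
#'
#' Coordinate RMSD between all pose pairs. With `superpose = TRUE` each pair
#' is optimally superposed (Kabsch least-squares rigid fit) before the RMSD;
#' without superposition raw coordinates are compared (appropriate when the
#' protein frame is positionally restrained).
#'
#' @param poses numeric array `natoms x 3 x nposes`
#' @param superpose superpose each pair before computing the RMSD?
#' @return symmetric matrix of RMSDs, Angstrom, zero diagonal
#' @export
poseRMSDMatrix <- function(poses, superpose = FALSE) {
  d <- dim(poses)
  if (length(d) != 3 || d[2] != 3)
    stop("poses must be an natoms x 3 x nposes array")
  n <- d[3]
  if (n < 2) stop("at least two poses are required")
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- poses[, , i]; b <- poses[, , j]
      if (superpose) b <- .kabsch(b, a)
      dm[i, j] <- dm[j, i] <- sqrt(mean(rowSums((a - b)^2)))
    }
  }
  dm
}

.clusterResult <- function(labels, dm, algorithm, parameters) {
  ids <- setdiff(sort(unique(labels)), 0L)
  reps <- vapply(ids, function(k) {
    members <- which(labels == k)
    if (length(members) == 1) return(members)
    avg <- vapply(members, function(m)
      mean(dm[m, setdiff(members, m)]), 1)
    members[which.min(avg)]  # which.min: lowest index on ties
  }, 1L)
  names(reps) <- as.character(ids)
  pop <- vapply(ids, function(k) mean(labels == k), 1)
  names(pop) <- as.character(ids)
  if (any(labels == 0L)) pop <- c(pop, unclustered = mean(labels == 0L))
  pop <- pop[order(-pop)]
  new("ClusterResult", labels = as.integer(labels), representatives = reps,
      populations = pop, algorithm = algorithm, parameters = parameters)
}

#' Jarvis-Patrick clustering
#'
#' Neighbour lists are defined by the distance cutoff; two poses are linked
#' when each is in the other's neighbour list and they share at least
#' `commonNeighbors` neighbours; clusters are the connected components of the
#' link graph. Singletons are collected in an `"unclustered"` bin (label 0).
#' The alternative fixed-size nearest-neighbour list variant is available via
#' `nearestNeighbors`.
#'
#' @param dm symmetric distance matrix
#' @param cutoff neighbour distance cutoff (default 65, the customary value
#'   for coarse-grained head-group clustering)
#' @param commonNeighbors required number of shared neighbours (default 3)
#' @param nearestNeighbors optional integer M: define neighbour lists as the M
#'   nearest poses instead of the distance cutoff
#' @return a [ClusterResult-class]
#' @export
jarvisPatrickCluster <- function(dm, cutoff = 65, commonNeighbors = 3L,
                                 nearestNeighbors = NULL) {
  if (is.null(nearestNeighbors) && cutoff <= 0) stop("cutoff must be positive")
  if (commonNeighbors < 0) stop("commonNeighbors must be >= 0")
  n <- nrow(dm)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.null(nearestNeighbors)) {
      nb[[i]] <- which(dm[i, ] <= cutoff & seq_len(n) != i)
    } else {
      ord <- order(dm[i, -i])
      cand <- setdiff(seq_len(n), i)[ord]
      nb[[i]] <- sort(cand[seq_len(min(nearestNeighbors, n - 1))])
    }
  }
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (j %in% nb[[i]] && i %in% nb[[j]] &&
          length(intersect(nb[[i]], nb[[j]])) >= commonNeighbors)
        link[i, j] <- link[j, i] <- TRUE
    }
  }
  labels <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (labels[i]) next
    comp <- i
    queue <- i
    while (length(queue)) {
      k <- queue[[1]]; queue <- queue[-1]
      nxt <- which(link[k, ] & labels[seq_len(n)] == 0L & !(seq_len(n) %in% comp))
      comp <- c(comp, nxt)
      queue <- c(queue, nxt)
    }
    if (length(comp) == 1 && !any(link[i, ])) {
      labels[i] <- -1L  # singleton, relabelled to 0 below
    } else {
      cur <- cur + 1L
      labels[comp] <- cur
    }
  }
  labels[labels == -1L] <- 0L
  .clusterResult(labels, dm, "jarvis_patrick",
                 list(cutoff = cutoff, commonNeighbors = commonNeighbors,
                      nearestNeighbors = nearestNeighbors))
}

#' GROMOS clustering
#'
#' Iterative greedy extraction: the pose with the largest number of
#' within-cutoff neighbours among the remaining poses becomes the centroid of
#' the next cluster and is removed from the pool together with all its
#' neighbours (permanently); the procedure repeats until the pool is empty.
#' Ties are broken toward the lowest pose index.
#'
#' @param dm symmetric distance matrix
#' @param cutoff neighbour distance cutoff (default 5, the customary all-atom
#'   value)
#' @return a [ClusterResult-class]
#' @export
gromosCluster <- function(dm, cutoff = 5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(dm)
  labels <- integer(n)
  pool <- seq_len(n)
  cur <- 0L
  while (length(pool)) {
    nnb <- vapply(pool, function(i) sum(dm[i, pool] <= cutoff) - 1L, 1L)
    centroid <- pool[which.max(nnb)]  # which.max: lowest index on ties
    members <- pool[dm[centroid, pool] <= cutoff]
    cur <- cur + 1L
    labels[members] <- cur
    pool <- setdiff(pool, members)
  }
  .clusterResult(labels, dm, "gromos", list(cutoff = cutoff))
}

#' Representative pose per cluster
#'
#' The cluster centre: the member with the smallest average RMSD from all
#' other members (ties toward the lowest pose index); a singleton returns its
#' sole member.
#'
#' @param result a [ClusterResult-class]
#' @param dm the distance matrix the clustering was computed from
#' @return named integer vector, cluster id -> pose index
#' @export
representativePose <- function(result, dm) {
  res <- .clusterResult(result@labels, dm, result@algorithm, result@parameters)
  res@representatives
}

#' Cluster population fractions
#'
#' Fraction of poses per cluster (including the `"unclustered"` singleton bin
#' when present), sorted descending; sums to 1.
#'
#' @param result a [ClusterResult-class]
#' @return named numeric vector
#' @export
clusterPopulations <- function(result) result@populations

#' Extract lipid poses from a trajectory
#'
#' Per-frame coordinates of a fixed atom selection (e.g. one lipid, or the
#' head-group atoms of one species), as an `natoms x 3 x nframes` pose array.
#'
#' @param traj a [Trajectory-class]
#' @param selection a `Selection`
#' @param frames frame indices (default all)
#' @return numeric array for [poseRMSDMatrix()]
#' @export
extractPoses <- function(traj, selection, frames = seq_len(nFrames(traj))) {
  traj@coords[selection, , frames, drop = FALSE]
}
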