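# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (no rle(), no stats::quantile(), no shared kernels).

# run-length statistics by explicit scan
oracleRunStats <- function(x) {
  total <- 0L; longest <- 0L; run <- 0L
  for (v in x) {
    if (isTRUE(as.logical(v))) {
      total <- total + 1L
      run <- run + 1L
      if (run > longest) longest <- run
    } else run <- 0L
  }
  c(total = total, longest = longest)
}

# per-residue union totals and per-pair-max longest runs from a boolean tensor
oracleResidueStats <- function(p, dt) {
  d <- dim(p)
  total <- numeric(d[3]); longest <- numeric(d[3])
  for (r in seq_len(d[3])) {
    anyv <- rep(FALSE, d[1])
    best <- 0L
    for (l in seq_len(d[2])) {
      anyv <- anyv | p[, l, r]
      rs <- oracleRunStats(p[, l, r])
      if (rs["longest"] > best) best <- rs["longest"]
    }
    total[r] <- sum(anyv) * dt
    longest[r] <- best * dt
  }
  list(total = total, longest = longest)
}

oracleLipidStats <- function(p, dt) {
  d <- dim(p)
  total <- numeric(d[2]); longest <- numeric(d[2])
  for (l in seq_len(d[2])) {
    anyv <- rep(FALSE, d[1])
    for (r in seq_len(d[3])) anyv <- anyv | p[, l, r]
    rs <- oracleRunStats(anyv)
    total[l] <- rs["total"] * dt
    longest[l] <- rs["longest"] * dt
  }
  list(total = total, longest = longest)
}

# sort-based linear-interpolation quantile (type 7), written from the formula
oracleQuantile <- function(x, prob) {
  s <- sort(x)
  h <- (length(s) - 1) * prob + 1
  lo <- floor(h)
  if (lo == length(s)) return(s[lo])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

oracleFenceSet <- function(values, ids) {
  q3 <- oracleQuantile(values, 0.75)
  q1 <- oracleQuantile(values, 0.25)
  fence <- q3 + 1.5 * (q3 - q1)
  ids[values > fence]
}

# minimum-image distance by explicit image enumeration (independent of the
# round()-based formula)
oracleMinImage <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- a - (b + c(ix, iy, iz) * box)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# brute-force contact presence for one frame
oracleContactFrame <- function(xyz, box, lipAtoms, lipGroup, resAtoms,
                               resGroup, cutoff) {
  nl <- max(lipGroup); nr <- max(resGroup)
  out <- matrix(FALSE, nl, nr)
  for (i in seq_along(lipAtoms)) for (j in seq_along(resAtoms)) {
    if (out[lipGroup[i], resGroup[j]]) next
    if (oracleMinImage(xyz[lipAtoms[i], ], xyz[resAtoms[j], ], box) <= cutoff)
      out[lipGroup[i], resGroup[j]] <- TRUE
  }
  out
}

# GROMOS greedy extraction, independent re-implementation
oracleGromos <- function(dm, cutoff) {
  n <- nrow(dm)
  labels <- rep(NA_integer_, n)
  remaining <- rep(TRUE, n)
  k <- 0L
  while (any(remaining)) {
    idx <- which(remaining)
    counts <- sapply(idx, function(i) sum(dm[i, idx] <= cutoff) - 1L)
    centroid <- idx[which(counts == max(counts))[1]]
    members <- idx[dm[centroid, idx] <= cutoff]
    k <- k + 1L
    labels[members] <- k
    remaining[members] <- FALSE
  }
  labels
}

# Jarvis-Patrick by explicit link enumeration + transitive closure
oracleJP <- function(dm, cutoff, common) {
  n <- nrow(dm)
  nb <- lapply(seq_len(n), function(i) which(dm[i, ] <= cutoff & seq_len(n) != i))
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if ((i %in% nb[[j]]) && (j %in% nb[[i]]) &&
        sum(nb[[i]] %in% nb[[j]]) >= common)
      link[i, j] <- TRUE
  }
  reach <- link | diag(TRUE, n)
  for (k in seq_len(n)) reach <- reach | (reach %*% (reach * 1) > 0)
  labels <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (labels[i]) next
    comp <- which(reach[i, ])
    if (length(comp) == 1 && !any(link[i, ])) labels[i] <- 0L
    else { cur <- cur + 1L; labels[comp] <- cur }
  }
  labels
}

# partitions equal up to label renaming
samePartition <- function(a, b) {
  # singleton bin (0) must match exactly; other labels up to renaming
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ka <- a[a != 0L]; kb <- b[b != 0L]
  if (length(ka) != length(kb)) return(FALSE)
  if (!length(ka)) return(TRUE)
  identical(as.integer(match(ka, unique(ka))),
            as.integer(match(kb, unique(kb))))
}

# random symmetric distance matrix
randomDM <- function(n, scale = 1) {
  m <- matrix(stats::runif(n * n, 0, scale), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
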