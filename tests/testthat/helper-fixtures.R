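# Small constructors used across the suite. Fixtures are built in code; the
# larger synthetic systems come from the package's own generator.

testTopology <- function(n, name = "CA", resid = seq_len(n), resname = "GLY",
                         chain = "A", molid = NULL, species = "PROT",
                         role = "protein", elem = "C",
                         bonds = matrix(integer(), 0, 2)) {
  a <- data.frame(name = rep_len(name, n), resid = rep_len(resid, n),
                  resname = rep_len(resname, n), chain = rep_len(chain, n),
                  molid = if (is.null(molid)) rep_len(resid, n)
                          else rep_len(molid, n),
                  species = rep_len(species, n), role = rep_len(role, n),
                  elem = rep_len(elem, n), stringsAsFactors = FALSE)
  st <- tapply(a$species, a$molid, `[`, 1)
  prot <- a[a$role == "protein", , drop = FALSE]
  ur <- !duplicated(prot$resid)
  new("Topology", atoms = a, bonds = bonds,
      speciesTable = stats::setNames(as.character(st), names(st)),
      subunitMap = split(prot$resid[ur], prot$chain[ur]))
}

# Trajectory from an natoms x 3 x nframes array (or an natoms x 3 matrix)
makeTraj <- function(xyz, top = NULL, box = c(20, 20, 20), dt = 1) {
  if (length(dim(xyz)) == 2) xyz <- array(xyz, dim = c(dim(xyz), 1))
  nf <- dim(xyz)[3]
  if (is.null(top)) top <- testTopology(dim(xyz)[1])
  new("Trajectory", topology = top, coords = xyz,
      box = matrix(rep(box, each = nf), nrow = nf),
      time = (seq_len(nf) - 1) * ifelse(is.na(dt), 1, dt), dt = dt)
}

# contact tensor directly from a logical array (frames x lipids x residues)
makeTensor <- function(presence, dt = 1, mode = "whole_lipid", cutoff = 6) {
  if (is.null(dimnames(presence)))
    dimnames(presence) <- list(NULL, as.character(seq_len(dim(presence)[2])),
                               as.character(seq_len(dim(presence)[3])))
  new("ContactTensor", presence = presence, dt = dt, mode = mode,
      cutoff = cutoff)
}

# the frozen small fixture: 4 x 20-residue tetramer, 24 lipids, 2000 frames
smallFixtureSpec <- function(seed = 42L, nFrames = 2000L, ...) {
  syntheticSystemSpec(nFrames = nFrames, seed = seed, ...)
}

# tiny all-atom-like system: a hydroxyl donor (O-H), a carboxylate acceptor,
# an amine nitrogen and two carbons, with controllable positions
aaTestTraj <- function(positions, box = c(30, 30, 30)) {
  # positions: named list of 3-vectors for atoms OD, HD, OA1, NB, C1, C2
  nm <- c("OD", "HD", "OA1", "NB", "C1", "C2")
  stopifnot(all(nm %in% names(positions)))
  a <- data.frame(
    name = nm, resid = c(1, 1, 2, 3, 4, 5), resname = "LIG",
    chain = "A", molid = c(1, 1, 2, 3, 4, 5), species = "LIG",
    role = "other", elem = c("O", "H", "O", "N", "C", "C"),
    stringsAsFactors = FALSE)
  top <- new("Topology", atoms = a,
             bonds = matrix(c(1L, 2L), 1, 2),
             speciesTable = c(`1` = "LIG", `2` = "LIG", `3` = "LIG",
                              `4` = "LIG", `5` = "LIG"),
             subunitMap = list())
  xyz <- t(vapply(nm, function(k) positions[[k]], numeric(3)))
  makeTraj(xyz, top, box = box, dt = NA_real_)
}
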