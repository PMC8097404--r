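#' Species and role annotation rules
#'
#' Rule-driven mapping from residue names to species labels and from atom
#' names to head/tail roles, so that both coarse-grained bead naming and
#' all-atom naming can be annotated without code changes.
#'
#' @param lipids named list: species label -> `list(resnames = <character>,
#'   headAtoms = <character atom names>)`; atoms of those residues that are
#'   not head atoms are tail atoms.
#' @param proteinResnames residue names mapped to the protein species; by
#'   default the 20 standard amino-acid codes.
#' @param proteinSpecies species label for protein molecules.
#' @param elem optional named character vector overriding the element-class
#'   heuristic (atom name -> one of C, N, O, S, H, bead, other).
#' @return a list of class `AnnotationRules`
#' @export
annotationRules <- function(lipids = list(),
                            proteinResnames = .AA3,
                            proteinSpecies = "PROT",
                            elem = character()) {
  structure(list(lipids = lipids, proteinResnames = proteinResnames,
                 proteinSpecies = proteinSpecies, elem = elem),
            class = "AnnotationRules")
}

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.elemClass <- function(name, override = character()) {
  out <- character(length(name))
  hit <- name %in% names(override)
  out[hit] <- override[name[hit]]
  first <- toupper(substr(gsub("[^A-Za-z].*", "", gsub("^[0-9]+", "", name[!hit])), 1, 1))
  out[!hit] <- ifelse(first %in% c("C", "N", "O", "S", "H"), first, "bead")
  out
}

# Build an annotated Topology from a raw atom table (name, resid, resname,
# chain). Protein chains get one molecule id per chain; each lipid residue is
# one molecule. Unknown residue names raise an annotation error.
.annotateTopology <- function(raw, rules, bonds = matrix(integer(), 0, 2)) {
  lipNames <- unlist(lapply(rules$lipids, `[[`, "resnames"))
  lipSpecies <- rep(names(rules$lipids),
                    vapply(rules$lipids, function(l) length(l$resnames), 1L))
  known <- c(rules$proteinResnames, lipNames)
  bad <- setdiff(unique(raw$resname), known)
  if (length(bad))
    stop("cannot annotate residue name(s): ", paste(bad, collapse = ", "))
  isProt <- raw$resname %in% rules$proteinResnames
  species <- character(nrow(raw))
  species[isProt] <- rules$proteinSpecies
  species[!isProt] <- lipSpecies[match(raw$resname[!isProt], lipNames)]
  role <- rep("other", nrow(raw))
  role[isProt] <- "protein"
  for (sp in names(rules$lipids)) {
    sel <- species == sp
    role[sel] <- ifelse(raw$name[sel] %in% rules$lipids[[sp]]$headAtoms,
                        "lipid_head", "lipid_tail")
  }
  molid <- integer(nrow(raw))
  protChains <- unique(raw$chain[isProt])
  molid[isProt] <- match(raw$chain[isProt], protChains)
  lipKey <- paste(raw$chain, raw$resid, raw$resname)[!isProt]
  molid[!isProt] <- length(protChains) + match(lipKey, unique(lipKey))
  speciesTable <- tapply(species, molid, `[`, 1)
  subunitMap <- lapply(split(raw$resid[isProt], raw$chain[isProt]), unique)
  a <- data.frame(name = raw$name, resid = raw$resid, resname = raw$resname,
                  chain = raw$chain, molid = molid, species = species,
                  role = role,
                  elem = .elemClass(raw$name, rules$elem),
                  stringsAsFactors = FALSE)
  new("Topology", atoms = a, bonds = bonds,
      speciesTable = stats::setNames(as.character(speciesTable),
                                     names(speciesTable)),
      subunitMap = subunitMap[order(names(subunitMap))])
}

# --- GRO (fixed width, nm) ---------------------------------------------------

.parseGRO <- function(path) {
  lines <- readLines(path)
  nat <- as.integer(trimws(lines[2]))
  rec <- lines[3:(2 + nat)]
  raw <- data.frame(
    resid = as.integer(substr(rec, 1, 5)),
    resname = trimws(substr(rec, 6, 10)),
    name = trimws(substr(rec, 11, 15)),
    x = as.numeric(substr(rec, 21, 28)) * 10,
    y = as.numeric(substr(rec, 29, 36)) * 10,
    z = as.numeric(substr(rec, 37, 44)) * 10,
    stringsAsFactors = FALSE)
  boxv <- as.numeric(strsplit(trimws(lines[3 + nat]), "\\s+")[[1]]) * 10
  if (length(boxv) > 3 && any(boxv[4:length(boxv)] != 0))
    stop("triclinic boxes are not supported; only orthorhombic boxes")
  list(atoms = raw, box = boxv[1:3])
}

#' Write one frame as a GRO file
#'
#' Coordinates are converted from Angstrom to nm (GRO native units, three
#' decimals).
#'
#' @param traj a [Trajectory-class]
#' @param path output file
#' @param frame frame index to write
#' @export
writeGRO <- function(traj, path, frame = 1L) {
  a <- atoms(traj)
  xyz <- traj@coords[, , frame] / 10
  box <- traj@box[frame, ] / 10
  lines <- c("written by LipidSites", format(nrow(a)))
  lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                            a$resid %% 100000, substr(a$resname, 1, 5),
                            substr(a$name, 1, 5),
                            seq_len(nrow(a)) %% 100000,
                            xyz[, 1], xyz[, 2], xyz[, 3]))
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}

# --- PDB ---------------------------------------------------------------------

.parsePDBBox <- function(path) {
  cl <- grep("^CRYST1", readLines(path, n = 500), value = TRUE)
  if (!length(cl)) return(NULL)
  v <- c(as.numeric(substr(cl[1], 7, 15)), as.numeric(substr(cl[1], 16, 24)),
         as.numeric(substr(cl[1], 25, 33)))
  ang <- c(as.numeric(substr(cl[1], 34, 40)), as.numeric(substr(cl[1], 41, 47)),
           as.numeric(substr(cl[1], 48, 54)))
  if (any(abs(ang - 90) > 1e-3))
    stop("triclinic boxes are not supported; only orthorhombic boxes")
  v
}

#' Write a (multi-model) PDB trajectory
#'
#' One MODEL per frame, with a CRYST1 record carrying the orthorhombic box.
#' Coordinates in Angstrom, three decimals (PDB native precision).
#'
#' @param traj a [Trajectory-class]
#' @param path output file
#' @param frames frame indices to write (default all)
#' @export
writeTrajectoryPDB <- function(traj, path, frames = seq_len(nFrames(traj))) {
  a <- atoms(traj)
  con <- file(path, "w")
  on.exit(close(con))
  box <- traj@box[frames[1], ]
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90), con)
  chain <- substr(a$chain, 1, 1)
  for (f in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj@coords[, , frames[f]]
    writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       seq_len(nrow(a)) %% 100000, substr(a$name, 1, 4),
                       substr(a$resname, 1, 3), chain, a$resid %% 10000,
                       xyz[, 1], xyz[, 2], xyz[, 3], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write per-residue statistics into the B-factor column of a PDB file
#'
#' Heat-map export: each atom's B-factor carries its residue's statistic,
#' two-decimal fixed format.
#'
#' @param traj a [Trajectory-class]
#' @param values named numeric vector, residue id -> value
#' @param path output file
#' @param frame frame whose coordinates are written
#' @export
writeBFactorPDB <- function(traj, values, path, frame = 1L) {
  a <- atoms(traj)
  b <- values[as.character(a$resid)]
  b[is.na(b)] <- 0
  xyz <- traj@coords[, , frame]
  con <- file(path, "w")
  on.exit(close(con))
  box <- traj@box[frame, ]
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90), con)
  writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     seq_len(nrow(a)) %% 100000, substr(a$name, 1, 4),
                     substr(a$resname, 1, 3), substr(a$chain, 1, 1),
                     a$resid %% 10000, xyz[, 1], xyz[, 2], xyz[, 3], 1,
                     pmin(pmax(b, -99.99), 999.99)), con)
  writeLines("END", con)
  invisible(path)
}

# --- Trajectory loading ------------------------------------------------------

#' Load a trajectory from topology and coordinate files
#'
#' Topology may be PDB or GRO; coordinates may be a DCD file or a multi-model
#' PDB (or omitted, in which case the frames in the topology file are used).
#' XTC is not supported. Coordinates are stored in Angstrom (GRO files are
#' converted from nm on read). When a bond list is supplied through `bonds`,
#' molecules are made whole across periodic boundaries on load.
#'
#' @param topologyPath PDB or GRO file
#' @param coordinatesPath optional DCD or multi-model PDB file
#' @param rules an [annotationRules()] object
#' @param dt frame spacing in ns (`NA` flags unknown spacing; a single frame
#'   always has `dt = NA`)
#' @param box optional length-3 box lengths (Angstrom) overriding / supplying
#'   the box when the files carry none
#' @param bonds optional two-column matrix of bonded atom-index pairs
#' @return a [Trajectory-class]
#' @export
loadTrajectory <- function(topologyPath, coordinatesPath = NULL, rules,
                           dt = NA_real_, box = NULL,
                           bonds = matrix(integer(), 0, 2)) {
  ext <- function(p) tolower(tools::file_ext(p))
  if (ext(topologyPath) == "gro") {
    g <- .parseGRO(topologyPath)
    raw <- g$atoms
    raw$chain <- "A"
    topBox <- g$box
    topXYZ <- array(t(as.matrix(g$atoms[, c("x", "y", "z")])),
                    dim = c(3, nrow(raw), 1))
    topXYZ <- aperm(topXYZ, c(2, 1, 3))
  } else if (ext(topologyPath) %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(topologyPath, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    raw <- data.frame(resid = at$resno, resname = at$resid, name = at$elety,
                      chain = ifelse(is.na(at$chain) | at$chain == "", "A",
                                     at$chain),
                      stringsAsFactors = FALSE)
    topBox <- .parsePDBBox(topologyPath)
    nfrm <- nrow(pdb$xyz)
    topXYZ <- aperm(array(t(pdb$xyz), dim = c(3, nrow(raw), nfrm)), c(2, 1, 3))
  } else stop("unsupported topology format: ", ext(topologyPath),
              " (use PDB or GRO)")
  top <- .annotateTopology(raw, rules, bonds = bonds)
  natoms <- nAtoms(top)

  if (is.null(coordinatesPath)) {
    xyz <- topXYZ
    boxv <- topBox
  } else if (ext(coordinatesPath) == "dcd") {
    d <- bio3d::read.dcd(coordinatesPath, verbose = FALSE)
    if (ncol(d) != 3 * natoms)
      stop(sprintf("atom-count mismatch: topology has %d atoms, frames have %d",
                   natoms, ncol(d) / 3))
    xyz <- aperm(array(t(d), dim = c(3, natoms, nrow(d))), c(2, 1, 3))
    boxv <- topBox
  } else if (ext(coordinatesPath) %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(coordinatesPath, multi = TRUE, verbose = FALSE)
    if (ncol(pdb$xyz) != 3 * natoms)
      stop(sprintf("atom-count mismatch: topology has %d atoms, frames have %d",
                   natoms, ncol(pdb$xyz) / 3))
    xyz <- aperm(array(t(pdb$xyz), dim = c(3, natoms, nrow(pdb$xyz))),
                 c(2, 1, 3))
    boxv <- .parsePDBBox(coordinatesPath)
    if (is.null(boxv)) boxv <- topBox
  } else if (ext(coordinatesPath) == "xtc") {
    stop("XTC coordinate files are not supported; convert to DCD or ",
         "multi-model PDB")
  } else stop("unsupported coordinate format: ", ext(coordinatesPath))

  if (!is.null(box)) boxv <- box
  if (is.null(boxv)) stop("no box information found; supply `box`")
  nf <- dim(xyz)[3]
  if (nf == 1 && !is.na(dt)) dt <- NA_real_
  tvec <- (seq_len(nf) - 1) * if (is.na(dt)) 1 else dt
  traj <- new("Trajectory", topology = top, coords = xyz,
              box = matrix(rep(boxv, each = nf), nrow = nf), time = tvec,
              dt = dt)
  if (nrow(bonds)) traj <- makeWhole(traj)
  traj
}
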