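test_that("voxel occupancy is binary per frame and matches simple cases", {
  top <- testTopology(1)
  # one stationary atom, 100 frames -> its voxel 1.0, everything else 0
  xyz <- array(c(5.4, 5.4, 5.4), c(1, 3, 100))
  g <- occupancyGrid(makeTraj(xyz, top, box = c(10, 10, 10)),
                     makeSelection(top, 1L), 1)
  expect_equal(max(g@occupancy), 1)
  expect_equal(sum(g@occupancy > 0), 1)
  expect_equal(g@occupancy[6, 6, 6], 1)
  # inside a voxel in 3 of 100 frames -> 3% occupancy
  xyz[, 1, 4:100] <- 8.2
  g2 <- occupancyGrid(makeTraj(xyz, top, box = c(10, 10, 10)),
                      makeSelection(top, 1L), 1)
  expect_equal(g2@occupancy[6, 6, 6], 0.03)
  expect_error(occupancyGrid(makeTraj(xyz, top), makeSelection(top, 1L), -1),
               "positive")
})

test_that("occupancy grid matches brute-force voxelisation of random walks", {
  set.seed(91)
  n <- 5L; nf <- 40L; box <- c(8, 8, 8)
  xyz <- array(stats::runif(n * 3 * nf, -4, 12), c(n, 3, nf))
  top <- testTopology(n)
  g <- occupancyGrid(makeTraj(xyz, top, box = box), makeSelection(top, 1:n), 1)
  brute <- array(0L, dim(g@counts))
  for (f in seq_len(nf)) {
    seen <- array(FALSE, dim(g@counts))
    for (i in seq_len(n)) {
      p <- xyz[i, , f] %% box
      v <- pmin(floor(p) + 1, dim(g@counts))
      seen[v[1], v[2], v[3]] <- TRUE
    }
    brute <- brute + seen
  }
  expect_identical(unname(g@counts), unname(brute))
  expect_true(all(g@occupancy >= 0 & g@occupancy <= 1))
  # rigid translation (with wrap) leaves occupancies invariant up to relabeling
  g2 <- occupancyGrid(makeTraj(xyz + 2, top, box = box),
                      makeSelection(top, 1:n), 1)
  expect_equal(sort(as.vector(g2@counts)), sort(as.vector(g@counts)))
})

test_that("threshold contours nest monotonically", {
  top <- testTopology(1)
  xyz <- array(c(5.5, 5.5, 5.5), c(1, 3, 10))
  xyz[, 1, 8:10] <- 2.5
  g <- occupancyGrid(makeTraj(xyz, top, box = c(10, 10, 10)),
                     makeSelection(top, 1L), 1)
  m15 <- thresholdContour(g, 0.15)
  m20 <- thresholdContour(g, 0.20)
  m30 <- thresholdContour(g, 0.30)
  expect_true(all(m20 <= m15))
  expect_true(all(m30 <= m20))
  expect_equal(sum(m15), 2)  # 0.7 and 0.3 voxels
  expect_equal(sum(m30), 2)
  expect_error(thresholdContour(g, 1.5), "threshold")
  # example values
  occ <- c(0.10, 0.16, 0.25)
  expect_identical(occ >= 0.15, c(FALSE, TRUE, TRUE))
  expect_identical(occ >= 0.30, c(FALSE, FALSE, FALSE))
})

test_that("layered maps confine density and conserve counts across layers", {
  set.seed(92)
  n <- 4L; nf <- 30L; box <- c(10, 10, 12)
  xyz <- array(stats::runif(n * 3 * nf, 0, 10), c(n, 3, nf))
  xyz[, 3, ] <- stats::runif(n * nf, 4, 8)  # confined to z in [4, 8)
  top <- testTopology(n)
  traj <- makeTraj(xyz, top, box = box)
  lm <- layeredOccupancyMaps(traj, makeSelection(top, 1:n),
                             zEdges = seq(0, 12, by = 4), resolution = 4)
  expect_true(all(lm$counts[[1]] == 0))
  expect_true(all(lm$counts[[3]] == 0))
  expect_gt(sum(lm$counts[[2]]), 0)
  # conservation against the full 3-D grid partitioned at the layer edges
  g <- occupancyGrid(traj, makeSelection(top, 1:n), 4)
  expect_equal(sum(vapply(lm$counts, sum, 1L)), sum(g@counts))
  expect_error(layeredOccupancyMaps(traj, makeSelection(top, 1:n),
                                    zEdges = c(0, 20)), "within the box")
})

test_that("slab contact profiles count shell contacts binned by z", {
  # head bead fixed at z = 5.1, within 3 A of a reference atom
  top <- testTopology(2, name = c("CA", "Q0"), resid = c(1L, 2L),
                      resname = c("GLY", "LIN"), molid = c(1L, 2L),
                      species = c("PROT", "LIN"),
                      role = c("protein", "lipid_head"), elem = c("C", "bead"))
  xyz <- array(0, c(2, 3, 100))
  xyz[1, , ] <- c(5, 5, 5); xyz[2, , ] <- c(5, 7, 5.1)
  traj <- makeTraj(xyz, top, box = c(20, 20, 20), dt = 1)
  sel <- selectAtoms(top, role = "lipid_head", label = "LIN")
  prof <- slabContactProfile(traj, sel, 1L, shellCutoff = 3, slab = 0.5)
  bin <- findInterval(5.1, prof$edges)
  expect_equal(prof$counts[bin, 1], 100)
  expect_equal(sum(prof$counts), 100)
  expect_equal(prof$edges[bin], 5.0)
  # just outside the shell -> all bins zero
  xyz[2, , ] <- c(5, 8.2, 5.1)
  prof0 <- slabContactProfile(makeTraj(xyz, top, box = c(20, 20, 20), dt = 1),
                              sel, 1L, shellCutoff = 3)
  expect_equal(sum(prof0$counts), 0)
  expect_error(slabContactProfile(traj, sel, 1L, shellCutoff = -3), "positive")
})

test_that("slab totals equal unbinned contact-event counts on random systems", {
  set.seed(93)
  spec <- smallFixtureSpec(nFrames = 300L)
  sim <- simulateLipidTrajectory(spec)
  traj <- sim$trajectory
  sel <- selectAtoms(topology(traj), species = "LIN", role = "lipid_head",
                     label = "LIN")
  site <- sim$truth$siteResidues[[1]]
  prof <- slabContactProfile(traj, sel, site, shellCutoff = 3, slab = 0.5,
                             intervalNs = 50)
  # unbinned recount
  a <- atoms(traj)
  ref <- which(a$role == "protein" & a$resid %in% site)
  events <- 0L
  for (f in seq_len(nFrames(traj))) {
    for (h in sel) {
      dmin <- Inf
      for (r in ref) dmin <- min(dmin, minimumImageDistance(
        traj@coords[h, , f], traj@coords[r, , f], traj@box[f, ]))
      events <- events + (dmin <= 3)
    }
  }
  expect_equal(sum(prof$counts), events)
  expect_equal(ncol(prof$counts), 3)  # 300 frames x 0.5 ns / 50 ns
})

test_that("fold enrichment handles ratios and degenerate bins", {
  mk <- function(counts) structure(list(
    edges = seq(0, length(counts) / 2, by = 0.5),
    counts = matrix(counts, ncol = 1), intervals = "all",
    shellCutoff = 3, slab = 0.5, label = "x"), class = "SlabProfile")
  fe <- foldEnrichment(mk(c(10, 20)), mk(c(5, 10)))
  expect_equal(fe$ratio, c(2, 2))
  expect_identical(fe$flag, c("ok", "ok"))
  fe2 <- foldEnrichment(mk(4), mk(0))
  expect_true(is.na(fe2$ratio))
  expect_identical(fe2$flag, "numerator_only")
  fe3 <- foldEnrichment(mk(c(3, 0)), mk(c(3, 0)))
  expect_equal(fe3$ratio[1], 1)
  expect_identical(fe3$flag[2], "empty")
  expect_error(foldEnrichment(mk(c(1, 2)), mk(1)), "binning")
})

test_that("lateral g(r) is flat for uniform points and peaked for a ring", {
  # uniform points: modest sample here (the larger check runs in acceptance)
  set.seed(94)
  n <- 2000L; nf <- 50L
  top <- testTopology(n + 1, role = c("protein", rep("other", n)),
                      species = c("PROT", rep("GAS", n)),
                      molid = c(1L, rep(2L, n)))
  xyz <- array(stats::runif((n + 1) * 3 * nf, 0, 100), c(n + 1, 3, nf))
  xyz[1, 1, ] <- 50; xyz[1, 2, ] <- 50; xyz[1, 3, ] <- 10
  traj <- makeTraj(xyz, top, box = c(100, 100, 20))
  rdf <- lateralRDF(traj, makeSelection(top, 2:(n + 1)),
                    rBreaks = seq(2, 48, by = 2))
  expect_true(all(abs(rdf$g - 1) < 0.1))
  # all points on a lateral ring at r = 15.3 -> single occupied bin [15, 16)
  th <- stats::runif(n, 0, 2 * pi)
  xyz2 <- xyz
  xyz2[-1, 1, ] <- 50 + 15.3 * cos(th); xyz2[-1, 2, ] <- 50 + 15.3 * sin(th)
  rdf2 <- lateralRDF(makeTraj(xyz2, top, box = c(100, 100, 20)),
                     makeSelection(top, 2:(n + 1)),
                     rBreaks = seq(0, 40, by = 1))
  expect_true(all(rdf2$g[rdf2$r != 15.5] == 0))
  expect_gt(rdf2$g[rdf2$r == 15.5], 1)
  # bins beyond half the lateral box are truncated with a warning
  expect_warning(lateralRDF(traj, makeSelection(top, 2:(n + 1)),
                            rBreaks = seq(0, 80, by = 5)), "truncated")
})

test_that("g(r) is intensive: doubling particle numbers leaves it unchanged", {
  set.seed(95)
  mkU <- function(n) {
    top <- testTopology(n + 1, role = c("protein", rep("other", n)),
                        molid = c(1L, rep(2L, n)))
    xyz <- array(stats::runif((n + 1) * 3 * 40, 0, 60), c(n + 1, 3, 40))
    xyz[1, , ] <- 30
    lateralRDF(makeTraj(xyz, top, box = c(60, 60, 60)),
               makeSelection(top, 2:(n + 1)), rBreaks = seq(4, 28, by = 4))
  }
  g1 <- mkU(1500L); g2 <- mkU(3000L)
  expect_true(all(abs(g1$g - g2$g) < 0.15))
})

test_that("OpenDX export round-trips the voxel data layout", {
  top <- testTopology(1)
  xyz <- array(c(1.5, 2.5, 0.5), c(1, 3, 4))
  g <- occupancyGrid(makeTraj(xyz, top, box = c(3, 3, 2)),
                     makeSelection(top, 1L), 1)
  path <- withr::local_tempfile(fileext = ".dx")
  writeOpenDX(g, path)
  lines <- readLines(path)
  expect_match(lines[1], "counts 3 3 2")
  dataStart <- grep("data follows", lines) + 1
  vals <- as.numeric(unlist(strsplit(
    lines[dataStart:(dataStart + ceiling(18 / 3) - 1)], " ")))
  arr <- aperm(array(vals, c(2, 3, 3)), c(3, 2, 1))  # z fastest in the file
  expect_equal(arr, unname(g@occupancy))
  expect_equal(arr[2, 3, 1], 1)
})
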