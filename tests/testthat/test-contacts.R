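test_that("contact detection respects the cutoff on either side", {
  # one single-bead residue and one single-bead lipid at controlled distance
  top <- testTopology(2, name = c("CA", "Q0"), resid = c(1L, 2L),
                      resname = c("GLY", "LIN"), molid = c(1L, 2L),
                      species = c("PROT", "LIN"),
                      role = c("protein", "lipid_head"), elem = c("C", "bead"))
  mk <- function(d) makeTraj(array(rbind(c(10, 10, 10), c(10 + d, 10, 10)),
                                   c(2, 3, 1)), top, box = c(40, 40, 40))
  near <- computeContactTensor(mk(5.9), "LIN", cutoff = 6)
  far <- computeContactTensor(mk(6.1), "LIN", cutoff = 6)
  expect_true(near@presence[1, 1, 1])
  expect_false(far@presence[1, 1, 1])
  expect_error(computeContactTensor(mk(5), "POPC"), "unknown species")
})

test_that("contact tensor matches a brute-force all-pairs scan", {
  set.seed(21)
  spec <- smallFixtureSpec(nFrames = 60L, box = c(60, 60, 40),
                           residuesPerSubunit = 3L, residueSpacing = 4,
                           nLipidsPerSpecies = c(LIN = 3L, STE = 2L),
                           outerPerSpecies = c(LIN = 2L, STE = 1L),
                           sites = list(syntheticSiteSpec("I", 2L)),
                           leafletOffset = 5, diffusionSigma = 2)
  sim <- simulateLipidTrajectory(spec)
  traj <- sim$trajectory
  a <- atoms(traj)
  for (mode in c("whole_lipid", "headgroup_only")) {
    tensor <- computeContactTensor(traj, "LIN", cutoff = 6, mode = mode)
    roles <- if (mode == "headgroup_only") "lipid_head"
             else c("lipid_head", "lipid_tail")
    lipSel <- which(a$species == "LIN" & a$role %in% roles)
    protSel <- which(a$role == "protein")
    mols <- sort(unique(a$molid[lipSel]))
    for (f in c(1L, 17L, 42L, 60L)) {
      brute <- oracleContactFrame(
        traj@coords[, , f], traj@box[f, ],
        lipSel, match(a$molid[lipSel], mols),
        protSel, match(a$resid[protSel], unique(a$resid[protSel])), 6)
      expect_identical(unname(tensor@presence[f, , ]), unname(brute))
    }
  }
})

test_that("head-group contact implies whole-lipid contact frame-wise", {
  sim <- simulateLipidTrajectory(smallFixtureSpec(nFrames = 400L))
  hg <- computeContactTensor(sim$trajectory, "LIN", mode = "headgroup_only")
  wl <- computeContactTensor(sim$trajectory, "LIN", mode = "whole_lipid")
  expect_true(all(wl@presence[hg@presence]))
})

test_that("lipid counting matches a per-frame recount and window rules hold", {
  sim <- simulateLipidTrajectory(smallFixtureSpec(nFrames = 500L))
  traj <- sim$trajectory
  cc <- countLipidsNearProtein(traj, "LIN", cutoff = 6, window = 10)
  # brute-force recount on a few frames
  a <- atoms(traj)
  heads <- which(a$species == "LIN" & a$role == "lipid_head")
  prot <- which(a$role == "protein")
  for (f in c(3L, 250L, 499L)) {
    n <- 0L
    for (h in heads) {
      hit <- FALSE
      for (p in prot) {
        if (minimumImageDistance(traj@coords[h, , f], traj@coords[p, , f],
                                 traj@box[f, ]) <= 6) { hit <- TRUE; break }
      }
      n <- n + hit
    }
    expect_identical(cc$count[f], as.numeric(n))
  }
  # a constant series has a constant running average
  cc2 <- data.frame(count = rep(3, 100))
  w <- 11
  ra <- as.numeric(stats::filter(cc2$count, rep(1 / w, w), sides = 2))
  expect_equal(ra[!is.na(ra)], rep(3, 100 - w + 1))
  expect_error(countLipidsNearProtein(traj, "LIN", window = 0.1),
               "window")
})

test_that("residue statistics follow the union / longest-run definitions", {
  # lipid A [1,1,0,1], lipid B [0,1,1,0], dt = 0.5 ns
  p <- array(FALSE, c(4, 2, 1))
  p[, 1, 1] <- c(TRUE, TRUE, FALSE, TRUE)
  p[, 2, 1] <- c(FALSE, TRUE, TRUE, FALSE)
  st <- residueStats(makeTensor(p, dt = 0.5))
  expect_equal(st$totalTime, 2.0)       # union: all 4 frames -> 2 ns
  expect_equal(st$longestLifetime, 1.0) # longest per-pair run: 2 frames
  # sum variant counts simultaneous contacts multiply
  expect_equal(residueStats(makeTensor(p, dt = 0.5),
                            sumOverLipids = TRUE)$totalTime, 2.5)
  # no contacts
  expect_equal(residueStats(makeTensor(array(FALSE, c(4, 2, 1))))$totalTime, 0)
  # full-duration contact equals the trajectory duration
  pf <- array(TRUE, c(100, 1, 1))
  expect_equal(residueStats(makeTensor(pf, dt = 0.5))$longestLifetime, 50)
})

test_that("residue and lipid statistics match brute-force scans on random tensors", {
  set.seed(33)
  for (rep in seq_len(60)) {
    d <- c(sample(5:50, 1), sample(1:3, 1), sample(1:4, 1))
    p <- array(stats::runif(prod(d)) < stats::runif(1, 0.1, 0.7), d)
    tens <- makeTensor(p, dt = 0.5)
    st <- residueStats(tens)
    or <- oracleResidueStats(p, 0.5)
    expect_equal(st$totalTime, or$total)
    expect_equal(st$longestLifetime, or$longest)
    ls <- lipidInteractionStats(tens)
    ol <- oracleLipidStats(p, 0.5)
    expect_equal(ls$totalTime, ol$total)
    expect_equal(ls$longestLifetime, ol$longest)
    # invariants: longest <= total <= duration; union <= sum over lipids
    expect_true(all(st$longestLifetime <= st$totalTime + 1e-12))
    expect_true(all(st$totalTime <= d[1] * 0.5 + 1e-12))
    expect_true(all(st$totalTime <=
                      residueStats(tens, sumOverLipids = TRUE)$totalTime + 1e-12))
  }
})

test_that("lifetime gap tolerance bridges short interruptions only", {
  p <- array(c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE), c(8, 1, 1))
  expect_equal(residueStats(makeTensor(p))$longestLifetime, 2)
  expect_equal(residueStats(makeTensor(p), gapTolerance = 1L)$longestLifetime, 5)
  expect_equal(residueStats(makeTensor(p), gapTolerance = 2L)$longestLifetime, 8)
})

test_that("symmetry averaging is positional and permutation invariant", {
  sm <- list(A = 1:3, B = 4:6, C = 7:9, D = 10:12)
  st <- data.frame(resid = 1:12, totalTime = c(0, 0, 0, 0, 0, 0,
                                               0, 0, 0, 4, 0, 0),
                   longestLifetime = rep(2, 12))
  avg <- symmetryAverage(st, sm)
  expect_equal(avg$totalTime, c(1, 0, 0))
  expect_equal(avg$resid, 1:3)
  # identical profiles average to themselves
  st2 <- data.frame(resid = 1:12, totalTime = rep(c(5, 1, 7), 4))
  expect_equal(symmetryAverage(st2, sm)$totalTime, c(5, 1, 7))
  # permuting subunit order leaves the result unchanged
  expect_equal(symmetryAverage(st, sm[c(3, 1, 4, 2)])$totalTime,
               avg$totalTime)
  expect_error(symmetryAverage(st, list(A = 1:3, B = 4:5)), "unequal")
})

test_that("Tukey-fence classification matches hand computation and sort oracle", {
  st <- data.frame(resid = 1:8, totalTime = c(2, 2, 2, 2, 2, 2, 2, 50),
                   longestLifetime = c(2, 2, 2, 2, 2, 2, 2, 50))
  cls <- classifyContactResidues(st)
  expect_identical(cls$highContact, 8L)
  expect_identical(cls$stableContact, 8L)
  expect_equal(cls$fences$q3, c(2, 2))
  expect_equal(cls$fences$fence, c(2, 2))
  # all equal -> no residue is strictly above the fence
  stEq <- data.frame(resid = 1:6, totalTime = rep(3, 6),
                     longestLifetime = rep(3, 6))
  expect_length(classifyContactResidues(stEq)$highContact, 0)
  expect_error(classifyContactResidues(st[1:3, ]), "4 residues")
  set.seed(44)
  for (rep in seq_len(60)) {
    n <- sample(4:60, 1)
    v <- round(stats::rexp(n, 0.2), 2)
    w <- round(stats::rexp(n, 0.5), 2)
    cl <- classifyContactResidues(data.frame(resid = seq_len(n),
                                             totalTime = v,
                                             longestLifetime = w))
    expect_identical(cl$highContact, oracleFenceSet(v, seq_len(n)))
    expect_identical(cl$stableContact, oracleFenceSet(w, seq_len(n)))
  }
})

test_that("coarser sampling of the same episodes preserves total times", {
  # halve the frame rate: totals change by < 1 frame-equivalent per episode
  set.seed(55)
  nf <- 400L
  x <- stats::runif(nf) < 0.4
  p1 <- array(x, c(nf, 1, 1))
  p2 <- array(x[seq(1, nf, by = 2)], c(nf / 2, 1, 1))
  t1 <- residueStats(makeTensor(p1, dt = 1))$totalTime
  t2 <- residueStats(makeTensor(p2, dt = 2))$totalTime
  nEpisodes <- sum(diff(c(FALSE, x)) == 1)
  expect_lt(abs(t1 - t2), nEpisodes * 1 + 2)
})
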