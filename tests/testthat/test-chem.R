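test_that("hydrogen bonds use the hydrogen-to-acceptor distance criterion", {
  base <- list(OD = c(5, 5, 5), HD = c(5.95, 5, 5), NB = c(20, 20, 20),
               C1 = c(25, 25, 25), C2 = c(28, 25, 25))
  # H at 3.4 A from the carboxylate O -> bond present
  tr1 <- aaTestTraj(c(base, list(OA1 = c(9.35, 5, 5))))
  top <- topology(tr1)
  don <- selectAtoms(top, resid = 1)
  acc <- selectAtoms(top, resid = 2)
  hb1 <- detectHBonds(tr1, don, acc)
  expect_true(any(hb1$presence))
  # H at 3.6 A -> absent
  tr2 <- aaTestTraj(c(base, list(OA1 = c(9.55, 5, 5))))
  expect_false(any(detectHBonds(tr2, don, acc)$presence))
  # no identifiable donor hydrogens (e.g. a CG selection) is an error
  expect_error(detectHBonds(tr1, selectAtoms(top, resid = 4), acc),
               "donor hydrogens")
})

test_that("salt bridges and hydrophobic contacts follow their cutoffs", {
  mk <- function(dNO, dCC) aaTestTraj(list(
    OD = c(5, 5, 5), HD = c(5.95, 5, 5), OA1 = c(12, 12, 12),
    NB = c(12 + dNO, 12, 12), C1 = c(22, 22, 22), C2 = c(22 + dCC, 22, 22)))
  tr <- mk(3.9, 3.8)
  top <- topology(tr)
  sb <- detectSaltBridges(tr, selectAtoms(top, name = "NB"),
                          selectAtoms(top, name = "OA1"))
  expect_true(all(sb$presence))
  expect_false(any(detectSaltBridges(mk(4.1, 3.8),
                                     selectAtoms(top, name = "NB"),
                                     selectAtoms(top, name = "OA1"))$presence))
  hc <- detectHydrophobicContacts(tr, selectAtoms(top, name = "C1"),
                                  selectAtoms(top, name = "C2"))
  expect_true(all(hc$presence))
  expect_false(any(detectHydrophobicContacts(
    mk(3.9, 4.2), selectAtoms(top, name = "C1"),
    selectAtoms(top, name = "C2"))$presence))
  # element-class validation
  expect_error(detectSaltBridges(tr, selectAtoms(top, name = "C1"),
                                 selectAtoms(top, name = "OA1")), "nitrogen")
  expect_error(detectHydrophobicContacts(tr, selectAtoms(top, name = "NB"),
                                         selectAtoms(top, name = "C2")),
               "carbon")
})

test_that("detections match brute-force scans on random periodic geometries", {
  set.seed(121)
  box <- c(12, 12, 12)
  for (rep in seq_len(150)) {
    pos <- lapply(stats::setNames(vector("list", 6),
                                  c("OD", "HD", "OA1", "NB", "C1", "C2")),
                  function(x) stats::runif(3, 0, 12))
    pos$HD <- pos$OD + c(0.98, 0, 0)  # keep the donor H covalently placed
    tr <- aaTestTraj(pos, box = box)
    top <- topology(tr)
    # hydrogen bond: H within 3.5 of the acceptor O under minimum image
    hb <- detectHBonds(tr, selectAtoms(top, resid = 1),
                       selectAtoms(top, resid = 2))
    expect_identical(unname(as.vector(hb$presence)),
                     oracleMinImage(pos$HD %% box, pos$OA1 %% box, box) <= 3.5)
    sb <- detectSaltBridges(tr, selectAtoms(top, name = "NB"),
                            selectAtoms(top, name = "OA1"))
    expect_identical(unname(as.vector(sb$presence)),
                     oracleMinImage(pos$NB %% box, pos$OA1 %% box, box) <= 4.0)
    hc <- detectHydrophobicContacts(tr, selectAtoms(top, name = "C1"),
                                    selectAtoms(top, name = "C2"))
    expect_identical(unname(as.vector(hc$presence)),
                     oracleMinImage(pos$C1 %% box, pos$C2 %% box, box) <= 4.0)
  }
})

test_that("detections are invariant under periodic image shifts", {
  set.seed(122)
  box <- c(15, 15, 15)
  for (rep in seq_len(30)) {
    pos <- list(OD = stats::runif(3, 0, 15), OA1 = stats::runif(3, 0, 15),
                NB = stats::runif(3, 0, 15), C1 = stats::runif(3, 0, 15),
                C2 = stats::runif(3, 0, 15))
    pos$HD <- pos$OD + c(0.98, 0, 0)
    shift <- sample(-2:2, 3, replace = TRUE) * box
    posS <- pos
    posS$OA1 <- pos$OA1 + shift
    tr <- aaTestTraj(pos, box = box); trS <- aaTestTraj(posS, box = box)
    top <- topology(tr)
    expect_identical(
      detectHBonds(tr, selectAtoms(top, resid = 1),
                   selectAtoms(top, resid = 2))$presence,
      detectHBonds(trS, selectAtoms(top, resid = 1),
                   selectAtoms(top, resid = 2))$presence)
  }
})

test_that("a close salt bridge with an intervening donor H is also an H-bond", {
  # N-H ... O at 3.3 A N-O with the H 2.4 A from O
  a <- data.frame(name = c("NZ", "HZ", "OE"), resid = c(1, 1, 2),
                  resname = c("LYS", "LYS", "GLU"), chain = "A",
                  molid = c(1, 1, 2), species = "PROT", role = "protein",
                  elem = c("N", "H", "O"), stringsAsFactors = FALSE)
  top <- new("Topology", atoms = a, bonds = matrix(c(1L, 2L), 1, 2),
             speciesTable = c(`1` = "PROT", `2` = "PROT"),
             subunitMap = list())
  xyz <- rbind(c(5, 5, 5), c(5.9, 5, 5), c(8.3, 5, 5))
  tr <- makeTraj(array(xyz, c(3, 3, 1)), top, box = c(20, 20, 20),
                 dt = NA_real_)
  sb <- detectSaltBridges(tr, selectAtoms(top, name = "NZ"),
                          selectAtoms(top, name = "OE"))
  hb <- detectHBonds(tr, selectAtoms(top, resid = 1),
                     selectAtoms(top, resid = 2))
  expect_true(all(sb$presence))
  expect_true(all(hb$presence))
})

test_that("bond time statistics share the run-length conventions", {
  series <- structure(list(
    presence = matrix(c(TRUE, TRUE, FALSE, TRUE), 4, 1),
    pairs = data.frame(i = 1L, j = 2L, iName = "a", jName = "b",
                       type = "hbond"),
    dt = 1, type = "hbond", cutoff = 3.5), class = "BondSeries")
  st <- bondTimeStats(series)
  expect_equal(st$totalTime, 3)
  expect_equal(st$longestLifetime, 2)
  series$presence[] <- FALSE
  st0 <- bondTimeStats(series)
  expect_equal(st0$totalTime, 0)
  expect_equal(st0$longestLifetime, 0)
  # random series against the oracle, per pair and as a union
  set.seed(123)
  for (rep in seq_len(40)) {
    nf <- sample(5:40, 1); np <- sample(1:4, 1)
    m <- matrix(stats::runif(nf * np) < 0.5, nf, np)
    s <- structure(list(presence = m,
                        pairs = data.frame(i = seq_len(np), j = 1L,
                                           iName = letters[seq_len(np)],
                                           jName = "x", type = "hbond"),
                        dt = 2, type = "hbond", cutoff = 3.5),
                   class = "BondSeries")
    st <- bondTimeStats(s)
    for (k in seq_len(np)) {
      o <- oracleRunStats(m[, k])
      expect_equal(st$totalTime[k], o[["total"]] * 2)
      expect_equal(st$longestLifetime[k], o[["longest"]] * 2)
    }
    u <- bondTimeStats(s, union = TRUE)
    ou <- oracleRunStats(rowSums(m) > 0)
    expect_equal(u$totalTime, ou[["total"]] * 2)
  }
})
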