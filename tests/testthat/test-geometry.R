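# Single-structure geometry: PDB I/O, lock/cage/TM3-TM6 metrics,
# superposition.

test_that("PDB write/read round-trips a bundle to coordinate precision", {
  b <- build_bundle()
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b, tmp)
  b2 <- read_structure(tmp)
  expect_equal(nrow(b2$atoms), nrow(b$atoms))
  expect_equal(b2$atoms$resno, b$atoms$resno)
  expect_equal(b2$atoms$elety, b$atoms$elety)
  expect_equal(as.matrix(b2$atoms[c("x", "y", "z")]),
               as.matrix(b$atoms[c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)  # PDB prints 3 decimals
})

test_that("multi-MODEL files become trajectories with shared topology", {
  tr <- gen_trajectory(n_frames = 3, noise_sd = 0.2, seed = 5)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tr, tmp)
  tr2 <- read_structure(tmp)
  expect_s3_class(tr2, "gpcr_trajectory")
  expect_equal(n_frames(tr2), 3)
  expect_equal(tr2$atoms$elety, tr$atoms$elety)
  expect_equal(tr2$frames[[2]], tr$frames[[2]], tolerance = 1e-3)
})

test_that("alternate locations keep the highest occupancy, ties keep A", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AGLY A   2       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   2       8.000   0.000   0.000  0.50  0.00           C",
    "END"), tmp)
  s <- read_structure(tmp)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x, c(9, 1))  # B wins on occupancy; tie goes to A
})

test_that("missing files and malformed PDB content raise errors", {
  expect_error(read_structure("no/such/file.pdb"), "no such file")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines("not a pdb record at all", tmp)
  expect_error(suppressWarnings(read_structure(tmp)))
})

test_that("ionic lock measures the nearest donor hydrogen", {
  # OG at origin, nearest H at (2,0,0) on NH1 at (3,0,0): collinear N-H-O
  s <- make_structure(
    list("CA", "ARG", 119, 6, 0, 0), list("NH1", "ARG", 119, 3, 0, 0),
    list("NE", "ARG", 119, 4.3, 0, 0), list("NH2", "ARG", 119, 3.5, 1.2, 0),
    list("HH11", "ARG", 119, 2, 0, 0), list("HH12", "ARG", 119, 3, 1, 0),
    list("CA", "SER", 230, -2, 0, 0), list("OG", "SER", 230, 0, 0, 0))
  s <- attach_numbering(s, toy_map())
  g <- ionic_lock(s)
  expect_equal(g$h_distance, 2.0)
  expect_equal(g$no_distance, 3.0)
  expect_equal(g$nho_angle, 180)
  expect_true(g$has_hydrogens)
})

test_that("hydrogen-free models degrade to the heavy-atom distance", {
  s <- make_structure(
    list("CA", "ARG", 119, 6, 0, 0), list("NH1", "ARG", 119, 3, 0, 0),
    list("NE", "ARG", 119, 4.3, 0, 0),
    list("CA", "SER", 230, -2, 0, 0), list("OG", "SER", 230, 0, 0, 0))
  s <- attach_numbering(s, toy_map())
  g <- ionic_lock(s)
  expect_false(g$has_hydrogens)
  expect_true(is.na(g$h_distance))
  expect_equal(g$no_distance, 3.0)
})

test_that("randomized side-chain poses match exhaustive pair enumeration", {
  set.seed(9)
  for (rep in 1:10) {
    hpos <- matrix(rnorm(9, sd = 0.4), 3, 3) +
      matrix(rep(c(3, 0, 0), each = 3), 3, 3)
    # keep hydrogens covalently attached to NH1 at (3,0,0)
    hpos <- t(apply(hpos, 1, function(p) c(3, 0, 0) + 1.0 * (p - c(3, 0, 0)) /
                      sqrt(sum((p - c(3, 0, 0))^2))))
    s <- make_structure(
      list("CA", "ARG", 119, 6, 0, 0), list("NH1", "ARG", 119, 3, 0, 0),
      list("HH11", "ARG", 119, hpos[1, 1], hpos[1, 2], hpos[1, 3]),
      list("HH12", "ARG", 119, hpos[2, 1], hpos[2, 2], hpos[2, 3]),
      list("HH21", "ARG", 119, hpos[3, 1], hpos[3, 2], hpos[3, 3]),
      list("CA", "SER", 230, -2, 0, 0), list("OG", "SER", 230, 0, 0, 0))
    s <- attach_numbering(s, toy_map())
    g <- ionic_lock(s)
    brute <- min(sqrt(rowSums(hpos^2)))  # OG is at the origin
    expect_equal(g$h_distance, brute)
    expect_true(all(g$h_distance <= sqrt(rowSums(hpos^2)) + 1e-12))
  }
})

test_that("aspartate cage takes the minimum N-O pair, symmetric in labels", {
  s <- make_structure(
    list("CA", "ARG", 119, 2, 0, 0), list("NH1", "ARG", 119, 0, 0, 0),
    list("NE", "ARG", 119, 5, 0, 5),
    list("CA", "ASP", 118, 2, 2, 2), list("OD1", "ASP", 118, 0, 0, 2.8),
    list("OD2", "ASP", 118, 0, 0, 4.5))
  map <- toy_map()
  s <- attach_numbering(s, map)
  g <- aspartate_cage(s)
  expect_equal(g$distance, 2.8)
  expect_true(g$salt_bridge)
  expect_equal(g$pair, c("NH1", "OD1"))
  # swapping the carboxylate oxygen labels changes nothing
  s2 <- s
  s2$atoms$elety[s2$atoms$elety == "OD1"] <- "TMP"
  s2$atoms$elety[s2$atoms$elety == "OD2"] <- "OD1"
  s2$atoms$elety[s2$atoms$elety == "TMP"] <- "OD2"
  expect_equal(aspartate_cage(s2)$distance, 2.8)
})

test_that("TM3-TM6 distance agrees with exhaustive pairing oracles", {
  b <- build_bundle(bundle_spec(tm3_tm6 = 11.0))
  p3 <- t(sapply(sprintf("3.%d", 51:55), function(g) gpcrstars:::ca_xyz(b, g)))
  p6 <- t(sapply(sprintf("6.%d", 30:34), function(g) gpcrstars:::ca_xyz(b, g)))
  dm <- as.matrix(dist(rbind(p3, p6)))[1:5, 6:10]
  expect_equal(as.numeric(tm3_tm6_distance(b, "paired")),
               mean(dm[cbind(1:5, 5:1)]))
  expect_equal(as.numeric(tm3_tm6_distance(b, "index")),
               mean(diag(dm)))
  expect_equal(as.numeric(tm3_tm6_distance(b, "all-pairs")), mean(dm))
  # all-pairs mean bounded by the extreme pair distances
  ap <- as.numeric(tm3_tm6_distance(b, "all-pairs"))
  expect_true(ap >= min(dm) && ap <= max(dm))
})

test_that("degenerate constant-separation stubs give d in every mode", {
  rows <- c(
    lapply(121:125, function(r) list("CA", "ALA", r, 0, 0, 0)),
    lapply(243:247, function(r) list("CA", "ALA", r, 11, 0, 0)))
  s <- do.call(make_structure, rows)
  map <- build_numbering(anchor_set(data.frame(
    segment = c(3, 6), start = c(120, 243), end = c(125, 263),
    anchor = c(120, 263))))
  s <- attach_numbering(s, map)
  for (mode in c("paired", "index", "all-pairs"))
    expect_equal(as.numeric(tm3_tm6_distance(s, mode)), 11)
})

test_that("state classification is monotone with the published regimes", {
  expect_equal(classify_state(11.0), "inactive")
  expect_equal(classify_state(15.28), "active")
  expect_equal(classify_state(13.0), "intermediate-ambiguous")
  d <- seq(8, 18, by = 0.25)
  lab <- classify_state(d)
  rankv <- c(inactive = 1, `intermediate-ambiguous` = 2, active = 3)[lab]
  expect_true(all(diff(rankv) >= 0))
})

test_that("Kabsch superposition matches the bio3d reference to 1e-8", {
  set.seed(21)
  for (rep in 1:5) {
    Q <- matrix(rnorm(30, sd = 5), 10, 3)
    P <- rigid_motion(gpcr_structure(data.frame(
      elety = "CA", resid = "ALA", chain = "A", resno = 1:10,
      insert = NA, x = Q[, 1], y = Q[, 2], z = Q[, 3])), seed = rep)
    P <- as.matrix(P$atoms[c("x", "y", "z")]) + matrix(rnorm(30, sd = 0.3), 10, 3)
    fit <- superpose(P, Q)
    mfit <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(Q)),
                                            mobile = as.vector(t(P))))
    ref_rmsd <- sqrt(mean(rowSums((matrix(mfit, ncol = 3, byrow = TRUE) -
                                     Q)^2)))
    expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
    # transform convention: fitted = mobile %*% R + t
    expect_equal(fit$fitted,
                 sweep(P %*% fit$rotation, 2, fit$translation, `+`),
                 ignore_attr = TRUE)
  }
})

test_that("superposition is exact on rigid copies and rejects degeneracy", {
  Q <- matrix(rnorm(24), 8, 3)
  expect_equal(superpose(Q, Q)$rmsd, 0, tolerance = 1e-12)
  s <- gpcr_structure(data.frame(elety = "CA", resid = "ALA", chain = "A",
                                 resno = 1:8, insert = NA,
                                 x = Q[, 1], y = Q[, 2], z = Q[, 3]))
  P <- as.matrix(rigid_motion(s, seed = 4)$atoms[c("x", "y", "z")])
  expect_equal(superpose(P, Q)$rmsd, 0, tolerance = 1e-8)
  expect_error(superpose(Q[1:2, ], Q[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("all geometry metrics are rigid-motion invariant", {
  b <- build_bundle(bundle_spec(tm3_tm6 = 11.5, lock = 2.4, cage = 3.1))
  b2 <- rigid_motion(b, seed = 13)
  expect_equal(ionic_lock(b2)$h_distance, ionic_lock(b)$h_distance,
               tolerance = 1e-9)
  expect_equal(cage_distance(b2), cage_distance(b), tolerance = 1e-9)
  expect_equal(tm3_tm6(b2), tm3_tm6(b), tolerance = 1e-9)
})
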