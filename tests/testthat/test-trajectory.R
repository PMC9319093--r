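# Per-frame metric series, RMSD vs frame 1, interaction fingerprints.

test_that("metric series commute with single-frame evaluation", {
  tr <- gen_trajectory(n_frames = 4, noise_sd = 0.15, seed = 2)
  ms <- metric_series(tr, tm3_tm6, name = "tm3_tm6")
  expect_equal(nrow(ms), 4)
  expect_equal(ms$time_ps, c(0, 100, 200, 300))
  per_frame <- vapply(1:4, function(i) tm3_tm6(frame_structure(tr, i)),
                      numeric(1))
  expect_equal(ms$value, per_frame)
})

test_that("noise-free trajectories give constant series", {
  tr <- gen_trajectory(n_frames = 3, noise_sd = 0, seed = 1)
  for (metric in list(lock_distance, cage_distance, tm3_tm6)) {
    ms <- metric_series(tr, metric)
    expect_equal(ms$value, rep(ms$value[1], 3))
  }
})

test_that("drifted generator targets are recovered at the series endpoints", {
  tr <- gen_trajectory(bundle_spec(), n_frames = 10, noise_sd = 0,
                       drift = list(tm3_tm6 = c(11, 13), lock = c(2, 3)),
                       seed = 3)
  ms <- metric_series(tr, tm3_tm6)
  expect_equal(ms$value[1], 11, tolerance = 1e-6)
  expect_equal(ms$value[10], 13, tolerance = 1e-6)
  ml <- metric_series(tr, lock_distance)
  expect_equal(ml$value[1], 2, tolerance = 1e-6)
  expect_equal(ml$value[10], 3, tolerance = 1e-6)
})

test_that("per-frame metric failures become gaps, frame-1 failure is fatal", {
  tr <- gen_trajectory(n_frames = 3, seed = 1)
  boom <- local({
    n <- 0
    function(s) { n <<- n + 1; if (n == 2) stop("frame 2 broken") else 1.0 }
  })
  ms <- metric_series(tr, boom)
  expect_equal(ms$value, c(1, NA, 1))
  expect_error(metric_series(tr, function(s) stop("dead on arrival")),
               "dead on arrival")
})

test_that("RMSD series is zero for rigid-motion trajectories", {
  b <- build_bundle()
  frames <- c(list(b), lapply(2:5, function(i) rigid_motion(b, seed = i)))
  tr <- as_trajectory(frames)
  rs <- rmsd_series(tr)
  expect_equal(rs$value, rep(0, 5), tolerance = 1e-8)
})

test_that("RMSD series matches a direct bio3d recomputation", {
  tr <- gen_trajectory(n_frames = 6, noise_sd = 0.3, seed = 8)
  rs <- rmsd_series(tr)
  expect_equal(rs$value[1], 0)
  sel <- which(tr$atoms$elety == "CA")
  ref <- tr$frames[[1]][sel, ]
  oracle <- vapply(2:6, function(i)
    oracle_fit_rmsd(ref, tr$frames[[i]][sel, ]), numeric(1))
  expect_equal(rs$value[-1], oracle, tolerance = 1e-8)
})

test_that("mean RMSD of an iid-noise trajectory is near sigma * sqrt(6)", {
  # both frames carry iid N(0, sigma^2) per coordinate, so each atom's
  # displacement variance is 2 sigma^2 per axis and E[RMSD^2] ~ 6 sigma^2
  sigma <- 0.2
  tr <- gen_trajectory(n_frames = 20, noise_sd = sigma, seed = 12)
  rs <- rmsd_series(tr)
  expect_equal(mean(rs$value[-1]), sigma * sqrt(6), tolerance = 0.1)
})

test_that("topology mismatches are rejected", {
  b <- build_bundle()
  b2 <- b
  b2$atoms <- b2$atoms[-5, ]
  expect_error(as_trajectory(list(b, b2)), "topology mismatch")
})

test_that("hydrogen bonds, hydrophobic and aromatic contacts are detected", {
  # ligand carbonyl O at 3.4 A from a backbone-style N; a C-C pair at 3.8 A;
  # a ligand phenyl ring 5.0 A from a protein PHE ring
  ring <- function(center, resno, resname, names) {
    lapply(seq_along(names), function(i) {
      th <- 2 * pi * (i - 1) / length(names)
      list(names[i], resname, resno,
           center[1] + 1.4 * cos(th), center[2] + 1.4 * sin(th), center[3])
    })
  }
  phe_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  rows <- c(
    list(list("N", "ALA", 10, 0, 0, 0),
         list("CB", "ALA", 11, 10, 0, 0),
         list("O1", "LIG", 500, 3.4, 0, 0),
         list("C1", "LIG", 500, 10, 3.8, 0)),
    ring(c(30, 0, 0), 12, "PHE", phe_names),
    ring(c(30, 0, 5), 500, "LIG", phe_names))
  s <- do.call(make_structure, rows)
  fp <- interaction_fingerprint(s, ligand_resno = 500,
                                ligand_rings = list(phe_names))
  expect_true(any(fp$resno == 10 & fp$class == "hbond"))
  expect_true(any(fp$resno == 11 & fp$class == "hydrophobic"))
  expect_true(any(fp$resno == 12 & fp$class == "aromatic"))
})

test_that("distant atoms produce an empty fingerprint", {
  s <- make_structure(list("N", "ALA", 1, 0, 0, 0),
                      list("O1", "LIG", 500, 50, 50, 50),
                      list("C1", "LIG", 500, 52, 50, 50))
  fp <- interaction_fingerprint(s, 500)
  expect_equal(nrow(fp), 0)
})

test_that("random frames match a brute-force all-pairs contact scan", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 14
    atoms <- data.frame(
      elety = sample(c("N", "O", "C1", "C2", "S"), n, replace = TRUE),
      resid = "ALA", chain = "A", resno = rep(1:7, each = 2),
      insert = NA, x = runif(n, 0, 10), y = runif(n, 0, 10),
      z = runif(n, 0, 10))
    atoms$resid[atoms$resno == 7] <- "LIG"
    atoms$elety <- make.unique(atoms$elety)  # unique names within residues
    s <- gpcr_structure(atoms)
    fp <- interaction_fingerprint(s, 7)
    # brute-force scan (no hydrogens anywhere, so angles do not apply)
    lig <- s$atoms[s$atoms$resno == 7, ]
    prot <- s$atoms[s$atoms$resno != 7, ]
    want <- list()
    for (i in seq_len(nrow(lig))) for (j in seq_len(nrow(prot))) {
      d <- sqrt(sum((unlist(lig[i, c("x", "y", "z")]) -
                       unlist(prot[j, c("x", "y", "z")]))^2))
      if (lig$elesy[i] %in% c("N", "O", "S") &&
          prot$elesy[j] %in% c("N", "O", "S") && d <= 3.5)
        want[[length(want) + 1]] <- c(prot$resno[j], "hbond")
      if (lig$elesy[i] == "C" && prot$elesy[j] == "C" && d <= 4.0)
        want[[length(want) + 1]] <- c(prot$resno[j], "hydrophobic")
    }
    want <- unique(do.call(rbind, want))
    expect_equal(nrow(fp), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want))
      expect_setequal(paste(fp$resno, fp$class),
                      paste(as.integer(want[, 1]), want[, 2]))
  }
})

test_that("persistence tallies contact fractions, order-invariantly", {
  fp_on <- data.frame(resno = 174L, class = "hbond")
  fp_off <- data.frame(resno = integer(0), class = character(0))
  fps <- c(rep(list(fp_on), 5), rep(list(fp_off), 5))
  p <- persistence(fps)
  expect_equal(p$fraction, 0.5)
  expect_equal(persistence(rev(fps)), p)
  expect_equal(persistence(rep(list(fp_on), 3))$fraction, 1.0)
  # random fingerprints against a counting oracle
  set.seed(5)
  fps <- lapply(1:12, function(i) {
    k <- sample(0:3, 1)
    data.frame(resno = sample(100:103, k), class = sample(c("hbond",
      "hydrophobic"), k, replace = TRUE))
  })
  p <- persistence(fps)
  for (r in seq_len(nrow(p))) {
    cnt <- sum(vapply(fps, function(fp)
      any(fp$resno == p$resno[r] & fp$class == p$class[r]), logical(1)))
    expect_equal(p$fraction[r], cnt / 12)
  }
})
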