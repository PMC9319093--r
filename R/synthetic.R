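# Synthetic-data generators.
#
# Everything the analysis stages consume can be produced here without
# downloads: idealized 7-TM Calpha bundles whose ionic-lock / cage / TM3-TM6
# geometry hits requested targets, noisy multi-frame trajectories of such
# bundles, quality-score tables with star totals known by construction, and
# two-class docking-score tables with an analytically known AUC.

unit <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Specification of a synthetic 7-TM bundle
#'
#' Ideal alpha-helical Calpha traces (1.5 A rise and 100 degrees twist per
#' residue, 2.3 A helix radius) for the seven TM segments of an anchor set,
#' axes placed on a circle; inter-loop segments are bridged by straight
#' interpolation. Pseudo side-chain atoms for the ionic-lock and
#' aspartate-cage residues (OG on S6.33; NE/NH1/NH2 plus polar hydrogens on
#' R3.50; OD1/OD2 on D3.49) are placed by constrained geometry so the
#' measured metrics equal the requested targets exactly.
#'
#' @param tm3_tm6 target cytoplasmic TM3-TM6 distance in Angstrom
#'   ("paired" mode; default 11, an inactive-state value). `NA` leaves the
#'   raw circular placement.
#' @param lock target ionic-lock H...O distance in Angstrom (default 2.0).
#'   `NA` places a canonically extended arginine side chain instead and
#'   lets the distance fall where it falls.
#' @param cage target R3.50-D3.49 heteroatom distance in Angstrom
#'   (default 2.8).
#' @param anchors anchor set defining segments and spans (default
#'   [gpr18_anchors()]).
#' @param circle_radius bundle radius in Angstrom (default 11.5).
#' @param helix_radius,rise,twist ideal helix parameters (2.3 A, 1.5
#'   A/residue, 100 degrees/residue).
#' @param hydrogens place polar hydrogens on the arginine (default `TRUE`).
#' @return A `bundle_spec` list.
#' @export
bundle_spec <- function(tm3_tm6 = 11, lock = 2.0, cage = 2.8,
                        anchors = gpr18_anchors(), circle_radius = 11.5,
                        helix_radius = 2.3, rise = 1.5, twist = 100,
                        hydrogens = TRUE) {
  for (t in list(tm3_tm6, lock, cage))
    if (!is.na(t) && t <= 0) stop("geometry targets must be positive")
  structure(list(tm3_tm6 = tm3_tm6, lock = lock, cage = cage,
                 anchors = anchors, circle_radius = circle_radius,
                 helix_radius = helix_radius, rise = rise, twist = twist,
                 hydrogens = hydrogens),
            class = "bundle_spec")
}

# Calpha trace of one ideal helix. dir = -1: extracellular (+z) to
# cytoplasmic (-z) as seqnum grows; +1 the other way (odd/even TM parity).
helix_trace <- function(n, axis_xy, phase, dir, helix_radius, rise, twist) {
  i <- seq_len(n) - (n + 1) / 2
  theta <- phase + (seq_len(n) - 1) * twist * pi / 180
  cbind(axis_xy[1] + helix_radius * cos(theta),
        axis_xy[2] + helix_radius * sin(theta),
        dir * rise * i)
}

#' Build a synthetic 7-TM bundle structure
#'
#' @param spec a [bundle_spec()].
#' @return A `gpcr_structure` (numbering map attached) of Calpha atoms plus
#'   the motif pseudo side-chain atoms, with residue names set for the
#'   ionic-lock/cage residues (ARG 3.50, ASP 3.49, SER 6.33) and ALA
#'   elsewhere.
#' @export
build_bundle <- function(spec = bundle_spec()) {
  stopifnot(inherits(spec, "bundle_spec"))
  map <- build_numbering(spec$anchors)
  seg <- spec$anchors$segments
  tm <- seg[seg$segment %in% 1:7, , drop = FALSE]
  loops <- seg[!seg$segment %in% 1:7, , drop = FALSE]

  helices <- list()
  for (i in seq_len(nrow(tm))) {
    k <- tm$segment[i]
    n <- tm$end[i] - tm$start[i] + 1
    axis_phase <- 2 * pi * (k - 1) / 7
    axis_xy <- spec$circle_radius * c(cos(axis_phase), sin(axis_phase))
    dir <- if (k %% 2 == 1) -1 else 1
    xyz <- helix_trace(n, axis_xy, axis_phase, dir,
                       spec$helix_radius, spec$rise, spec$twist)
    helices[[as.character(k)]] <-
      data.frame(resno = tm$start[i]:tm$end[i],
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }

  # shift TM6 as a rigid unit until the paired cytoplasmic distance meets
  # the target (mean pair distance is monotone along the shift direction)
  res35x <- unname(lookup_residue(map, sprintf("3.%d", 51:55)))
  res63x <- unname(lookup_residue(map, sprintf("6.%d", 34:30)))  # paired order
  if (!is.na(spec$tm3_tm6)) {
    for (iter in 1:60) {
      p3 <- as.matrix(helices[["3"]][match(res35x, helices[["3"]]$resno),
                                     c("x", "y", "z")])
      p6 <- as.matrix(helices[["6"]][match(res63x, helices[["6"]]$resno),
                                     c("x", "y", "z")])
      d <- mean(sqrt(rowSums((p3 - p6)^2)))
      if (abs(d - spec$tm3_tm6) < 1e-9) break
      shift <- (spec$tm3_tm6 - d) * unit(colMeans(p6) - colMeans(p3))
      helices[["6"]]$x <- helices[["6"]]$x + shift[1]
      helices[["6"]]$y <- helices[["6"]]$y + shift[2]
      helices[["6"]]$z <- helices[["6"]]$z + shift[3]
    }
    if (abs(d - spec$tm3_tm6) > 0.05)
      stop("TM3-TM6 placement did not converge to the target")
  }

  # loop residues: straight interpolation between flanking helix ends
  loop_rows <- list()
  helix_ca <- do.call(rbind, helices)
  for (i in seq_len(nrow(loops))) {
    lo <- loops[i, ]
    prev_end <- max(helix_ca$resno[helix_ca$resno < lo$start])
    next_start <- min(helix_ca$resno[helix_ca$resno > lo$end])
    a <- unlist(helix_ca[helix_ca$resno == prev_end, c("x", "y", "z")])
    b <- unlist(helix_ca[helix_ca$resno == next_start, c("x", "y", "z")])
    frac <- (lo$start:lo$end - prev_end) / (next_start - prev_end)
    loop_rows[[i]] <- data.frame(resno = lo$start:lo$end,
                                 x = a[1] + frac * (b[1] - a[1]),
                                 y = a[2] + frac * (b[2] - a[2]),
                                 z = a[3] + frac * (b[3] - a[3]))
  }
  ca <- rbind(helix_ca, do.call(rbind, loop_rows))
  ca <- ca[order(ca$resno), , drop = FALSE]

  res_arg <- unname(lookup_residue(map, "3.50"))
  res_asp <- unname(lookup_residue(map, "3.49"))
  res_ser <- unname(lookup_residue(map, "6.33"))
  resid <- rep("ALA", nrow(ca))
  resid[ca$resno == res_arg] <- "ARG"
  resid[ca$resno == res_asp] <- "ASP"
  resid[ca$resno == res_ser] <- "SER"
  atoms <- data.frame(elety = "CA", resid = resid, chain = spec$anchors$chain,
                      resno = ca$resno, insert = NA_character_,
                      x = ca$x, y = ca$y, z = ca$z,
                      stringsAsFactors = FALSE)

  ca_of <- function(resno) unlist(ca[ca$resno == resno, c("x", "y", "z")])
  ca350 <- ca_of(res_arg); ca633 <- ca_of(res_ser)
  u <- unit(ca633 - ca350)
  w1 <- cross3(u, c(0, 0, 1))
  if (sqrt(sum(w1^2)) < 1e-6) w1 <- cross3(u, c(1, 0, 0))
  w1 <- unit(w1)
  w2 <- unit(cross3(u, w1))

  og <- ca633 - 1.5 * u
  if (!is.na(spec$lock)) {
    h1 <- og - spec$lock * u
    nh1 <- h1 - 1.0 * u
  } else {
    nh1 <- ca350 + 5.5 * u
    h1 <- nh1 + 1.0 * u
  }
  reach <- sum((nh1 - ca350) * u)
  if (reach < 0.5 || sqrt(sum((nh1 - ca350)^2)) > 7.0)
    stop("infeasible lock target: arginine cannot reach ",
         "(requested H...O ", spec$lock, " A across a ",
         round(sqrt(sum((ca633 - ca350)^2)), 2), " A Calpha gap)")
  ne <- nh1 - 1.35 * u
  nh2 <- nh1 - 1.2 * w1
  cage <- if (is.na(spec$cage)) 2.8 else spec$cage
  od1 <- nh1 + cage * w1
  od2 <- od1 + 1.4 * w2

  sc <- function(elety, resno, resname, xyz)
    data.frame(elety = elety, resid = resname, chain = spec$anchors$chain,
               resno = resno, insert = NA_character_,
               x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  extra <- rbind(
    sc("OG", res_ser, "SER", og),
    sc("NE", res_arg, "ARG", ne),
    sc("NH1", res_arg, "ARG", nh1),
    sc("NH2", res_arg, "ARG", nh2),
    sc("OD1", res_asp, "ASP", od1),
    sc("OD2", res_asp, "ASP", od2))
  if (spec$hydrogens)
    extra <- rbind(extra,
                   sc("HH11", res_arg, "ARG", h1),
                   sc("HH12", res_arg, "ARG", nh1 + 1.0 * w2),
                   sc("HE", res_arg, "ARG", ne + 1.0 * w2))
  atoms <- rbind(atoms, extra)
  atoms <- atoms[order(atoms$resno, atoms$elety != "CA"), , drop = FALSE]
  gpcr_structure(atoms, map = map)
}

#' Generate a noisy synthetic trajectory
#'
#' Frames are rebuilt bundles whose geometry targets follow linear drifts,
#' with iid Gaussian displacement added to every coordinate. Deterministic
#' given the seed.
#'
#' @param spec a [bundle_spec()] giving the frame-1 targets.
#' @param n_frames number of frames (>= 1).
#' @param noise_sd per-coordinate Gaussian noise, Angstrom (default 0).
#' @param drift named list of length-2 numeric vectors `c(start, end)` for
#'   any of `tm3_tm6`, `lock`, `cage`; each target is interpolated linearly
#'   across frames.
#' @param seed RNG seed.
#' @param interval_ps frame spacing in picoseconds (default 100).
#' @return A `gpcr_trajectory`.
#' @export
gen_trajectory <- function(spec = bundle_spec(), n_frames = 11,
                           noise_sd = 0, drift = NULL, seed = 1,
                           interval_ps = 100) {
  stopifnot(n_frames >= 1, noise_sd >= 0)
  if (!is.null(drift)) {
    bad <- setdiff(names(drift), c("tm3_tm6", "lock", "cage"))
    if (length(bad)) stop("unknown drift target(s): ", paste(bad, collapse = ", "))
  }
  set.seed(seed)
  frac <- if (n_frames == 1) 0 else (seq_len(n_frames) - 1) / (n_frames - 1)
  structures <- lapply(seq_len(n_frames), function(f) {
    s <- spec
    for (nm in names(drift))
      s[[nm]] <- drift[[nm]][1] + frac[f] * (drift[[nm]][2] - drift[[nm]][1])
    b <- build_bundle(s)
    if (noise_sd > 0) {
      n <- nrow(b$atoms)
      b$atoms$x <- b$atoms$x + stats::rnorm(n, 0, noise_sd)
      b$atoms$y <- b$atoms$y + stats::rnorm(n, 0, noise_sd)
      b$atoms$z <- b$atoms$z + stats::rnorm(n, 0, noise_sd)
    }
    b
  })
  as_trajectory(structures, interval_ps = interval_ps)
}

# --- quality-table generator -------------------------------------------------

# Sample a raw metric value landing in the bin for `stars` under `spec`.
# Percent metrics are kept inside [0, 100]; the labelled-residue count is
# integer-valued.
sample_value_in_bin <- function(spec, stars, integer_valued = FALSE,
                                percent = FALSE) {
  t <- spec$thresholds
  width <- max(abs(t[1] - t[3]) / 2, 1)
  if (integer_valued) {
    # lower-better integer count (e.g. labelled residues)
    lo <- c(0, t[1] + 1, t[2] + 1, t[3] + 1)[4 - stars]
    hi <- c(t[1], t[2], t[3], t[3] + 8)[4 - stars]
    return(sample(seq(lo, hi), 1))
  }
  if (spec$direction == "higher") {
    lo <- c(t[1], t[2], t[3], t[3] - width)[4 - stars]
    hi <- c(t[1] + width, t[1], t[2], t[3])[4 - stars]
    v <- stats::runif(1, lo, hi)
    # avoid crossing the inclusive boundary of the next-better bin
    if (stars < 3 && v >= hi) v <- lo
    if (percent) v <- min(v, 100)
    if (percent && stars == 3 && t[1] >= 100) v <- 100
  } else {
    lo <- c(t[1] - width, t[1], t[2], t[3])[4 - stars]
    hi <- c(t[1], t[2], t[3], t[3] + width)[4 - stars]
    v <- stats::runif(1, lo, hi)
    if (stars < 3 && v <= lo) v <- hi
    if (percent) v <- max(v, 0)
    if (percent && stars == 3 && t[1] <= 0) v <- 0
  }
  v
}

#' Generate a quality-score table with known star totals
#'
#' Metric values are sampled inside the star bin chosen per metric, so the
#' expected star assignment - and hence the weighted total - is known by
#' construction and can be compared against [star_table()].
#'
#' @param n_models number of models to generate.
#' @param seed RNG seed.
#' @param profile `"random"` (independent uniform star level per metric and
#'   model), `"all3"` (every metric in the 3-star bin), or a named integer
#'   vector of star levels (names from [quality_metrics()]) applied to all
#'   models.
#' @param specs metric specs (default [default_star_spec()]).
#' @return List with `records` (raw values, as from
#'   [read_quality_table()]), `expected` (per-model weighted-star table with
#'   `total`), `star_levels` (the sampled unweighted levels).
#' @export
gen_quality_table <- function(n_models, seed = 1, profile = "random",
                              specs = default_star_spec()) {
  stopifnot(n_models >= 1)
  set.seed(seed)
  metrics <- names(specs)
  levels <- matrix(NA_integer_, n_models, length(metrics),
                   dimnames = list(NULL, metrics))
  for (i in seq_len(n_models)) {
    levels[i, ] <- if (identical(profile, "random"))
      sample(0:3, length(metrics), replace = TRUE)
    else if (identical(profile, "all3")) rep(3L, length(metrics))
    else {
      if (!all(metrics %in% names(profile)))
        stop("profile must name every metric")
      as.integer(profile[metrics])
    }
  }
  records <- data.frame(model = sprintf("SYN_%03d", seq_len(n_models)),
                        stringsAsFactors = FALSE)
  pct <- c("errat", "verify3d", "prove", "rama_core", "rama_disallowed")
  for (m in metrics) {
    records[[m]] <- vapply(seq_len(n_models), function(i)
      sample_value_in_bin(specs[[m]], levels[i, m],
                          integer_valued = m == "labelled_residues",
                          percent = m %in% pct), numeric(1))
  }
  weights <- vapply(specs, `[[`, numeric(1), "weight")
  expected <- data.frame(model = records$model,
                         sweep(levels, 2, weights, `*`))
  expected$total <- rowSums(sweep(levels, 2, weights, `*`))
  list(records = records, expected = expected, star_levels = levels)
}

# --- docking-score generator -------------------------------------------------

#' Generate a two-class docking-score table with known AUC
#'
#' Scores are Gaussian with a shared standard deviation and
#' class-dependent means; the population AUC is then
#' `pnorm(|mean_active - mean_inactive| / (sd * sqrt(2)))` exactly. Default
#' class sizes (26 active / 98 inactive) mirror a typical focused screening
#' library. IC50 values consistent with the labels are attached so the
#' potency-labelling stage can be exercised on the same records.
#'
#' @param n_active,n_inactive class sizes (default 26 / 98).
#' @param mean_active,mean_inactive class score means for the
#'   more-negative-is-better convention (defaults -9.2 / -8.0, giving a
#'   population AUC of about 0.80).
#' @param sd shared score standard deviation (> 0, default 1).
#' @param direction `"lower"` (default) or `"higher"`; `"higher"` negates
#'   the scores.
#' @param seed RNG seed.
#' @return List with `records` (`ligand_id`, `ic50_uM`, `label`, `score`)
#'   and `analytic_auc`.
#' @export
gen_docking_scores <- function(n_active = 26, n_inactive = 98,
                               mean_active = -9.2, mean_inactive = -8.0,
                               sd = 1, direction = c("lower", "higher"),
                               seed = 1) {
  direction <- match.arg(direction)
  stopifnot(n_active >= 1, n_inactive >= 1, sd > 0)
  set.seed(seed)
  n <- n_active + n_inactive
  label <- c(rep("active", n_active), rep("inactive", n_inactive))
  score <- c(stats::rnorm(n_active, mean_active, sd),
             stats::rnorm(n_inactive, mean_inactive, sd))
  if (direction == "higher") score <- -score
  ic50 <- c(10^stats::runif(n_active, -2, log10(9.99)),
            10^stats::runif(n_inactive, 1, 3))
  records <- data.frame(ligand_id = sprintf("L%03d", seq_len(n)),
                        ic50_uM = ic50, label = label, score = score,
                        stringsAsFactors = FALSE)
  list(records = records,
       analytic_auc = stats::pnorm(abs(mean_active - mean_inactive) /
                                     (sd * sqrt(2))))
}
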