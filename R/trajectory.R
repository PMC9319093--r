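# Per-frame analysis over an ordered set of frames sharing one topology.

new_trajectory <- function(atoms, frames, interval_ps = 100, map = NULL) {
  structure(list(atoms = atoms, frames = frames, interval_ps = interval_ps,
                 map = map), class = "gpcr_trajectory")
}

#' Build a trajectory from structures
#'
#' All structures must share one topology (same chain/residue/atom
#' inventory, in the same order).
#'
#' @param structures list of `gpcr_structure` objects (ordered frames).
#' @param interval_ps time between frames in picoseconds (default 100, a
#'   common MD frame-saving interval).
#' @return A `gpcr_trajectory`.
#' @export
as_trajectory <- function(structures, interval_ps = 100) {
  stopifnot(length(structures) >= 1)
  ref <- structures[[1]]$atoms
  sig <- function(a) paste(a$chain, a$resno, a$insert, a$elety, collapse = "|")
  ok <- vapply(structures, function(s) identical(sig(s$atoms), sig(ref)),
               logical(1))
  if (!all(ok))
    stop("topology mismatch at frame(s): ",
         paste(which(!ok), collapse = ", "))
  frames <- lapply(structures, function(s)
    unname(as.matrix(s$atoms[c("x", "y", "z")])))
  topo <- ref
  topo$x <- topo$y <- topo$z <- NULL
  new_trajectory(topo, frames, interval_ps, map = structures[[1]]$map)
}

#' Number of frames in a trajectory
#' @param traj a `gpcr_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame as a structure
#'
#' @param traj a `gpcr_trajectory`.
#' @param i frame index (1-based).
#' @return A `gpcr_structure` carrying the trajectory's numbering map.
#' @export
frame_structure <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  a <- traj$atoms
  a$x <- traj$frames[[i]][, 1]
  a$y <- traj$frames[[i]][, 2]
  a$z <- traj$frames[[i]][, 3]
  gpcr_structure(a, map = traj$map)
}

#' @export
print.gpcr_trajectory <- function(x, ...) {
  cat("gpcr_trajectory:", n_frames(x), "frames x", nrow(x$atoms), "atoms,",
      x$interval_ps, "ps/frame\n")
  invisible(x)
}

#' Evaluate a scalar geometry metric on every frame
#'
#' The metric function is applied independently per frame. It must succeed
#' on frame 1 (otherwise the metric is considered inapplicable and an error
#' is raised); failures on later frames are recorded as `NA` gaps, never
#' interpolated.
#'
#' @param traj a `gpcr_trajectory`.
#' @param metric function taking a `gpcr_structure` and returning one
#'   number, e.g. [lock_distance()], [cage_distance()], [tm3_tm6()].
#' @param name metric name stored on the series.
#' @return A `metric_series`: data frame with `frame`, `time_ps`, `value`,
#'   plus `metric` and `summary` attributes.
#' @export
metric_series <- function(traj, metric, name = deparse(substitute(metric))) {
  stopifnot(inherits(traj, "gpcr_trajectory"), is.function(metric))
  first <- metric(frame_structure(traj, 1))  # propagate frame-1 failure
  vals <- c(as.numeric(first),
            vapply(seq_len(n_frames(traj))[-1], function(i)
              tryCatch(as.numeric(metric(frame_structure(traj, i))),
                       error = function(e) NA_real_),
              numeric(1)))
  make_series(vals, traj$interval_ps, name)
}

make_series <- function(vals, interval_ps, name) {
  out <- data.frame(frame = seq_along(vals),
                    time_ps = (seq_along(vals) - 1) * interval_ps,
                    value = vals)
  attr(out, "metric") <- name
  attr(out, "summary") <- c(mean = mean(vals, na.rm = TRUE),
                            min = min(vals, na.rm = TRUE),
                            max = max(vals, na.rm = TRUE))
  class(out) <- c("metric_series", "data.frame")
  out
}

#' RMSD series against the first frame
#'
#' Each frame is rigidly superposed (see [superpose()]) onto frame 1 on the
#' selected atoms, and the RMSD after fitting over the same selection is
#' reported; frame 1 scores 0 by construction.
#'
#' @param traj a `gpcr_trajectory` with at least 2 frames.
#' @param selection integer atom indices, or `NULL` for all Calpha atoms.
#' @return A `metric_series` of RMSD values (Angstrom).
#' @export
rmsd_series <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "gpcr_trajectory"))
  if (n_frames(traj) < 2) stop("need at least 2 frames")
  if (is.null(selection)) selection <- which(traj$atoms$elety == "CA")
  if (length(selection) < 3) stop("selection must cover at least 3 atoms")
  ref <- traj$frames[[1]][selection, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    if (i == 1) return(0)
    superpose(traj$frames[[i]][selection, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  make_series(vals, traj$interval_ps, "rmsd_vs_frame1")
}

#' @export
plot.metric_series <- function(x, ...) {
  graphics::plot(x$time_ps, x$value, type = "l",
                 xlab = "time [ps]",
                 ylab = attr(x, "metric"), ...)
  invisible(x)
}

# --- interaction fingerprints ------------------------------------------------

# Standard aromatic ring atom names per residue template.
RING_ATOMS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

ring_centroids <- function(atoms, templates = RING_ATOMS) {
  # one centroid per complete ring found in each residue
  out <- list()
  key <- paste(atoms$chain, atoms$resno, atoms$insert)
  for (k in unique(key)) {
    res <- atoms[key == k, , drop = FALSE]
    tmpl <- templates[[res$resid[1]]]
    if (is.null(tmpl)) next
    for (ring in tmpl) {
      hit <- res[res$elety %in% ring, , drop = FALSE]
      if (nrow(hit) == length(ring))
        out[[length(out) + 1]] <- list(resno = res$resno[1],
                                       centroid = colMeans(hit[, c("x", "y", "z")]))
    }
  }
  out
}

#' Per-frame protein-ligand interaction fingerprint
#'
#' Classifies contacts between a designated ligand residue group and the
#' protein by simple geometric criteria (all thresholds configurable):
#' `hbond` - donor/acceptor heavy atoms (N, O, S) within `hbond_dist`
#' (default 3.5 A); when the donor carries resolved hydrogens, a
#' D-H...A angle of at least `hbond_angle` (default 120 degrees) is also
#' required. `hydrophobic` - any carbon-carbon pair within `hydrophobic_dist`
#' (default 4.0 A). `aromatic` - ring-centroid separation within
#' `aromatic_dist` (default 5.5 A) between protein Phe/Tyr/Trp/His rings and
#' ligand rings; ligand residues whose ring atoms are unknown are skipped
#' for this class with a warning unless `ligand_rings` supplies them.
#'
#' @param structure a `gpcr_structure` (one frame).
#' @param ligand_resno author residue number(s) forming the ligand group.
#' @param ligand_rings optional list of character vectors of ligand atom
#'   names, one per ring.
#' @param hbond_dist,hbond_angle,hydrophobic_dist,aromatic_dist thresholds.
#' @return Data frame with columns `resno` (protein residue) and `class`;
#'   zero rows when no contact is found.
#' @export
interaction_fingerprint <- function(structure, ligand_resno,
                                    ligand_rings = NULL,
                                    hbond_dist = 3.5, hbond_angle = 120,
                                    hydrophobic_dist = 4.0,
                                    aromatic_dist = 5.5) {
  atoms <- structure$atoms
  is_lig <- atoms$resno %in% ligand_resno
  if (!any(is_lig)) stop("empty ligand selection")
  lig <- atoms[is_lig, , drop = FALSE]
  prot <- atoms[!is_lig, , drop = FALSE]
  hits <- list()
  add <- function(resno, cls)
    hits[[length(hits) + 1]] <<- data.frame(resno = resno, class = cls)

  lx <- as.matrix(lig[c("x", "y", "z")])
  px <- as.matrix(prot[c("x", "y", "z")])
  d2 <- outer(rowSums(lx^2), rowSums(px^2), `+`) - 2 * lx %*% t(px)
  d2[d2 < 0] <- 0

  # hydrogen bonds
  polar_l <- which(lig$elesy %in% c("N", "O", "S"))
  polar_p <- which(prot$elesy %in% c("N", "O", "S"))
  h_all <- atoms[atoms$elesy == "H", , drop = FALSE]
  hx <- as.matrix(h_all[c("x", "y", "z")])
  has_h <- nrow(h_all) > 0
  angle_ok <- function(dxyz, axyz) {
    # some H covalently bound to the donor makes a D-H...A angle >= cutoff
    if (!has_h) return(TRUE)
    dd <- sqrt(rowSums((hx - matrix(dxyz, nrow(hx), 3, byrow = TRUE))^2))
    bonded <- which(dd <= 1.25)
    if (!length(bonded)) return(TRUE)  # donor itself has no H resolved
    any(vapply(bonded, function(i)
      vec_angle(dxyz, hx[i, ], axyz) >= hbond_angle, logical(1)))
  }
  for (i in polar_l) for (j in polar_p) {
    if (sqrt(d2[i, j]) > hbond_dist) next
    a <- lx[i, ]; b <- px[j, ]
    if (angle_ok(a, b) || angle_ok(b, a))  # either side may donate
      add(prot$resno[j], "hbond")
  }

  # hydrophobic carbon-carbon contacts
  ci <- which(lig$elesy == "C"); cj <- which(prot$elesy == "C")
  if (length(ci) && length(cj)) {
    sub <- sqrt(d2[ci, cj, drop = FALSE]) <= hydrophobic_dist
    for (j in which(colSums(sub) > 0)) add(prot$resno[cj[j]], "hydrophobic")
  }

  # aromatic ring proximity
  prot_rings <- ring_centroids(prot)
  lig_templates <- RING_ATOMS
  if (!is.null(ligand_rings))
    for (rn in unique(lig$resid)) lig_templates[[rn]] <- ligand_rings
  lig_rings <- ring_centroids(lig, lig_templates)
  unknown <- setdiff(unique(lig$resid), names(lig_templates))
  if (length(prot_rings) && length(unknown))
    warning("no ring template for ligand residue(s): ",
            paste(unknown, collapse = ", "), "; aromatic class skipped")
  for (pr in prot_rings) for (lr in lig_rings)
    if (vec_dist(pr$centroid, lr$centroid) <= aromatic_dist)
      add(pr$resno, "aromatic")

  if (!length(hits))
    return(data.frame(resno = integer(0), class = character(0)))
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$resno, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contact persistence across frames
#'
#' Fraction of frames in which each (residue, interaction class) contact is
#' present. Invariant to frame order.
#'
#' @param fingerprints list of data frames from [interaction_fingerprint()],
#'   one per frame.
#' @return Data frame with `resno`, `class`, `fraction`, sorted by
#'   decreasing fraction then residue number.
#' @export
persistence <- function(fingerprints) {
  stopifnot(length(fingerprints) >= 1)
  n <- length(fingerprints)
  tagged <- do.call(rbind, lapply(seq_len(n), function(i) {
    fp <- unique(fingerprints[[i]])
    if (!nrow(fp)) return(NULL)
    fp$frame <- i
    fp
  }))
  if (is.null(tagged))
    return(data.frame(resno = integer(0), class = character(0),
                      fraction = numeric(0)))
  counts <- stats::aggregate(frame ~ resno + class, tagged,
                             function(f) length(unique(f)))
  counts$fraction <- counts$frame / n
  counts$frame <- NULL
  counts <- counts[order(-counts$fraction, counts$resno, counts$class), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  counts
}
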