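# Activation-state geometry on a single coordinate set.
#
# All distances are in Angstrom on author-numbered residues addressed through
# the attached generic-numbering map. Class A GPCR inactive-state hallmarks
# measured here: the R3.50-S6.33 ionic lock, the R3.50-D3.49 "aspartate cage"
# salt bridge, and the TM3-TM6 cytoplasmic Calpha distance.

vec_dist <- function(a, b) sqrt(sum((a - b)^2))

vec_angle <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

ARG_DONOR_N <- c("NE", "NH1", "NH2")

# Hydrogens bonded to the guanidinium nitrogens: element H within covalent
# range (1.25 A) of NE/NH1/NH2. Name-agnostic so pseudo-atoms and different
# H-naming schemes all work.
arg_polar_h <- function(res_atoms, n_xyz) {
  h <- res_atoms[guess_element(res_atoms$elety) == "H", , drop = FALSE]
  if (!nrow(h)) return(h[0, ])
  hx <- as.matrix(h[c("x", "y", "z")])
  keep <- vapply(seq_len(nrow(hx)), function(i)
    min(sqrt(rowSums((n_xyz - matrix(hx[i, ], nrow(n_xyz), 3,
                                     byrow = TRUE))^2))) <= 1.25,
    logical(1))
  h[keep, , drop = FALSE]
}

#' Ionic-lock geometry between R3.50 and S6.33
#'
#' Measures the hallmark class A inactive-state lock: the serine side-chain
#' oxygen (acceptor) against the arginine guanidinium group (donor).
#' `h_distance` is the minimum over arginine side-chain hydrogens of the
#' H-to-OG separation (the ranking criterion); `no_distance` is the minimum
#' N-to-OG separation over NE/NH1/NH2; `nho_angle` is the N-H...O angle at
#' the hydrogen realising the minimum. Structures without hydrogens (common
#' for backbone-only model outputs) return `h_distance = NA` with
#' `has_hydrogens = FALSE`; the heavy-atom distance is always reported.
#'
#' @param structure a `gpcr_structure` with a numbering map attached.
#' @param arg,ser generic numbers of the lock residues (defaults `"3.50"`,
#'   `"6.33"`).
#' @return List with `h_distance`, `no_distance`, `nho_angle`,
#'   `has_hydrogens`, `donor` (N realising `no_distance`).
#' @export
ionic_lock <- function(structure, arg = "3.50", ser = "6.33") {
  og <- residue_atom_xyz(structure, "OG", gn = ser)[1, ]
  n_xyz <- residue_atom_xyz(structure, ARG_DONOR_N, gn = arg,
                            required = FALSE)
  if (!nrow(n_xyz))
    stop("residue ", normalize_gn(arg), " has no guanidinium nitrogens")
  nd <- sqrt(rowSums((n_xyz - matrix(og, nrow(n_xyz), 3, byrow = TRUE))^2))
  arg_rows <- structure$atoms[residue_rows(structure, gn = arg), , drop = FALSE]
  h <- arg_polar_h(arg_rows, n_xyz)
  if (nrow(h)) {
    hx <- as.matrix(h[c("x", "y", "z")])
    hd <- sqrt(rowSums((hx - matrix(og, nrow(hx), 3, byrow = TRUE))^2))
    best <- which.min(hd)
    hbest <- hx[best, ]
    # the donor N covalently bound to that hydrogen
    dn <- which.min(sqrt(rowSums((n_xyz - matrix(hbest, nrow(n_xyz), 3,
                                                 byrow = TRUE))^2)))
    list(h_distance = unname(hd[best]),
         no_distance = unname(min(nd)),
         nho_angle = vec_angle(n_xyz[dn, ], hbest, og),
         has_hydrogens = TRUE,
         donor = rownames(n_xyz)[which.min(nd)])
  } else {
    list(h_distance = NA_real_, no_distance = unname(min(nd)),
         nho_angle = NA_real_, has_hydrogens = FALSE,
         donor = rownames(n_xyz)[which.min(nd)])
  }
}

#' Aspartate-cage (R3.50-D3.49) salt-bridge distance
#'
#' Minimum heteroatom-to-heteroatom distance between the arginine
#' guanidinium nitrogens and the aspartate carboxylate oxygens of the DRY
#' motif. A companion boolean flags a salt bridge at the conventional 4.0 A
#' cutoff; the raw distance is always the primary output.
#'
#' @param structure a `gpcr_structure` with numbering attached.
#' @param arg,asp generic numbers (defaults `"3.50"`, `"3.49"`).
#' @param bridge_cutoff salt-bridge call threshold in Angstrom (default 4.0).
#' @return List with `distance`, `salt_bridge`, `pair` (atom names).
#' @export
aspartate_cage <- function(structure, arg = "3.50", asp = "3.49",
                           bridge_cutoff = 4.0) {
  n_xyz <- residue_atom_xyz(structure, ARG_DONOR_N, gn = arg, required = FALSE)
  o_xyz <- residue_atom_xyz(structure, c("OD1", "OD2"), gn = asp,
                            required = FALSE)
  if (!nrow(n_xyz) || !nrow(o_xyz))
    stop("side-chain heteroatoms absent on ", normalize_gn(arg), " or ",
         normalize_gn(asp))
  d <- outer(seq_len(nrow(n_xyz)), seq_len(nrow(o_xyz)),
             Vectorize(function(i, j) vec_dist(n_xyz[i, ], o_xyz[j, ])))
  best <- which(d == min(d), arr.ind = TRUE)[1, ]
  list(distance = min(d),
       salt_bridge = min(d) <= bridge_cutoff,
       pair = c(rownames(n_xyz)[best[1]], rownames(o_xyz)[best[2]]))
}

#' TM3-TM6 cytoplasmic Calpha distance
#'
#' Mean Calpha separation between the last five cytoplasmic residues of TM3
#' (3.51-3.55) and TM6 (6.30-6.34), the standard activation-state gauge:
#' roughly 10-12 A in inactive class A receptors, 15-16 A in active ones.
#'
#' The published gauge averages "the distances between" the two stretches
#' without fixing a pairing; three modes are provided and the mode used is
#' recorded on the result. `"paired"` (default) aligns the stretches at the
#' cytoplasmic ends - TM3 runs extracellular-to-cytoplasmic while TM6 runs
#' the opposite way, so 3.51 pairs with 6.34, 3.52 with 6.33, and so on.
#' `"index"` pairs in raw position order (3.51 with 6.30, ...);
#' `"all-pairs"` averages the full 5 x 5 distance matrix.
#'
#' @param structure a `gpcr_structure` with numbering attached.
#' @param mode pairing convention, see Details.
#' @return Numeric distance (Angstrom) with attribute `mode`.
#' @export
tm3_tm6_distance <- function(structure,
                             mode = c("paired", "index", "all-pairs")) {
  mode <- match.arg(mode)
  tm3 <- sprintf("3.%d", 51:55)
  tm6 <- sprintf("6.%d", 30:34)
  p3 <- t(vapply(tm3, function(g) ca_xyz(structure, g), numeric(3)))
  p6 <- t(vapply(tm6, function(g) ca_xyz(structure, g), numeric(3)))
  val <- switch(mode,
    paired = mean(vapply(1:5, function(i) vec_dist(p3[i, ], p6[6 - i, ]),
                         numeric(1))),
    index = mean(vapply(1:5, function(i) vec_dist(p3[i, ], p6[i, ]),
                        numeric(1))),
    `all-pairs` = mean(outer(1:5, 1:5, Vectorize(function(i, j)
      vec_dist(p3[i, ], p6[j, ])))))
  attr(val, "mode") <- mode
  val
}

#' Classify receptor activation state from the TM3-TM6 distance
#'
#' Distances up to `inactive_max` (default 12 A) are called `inactive`,
#' distances of `active_min` (default 14 A) or more `active`, the gap
#' between them `intermediate-ambiguous`.
#'
#' @param distance TM3-TM6 distance(s) in Angstrom, positive.
#' @param inactive_max upper bound of the inactive regime.
#' @param active_min lower bound of the active regime.
#' @return Character label(s).
#' @export
classify_state <- function(distance, inactive_max = 12, active_min = 14) {
  stopifnot(all(distance > 0), inactive_max < active_min)
  ifelse(distance <= inactive_max, "inactive",
         ifelse(distance >= active_min, "active", "intermediate-ambiguous"))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets, by singular value decomposition of the covariance
#' matrix with a reflection correction (det = +1).
#'
#' @param mobile,reference n x 3 coordinate matrices with paired rows,
#'   n >= 3 and not collinear.
#' @return List with `rotation` (3 x 3, applied on the right as
#'   `x %*% rotation`), `translation` (length 3), `rmsd`, and `fitted`
#'   (mobile after the transform).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be matched n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  if (qr(Q)$rank < 2 || qr(P)$rank < 2)
    stop("degenerate (collinear) selection; superposition is not unique")
  S <- t(P) %*% Q
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- sweep(P %*% R, 2, cr, `+`)
  list(rotation = R, translation = as.vector(cr - cm %*% R),
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))),
       fitted = fitted)
}

#' Convenience scalar metrics for per-frame series
#'
#' Wrappers returning a single number from a structure, suitable for
#' [metric_series()]: the ionic-lock H...O distance (falling back to the
#' heavy-atom N-O distance when the model has no hydrogens), the cage
#' distance, and the TM3-TM6 distance.
#'
#' @param structure a `gpcr_structure` with numbering attached.
#' @return A single numeric value (Angstrom).
#' @export
lock_distance <- function(structure) {
  g <- ionic_lock(structure)
  if (g$has_hydrogens) g$h_distance else g$no_distance
}

#' @rdname lock_distance
#' @export
cage_distance <- function(structure) aspartate_cage(structure)$distance

#' @rdname lock_distance
#' @export
tm3_tm6 <- function(structure) as.numeric(tm3_tm6_distance(structure))
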