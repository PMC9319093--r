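# Structure container and PDB I/O.
#
# A gpcr_structure is a plain atom table (one row per atom, bio3d-style
# columns) plus an optional attached numbering map. Multi-MODEL PDB files
# become trajectories (shared topology + per-frame coordinates).

ATOM_COLS <- c("elety", "resid", "chain", "resno", "insert", "x", "y", "z",
               "o", "elesy")

#' Construct a structure from an atom table
#'
#' @param atoms data frame with columns `elety` (atom name), `resid`
#'   (residue name), `chain`, `resno`, `insert`, `x`, `y`, `z`, and
#'   optionally `o` (occupancy) and `elesy` (element symbol; inferred from
#'   the atom name when absent).
#' @param map optional `numbering_map` to attach (see [build_numbering()]).
#' @return A `gpcr_structure`.
#' @export
gpcr_structure <- function(atoms, map = NULL) {
  atoms <- as.data.frame(atoms)
  if (!"insert" %in% names(atoms)) atoms$insert <- NA_character_
  if (!"o" %in% names(atoms)) atoms$o <- 1
  if (!"elesy" %in% names(atoms)) atoms$elesy <- guess_element(atoms$elety)
  need <- setdiff(ATOM_COLS, names(atoms))
  if (length(need)) stop("atom table lacks column(s): ",
                         paste(need, collapse = ", "))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate atom name within a residue (resolve alt-locs first)")
  structure(list(atoms = atoms[ATOM_COLS], map = map),
            class = "gpcr_structure")
}

guess_element <- function(elety) {
  # PDB convention: element is the first letter after any leading digits;
  # hydrogens may be written "1HH1" etc.
  substr(gsub("^[0-9]*", "", elety), 1, 1)
}

#' @export
print.gpcr_structure <- function(x, ...) {
  res <- unique(paste(x$atoms$chain, x$atoms$resno))
  cat("gpcr_structure:", nrow(x$atoms), "atoms,", length(res), "residues",
      if (!is.null(x$map)) "(numbering attached)" else "", "\n")
  invisible(x)
}

#' Attach a numbering map to a structure or trajectory
#'
#' @param x a `gpcr_structure` or `gpcr_trajectory`.
#' @param map a `numbering_map` (or an `anchor_set`, expanded on the fly).
#' @return `x` with the map attached.
#' @export
attach_numbering <- function(x, map) {
  if (inherits(map, "anchor_set")) map <- build_numbering(map)
  stopifnot(inherits(map, "numbering_map"))
  x$map <- map
  x
}

# Resolve alternate locations: keep the highest-occupancy conformer per
# (chain, resno, insert, elety); ties keep alt-loc 'A' (or the blank record).
resolve_altloc <- function(atom) {
  if (!"alt" %in% names(atom) || all(is.na(atom$alt))) return(atom)
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
  pref <- ifelse(is.na(atom$alt) | atom$alt == "A", 0L, 1L)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  ord <- order(key, -occ, pref)
  atom <- atom[ord, , drop = FALSE]
  atom[!duplicated(paste(atom$chain, atom$resno, atom$insert, atom$elety)), ,
       drop = FALSE]
}

#' Read a PDB file as a structure or trajectory
#'
#' Fixed-column PDB ATOM/HETATM records are parsed (via bio3d); MODEL/ENDMDL
#' records delimit frames. Alternate locations are resolved to the
#' highest-occupancy conformer (ties keep 'A').
#'
#' @param path PDB file.
#' @param map optional `numbering_map` to attach.
#' @return A `gpcr_structure` for single-model files; a `gpcr_trajectory`
#'   (see [as_trajectory()]) when the file holds several MODELs.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("no ATOM/HETATM records found in '", path, "'")
  rownames(pdb$atom) <- NULL
  atom <- resolve_altloc(pdb$atom)
  keep <- sort(as.integer(rownames(atom)))  # original file order
  atom <- pdb$atom[keep, , drop = FALSE]
  if (is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1) {
    frames <- lapply(seq_len(nrow(pdb$xyz)), function(i) {
      m <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
      m[keep, , drop = FALSE]
    })
    topo <- atom
    topo$x <- topo$y <- topo$z <- NULL
    return(new_trajectory(topo, frames))
  }
  gpcr_structure(atom)
}

#' Write a structure (or trajectory) to a PDB file
#'
#' @param x a `gpcr_structure` or `gpcr_trajectory` (written as a
#'   multi-MODEL file).
#' @param path output PDB path.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "gpcr_trajectory")) {
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
    a <- x$atoms
    bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno,
                     resid = a$resid, elety = a$elety, chain = a$chain,
                     insert = a$insert, o = a$o, elesy = a$elesy)
  } else {
    a <- x$atoms
    bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(a[c("x", "y", "z")]))),
                     resno = a$resno, resid = a$resid, elety = a$elety,
                     chain = a$chain, insert = a$insert, o = a$o,
                     elesy = a$elesy)
  }
  invisible(path)
}

# --- selection helpers -------------------------------------------------------

# Rows of the atom table belonging to one residue addressed by generic
# number (needs an attached map) or by author residue number.
residue_rows <- function(structure, gn = NULL, resno = NULL) {
  atoms <- structure$atoms
  if (!is.null(gn)) {
    if (is.null(structure$map))
      stop("structure has no numbering map; use attach_numbering()")
    resno <- unname(lookup_residue(structure$map, gn))
  }
  idx <- which(atoms$resno == resno)
  if (!length(idx))
    stop("residue ", if (!is.null(gn)) paste0(normalize_gn(gn), " (", resno, ")")
         else resno, " not present in structure")
  idx
}

# Coordinates (n x 3) of named atoms within a residue; error when any is
# absent and required = TRUE.
residue_atom_xyz <- function(structure, names, gn = NULL, resno = NULL,
                             required = TRUE) {
  idx <- residue_rows(structure, gn = gn, resno = resno)
  sub <- structure$atoms[idx, , drop = FALSE]
  hit <- sub[sub$elety %in% names, , drop = FALSE]
  if (required && !all(names %in% hit$elety))
    stop("residue ", if (!is.null(gn)) normalize_gn(gn) else resno,
         " lacks atom(s): ", paste(setdiff(names, hit$elety), collapse = ", "))
  m <- as.matrix(hit[c("x", "y", "z")])
  rownames(m) <- hit$elety
  m
}

# Calpha coordinate of the residue carrying a generic number.
ca_xyz <- function(structure, gn) {
  residue_atom_xyz(structure, "CA", gn = gn)[1, ]
}
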