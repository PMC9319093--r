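# Independent brute-force oracles, deliberately naive: each re-derives a
# quantity by direct enumeration so the package implementation is checked
# against a second route.

# AUC as the fraction of (active, inactive) ordered pairs the active wins,
# ties counted half.
oracle_auc_paircount <- function(records, direction = "lower") {
  s <- if (direction == "lower") -records$score else records$score
  a <- s[records$label == "active"]
  i <- s[records$label == "inactive"]
  wins <- 0
  for (x in a) for (y in i)
    wins <- wins + if (x > y) 1 else if (x == y) 0.5 else 0
  wins / (length(a) * length(i))
}

# Weighted star total by linear scan over bin boundaries.
oracle_total_stars <- function(record, specs) {
  total <- 0
  for (m in names(specs)) {
    sp <- specs[[m]]
    v <- record[[m]]
    stars <- 0
    if (!is.null(v) && !is.na(v)) {
      for (k in 1:3) {
        ok <- if (sp$direction == "higher") v >= sp$thresholds[k]
              else v <= sp$thresholds[k]
        if (ok) { stars <- 4 - k; break }
      }
    }
    total <- total + stars * sp$weight
  }
  total
}

# Reference superposed RMSD via bio3d's fitting routine (full precision:
# bio3d::rmsd() itself rounds to 3 decimals, so refit and measure directly).
oracle_fit_rmsd <- function(ref, mob) {
  mfit <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(ref)),
                                          mobile = as.vector(t(mob))))
  sqrt(mean(rowSums((matrix(mfit, ncol = 3, byrow = TRUE) - ref)^2)))
}

# Apply a random rigid motion (proper rotation + translation) to a
# structure's coordinates.
rigid_motion <- function(structure, seed = 1) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0.3, 2.8)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tvec <- stats::rnorm(3, 0, 10)
  xyz <- as.matrix(structure$atoms[c("x", "y", "z")]) %*% t(R)
  structure$atoms$x <- xyz[, 1] + tvec[1]
  structure$atoms$y <- xyz[, 2] + tvec[2]
  structure$atoms$z <- xyz[, 3] + tvec[3]
  structure
}

# Minimal structure from explicit atom rows (name, resname, resno, x, y, z).
make_structure <- function(...) {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(rows, function(r)
    data.frame(elety = r[[1]], resid = r[[2]], chain = "A",
               resno = as.integer(r[[3]]), insert = NA_character_,
               x = as.numeric(r[[4]]), y = as.numeric(r[[5]]),
               z = as.numeric(r[[6]]), stringsAsFactors = FALSE)))
  gpcr_structure(atoms)
}

# Map covering the residues used by hand-built lock/cage fixtures
# (119 = 3.50, 118 = 3.49, 230 = 6.33; spans wider than the toy structures,
# which is fine - the map is independent of any structure).
toy_map <- function() {
  build_numbering(anchor_set(data.frame(
    segment = c(3, 6), start = c(110, 225), end = c(119, 247),
    anchor = c(119, 247))))
}
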