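# Ballesteros-Weinstein generic numbering from per-segment anchors.
#
# Each helix (or numbered loop, e.g. segment 45 for EL2) carries one anchor
# residue declared to be X.50; every other residue in the segment span gets
# its position by sequence offset: position = 50 + (seqnum - anchor_seqnum).

#' Create an anchor set for generic numbering
#'
#' An anchor set declares, per segment, the author residue-number span of the
#' segment and the residue that carries the conserved X.50 position. Segments
#' are the seven transmembrane helices (1-7) and, optionally, inter-helix
#' loops labelled by their flanking helices (12, 23, 34, 45, 56, 67), as in
#' GPCRdb-style numbering where the conserved EL2 cysteine is 45.50.
#'
#' @param segments data frame with integer columns `segment`, `start`, `end`,
#'   `anchor`: the span `[start, end]` (author numbering, 1-based) and the
#'   seqnum of the residue defined as `segment.50`.
#' @param chain chain identifier the spans refer to (default `"A"`).
#' @return An object of class `anchor_set`.
#' @examples
#' anchor_set(data.frame(segment = 3, start = 95, end = 127, anchor = 119))
#' @export
anchor_set <- function(segments, chain = "A") {
  segments <- as.data.frame(segments)
  need <- c("segment", "start", "end", "anchor")
  if (!all(need %in% names(segments)))
    stop("anchor segments need columns: ", paste(need, collapse = ", "))
  segments <- segments[order(segments$start), need, drop = FALSE]
  for (col in need) {
    segments[[col]] <- as.integer(segments[[col]])
    if (anyNA(segments[[col]])) stop("non-integer value in column '", col, "'")
  }
  if (any(segments$start < 1)) stop("residue numbers must be >= 1")
  if (any(segments$end < segments$start)) stop("segment end precedes start")
  if (any(duplicated(segments$segment))) stop("duplicate segment label")
  bad <- segments$anchor < segments$start | segments$anchor > segments$end
  if (any(bad))
    stop("anchor outside its span for segment(s): ",
         paste(segments$segment[bad], collapse = ", "))
  if (nrow(segments) > 1) {
    overlap <- segments$start[-1] <= segments$end[-nrow(segments)]
    if (any(overlap))
      stop("overlapping segment spans: segments ",
           paste(segments$segment[c(which(overlap), which(overlap) + 1)],
                 collapse = ", "))
  }
  structure(list(segments = segments, chain = chain), class = "anchor_set")
}

#' Read anchor annotations from JSON or CSV
#'
#' JSON files carry a top-level `segments` array of objects with fields
#' `segment`, `start`, `end`, `anchor` (and optionally `chain`); CSV files
#' carry the same columns.
#'
#' @param path file path; format chosen by extension (`.json` vs anything
#'   else, read as CSV).
#' @return An [anchor_set()].
#' @export
read_anchors <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    chain <- if (!is.null(obj$chain)) obj$chain else "A"
    anchor_set(obj$segments, chain = chain)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    chain <- if ("chain" %in% names(df)) df$chain[1] else "A"
    anchor_set(df, chain = chain)
  }
}

#' Build a residue <-> generic number map
#'
#' Expands an anchor set into the full bijection between author residue
#' numbers and generic numbers. Within a segment the offset law holds:
#' `seqnum - anchor_seqnum = position - 50`.
#'
#' @param anchors an [anchor_set()].
#' @return A `numbering_map`: data frame with columns `chain`, `seqnum`,
#'   `segment`, `position`, `gn` (rendered "segment.position").
#' @export
build_numbering <- function(anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  seg <- anchors$segments
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    seqnum <- seg$start[i]:seg$end[i]
    position <- 50L + (seqnum - seg$anchor[i])
    if (any(position < 1L | position > 99L))
      stop("segment ", seg$segment[i],
           ": positions fall outside [1, 99]; shorten the span")
    data.frame(chain = anchors$chain, seqnum = seqnum,
               segment = seg$segment[i], position = position,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  map$gn <- sprintf("%d.%02d", map$segment, map$position)
  class(map) <- c("numbering_map", "data.frame")
  map
}

# Normalise "3.50", "3.5" (meaning 3.50), c(3, 50) etc. to "S.PP" text form.
normalize_gn <- function(gn) {
  if (is.numeric(gn) && length(gn) == 2)
    return(sprintf("%d.%02d", as.integer(gn[1]), as.integer(gn[2])))
  gn <- as.character(gn)
  parts <- strsplit(gn, ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2) stop("malformed generic number: ", paste(p, collapse = "."))
    pos <- p[2]
    if (nchar(pos) == 1) pos <- paste0(pos, "0")  # "3.5" printed for 3.50
    sprintf("%d.%02d", as.integer(p[1]), as.integer(pos))
  }, character(1))
}

#' Look up the residue carrying a generic number
#'
#' @param map a `numbering_map` from [build_numbering()].
#' @param gn generic number as text (`"3.50"`) or a `(segment, position)`
#'   pair.
#' @return Integer author residue number (named by chain).
#' @export
lookup_residue <- function(map, gn) {
  stopifnot(inherits(map, "numbering_map"))
  key <- normalize_gn(gn)
  idx <- match(key, map$gn)
  if (anyNA(idx))
    stop("generic number(s) not in map: ", paste(key[is.na(idx)], collapse = ", "))
  stats::setNames(map$seqnum[idx], map$chain[idx])
}

#' Look up the generic number of a residue
#'
#' @param map a `numbering_map`.
#' @param seqnum author residue number(s).
#' @return Character generic number(s), `NA` for residues outside all spans.
#' @export
gn_of_residue <- function(map, seqnum) {
  stopifnot(inherits(map, "numbering_map"))
  map$gn[match(as.integer(seqnum), map$seqnum)]
}

#' GPR18 anchor fixture
#'
#' Transmembrane/loop spans and X.50 anchors covering every residue the
#' package's worked examples address on the GPR18 receptor (e.g. R119 as
#' 3.50, S230 as 6.33, C172 as 45.50). Spans are a curated fixture: helix
#' boundaries are not part of the published record and may be overridden by
#' supplying your own annotation file to [read_anchors()].
#'
#' @return An [anchor_set()].
#' @export
gpr18_anchors <- function() {
  read_anchors(system.file("extdata", "gpr18_anchors.json",
                           package = "gpcrstars", mustWork = TRUE))
}
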