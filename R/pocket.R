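# Binding-pocket residue fingerprints across models.
#
# Per-model pocket predictions (e.g. PrankWeb residue lists) become a binary
# model x residue matrix; consensus residues are those predicted for at
# least a chosen number of models.
#
# Residues are keyed by generic number ("2.60") where available; loop
# residues outside any numbered segment use a "chain:resno" composite label
# (e.g. "A:175") so they still appear as matrix columns.

parse_pocket_residue <- function(x) {
  # returns list(key, segment, position) with segment/position NA for
  # chain:resno labels
  x <- trimws(as.character(x))
  if (grepl("^[0-9]+\\.[0-9]+$", x)) {
    key <- normalize_gn(x)
    p <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]])
    list(key = key, segment = p[1], position = p[2])
  } else if (grepl("^[A-Za-z0-9]:[0-9]+$", x)) {
    list(key = x, segment = NA_integer_,
         position = as.integer(sub("^.*:", "", x)))
  } else stop("unrecognised pocket residue label: '", x, "'")
}

#' Read per-model pocket predictions
#'
#' Accepts a long CSV with columns `model`, `residue` (one row per predicted
#' residue; labels are generic numbers like `"2.60"` or `"A:175"` composite
#' labels for un-numbered loop residues), or a JSON object mapping model
#' names to residue-label arrays.
#'
#' @param path CSV or JSON file.
#' @return Named list of character vectors (residue labels per model).
#' @export
read_pocket_predictions <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    lapply(obj, as.character)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("model", "residue") %in% names(df)))
      stop("pocket CSV needs columns 'model' and 'residue'")
    split(as.character(df$residue), df$model)
  }
}

#' Binary model x residue pocket fingerprint matrix
#'
#' @param predictions named list of residue-label vectors, one per model
#'   (see [read_pocket_predictions()]).
#' @return Integer 0/1 matrix; rows are models (input order), columns the
#'   union of predicted residues ordered by segment then position, with
#'   composite-labelled loop residues after the numbered ones.
#' @export
pocket_matrix <- function(predictions) {
  stopifnot(length(predictions) >= 1, !is.null(names(predictions)))
  if (anyDuplicated(names(predictions))) stop("duplicate model identifiers")
  parsed <- lapply(predictions, function(res)
    vapply(unique(res), function(r) parse_pocket_residue(r)$key, character(1)))
  all_keys <- unique(unlist(parsed, use.names = FALSE))
  info <- lapply(all_keys, parse_pocket_residue)
  seg <- vapply(info, function(i) i$segment, integer(1))
  pos <- vapply(info, function(i) i$position, integer(1))
  ord <- order(is.na(seg), seg, pos)
  all_keys <- all_keys[ord]
  m <- vapply(all_keys, function(k)
    vapply(parsed, function(p) as.integer(k %in% p), integer(1)),
    integer(length(parsed)))
  m <- matrix(m, nrow = length(parsed),
              dimnames = list(names(predictions), all_keys))
  m
}

#' Consensus pocket residues
#'
#' Residues predicted for at least `min_models` of the models, ordered by
#' prediction frequency (descending) then matrix column order. The cut-off
#' is a required explicit choice: `min_models = nrow` gives the strict
#' intersection, `1` the union.
#'
#' @param matrix binary matrix from [pocket_matrix()].
#' @param min_models minimum number of supporting models, in
#'   `1:nrow(matrix)`.
#' @return Character vector of residue labels.
#' @export
pocket_consensus <- function(matrix, min_models) {
  stopifnot(is.matrix(matrix), min_models >= 1, min_models <= nrow(matrix))
  counts <- colSums(matrix)
  keep <- which(counts >= min_models)
  keep <- keep[order(-counts[keep], keep)]
  colnames(matrix)[keep]
}

#' Pairwise Jaccard similarity of pocket predictions
#'
#' @param matrix binary matrix from [pocket_matrix()] with >= 2 rows.
#' @return Symmetric model x model matrix of Jaccard indices (intersection
#'   over union of predicted residue sets; 1 on the diagonal for nonempty
#'   predictions).
#' @export
pocket_jaccard <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2)
  m <- matrix > 0
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, `+`) - inter
  j <- ifelse(uni == 0, NA_real_, inter / uni)
  dimnames(j) <- list(rownames(matrix), rownames(matrix))
  j
}

#' Write / read a pocket matrix as CSV
#'
#' Round-trips bit-exactly: rows are models (first column `model`), columns
#' residue labels.
#'
#' @param matrix binary matrix from [pocket_matrix()].
#' @param path CSV path.
#' @export
write_pocket_matrix <- function(matrix, path) {
  df <- data.frame(model = rownames(matrix), matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pocket_matrix
#' @export
read_pocket_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$model
  m
}

#' Packaged pocket-prediction fixture (eight receptor models)
#'
#' A synthetic per-model prediction set shaped like PrankWeb output for the
#' eight GPR18 models of the worked example: the fifteen consensus pocket
#' residues recur across at least six models, model-specific EL2 loop
#' residues (composite labels) appear in fewer.
#'
#' @return Named list of residue-label vectors.
#' @export
gpr18_pocket_predictions <- function() {
  read_pocket_predictions(system.file("extdata",
                                      "gpr18_pocket_predictions_synthetic.csv",
                                      package = "gpcrstars", mustWork = TRUE))
}
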