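# Secondary (V1/V2/V3) model ranking.
#
# After the preliminary star totals, three coarse criteria each earn 0-3
# stars: V1 bins the star total, V2 the ionic-lock hydrogen-bond distance
# (Angstrom), V3 the virtual-screening enrichment AUC. Their sum, ranked in
# descending order, selects the final models.

V1_BOUNDS <- c(27, 20, 13)       # total stars, higher better
V2_BOUNDS <- c(2.5, 3.5, 4.5)    # lock distance [A], lower better
V3_BOUNDS <- c(0.79, 0.77, 0.75) # enrichment AUC, higher better

#' V1 stars from the preliminary star total
#'
#' 3 stars for totals >= 27, 2 for >= 20, 1 for >= 13, else 0.
#'
#' @param total_stars numeric total(s) from [star_table()].
#' @return Integer star count(s) in `0:3`.
#' @export
v1_stars <- function(total_stars) {
  stopifnot(all(total_stars >= 0))
  bin_stars(total_stars, V1_BOUNDS, higher = TRUE)
}

#' V2 stars from the ionic-lock distance
#'
#' 3 stars for distances <= 2.5 A, 2 for <= 3.5 A, 1 for <= 4.5 A, else 0.
#' The distance is the acceptor-oxygen to nearest donor-hydrogen separation
#' of the R3.50-S6.33 ionic lock (see [ionic_lock()]).
#'
#' @param lock_distance distance(s) in Angstrom, positive.
#' @return Integer star count(s) in `0:3`.
#' @export
v2_stars <- function(lock_distance) {
  stopifnot(all(lock_distance > 0))
  bin_stars(lock_distance, V2_BOUNDS, higher = FALSE)
}

#' V3 stars from the enrichment AUC
#'
#' 3 stars for AUC >= 0.79, 2 for >= 0.77, 1 for >= 0.75, else 0.
#'
#' @param auc area(s) under the ROC curve, in `[0, 1]`.
#' @return Integer star count(s) in `0:3`.
#' @export
v3_stars <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  bin_stars(auc, V3_BOUNDS, higher = TRUE)
}

bin_stars <- function(x, bounds, higher) {
  vapply(x, function(v) {
    meets <- if (higher) v >= bounds else v <= bounds
    if (meets[1]) 3L else if (meets[2]) 2L else if (meets[3]) 1L else 0L
  }, integer(1))
}

#' Assemble secondary scores for a set of models
#'
#' @param models data frame with columns `model`, `total_stars`,
#'   `lock_distance`, `auc` (as written by the upstream stages, or read from
#'   CSV).
#' @return Data frame adding `v1`, `v2`, `v3`, `v12` (= v1 + v2) and
#'   `sum` (= v1 + v2 + v3).
#' @export
secondary_scores <- function(models) {
  need <- c("model", "total_stars", "lock_distance", "auc")
  if (!all(need %in% names(models)))
    stop("need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(models$model)) stop("duplicate model identifiers")
  models$v1 <- v1_stars(models$total_stars)
  models$v2 <- v2_stars(models$lock_distance)
  models$v3 <- v3_stars(models$auc)
  models$v12 <- models$v1 + models$v2
  models$sum <- models$v12 + models$v3
  models
}

#' Rank models by their V1+V2+V3 sum
#'
#' Sorts in descending order of the summed secondary stars. Ties are broken
#' deterministically: higher preliminary star total first, then smaller
#' ionic-lock distance, then lexicographic model name.
#'
#' @param scores data frame from [secondary_scores()] (recomputed if the
#'   `sum` column is absent).
#' @return The input rows in rank order with a leading `rank` column.
#' @export
rank_models <- function(scores) {
  if (nrow(scores) < 1) stop("empty score table")
  if (!"sum" %in% names(scores)) scores <- secondary_scores(scores)
  if (anyDuplicated(scores$model)) stop("duplicate model identifiers")
  ord <- order(-scores$sum, -scores$total_stars, scores$lock_distance,
               scores$model, method = "radix")
  out <- scores[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Packaged secondary-ranking fixture (eight receptor models)
#'
#' The printed (star total, lock distance, AUC) triples for the eight GPR18
#' models of the worked example.
#'
#' @return Data frame with columns `model`, `total_stars`, `lock_distance`,
#'   `auc`.
#' @export
gpr18_secondary_table <- function() {
  utils::read.csv(system.file("extdata", "gpr18_secondary.csv",
                              package = "gpcrstars", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
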