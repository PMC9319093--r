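# Virtual-screening enrichment: activity labelling by potency threshold,
# tie-aware ROC curve and AUC from docking scores.

#' Label ligands active/inactive by potency threshold
#'
#' Strict comparison: a ligand is active iff its IC50 is below the
#' threshold; a ligand exactly at the threshold is inactive.
#'
#' @param records data frame with column `ic50_uM` (micromolar, positive).
#' @param threshold activity cutoff in micromolar (default 10).
#' @return `records` with a `label` column (`"active"`/`"inactive"`).
#' @export
label_by_potency <- function(records, threshold = 10) {
  if (!"ic50_uM" %in% names(records)) stop("records need an 'ic50_uM' column")
  if (anyNA(records$ic50_uM)) stop("ic50_uM missing for some records")
  if (any(records$ic50_uM <= 0)) stop("ic50_uM must be positive")
  records$label <- ifelse(records$ic50_uM < threshold, "active", "inactive")
  records
}

#' ROC curve and AUC from docking scores
#'
#' Ranks ligands by docking score and sweeps a threshold to produce the ROC
#' curve, with tied scores collapsed to single ROC points (diagonal
#' segments). The trapezoidal area under this tie-aware curve equals the
#' Mann-Whitney U statistic with half credit for ties.
#'
#' @param records data frame with columns `label`
#'   (`"active"`/`"inactive"`) and `score`.
#' @param direction `"lower"` when more negative scores mean stronger
#'   predicted binding (Vina-style; the default) or `"higher"` when larger
#'   scores do (DockThor-style affinity scores).
#' @return An `enrichment_result`: list with `roc` (data frame `fpr`,
#'   `tpr`), `auc`, `n_active`, `n_inactive`.
#' @export
roc_auc <- function(records, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  need <- c("label", "score")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  lab <- records$label
  if (!all(lab %in% c("active", "inactive")))
    stop("labels must be 'active' or 'inactive'")
  n_act <- sum(lab == "active"); n_inact <- sum(lab == "inactive")
  if (n_act < 1 || n_inact < 1)
    stop("need at least one active and one inactive ligand")
  s <- if (direction == "lower") -records$score else records$score
  if (anyNA(s)) stop("missing docking scores")
  # sweep thresholds from the best score down; ties collapse to one point
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; act <- lab[ord] == "active"
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(act)[last] / n_act)
  fpr <- c(0, cumsum(!act)[last] / n_inact)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 n_active = n_act, n_inactive = n_inact),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: AUC %.3f (%d active / %d inactive)\n",
              x$auc, x$n_active, x$n_inactive))
  invisible(x)
}

#' @export
plot.enrichment_result <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "FPR",
                 ylab = "TPR", ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Enrichment AUC and V3 stars across models
#'
#' Computes the AUC per model score table and bins it into V3 stars (see
#' [v3_stars()]). A warning is raised when models were scored on different
#' ligand sets.
#'
#' @param tables named list of score tables (each as for [roc_auc()]; a
#'   `ligand_id` column, when present, is used for the same-ligand-set
#'   check).
#' @param direction score direction, as in [roc_auc()].
#' @return Data frame with `model`, `auc`, `v3`.
#' @export
compare_models <- function(tables, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(is.list(tables), length(tables) >= 1, !is.null(names(tables)))
  ids <- lapply(tables, function(t)
    if ("ligand_id" %in% names(t)) sort(as.character(t$ligand_id)) else NULL)
  if (!is.null(ids[[1]]) &&
      !all(vapply(ids, identical, logical(1), ids[[1]])))
    warning("models were scored on different ligand sets")
  auc <- vapply(tables, function(t) roc_auc(t, direction)$auc, numeric(1))
  data.frame(model = names(tables), auc = unname(auc),
             v3 = v3_stars(unname(auc)), stringsAsFactors = FALSE)
}
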