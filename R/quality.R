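# "Stars" aggregation of protein global-quality metrics.
#
# Each metric gets 0-3 stars from three ordered boundary values (best -> worst,
# boundaries inclusive as printed, e.g. ">= 61" or "<= 1.0"); the two
# Ramachandran percentages carry weight 0.5 each and are summed after binning,
# so model totals move in half-star steps on a 0-36 scale.

#' Define a star-binning specification for one quality metric
#'
#' @param metric metric name (one of the canonical names, see
#'   [quality_metrics()], or any user-defined name).
#' @param direction `"higher"` if larger values are better (e.g. ERRAT
#'   percent), `"lower"` if smaller values are better (e.g. MolProbity,
#'   statistical potentials).
#' @param thresholds numeric length-3 vector of boundary values for 3, 2 and
#'   1 stars, ordered best to worst; values failing the 1-star boundary get 0
#'   stars. Boundaries are inclusive.
#' @param weight multiplier applied to the star count (default 1; the two
#'   Ramachandran percentages use 0.5).
#' @return A `metric_spec` object.
#' @export
metric_spec <- function(metric, direction = c("higher", "lower"),
                        thresholds, weight = 1) {
  direction <- match.arg(direction)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 3 || anyNA(thresholds))
    stop("thresholds must be three finite boundary values (3, 2, 1 stars)")
  ord <- if (direction == "higher") all(diff(thresholds) <= 0)
         else all(diff(thresholds) >= 0)
  if (!ord)
    stop("thresholds must be ordered best to worst for direction '",
         direction, "'")
  stopifnot(is.numeric(weight), length(weight) == 1, weight >= 0)
  structure(list(metric = metric, direction = direction,
                 thresholds = thresholds, weight = weight),
            class = "metric_spec")
}

#' Canonical quality-metric names
#'
#' The twelve metrics aggregated by the default star scheme, in table order.
#' `rama_core` and `rama_disallowed` together form the Ramachandran metric
#' (weight 0.5 each); `labelled_residues` is the summed count of residues
#' flagged by the Ramachandran and chi1-chi2 analyses.
#'
#' @return Character vector of metric names.
#' @export
quality_metrics <- function() {
  c("errat", "verify3d", "prove", "rama_core", "rama_disallowed",
    "labelled_residues", "rwplus", "molprobity", "rosetta", "dfire",
    "goap", "opus_psp", "global_quality")
}

#' Default star ranges for the twelve quality metrics
#'
#' Loads the packaged star-range table (per-metric direction, weight and the
#' three star boundaries) used for GPCR model ranking. Energy-type potentials
#' (RWplus, GOAP) are on their full scale here (e.g. RWplus 3-star boundary
#' -79000 kcal/mol).
#'
#' @param path optional path to a JSON spec file with the same schema; the
#'   packaged default is used when missing.
#' @return Named list of [metric_spec()] objects.
#' @export
default_star_spec <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "star_ranges_default.json",
                        package = "gpcrstars", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  specs <- lapply(raw, function(x)
    metric_spec(x$metric, x$direction, unlist(x$thresholds), x$weight))
  stats::setNames(specs, vapply(specs, `[[`, "", "metric"))
}

#' Write a metric-spec list to JSON
#'
#' @param specs named list of [metric_spec()] objects.
#' @param path output file.
#' @export
write_star_spec <- function(specs, path) {
  jsonlite::write_json(unname(lapply(specs, unclass)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Assign 0-3 stars to a single metric value
#'
#' Three stars if the value meets the best boundary, cascading down;
#' boundaries are inclusive in the direction of the comparator as printed
#' (e.g. VERIFY 3D ">= 61" gives exactly 61 one star). A missing value gets
#' 0 stars. The returned count is unweighted.
#'
#' @param value metric value (may be `NA`).
#' @param spec a [metric_spec()].
#' @return Integer star count in `0:3`.
#' @export
assign_stars <- function(value, spec) {
  stopifnot(inherits(spec, "metric_spec"))
  if (length(value) != 1) stop("assign_stars() is scalar; see star_table()")
  if (is.na(value)) return(0L)
  if (!is.finite(value)) stop("non-finite value for metric '", spec$metric, "'")
  meets <- if (spec$direction == "higher") value >= spec$thresholds
           else value <= spec$thresholds
  # thresholds ordered best->worst, so stars = count of boundaries met from
  # the worst end upward
  if (meets[1]) 3L else if (meets[2]) 2L else if (meets[3]) 1L else 0L
}

#' Derive star boundaries from a metric population by quartiles
#'
#' Splits the observed values of one metric across a model population into
#' four ranges at the quartiles, oriented so that better values earn more
#' stars. This is the procedure used to construct a star-range table from a
#' pool of scored structures; a published range table can be used instead
#' via [default_star_spec()].
#'
#' @param values numeric vector of at least 4 finite observations (NAs
#'   dropped).
#' @param direction `"higher"` or `"lower"` (better direction).
#' @param metric name recorded in the resulting spec.
#' @param weight weight recorded in the resulting spec.
#' @return A [metric_spec()] with thresholds at the quartiles.
#' @export
derive_thresholds <- function(values, direction = c("higher", "lower"),
                              metric = "metric", weight = 1) {
  direction <- match.arg(direction)
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("need at least 4 finite values")
  if (max(values) == min(values)) stop("degenerate population: all values equal")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  thr <- if (direction == "higher") rev(q) else q
  metric_spec(metric, direction, thr, weight)
}

#' Combined Ramachandran sub-star value
#'
#' The Ramachandran core and disallowed percentages are binned separately,
#' each weighted 0.5, then summed, giving a half-star-granular value in
#' `[0, 3]`. A missing component contributes 0.
#'
#' @param core percent of residues in the core region.
#' @param disallowed percent of residues in disallowed regions.
#' @param specs named list of metric specs containing `rama_core` and
#'   `rama_disallowed` (default [default_star_spec()]).
#' @return Numeric in `[0, 3]` with 0.5 granularity.
#' @export
ramachandran_substar <- function(core, disallowed, specs = default_star_spec()) {
  s_core <- assign_stars(core, specs$rama_core)
  s_dis <- assign_stars(disallowed, specs$rama_disallowed)
  specs$rama_core$weight * s_core + specs$rama_disallowed$weight * s_dis
}

#' Read a model quality-score table
#'
#' Reads a CSV/TSV table of raw quality-metric values, one row per model.
#' Header synonyms for the canonical metric names are accepted (e.g.
#' `verify_3d`, `molprob`, `rw`, `pred_global_quality`); `"-"` or empty
#' cells are missing values. Columns that match no known metric are dropped
#' with a message (score workbooks often carry bookkeeping columns).
#'
#' @param path CSV or TSV file (separator sniffed from the header line).
#' @param rescale_energies if `TRUE` (default) the `rwplus` and `goap`
#'   columns are multiplied by 10 on ingest. Published score tables often
#'   print these two potentials divided by ten relative to the star-range
#'   scale (e.g. -7987 against a 3-star boundary of -79000); the flag makes
#'   that convention explicit.
#' @param rama_split if the table carries separate `rama_labelled` and
#'   `chi_labelled` columns they are summed into `labelled_residues`.
#' @return Data frame with `model` plus canonical metric columns.
#' @export
read_quality_table <- function(path, rescale_energies = TRUE,
                               rama_split = TRUE) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("-", ""),
                          check.names = FALSE, strip.white = TRUE)
  canon <- c(
    model = "model", model_id = "model",
    errat = "errat", verify3d = "verify3d", verify_3d = "verify3d",
    prove = "prove", rama_core = "rama_core", core = "rama_core",
    rama_disallowed = "rama_disallowed", disall = "rama_disallowed",
    labelled_residues = "labelled_residues", labelled = "labelled_residues",
    rama_labelled = "rama_labelled", chi_labelled = "chi_labelled",
    rwplus = "rwplus", rw = "rwplus",
    molprobity = "molprobity", molprob = "molprobity",
    rosetta = "rosetta", rosetta_energy = "rosetta",
    dfire = "dfire", goap = "goap",
    opus_psp = "opus_psp", opus = "opus_psp",
    global_quality = "global_quality",
    pred_global_quality = "global_quality",
    predicted_global_quality = "global_quality")
  key <- tolower(gsub("[^a-z0-9]+", "_", tolower(names(df))))
  key <- gsub("^_|_$", "", key)
  mapped <- canon[key]
  drop <- is.na(mapped)
  if (any(drop))
    message("dropping unrecognised column(s): ",
            paste(names(df)[drop], collapse = ", "))
  df <- df[!drop]
  names(df) <- mapped[!drop]
  if (!"model" %in% names(df)) stop("no model identifier column found")
  if (rama_split && all(c("rama_labelled", "chi_labelled") %in% names(df))) {
    df$labelled_residues <- df$rama_labelled + df$chi_labelled
    df$rama_labelled <- df$chi_labelled <- NULL
  }
  for (m in setdiff(quality_metrics(), names(df))) df[[m]] <- NA_real_
  df <- df[c("model", quality_metrics())]
  if (rescale_energies) {
    df$rwplus <- df$rwplus * 10
    df$goap <- df$goap * 10
  }
  pct <- c("errat", "verify3d", "prove", "rama_core", "rama_disallowed")
  for (m in pct)
    if (any(df[[m]] < 0 | df[[m]] > 100, na.rm = TRUE))
      stop("percent metric '", m, "' outside [0, 100]")
  if (any(df$labelled_residues < 0, na.rm = TRUE))
    stop("labelled_residues must be >= 0")
  df
}

#' Packaged quality-score fixture (eight ranked receptor models)
#'
#' Raw metric values for the eight GPR18 models carried through the worked
#' examples, as printed in the source score table (energies on the
#' divided-by-ten print scale; pass through [read_quality_table()] with
#' `rescale_energies = TRUE`, the default).
#'
#' @inheritParams read_quality_table
#' @return Data frame as from [read_quality_table()].
#' @export
gpr18_quality_table <- function(rescale_energies = TRUE) {
  read_quality_table(system.file("extdata", "gpr18_quality.csv",
                                 package = "gpcrstars", mustWork = TRUE),
                     rescale_energies = rescale_energies)
}

#' Per-model star table and weighted totals
#'
#' Assigns stars to every metric of every model and sums them with the spec
#' weights. Missing metrics contribute 0 stars. Under the default 12-metric
#' scheme totals lie in `[0, 36]` with 0.5 granularity.
#'
#' @param records data frame from [read_quality_table()] (or with the same
#'   canonical columns).
#' @param specs named list of [metric_spec()] objects (default
#'   [default_star_spec()]).
#' @return Data frame with `model`, one weighted-star column per metric, and
#'   `total`.
#' @export
star_table <- function(records, specs = default_star_spec()) {
  stopifnot(is.data.frame(records), "model" %in% names(records))
  if (anyDuplicated(records$model)) stop("duplicate model identifiers")
  metrics <- names(specs)
  missing_cols <- setdiff(metrics, names(records))
  if (length(missing_cols))
    stop("records lack metric column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(model = records$model, stringsAsFactors = FALSE)
  for (m in metrics) {
    stars <- vapply(records[[m]], assign_stars, integer(1), spec = specs[[m]])
    out[[m]] <- stars * specs[[m]]$weight
  }
  out$total <- rowSums(out[metrics])
  out
}

#' Total weighted stars for one model record
#'
#' @param record one-row data frame or named list/vector of metric values.
#' @param specs named list of [metric_spec()] objects.
#' @return Numeric total.
#' @export
total_stars <- function(record, specs = default_star_spec()) {
  vals <- vapply(names(specs), function(m) {
    v <- record[[m]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  sum(vapply(names(specs), function(m)
    assign_stars(vals[[m]], specs[[m]]) * specs[[m]]$weight, numeric(1)))
}

#' Write a star table to CSV or JSON
#'
#' @param stars data frame from [star_table()].
#' @param path output path; `.json` writes JSON records, anything else CSV.
#' @export
write_star_table <- function(stars, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(stars, path, auto_unbox = TRUE, digits = NA)
  else
    utils::write.csv(stars, path, row.names = FALSE)
  invisible(path)
}
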