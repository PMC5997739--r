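#' Read a correlation structure from CSV
#'
#' Expects a first column `item` holding the item labels, one column per
#' item label with the correlations, and optionally columns `sd` and
#' `r_crit`. The diagonal cells must be 1. Files carrying only the lower
#' or upper triangle (other cells empty) are mirrored automatically;
#' when both triangles are present they must agree within 1e-12. Parse
#' problems are reported with row/column coordinates.
#'
#' @param path path to the CSV file.
#' @return A [corr_structure()].
#' @seealso [write_structure()]
#' @export
read_structure <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (!"item" %in% names(df))
    stop("malformed header: first column must be 'item'", call. = FALSE)
  labels <- df$item
  extra <- setdiff(names(df), c("item", labels, "sd", "r_crit"))
  if (length(extra))
    stop("unrecognized column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing_cols <- setdiff(labels, names(df))
  if (length(missing_cols))
    stop("missing correlation column(s) for item(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  p <- length(labels)
  num <- function(x, row, col) {
    x[x == ""] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s'",
                   row[bad[1]], col), call. = FALSE)
    v
  }
  M <- sapply(labels, function(l) num(df[[l]], seq_len(p), l))
  M <- matrix(as.numeric(M), p, p, dimnames = list(labels, labels))
  for (i in seq_len(p)) {
    if (is.na(M[i, i]))
      stop(sprintf("missing diagonal cell at row %d, column '%s'",
                   i, labels[i]), call. = FALSE)
    if (M[i, i] != 1)
      stop(sprintf("diagonal cell at row %d, column '%s' is %s, must be 1",
                   i, labels[i], format(M[i, i])), call. = FALSE)
  }
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    a <- M[i, j]; b <- M[j, i]
    if (is.na(a) && is.na(b))
      stop(sprintf("correlation between items '%s' and '%s' missing in both triangles",
                   labels[i], labels[j]), call. = FALSE)
    if (is.na(a)) M[i, j] <- b
    else if (is.na(b)) M[j, i] <- a
    else if (abs(a - b) > 1e-12)
      stop(sprintf("asymmetry beyond tolerance at row %d, column '%s' (%s vs %s)",
                   i, labels[j], format(a), format(b)), call. = FALSE)
  }
  sd <- if ("sd" %in% names(df)) num(df$sd, seq_len(p), "sd")
  r_crit <- if ("r_crit" %in% names(df)) num(df$r_crit, seq_len(p), "r_crit")
  corr_structure(M, labels = labels, sd = sd, r_crit = r_crit)
}

#' Write a correlation structure to CSV
#'
#' Emits the full symmetric matrix in the schema read by
#' [read_structure()], with `sd` and `r_crit` columns when present.
#'
#' @param structure a [corr_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "corr_structure"))
  df <- data.frame(item = structure$labels,
                   structure$R, check.names = FALSE)
  if (!all(structure$sd == 1)) df$sd <- structure$sd
  if (!is.null(structure$r_crit)) df$r_crit <- structure$r_crit
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read respondent-by-item scores from CSV
#'
#' Expects a header of item labels plus, optionally, a final `criterion`
#' column holding a 0/1 classification; one respondent per row.
#'
#' @param path path to the CSV file.
#' @return An `item_response_data` object.
#' @seealso [write_responses()], [estimate_structure()]
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!ncol(df))
    stop("malformed responses file: no columns", call. = FALSE)
  crit <- NULL
  if ("criterion" %in% names(df)) {
    crit <- df$criterion
    df <- df[, setdiff(names(df), "criterion"), drop = FALSE]
    if (!all(crit %in% c(0, 1)))
      stop("criterion column must be binary 0/1", call. = FALSE)
    crit <- as.integer(crit)
  }
  for (cl in names(df)) {
    if (!is.numeric(df[[cl]]))
      stop(sprintf("non-numeric cell(s) in item column '%s'", cl),
           call. = FALSE)
  }
  scores <- as.matrix(df)
  structure(list(scores = scores, criterion = crit),
            class = "item_response_data")
}

#' @rdname read_responses
#' @param data an `item_response_data` object.
#' @export
write_responses <- function(data, path) {
  scores <- as.matrix(data$scores)
  df <- as.data.frame(scores)
  names(df) <- colnames(scores) %||% as.character(seq_len(ncol(scores)))
  if (!is.null(data$criterion)) df$criterion <- data$criterion
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation design from JSON or YAML
#'
#' The file carries the fields of [simulation_design()] (`loadings` as a
#' list of per-item rows, `factor_corr` as a list of rows, `thresholds`,
#' `crit_weights`, `crit_noise_var`, `prevalence`, `n`). YAML files
#' require the `yaml` package.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated [simulation_design()].
#' @export
read_design <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML designs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_matrix <- function(x) {
    if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  }
  simulation_design(
    loadings = as_matrix(spec$loadings),
    factor_corr = if (!is.null(spec$factor_corr)) as_matrix(spec$factor_corr),
    thresholds = if (!is.null(spec$thresholds)) spec$thresholds
                 else stats::qnorm(c(.25, .5, .75)),
    crit_weights = spec$crit_weights,
    crit_noise_var = spec$crit_noise_var %||% 1,
    prevalence = spec$prevalence %||% 0.25,
    n = spec$n %||% 242)
}

#' Item-level description of a correlation structure
#'
#' The first-inspection table a constructor looks at before selecting
#' items: the range of inter-item correlations, each item's corrected
#' item-total correlation, its criterion correlation when available, and
#' the full-pool alpha (and validity).
#'
#' @param structure a [corr_structure()].
#' @return Object of class `structure_description`: list with
#'   `inter_item_range`, `items` (data frame with per-item statistics),
#'   `alpha`, `validity`.
#' @export
describe_structure <- function(structure) {
  stopifnot(inherits(structure, "corr_structure"))
  off <- structure$R[upper.tri(structure$R)]
  items <- data.frame(
    item = structure$labels,
    item_total = if (length(structure$labels) >= 2)
      as.numeric(corrected_item_total(structure)) else NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(structure$r_crit))
    items$r_criterion <- as.numeric(structure$r_crit)
  structure(list(
    inter_item_range = range(off),
    items = items,
    alpha = if (length(structure$labels) >= 2) cronbach_alpha(structure)
            else NA_real_,
    validity = if (!is.null(structure$r_crit))
      predictive_validity(structure) else NA_real_,
    n_obs = structure$n_obs), class = "structure_description")
}

#' @export
print.structure_description <- function(x, digits = 2, ...) {
  cat(sprintf("Item pool description%s\n",
              if (!is.null(x$n_obs)) sprintf(" (n = %d)", x$n_obs) else ""))
  cat(sprintf("  inter-item correlations: %.2f to %.2f\n",
              x$inter_item_range[1], x$inter_item_range[2]))
  print(format(x$items, digits = digits), row.names = FALSE)
  cat(sprintf("  full pool: alpha = %.2f%s\n", x$alpha,
              if (!is.na(x$validity))
                sprintf(", validity = %.2f", x$validity) else ""))
  invisible(x)
}

#' Assemble and serialize an analysis report
#'
#' `analysis_report()` collects results keyed by operation name together
#' with run metadata (input descriptor, mode, warnings, package version,
#' seed); `write_report()` serializes it to JSON with deterministic key
#' order and full precision, and `read_report()` loads it back so that a
#' write/read round trip reproduces an equal value.
#'
#' @param results named list of operation results (numbers, vectors or
#'   lists).
#' @param input description of the input data (e.g. a file path).
#' @param mode `"standardized"` or `"covariance"`.
#' @param warnings character vector of warnings accumulated during the run.
#' @param seed the seed in force, if any.
#' @return `analysis_report()`: an `analysis_report` object;
#'   `read_report()`: the reloaded report.
#' @export
analysis_report <- function(results, input = "unspecified",
                            mode = c("standardized", "covariance"),
                            warnings = character(), seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(names(results)) || any(names(results) == ""))
    stop("'results' must be a fully named list", call. = FALSE)
  structure(list(
    input = input, mode = mode,
    results = results[order(names(results))],
    warnings = warnings,
    version = as.character(utils::packageVersion("cttselect")),
    seed = seed), class = "analysis_report")
}

#' @rdname analysis_report
#' @param report an `analysis_report` (or any serializable list).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname analysis_report
#' @export
read_report <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(out) <- "analysis_report"
  out
}
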