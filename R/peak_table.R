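#' Construct a peak-area table
#'
#' A `peak_table` holds a samples x metabolites matrix of non-negative LC-MS
#' peak areas together with per-sample group labels (e.g. treated/control or
#' KO/WT) and, optionally, the name of a spiked instrument-control analyte
#' (such as olomoucine) that is monitored for QC but excluded from
#' normalization and downstream statistics.
#'
#' @param areas numeric matrix, samples in rows, metabolites in columns.
#'   Row names are taken as sample ids, column names as metabolite ids.
#' @param groups character or factor of per-sample group labels, length
#'   `nrow(areas)`.
#' @param control_analyte optional name of the spiked instrument-control
#'   analyte; must be a column of `areas` if given.
#' @param normalized logical; has total-sum normalization been applied?
#' @return An object of class `"peak_table"`: a list with elements
#'   `areas`, `sample_ids`, `groups`, `metabolite_ids`, `control_analyte`
#'   and `normalized`.
#' @seealso [total_sum_normalize()], [read_peak_table()]
#' @export
peak_table <- function(areas, groups, control_analyte = NULL, normalized = FALSE) {
  areas <- as.matrix(areas)
  if (!is.numeric(areas)) stop("'areas' must be a numeric matrix")
  if (is.null(rownames(areas))) rownames(areas) <- paste0("sample_", seq_len(nrow(areas)))
  if (is.null(colnames(areas))) colnames(areas) <- paste0("met_", seq_len(ncol(areas)))
  if (anyDuplicated(rownames(areas))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(areas))) stop("duplicate metabolite ids")
  if (length(groups) != nrow(areas)) stop("'groups' must have one label per sample")
  neg <- which(!is.na(areas) & areas < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative peak area for sample '%s', metabolite '%s'",
                 rownames(areas)[neg[1, 1]], colnames(areas)[neg[1, 2]]))
  }
  if (!is.null(control_analyte) && !control_analyte %in% colnames(areas)) {
    stop(sprintf("control analyte '%s' not found in table", control_analyte))
  }
  structure(list(
    areas = areas,
    sample_ids = rownames(areas),
    groups = as.character(groups),
    metabolite_ids = colnames(areas),
    control_analyte = control_analyte,
    normalized = isTRUE(normalized)
  ), class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d samples x %d metabolites (%s)\n",
              nrow(x$areas), ncol(x$areas),
              if (x$normalized) "total-sum normalized" else "raw areas"))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$control_analyte)) {
    cat("instrument control:", x$control_analyte, "\n")
  }
  invisible(x)
}

# metabolite columns entering analysis: everything but the spiked control
analysis_columns <- function(table) {
  setdiff(table$metabolite_ids, table$control_analyte)
}

#' Read a peak-area table from CSV
#'
#' Two dialects are supported. `wide_csv`: first column `sample`, second
#' column `group`, remaining columns one metabolite each. `long_csv`:
#' columns `sample`, `group`, `metabolite`, `area`, one record per cell;
#' the long form is pivoted to wide. Cells absent from a long file become
#' `NA`, never zero.
#'
#' @param path path to a CSV file.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @param control_analyte optional instrument-control analyte name.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, dialect = c("wide_csv", "long_csv"),
                            control_analyte = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide_csv") {
    if (ncol(df) < 3 || !all(c("sample", "group") %in% names(df)[1:2])) {
      stop("wide CSV must start with 'sample' and 'group' columns")
    }
    areas <- as.matrix(df[, -(1:2), drop = FALSE])
    storage.mode(areas) <- "double"
    rownames(areas) <- df$sample
    groups <- df$group
  } else {
    need <- c("sample", "group", "metabolite", "area")
    if (!all(need %in% names(df))) {
      stop("long CSV needs columns: ", paste(need, collapse = ", "))
    }
    if (anyDuplicated(df[, c("sample", "metabolite")])) {
      stop("duplicate (sample, metabolite) records in long CSV")
    }
    samples <- unique(df$sample)
    mets <- unique(df$metabolite)
    areas <- matrix(NA_real_, length(samples), length(mets),
                    dimnames = list(samples, mets))
    areas[cbind(match(df$sample, samples), match(df$metabolite, mets))] <- df$area
    groups <- df$group[match(samples, df$sample)]
  }
  bad <- which(!is.na(areas) & areas < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative area at sample '%s', metabolite '%s' in %s",
                 rownames(areas)[bad[1, 1]], colnames(areas)[bad[1, 2]], path))
  }
  peak_table(areas, groups, control_analyte = control_analyte)
}

#' Write a peak-area table to CSV
#'
#' @param table a [peak_table()].
#' @param path output path.
#' @param dialect `"wide_csv"` or `"long_csv"` (see [read_peak_table()]).
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path, dialect = c("wide_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "peak_table"))
  if (dialect == "wide_csv") {
    df <- data.frame(sample = table$sample_ids, group = table$groups,
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(table$areas, check.names = FALSE))
  } else {
    df <- expand.grid(sample = table$sample_ids, metabolite = table$metabolite_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$group <- table$groups[match(df$sample, table$sample_ids)]
    df$area <- table$areas[cbind(match(df$sample, table$sample_ids),
                                 match(df$metabolite, table$metabolite_ids))]
    df <- df[!is.na(df$area), c("sample", "group", "metabolite", "area")]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Total-sum normalization of peak areas
#'
#' Divides each sample's areas by that sample's total area over all
#' quantified cellular metabolites, so every sample's (non-missing) row sums
#' to one. The spiked instrument-control analyte, if designated, is excluded
#' from the denominator: it is added at fixed concentration after extraction
#' and carries no information about cellular content. Missing cells are
#' excluded from the denominator and stay missing. Normalization removes
#' per-sample global scale (loading, injection-volume) factors while
#' preserving within-sample proportions.
#'
#' @param table an unnormalized [peak_table()].
#' @return The normalized [peak_table()] (`normalized = TRUE`).
#' @export
total_sum_normalize <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  if (table$normalized) stop("table is already total-sum normalized")
  cols <- analysis_columns(table)
  totals <- rowSums(table$areas[, cols, drop = FALSE], na.rm = TRUE)
  zero <- totals <= 0
  if (any(zero)) {
    stop(sprintf("sample '%s' has zero total area; cannot normalize",
                 table$sample_ids[which(zero)[1]]))
  }
  table$areas <- sweep(table$areas, 1, totals, "/")
  table$normalized <- TRUE
  table
}

#' Instrument-control QC from a spiked analyte
#'
#' Computes the coefficient of variation (sd/mean, n-1 denominator) of the
#' spiked control analyte's raw areas across all samples and compares it to
#' an acceptance limit. The default limit of 0.2 follows common practice for
#' spiked LC-MS controls.
#'
#' @param table a [peak_table()] of raw (unnormalized) areas.
#' @param control_analyte analyte name; defaults to the table's designated
#'   control.
#' @param cv_limit maximum acceptable CV (fraction).
#' @return A list of class `"qc_report"`: `control_analyte`, `control_cv`,
#'   `cv_limit`, `pass`, `excluded_samples`.
#' @export
qc_instrument_control <- function(table, control_analyte = table$control_analyte,
                                  cv_limit = 0.2) {
  stopifnot(inherits(table, "peak_table"))
  if (is.null(control_analyte)) stop("no control analyte designated")
  if (!control_analyte %in% table$metabolite_ids) {
    stop(sprintf("control analyte '%s' not in table", control_analyte))
  }
  if (table$normalized) {
    warning("instrument-control CV should be computed on raw areas")
  }
  v <- table$areas[, control_analyte]
  cv <- stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE)
  structure(list(
    control_analyte = control_analyte,
    control_cv = cv,
    cv_limit = cv_limit,
    pass = cv <= cv_limit,
    excluded_samples = character(0)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("instrument control '%s': CV = %.4f (limit %.2f) -> %s\n",
              x$control_analyte, x$control_cv, x$cv_limit,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' TEER monolayer-integrity filter
#'
#' Wells with transepithelial electrical resistance strictly greater than
#' the threshold are considered intact monolayers. The default threshold is
#' 1000 ohm cm2.
#'
#' @param teer_values numeric vector of TEER readings (ohm cm2), all >= 0.
#' @param threshold pass threshold (ohm cm2); comparison is strict (`>`).
#' @return Logical mask, `TRUE` for intact wells.
#' @export
teer_filter <- function(teer_values, threshold = 1000) {
  if (length(teer_values) == 0) return(logical(0))
  if (any(teer_values < 0, na.rm = TRUE)) stop("TEER values must be >= 0")
  !is.na(teer_values) & teer_values > threshold
}
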