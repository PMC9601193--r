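#' Transporter classification thresholds
#'
#' The published inhibition-score ranges: Pgp inhibition is called for a
#' score strictly above `pgp_min` (600), MRP2 inhibition for a score in
#' the closed interval `[mrp2_min, mrp2_max]` (300 to 600), and BCRP
#' interaction for a score strictly below `bcrp_max` (0).
#'
#' @param pgp_min,mrp2_min,mrp2_max,bcrp_max numeric bounds (%-points).
#' @return List of class `"score_thresholds"`.
#' @export
score_thresholds <- function(pgp_min = 600, mrp2_min = 300, mrp2_max = 600,
                             bcrp_max = 0) {
  if (mrp2_min >= mrp2_max) stop("mrp2_min must be < mrp2_max")
  structure(list(pgp_min = pgp_min, mrp2_min = mrp2_min,
                 mrp2_max = mrp2_max, bcrp_max = bcrp_max),
            class = "score_thresholds")
}

#' Summed percent-change inhibition score
#'
#' The transporter inhibition score: the signed sum, over the signature
#' metabolites, of the percent change of treated vs control normalized
#' areas. Directions are not folded in — decreases contribute
#' negatively, which is what makes the BCRP range negative.
#'
#' Missing signature members are tolerated up to half the panel: the
#' score is computed over the present members and the omissions are
#' recorded in the `"missing_members"` attribute; with more than 50%
#' missing an error is raised.
#'
#' @param changes a [percent_change_table()].
#' @param signature a `signature_set` (see [derive_signature()] /
#'   [reference_signatures()]).
#' @return Numeric score (%-points) with attributes `missing_members`
#'   and `n_used`.
#' @export
inhibition_score <- function(changes, signature) {
  members <- signature$members$metabolite
  if (length(members) == 0) stop("signature has no members")
  idx <- match(members, changes$metabolite)
  present <- !is.na(idx) & !is.na(changes$percent_change[idx])
  missing <- members[!present]
  if (length(missing) > length(members) / 2) {
    stop(sprintf("%d of %d signature metabolites missing from the data",
                 length(missing), length(members)))
  }
  score <- sum(changes$percent_change[idx[present]])
  structure(score, missing_members = missing, n_used = sum(present))
}

#' Classify transporter scores against the published ranges
#'
#' Independent boolean flags per transporter (no forced single label;
#' overlapping flags are all reported): `pgp` if score > `pgp_min`,
#' `mrp2` if `mrp2_min <= score <= mrp2_max`, `bcrp` if score <
#' `bcrp_max`.
#'
#' @param scores named numeric vector or list with elements `pgp`,
#'   `mrp2`, `bcrp` (%-points).
#' @param thresholds a [score_thresholds()].
#' @return Named logical vector of flags.
#' @export
classify_scores <- function(scores, thresholds = score_thresholds()) {
  scores <- unlist(scores)
  need <- c("pgp", "mrp2", "bcrp")
  if (!all(need %in% names(scores))) {
    stop("scores must include pgp, mrp2 and bcrp")
  }
  c(pgp = unname(scores["pgp"] > thresholds$pgp_min),
    mrp2 = unname(scores["mrp2"] >= thresholds$mrp2_min &
                    scores["mrp2"] <= thresholds$mrp2_max),
    bcrp = unname(scores["bcrp"] < thresholds$bcrp_max))
}

#' Score and classify a set of experiments
#'
#' For each experiment (one compound's treated-vs-control percent-change
#' table), computes the inhibition score against each transporter's
#' signature and classifies the score triple against the published
#' ranges.
#'
#' @param experiments list; each element a list with `changes` (a
#'   [percent_change_table()]) and optionally `compound`.
#' @param signatures named list of `signature_set`s for `pgp`, `mrp2`,
#'   `bcrp`; defaults to the packaged reference signatures.
#' @param thresholds a [score_thresholds()].
#' @return Data frame of class `"inhibition_score_report"`, one row per
#'   experiment: `compound`, `pgp_score`, `mrp2_score`, `bcrp_score`,
#'   `pgp_flag`, `mrp2_flag`, `bcrp_flag`, `missing_members`.
#' @export
score_report <- function(experiments, signatures = reference_signatures(),
                         thresholds = score_thresholds()) {
  need <- c("pgp", "mrp2", "bcrp")
  if (!all(need %in% names(signatures))) {
    stop("signatures must be supplied for pgp, mrp2 and bcrp")
  }
  rows <- lapply(seq_along(experiments), function(i) {
    e <- experiments[[i]]
    scores <- vapply(need, function(tr)
      as.numeric(inhibition_score(e$changes, signatures[[tr]])), numeric(1))
    miss <- unlist(lapply(need, function(tr)
      attr(inhibition_score(e$changes, signatures[[tr]]), "missing_members")))
    flags <- classify_scores(scores, thresholds)
    data.frame(compound = e$compound %||% paste0("experiment_", i),
               pgp_score = scores["pgp"], mrp2_score = scores["mrp2"],
               bcrp_score = scores["bcrp"],
               pgp_flag = flags["pgp"], mrp2_flag = flags["mrp2"],
               bcrp_flag = flags["bcrp"],
               missing_members = paste(miss, collapse = ";"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("inhibition_score_report", "data.frame")
  out
}

#' One-call analysis of a single raw experiment
#'
#' Convenience wrapper chaining total-sum normalization, OPLS-DA,
#' VIP scores and the percent-change table for one raw treated/control
#' peak table. The synthetic experiments of [generate_experiment_set()]
#' plant purely class-predictive structure, so `n_orthogonal = 0` is the
#' appropriate default there; pass `n_orthogonal = NULL` to select it by
#' cross-validation.
#'
#' @param table a raw [peak_table()].
#' @param labels per-sample labels (default: the table's groups).
#' @param n_orthogonal orthogonal components; `NULL` selects via
#'   [select_n_orthogonal()].
#' @param cv_folds folds for q2 (0 skips it, the fast path for scoring).
#' @param ... further arguments to [opls_da()].
#' @return List with `table` (normalized), `model`, `vip`, `changes`.
#' @export
analyze_experiment <- function(table, labels = NULL, n_orthogonal = 0,
                               cv_folds = 0, ...) {
  labels <- labels %||% table$groups
  norm <- total_sum_normalize(table)
  if (is.null(n_orthogonal)) {
    n_orthogonal <- as.integer(select_n_orthogonal(norm, labels))
  }
  model <- opls_da(norm, labels, n_orthogonal = n_orthogonal,
                   cv_folds = cv_folds, ...)
  list(table = norm, model = model, vip = vip_scores(model),
       changes = percent_change_table(norm, labels))
}
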