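#' Per-metabolite percent change with Mann-Whitney statistics
#'
#' For every cellular metabolite, the percent change of the treated group
#' relative to control on normalized areas,
#' `100 * (mean_treated - mean_control) / mean_control`, together with a
#' two-sided Mann-Whitney U test and the conventional significance tier.
#' No multiplicity correction is applied to the tiers; a
#' Benjamini-Hochberg adjusted column (`p_bh`) is provided as
#' supplementary output only.
#'
#' @param table a normalized [peak_table()].
#' @param labels two-class per-sample labels; the second factor level is
#'   "treated". Defaults to the table's groups with control as reference
#'   when labelled `control`/`WT`.
#' @return Data frame of class `"percent_change_table"` with columns
#'   `metabolite`, `percent_change`, `u_statistic`, `p_value`, `p_bh`,
#'   `tier`. Metabolites with a zero control mean get `NA` percent change
#'   (undefined), never silently dropped.
#' @export
percent_change_table <- function(table, labels = NULL) {
  stopifnot(inherits(table, "peak_table"))
  if (!table$normalized) stop("percent changes are defined on normalized areas")
  labels <- labels %||% table$groups
  y <- encode_labels(labels)
  treated <- y$y > 0
  cols <- analysis_columns(table)
  X <- table$areas[, cols, drop = FALSE]
  res <- lapply(cols, function(m) {
    a <- X[treated, m]
    b <- X[!treated, m]
    mc <- mean(b, na.rm = TRUE)
    pc <- if (is.na(mc) || mc == 0) NA_real_ else
      100 * (mean(a, na.rm = TRUE) - mc) / mc
    mw <- mann_whitney_u(a[!is.na(a)], b[!is.na(b)])
    data.frame(metabolite = m, percent_change = pc,
               u_statistic = mw$u, p_value = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$tier <- significance_tier(out$p_value)
  out <- out[, c("metabolite", "percent_change", "u_statistic", "p_value",
                 "p_bh", "tier")]
  class(out) <- c("percent_change_table", "data.frame")
  out
}

significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Two-sided Mann-Whitney U test
#'
#' Unpaired two-sample rank test. The exact null distribution is used
#' when both samples have at most 8 observations and there are no ties;
#' otherwise the normal approximation with midrank tie correction and
#' continuity correction is used.
#'
#' @param a,b numeric samples (each non-empty).
#' @return List with `u` (the U statistic for `a`, i.e. the number of
#'   pairs where `a > b`, counting ties as half) and `p` (two-sided).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= 8 && length(b) <= 8
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # degenerate case: all observations identical
  list(u = unname(wt$statistic), p = min(p, 1))
}

#' Derive a consensus transporter signature
#'
#' A metabolite enters the signature when its VIP score exceeds
#' `vip_threshold` (strictly) in every derivation experiment — the
#' main-inhibitor experiments and the knockout experiment — and the sign
#' of its percent change is identical across all experiments, including
#' any additional validation inhibitors. Experiments marked
#' `validation = TRUE` do not gate on VIP but still participate in the
#' direction-consistency check. Metabolites passing the VIP rule but
#' changing direction between experiments are excluded and recorded,
#' not raised as errors. Requiring the VIP threshold in every derivation
#' experiment is what suppresses chance passes at small replicate
#' numbers; a single-experiment VIP gate admits spurious members.
#'
#' @param experiments list of experiments, each a list with elements
#'   `changes` (a [percent_change_table()]), `vip` (a [vip_scores()]
#'   result), `kind` (`"inhibitor"` or `"knockout"`) and optionally
#'   `validation` (logical: direction check only) and `compound`.
#' @param vip_threshold signature cut-off (strict `>`), default 0.75.
#' @param transporter optional transporter label stored in the result.
#' @return List of class `"signature_set"`: `transporter`, `members`
#'   (data frame `metabolite`, `direction`), `provenance` (per member,
#'   the experiments where VIP passed) and `excluded` (direction
#'   conflicts, with reasons).
#' @export
derive_signature <- function(experiments, vip_threshold = 0.75,
                             transporter = NA_character_) {
  kinds <- vapply(experiments, function(e) e$kind, character(1))
  if (!any(kinds == "inhibitor") || !any(kinds == "knockout")) {
    stop("need at least one inhibitor and one knockout experiment")
  }
  gating <- !vapply(experiments, function(e) isTRUE(e$validation), logical(1))
  if (!any(gating)) stop("all experiments are marked validation-only")
  labels <- vapply(seq_along(experiments), function(i) {
    experiments[[i]]$compound %||% paste0(experiments[[i]]$kind, "_", i)
  }, character(1))

  vip_of <- function(e) e$vip$vip
  candidates <- sort(Reduce(intersect, lapply(experiments[gating], function(e) {
    names(which(vip_of(e) > vip_threshold))
  })))

  members <- list(); provenance <- list(); excluded <- list()
  for (m in candidates) {
    signs <- vapply(experiments, function(e) {
      pc <- e$changes$percent_change[match(m, e$changes$metabolite)]
      if (is.na(pc)) NA_real_ else sign(pc)
    }, numeric(1))
    signs_ok <- signs[!is.na(signs)]
    if (length(signs_ok) == 0 || any(signs_ok == 0) ||
        length(unique(signs_ok)) > 1) {
      excluded[[m]] <- sprintf(
        "direction conflict across experiments (%s)",
        paste(sprintf("%s:%+d", labels[!is.na(signs)], as.integer(signs_ok)),
              collapse = ", "))
      next
    }
    members[[m]] <- if (signs_ok[1] > 0) "up" else "down"
    provenance[[m]] <- labels[vapply(experiments, function(e)
      isTRUE(vip_of(e)[m] > vip_threshold), logical(1))]
  }
  members_df <- if (length(members)) {
    data.frame(metabolite = names(members), direction = unname(unlist(members)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(metabolite = character(0), direction = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(
    transporter = transporter,
    members = members_df,
    provenance = provenance,
    excluded = excluded,
    vip_threshold = vip_threshold
  ), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature set (%s): %d member(s), VIP > %.2f\n",
              x$transporter, nrow(x$members), x$vip_threshold))
  if (nrow(x$members)) print(x$members)
  if (length(x$excluded)) {
    cat("excluded:\n")
    for (m in names(x$excluded)) cat(sprintf("  %s: %s\n", m, x$excluded[[m]]))
  }
  invisible(x)
}

#' Packaged reference signatures
#'
#' The published consensus signatures: 11 metabolites increased under Pgp
#' inhibition; glutamate, hypoxanthine and xanthine decreased and
#' pantothenate increased under BCRP inhibition; 9 metabolites altered
#' under MRP2 inhibition (acetylcarnitine decreased, the rest increased).
#' Stored as JSON under `inst/extdata/signatures/`.
#'
#' @return Named list of `signature_set` objects: `pgp`, `bcrp`, `mrp2`.
#' @export
reference_signatures <- function() {
  dir <- system.file("extdata", "signatures", package = "effluxsig")
  out <- lapply(c(pgp = "pgp", bcrp = "bcrp", mrp2 = "mrp2"), function(tr) {
    j <- jsonlite::read_json(file.path(dir, paste0(tr, ".json")),
                             simplifyVector = TRUE)
    structure(list(transporter = j$transporter,
                   members = as.data.frame(j$members),
                   provenance = list(), excluded = list(),
                   vip_threshold = j$vip_threshold),
              class = "signature_set")
  })
  out
}

#' Concentration-dependence trend test
#'
#' Spearman rank correlation of a metabolite's percent change against the
#' dose level across an ordered series of experiments, with the exact
#' small-sample p-value when possible. A constant percent-change profile
#' (all tied) has an undefined correlation and is reported as `rho = 0`,
#' `p = 1` by convention.
#'
#' @param tables list of [percent_change_table()]s, ordered by dose.
#' @param metabolite metabolite name, present in every table.
#' @param doses optional numeric dose levels (defaults to the rank order).
#' @return List with `rho` and `p`.
#' @export
concentration_trend <- function(tables, metabolite, doses = seq_along(tables)) {
  if (length(tables) < 3) stop("need at least 3 dose levels")
  pcs <- vapply(tables, function(tb) {
    i <- match(metabolite, tb$metabolite)
    if (is.na(i)) stop(sprintf("metabolite '%s' absent from a dose table", metabolite))
    tb$percent_change[i]
  }, numeric(1))
  if (length(unique(pcs)) == 1) return(list(rho = 0, p = 1))
  ct <- suppressWarnings(stats::cor.test(doses, pcs, method = "spearman",
                                         exact = TRUE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
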