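#' VIP scores of an OPLS-DA model
#'
#' Variable importance in the projection for the single predictive
#' component: `VIP_j = sqrt(p * SSY * (w_j/|w|)^2 / SSY) = sqrt(p) * |w_j| / |w|`,
#' where `p` is the number of variables and `w` the predictive weight
#' vector. By construction the mean of the squared VIP over all variables
#' is exactly 1, so metabolites with VIP above ~1 contribute more than
#' average to the class separation; the conventional signature cut-off
#' here is VIP > 0.75.
#'
#' @param model a fitted [opls_da()] model.
#' @param threshold reporting threshold stored with the result.
#' @return List of class `"vip_result"` with `vip` (named per-metabolite
#'   scores) and `threshold`.
#' @export
vip_scores <- function(model, threshold = 0.75) {
  stopifnot(inherits(model, "opls_da"))
  w <- model$weights
  p <- length(w)
  vip <- sqrt(p) * abs(w) / sqrt(sum(w^2))
  structure(list(vip = stats::setNames(vip, model$variable_ids),
                 threshold = threshold),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  above <- sum(x$vip > x$threshold)
  cat(sprintf("VIP scores for %d variables; %d above threshold %.2f\n",
              length(x$vip), above, x$threshold))
  print(round(sort(x$vip, decreasing = TRUE)[seq_len(min(8, length(x$vip)))], 3))
  invisible(x)
}

#' DModX and Hotelling T-squared outlier report
#'
#' Flags model outliers by two complementary criteria, as in standard
#' OPLS-DA practice: samples with a large distance to the model in X-space
#' (DModX — normalized residual standard deviation, critical value from an
#' F-quantile) and samples outside the Hotelling T-squared confidence
#' ellipse of the combined predictive + orthogonal score space.
#'
#' @param model a fitted [opls_da()] model.
#' @param alpha significance level in (0, 1) for both critical values.
#' @return List of class `"outlier_report"`: `dmodx`, `dmodx_critical`,
#'   `t2`, `t2_critical`, `flagged` (data frame of sample id + criterion).
#' @export
outlier_report <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "opls_da"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  E <- model$residuals
  n <- nrow(E)
  p <- ncol(E)
  a <- 1 + ncol(model$ortho_scores)
  dof_i <- max(p - a, 1)
  dof_m <- max((n - a - 1) * (p - a), 1)
  s_i <- sqrt(rowSums(E^2) / dof_i)
  s0 <- sqrt(sum(E^2) / dof_m)
  dmodx <- if (s0 > 0) s_i / s0 else rep(0, n)
  dcrit <- sqrt(stats::qf(1 - alpha, dof_i, dof_m))

  Tm <- cbind(model$scores, model$ortho_scores)
  v <- apply(Tm, 2, stats::var)
  v[v == 0] <- Inf
  t2 <- rowSums(sweep(Tm^2, 2, v, "/"))
  t2crit <- if (n > a) a * (n - 1) / (n - a) * stats::qf(1 - alpha, a, n - a) else Inf

  flag_d <- dmodx > dcrit
  flag_t <- t2 > t2crit
  ids <- model$sample_ids
  flagged <- data.frame(
    sample = ids[flag_d | flag_t],
    criterion = vapply(which(flag_d | flag_t), function(i) {
      paste(c(if (flag_d[i]) "dmodx", if (flag_t[i]) "t2"), collapse = "+")
    }, character(1)),
    stringsAsFactors = FALSE)
  structure(list(dmodx = stats::setNames(dmodx, ids), dmodx_critical = dcrit,
                 t2 = stats::setNames(t2, ids), t2_critical = t2crit,
                 alpha = alpha, flagged = flagged),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier diagnostics (alpha = %.2f): DModX crit %.3f, T2 crit %.3f\n",
              x$alpha, x$dmodx_critical, x$t2_critical))
  if (nrow(x$flagged) == 0) cat("no samples flagged\n") else print(x$flagged)
  invisible(x)
}

#' Iterative outlier elimination with refitting
#'
#' Repeats fit, flag, drop until no sample is flagged or `max_rounds` is
#' reached. Never drops a class below 3 samples: if flagged samples would
#' do so, only the worst offenders down to that floor are removed and a
#' warning is raised.
#'
#' @inheritParams opls_da
#' @param alpha significance level for [outlier_report()].
#' @param max_rounds maximum elimination passes (>= 1).
#' @param ... further arguments to [opls_da()].
#' @return List with `table` (cleaned [peak_table()] or matrix), `labels`,
#'   `model` (final fit), `report` (final [outlier_report()]) and
#'   `removed` (sample ids dropped, in order).
#' @export
remove_outliers_and_refit <- function(x, y, alpha = 0.05, max_rounds = 3, ...) {
  if (max_rounds < 1) stop("max_rounds must be >= 1")
  labels <- as.character(y)
  removed <- character(0)
  for (round in seq_len(max_rounds + 1)) {
    model <- opls_da(x, labels, ...)
    rep <- outlier_report(model, alpha = alpha)
    if (round > max_rounds || nrow(rep$flagged) == 0) break
    drop_ids <- rep$flagged$sample
    keep <- !(model$sample_ids %in% drop_ids)
    for (cls in unique(labels)) {
      in_cls <- labels == cls
      if (sum(keep & in_cls) < 3) {
        n_allow <- sum(in_cls) - 3
        if (n_allow <= 0) {
          warning(sprintf("class '%s' would fall below 3 samples; keeping flagged samples", cls))
          keep[in_cls] <- TRUE
          next
        }
        flag_cls <- which(in_cls & !keep)
        sev <- rep$dmodx[flag_cls] / rep$dmodx_critical +
          rep$t2[flag_cls] / rep$t2_critical
        keep[flag_cls[order(sev, decreasing = TRUE)][-seq_len(n_allow)]] <- TRUE
        warning(sprintf("class '%s': limited outlier removal to keep 3 samples", cls))
      }
    }
    if (all(keep)) break
    if (length(unique(labels[keep])) < 2) stop("outlier removal would empty a class")
    removed <- c(removed, model$sample_ids[!keep])
    x <- subset_samples(x, keep)
    labels <- labels[keep]
  }
  list(table = x, labels = labels, model = model, report = rep, removed = removed)
}

subset_samples <- function(x, keep) {
  if (inherits(x, "peak_table")) {
    peak_table(x$areas[keep, , drop = FALSE], x$groups[keep],
               control_analyte = x$control_analyte, normalized = x$normalized)
  } else {
    as.matrix(x)[keep, , drop = FALSE]
  }
}
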