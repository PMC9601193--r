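#' Orthogonal partial least squares discriminant analysis
#'
#' Fits a two-class OPLS-DA model with one predictive component and
#' `n_orthogonal` y-orthogonal components, using the deterministic O-PLS
#' construction: after centering/scaling, components of X-variation
#' orthogonal to the class response are extracted and deflated one at a
#' time, then a single predictive PLS component is fitted on the filtered
#' matrix. With a single response the weight vectors are closed-form
#' (`w = X'y / |X'y|`), so the fit involves no iteration and no random
#' initialization.
#'
#' `q2`, the cross-validated fraction of class variance predicted, is
#' estimated by k-fold cross-validation with class-interleaved
#' ("venetian blind") fold assignment, deterministic given `cv_seed`.
#'
#' @param x a normalized [peak_table()] (the spiked control analyte, if
#'   designated, is dropped) or a numeric samples x variables matrix.
#' @param y two-class factor/character/logical of per-sample labels; the
#'   second factor level is coded +1 ("treated").
#' @param n_orthogonal number of y-orthogonal components (>= 0).
#' @param scaling variable scaling after mean-centering: `"unit_variance"`
#'   (default, the usual choice for peak-area metabolomics), `"pareto"`
#'   or `"center_only"`.
#' @param cv_folds folds for the q2 estimate; `0` skips cross-validation.
#' @param cv_seed integer controlling the (deterministic) fold layout.
#' @return An object of class `"opls_da"` with elements `weights`,
#'   `loadings`, `scores`, `y_loading` (the predictive part),
#'   `ortho_weights`, `ortho_loadings`, `ortho_scores` (p x k and n x k
#'   matrices), `center`, `scale`, `scaling`, `residuals` (X residual
#'   matrix after all components), `r2x`, `r2y`, `q2`, `fitted_y`,
#'   `y`, `y_levels`, `sample_ids`, `variable_ids`.
#' @examples
#' sim <- generate_peak_table(builtin_scenarios()$pgp_inhibitor, seed = 1)
#' fit <- opls_da(total_sum_normalize(sim$table),
#'                sim$table$groups, n_orthogonal = 0)
#' fit
#' head(sort(vip_scores(fit)$vip, decreasing = TRUE), 12)
#' @export
opls_da <- function(x, y, n_orthogonal = 0,
                    scaling = c("unit_variance", "pareto", "center_only"),
                    cv_folds = 7, cv_seed = 1) {
  scaling <- match.arg(scaling)
  if (inherits(x, "peak_table")) {
    if (!x$normalized) stop("peak table must be total-sum normalized before fitting")
    X <- x$areas[, analysis_columns(x), drop = FALSE]
  } else {
    X <- as.matrix(x)
  }
  y_num <- encode_labels(y)
  if (n_orthogonal < 0) stop("n_orthogonal must be >= 0")
  n <- nrow(X)
  if (length(y_num$y) != n) stop("labels do not match the number of samples")

  sc <- scale_matrix(X, scaling)
  fit <- opls_core(sc$X, y_num$y - mean(y_num$y), n_orthogonal)

  q2 <- NA_real_
  if (cv_folds > 0) {
    if (cv_folds > n) stop("more cross-validation folds than samples")
    q2 <- opls_q2(X, y_num$y, n_orthogonal, scaling, cv_folds, cv_seed)
  }

  structure(c(fit, list(
    center = sc$center, scale = sc$scale, scaling = scaling,
    n_orthogonal = n_orthogonal, q2 = q2,
    y = y_num$y, y_levels = y_num$levels,
    sample_ids = rownames(X) %||% as.character(seq_len(n)),
    variable_ids = colnames(X) %||% as.character(seq_len(ncol(X)))
  )), class = "opls_da")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

encode_labels <- function(y) {
  f <- as.factor(y)
  lev <- levels(droplevels(f))
  if (length(lev) != 2) stop("labels must define exactly two classes")
  yn <- ifelse(as.character(f) == lev[2], 1, -1)
  if (min(table(f)) < 2) stop("both classes need at least 2 samples")
  list(y = yn, levels = lev)
}

scale_matrix <- function(X, scaling) {
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  scl <- switch(scaling,
                unit_variance = sds,
                pareto = sqrt(sds),
                center_only = rep(1, ncol(X)))
  scl[scl == 0 | !is.finite(scl)] <- 1  # constant variables carry no signal
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  list(X = Xs, center = ctr, scale = scl)
}

# core O-PLS on centered/scaled X and centered y
opls_core <- function(Xs, yc, n_orthogonal) {
  ssx_total <- sum(Xs^2)
  ssy_total <- sum(yc^2)
  p <- ncol(Xs)
  Wo <- matrix(0, p, 0); Po <- matrix(0, p, 0); To <- matrix(0, nrow(Xs), 0)
  E <- Xs
  for (k in seq_len(n_orthogonal)) {
    w <- drop(crossprod(E, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("rank of X does not support the requested orthogonal components")
    w <- w / nw
    t <- drop(E %*% w)
    pv <- drop(crossprod(E, t)) / sum(t^2)
    wo <- pv - drop(crossprod(pv, w)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) stop("rank of X does not support the requested orthogonal components")
    wo <- wo / nwo
    to <- drop(E %*% wo)
    po <- drop(crossprod(E, to)) / sum(to^2)
    E <- E - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  w <- drop(crossprod(E, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("response is orthogonal to X; cannot fit a predictive component")
  w <- w / nw
  t <- drop(E %*% w)
  pv <- drop(crossprod(E, t)) / sum(t^2)
  cc <- sum(yc * t) / sum(t^2)
  resid <- E - tcrossprod(t, pv)
  fitted <- t * cc
  r2x <- 1 - sum(resid^2) / ssx_total
  r2y <- 1 - sum((yc - fitted)^2) / ssy_total
  list(weights = w, loadings = pv, scores = t, y_loading = cc,
       ortho_weights = Wo, ortho_loadings = Po, ortho_scores = To,
       residuals = resid, fitted_y = fitted, r2x = r2x, r2y = r2y)
}

# project new (already centered/scaled) rows through a fitted core model
opls_filter_project <- function(fit, Xs) {
  k <- ncol(fit$ortho_weights)
  for (j in seq_len(k)) {
    to <- drop(Xs %*% fit$ortho_weights[, j])
    Xs <- Xs - tcrossprod(to, fit$ortho_loadings[, j])
  }
  t_new <- drop(Xs %*% fit$weights)
  list(scores = t_new, y_hat = t_new * fit$y_loading)
}

# deterministic class-interleaved fold assignment
venetian_folds <- function(y, k, seed) {
  n <- length(y)
  ord <- with_seed(seed, sample.int(n))      # seeded shuffle
  by_class <- split(ord, y[ord])             # then alternate the classes so
  inter <- rbind_fill(by_class)              # every fold sees both
  folds <- integer(n)
  folds[inter] <- rep_len(seq_len(k), n)
  folds
}

rbind_fill <- function(lst) {
  m <- max(lengths(lst))
  out <- unlist(lapply(seq_len(m), function(i) {
    unlist(lapply(lst, function(v) if (i <= length(v)) v[i] else NULL))
  }))
  out
}

opls_q2 <- function(X, y, n_orthogonal, scaling, cv_folds, cv_seed) {
  folds <- venetian_folds(y, cv_folds, cv_seed)
  press <- 0
  for (f in unique(folds)) {
    test <- folds == f
    if (length(unique(y[!test])) < 2) {
      stop("cross-validation fold leaves a single class in training data")
    }
    sc <- scale_matrix(X[!test, , drop = FALSE], scaling)
    yc_train <- y[!test] - mean(y[!test])
    fit <- opls_core(sc$X, yc_train, n_orthogonal)
    Xt <- sweep(sweep(X[test, , drop = FALSE], 2, sc$center, "-"), 2, sc$scale, "/")
    pred <- opls_filter_project(fit, Xt)$y_hat + mean(y[!test])
    press <- press + sum((y[test] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' @export
print.opls_da <- function(x, ...) {
  cat(sprintf("OPLS-DA fit: %d samples x %d variables, 1 predictive + %d orthogonal component(s)\n",
              length(x$scores), length(x$weights), ncol(x$ortho_scores)))
  cat(sprintf("classes: %s (-1) vs %s (+1); scaling: %s\n",
              x$y_levels[1], x$y_levels[2], x$scaling))
  cat(sprintf("R2X = %.3f  R2Y = %.3f  Q2 = %s\n", x$r2x, x$r2y,
              if (is.na(x$q2)) "not computed" else sprintf("%.3f", x$q2)))
  invisible(x)
}

#' @export
summary.opls_da <- function(object, ...) {
  vip <- vip_scores(object)
  out <- list(fit = object,
              top_vip = sort(vip$vip, decreasing = TRUE)[seq_len(min(10, length(vip$vip)))])
  class(out) <- "summary.opls_da"
  out
}

#' @export
print.summary.opls_da <- function(x, ...) {
  print(x$fit)
  cat("\ntop VIP scores:\n")
  print(round(x$top_vip, 3))
  invisible(x)
}

#' @describeIn opls_da Predictive weights (`"weights"`), loadings
#'   (`"loadings"`) or both as a matrix.
#' @param object,... method arguments.
#' @param type which coefficients to return.
#' @export
coef.opls_da <- function(object, type = c("weights", "loadings"), ...) {
  type <- match.arg(type)
  stats::setNames(object[[type]], object$variable_ids)
}

#' @describeIn opls_da X-residual matrix after all fitted components.
#' @export
residuals.opls_da <- function(object, ...) {
  structure(object$residuals,
            dimnames = list(object$sample_ids, object$variable_ids))
}

#' Predict classes from an OPLS-DA model
#'
#' New samples are centered/scaled with the training parameters, the
#' fitted orthogonal variation is filtered out, and the predictive score
#' is mapped to a class by the sign of the predicted response.
#'
#' @param object a fitted [opls_da()] model.
#' @param newdata normalized [peak_table()] or matrix with the training
#'   variables; defaults to the training data.
#' @param ... unused.
#' @return Data frame with `score` (predictive score), `y_hat` (predicted
#'   numeric response) and `class` (predicted label).
#' @export
predict.opls_da <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    t_new <- object$scores
    y_hat <- object$fitted_y
    ids <- object$sample_ids
  } else {
    X <- if (inherits(newdata, "peak_table")) {
      newdata$areas[, analysis_columns(newdata), drop = FALSE]
    } else as.matrix(newdata)
    X <- X[, object$variable_ids, drop = FALSE]
    Xs <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
    pr <- opls_filter_project(object, Xs)
    t_new <- pr$scores
    y_hat <- pr$y_hat
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  }
  data.frame(sample = ids, score = t_new, y_hat = y_hat,
             class = ifelse(y_hat >= 0, object$y_levels[2], object$y_levels[1]),
             stringsAsFactors = FALSE)
}

#' Score plot for an OPLS-DA model
#'
#' Plots the predictive score against the first orthogonal score (or
#' sample index when no orthogonal component was fitted), with the
#' Hotelling T-squared confidence ellipse when available.
#'
#' @param x a fitted [opls_da()] model.
#' @param alpha significance level for the T-squared ellipse.
#' @param ... passed to [graphics::plot()].
#' @export
plot.opls_da <- function(x, alpha = 0.05, ...) {
  t1 <- x$scores
  cls <- ifelse(x$y > 0, 2L, 4L)
  if (ncol(x$ortho_scores) >= 1) {
    t2 <- x$ortho_scores[, 1]
    graphics::plot(t1, t2, col = cls, pch = 19,
                   xlab = "t (predictive)", ylab = "t_o1 (orthogonal)", ...)
    n <- length(t1)
    f <- 2 * (n - 1) / (n - 2) * stats::qf(1 - alpha, 2, n - 2)
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(sqrt(f * stats::var(t1)) * cos(th),
                    sqrt(f * stats::var(t2)) * sin(th), lty = 2)
  } else {
    graphics::plot(seq_along(t1), t1, col = cls, pch = 19,
                   xlab = "sample", ylab = "t (predictive)", ...)
    graphics::abline(h = 0, lty = 3)
  }
  graphics::legend("topright", legend = x$y_levels, col = c(4, 2), pch = 19,
                   bty = "n")
  invisible(x)
}

#' Choose the number of orthogonal components by cross-validation
#'
#' Computes the cross-validated q2 for `0..max_k` orthogonal components
#' and returns the smallest k whose q2 is within 0.01 of the best —
#' favouring parsimony when extra components do not pay for themselves.
#'
#' @inheritParams opls_da
#' @param max_k largest number of orthogonal components to consider.
#' @param cv_folds cross-validation folds (>= 2).
#' @param seed fold-layout seed.
#' @return The selected k (integer). The q2 profile is attached as
#'   attribute `"q2_profile"`.
#' @export
select_n_orthogonal <- function(x, y, max_k = 3, cv_folds = 7, seed = 1) {
  if (max_k < 0) stop("max_k must be >= 0")
  if (cv_folds < 2) stop("need at least 2 cross-validation folds")
  X <- if (inherits(x, "peak_table")) x$areas[, analysis_columns(x), drop = FALSE] else as.matrix(x)
  if (cv_folds > nrow(X)) stop("fewer samples than folds")
  y_num <- encode_labels(y)
  q2s <- rep(NA_real_, max_k + 1)
  for (k in 0:max_k) {
    q2s[k + 1] <- tryCatch(
      opls_q2(X, y_num$y, k, "unit_variance", cv_folds, seed),
      error = function(e) NA_real_)  # rank exhausted: k not a candidate
  }
  if (all(is.na(q2s))) stop("cross-validation failed for every candidate k")
  best <- max(q2s, na.rm = TRUE)
  k_sel <- which(!is.na(q2s) & q2s >= best - 0.01)[1] - 1L
  structure(k_sel, q2_profile = stats::setNames(q2s, paste0("k", 0:max_k)))
}

#' Label-permutation validation of an OPLS-DA model
#'
#' Refits the model (including, optionally, orthogonal-component
#' selection) under random permutations of the class labels and compares
#' the observed cross-validated q2 with the permutation null. The p-value
#' uses the add-one convention
#' `p = (1 + #\{permuted q2 >= observed q2\}) / (n_permutations + 1)`.
#'
#' @inheritParams opls_da
#' @param n_permutations number of label permutations (>= 19).
#' @param seed permutation seed.
#' @param n_orthogonal fixed number of orthogonal components; `NULL`
#'   reselects per fit via [select_n_orthogonal()] with `max_k`.
#' @param max_k selection bound when `n_orthogonal` is `NULL`.
#' @return List of class `"permutation_result"`: `observed_r2y`,
#'   `observed_q2`, `permuted_r2y`, `permuted_q2`, `p_value_q2`,
#'   `n_permutations`.
#' @export
permutation_test <- function(x, y, n_permutations = 99, seed = 1,
                             n_orthogonal = NULL, max_k = 2, cv_folds = 7) {
  if (n_permutations < 19) stop("use at least 19 permutations")
  fit_one <- function(labels, fold_seed) {
    k <- if (is.null(n_orthogonal)) {
      as.integer(select_n_orthogonal(x, labels, max_k = max_k,
                                     cv_folds = cv_folds, seed = fold_seed))
    } else n_orthogonal
    opls_da(x, labels, n_orthogonal = k, cv_folds = cv_folds, cv_seed = fold_seed)
  }
  obs <- fit_one(y, fold_seed = seed)
  perms <- with_seed(seed, {
    lapply(seq_len(n_permutations), function(i) sample(y))
  })
  perm_stats <- vapply(seq_along(perms), function(i) {
    f <- tryCatch(fit_one(perms[[i]], fold_seed = seed + i),
                  error = function(e) NULL)
    if (is.null(f)) c(NA_real_, -Inf) else c(f$r2y, f$q2)
  }, numeric(2))
  permuted_q2 <- perm_stats[2, ]
  p <- (1 + sum(permuted_q2 >= obs$q2)) / (n_permutations + 1)
  structure(list(observed_r2y = obs$r2y, observed_q2 = obs$q2,
                 permuted_r2y = perm_stats[1, ], permuted_q2 = permuted_q2,
                 p_value_q2 = p, n_permutations = n_permutations),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation validation: observed R2Y = %.3f, Q2 = %.3f\n",
              x$observed_r2y, x$observed_q2))
  cat(sprintf("permuted Q2 median = %.3f; p(Q2) = %.4g (%d permutations)\n",
              stats::median(x$permuted_q2, na.rm = TRUE), x$p_value_q2,
              x$n_permutations))
  invisible(x)
}
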