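#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares of the activity on the named descriptors with an
#' intercept.  Alongside the coefficients the fit carries the internal
#' statistics conventional in QSAR reporting: \eqn{R^2}, adjusted
#' \eqn{R^2}, the regression F ratio, the standard error of regression SE,
#' and the leave-one-out cross-validation statistics \eqn{Q^2}, RMScv and
#' PRESS (computed by the hat-matrix shortcut, see [loo_cv()]).
#'
#' @param data Descriptor table with the activity column present.
#' @param descriptors Character vector of descriptor names to include.
#' @param id,activity Column names of compound ID and activity.
#' @return An object of class `qsar_mlr`: coefficients, standard errors,
#'   fit statistics (`$stats`), the stored training design (for leverage
#'   computation) and training compound IDs.  Methods: [tidy()],
#'   [glance()], [augment()], [predict()][predict.qsar_mlr], `print()`.
#' @examples
#' sim <- simulate_qsar_data(n_compounds = 30, n_descriptors = 5,
#'                           n_active = 2, true_coefficients = c(1, -1),
#'                           n_collinear_pairs = 0, n_constant = 0, seed = 7)
#' fit <- fit_mlr(sim$data, sim$active_names)
#' glance(fit)
#' @export
fit_mlr <- function(data, descriptors, id = "compound_id",
                    activity = "pIC50") {
  if (length(descriptors) < 1L) {
    abort("at least one descriptor is required", class = "qsar_config_error")
  }
  x <- descriptor_matrix(data, descriptors, id, activity)
  y <- activity_vector(data, activity)
  n <- nrow(x); k <- ncol(x)
  if (n <= k + 1L) {
    abort(paste0("need n > k + 1 compounds (n = ", n, ", k = ", k, ")"),
          class = "qsar_config_error")
  }
  X <- cbind(`(Intercept)` = 1, x)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    abort(paste0("design is rank deficient; dependent column(s): ",
                 paste(dep, collapse = ", ")),
          class = "qsar_modeling_error")
  }
  beta <- qr.coef(qr_x, y)
  fitted <- unname(drop(X %*% beta))
  e <- y - fitted
  h <- unname(rowSums(qr.Q(qr_x)^2))

  ss_res <- sum(e^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  df_res <- n - k - 1L
  r2_adj <- 1 - (1 - r2) * (n - 1) / df_res
  f_stat <- ((ss_tot - ss_res) / k) / (ss_res / df_res)
  se <- sqrt(ss_res / df_res)

  piv <- qr_x$pivot
  XtX_inv <- matrix(0, ncol(X), ncol(X))
  XtX_inv[piv, piv] <- chol2inv(qr.R(qr_x))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  coef_se <- se * sqrt(diag(XtX_inv))

  if (any(h >= 1 - 1e-12)) {
    abort("a training compound has leverage 1; leave-one-out undefined",
          class = "qsar_modeling_error")
  }
  press_res <- e / (1 - h)
  press <- sum(press_res^2)
  q2 <- 1 - press / ss_tot
  rmscv <- sqrt(press / n)

  ids <- if (id %in% names(data)) as.character(data[[id]])
         else as.character(seq_len(n))
  structure(list(
    descriptors = descriptors,
    intercept = unname(beta[1]),
    coefficients = setNames(unname(beta[-1]), descriptors),
    coefficient_ses = setNames(unname(coef_se[-1]), descriptors),
    intercept_se = unname(coef_se[1]),
    stats = list(r2 = r2, r2_adj = r2_adj, f_stat = f_stat, se = se,
                 q2_loo = q2, rmscv = rmscv, press = press),
    fitted = fitted, residuals = e, leverages = h,
    training_design = x, training_y = y, training_ids = ids,
    xtx_inv = XtX_inv,
    id = id, activity = activity), class = "qsar_mlr")
}

#' Leave-one-out cross-validation statistics
#'
#' PRESS \eqn{= \sum_i (y_i - \hat y_{(-i),i})^2} computed via the
#' hat-matrix shortcut \eqn{e_i / (1 - h_{ii})}, \eqn{Q^2 = 1 -
#' PRESS / \sum (y_i - \bar y)^2}, and \eqn{RMScv = \sqrt{PRESS / n}}.
#' For OLS the shortcut is algebraically exact, so no refitting occurs.
#'
#' @inheritParams fit_mlr
#' @return A tibble with one row: `q2`, `rmscv`, `press`.
#' @export
loo_cv <- function(data, descriptors, id = "compound_id",
                   activity = "pIC50") {
  fit <- fit_mlr(data, descriptors, id, activity)
  tibble::tibble(q2 = fit$stats$q2_loo, rmscv = fit$stats$rmscv,
                 press = fit$stats$press)
}

#' @export
print.qsar_mlr <- function(x, digits = 3, ...) {
  cat("<qsar_mlr> ", length(x$descriptors), " descriptors, n = ",
      length(x$training_y), "\n", sep = "")
  terms <- c("(Intercept)" = x$intercept, x$coefficients)
  ses <- c(x$intercept_se, x$coefficient_ses)
  eq <- paste0(format(round(terms, digits)), " (+/- ",
               format(round(ses, digits)), ") ",
               c("", names(x$coefficients)))
  cat(paste(" ", eq, collapse = "\n"), "\n")
  s <- x$stats
  cat(sprintf("  R2 = %.3f  adj-R2 = %.3f  F = %.3f  SE = %.3f\n",
              s$r2, s$r2_adj, s$f_stat, s$se))
  cat(sprintf("  Q2(LOO) = %.3f  RMScv = %.3f\n", s$q2_loo, s$rmscv))
  invisible(x)
}

#' @describeIn fit_mlr Coefficient-level summary (broom convention):
#'   `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @param x,object A `qsar_mlr` model.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qsar_mlr <- function(x, ...) {
  est <- c(x$intercept, unname(x$coefficients))
  se <- c(x$intercept_se, unname(x$coefficient_ses))
  tstat <- est / se
  df <- length(x$training_y) - length(x$descriptors) - 1L
  tibble::tibble(term = c("(Intercept)", x$descriptors),
                 estimate = est, std.error = se, statistic = tstat,
                 p.value = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

#' @describeIn fit_mlr Model-level summary: one row with n, k and the fit
#'   statistics.
#' @exportS3Method generics::glance
glance.qsar_mlr <- function(x, ...) {
  s <- x$stats
  tibble::tibble(n = length(x$training_y), k = length(x$descriptors),
                 r.squared = s$r2, adj.r.squared = s$r2_adj,
                 statistic = s$f_stat, sigma = s$se,
                 q2.loo = s$q2_loo, rmscv = s$rmscv, press = s$press)
}

#' @describeIn fit_mlr Per-training-compound table: observed, fitted,
#'   residual, leverage, standardized residual and outlier flag.
#' @exportS3Method generics::augment
augment.qsar_mlr <- function(x, ...) {
  sr <- standardized_residuals(x)
  tibble::tibble(compound_id = x$training_ids,
                 observed = x$training_y, fitted = x$fitted,
                 residual = x$residuals, leverage = x$leverages,
                 std.residual = sr$std_residual, flagged = sr$flagged)
}

#' Predict activity for new compounds
#'
#' \eqn{\hat y = b_0 + \sum_j b_j x_j} per row.  Every model descriptor
#' must be present in `newdata`; extra columns are ignored.
#'
#' @param object A `qsar_mlr` model.
#' @param newdata Descriptor table.
#' @param ... Unused.
#' @return Numeric vector of predicted activities (pIC50).
#' @export
predict.qsar_mlr <- function(object, newdata, ...) {
  x <- descriptor_matrix(newdata, object$descriptors, object$id,
                         object$activity)
  if (any(!is.finite(x))) {
    bad <- unique(which(!is.finite(x), arr.ind = TRUE)[, 1])
    abort(paste0("non-finite descriptor values in row(s) ",
                 paste(bad, collapse = ", ")),
          class = "qsar_modeling_error")
  }
  unname(drop(object$intercept + x %*% object$coefficients))
}

#' Internally studentized residuals with the QSAR outlier rule
#'
#' \eqn{r_i = e_i / (SE \sqrt{1 - h_{ii}})}; compounds with
#' \eqn{|r_i| > 2.5} are flagged as potential outliers (strict
#' inequality).  Rows with leverage 1 get `NA` residuals and are flagged.
#'
#' @param model A `qsar_mlr` model.
#' @param threshold Flagging threshold (default 2.5).
#' @return Tibble: `compound_id`, `std_residual`, `flagged`.
#' @export
standardized_residuals <- function(model, threshold = 2.5) {
  h <- model$leverages
  se <- model$stats$se
  r <- if (se <= 1e-10 * sd(model$training_y)) {
    # numerically exact fit: all residuals are zero by construction
    rep(0, length(h))
  } else {
    ifelse(h >= 1 - 1e-12, NA_real_,
           model$residuals / (se * sqrt(1 - h)))
  }
  tibble::tibble(compound_id = model$training_ids, std_residual = r,
                 flagged = is.na(r) | abs(r) > threshold)
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1 / (1 - R_j^2)} where \eqn{R_j^2} comes from regressing
#' descriptor j on the remaining descriptors (with intercept).  Perfectly
#' collinear descriptors report `Inf` rather than erroring.
#'
#' @inheritParams fit_mlr
#' @return Tibble: `descriptor`, `vif`.
#' @export
vif <- function(data, descriptors, id = "compound_id", activity = "pIC50") {
  if (length(descriptors) < 2L) {
    abort("VIF needs at least two descriptors", class = "qsar_config_error")
  }
  x <- descriptor_matrix(data, descriptors, id, activity)
  vals <- vapply(seq_along(descriptors), function(j) {
    yj <- x[, j]
    Xj <- cbind(1, x[, -j, drop = FALSE])
    fit <- stats::lm.fit(Xj, yj)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((yj - mean(yj))^2)
    r2 <- 1 - ss_res / ss_tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(descriptor = descriptors, vif = vals)
}
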