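#' External validation statistics with Golbraikh-Tropsha and rm2 rules
#'
#' Given observed and predicted activities for an external prediction set,
#' computes:
#' * `r2_pred` — squared Pearson correlation of predicted vs observed;
#' * `k`, `k_prime` — slopes of the regressions through the origin,
#'   observed on predicted (\eqn{k = \sum y\hat y / \sum \hat y^2}) and
#'   predicted on observed (\eqn{k' = \sum y\hat y / \sum y^2});
#' * `r0sq`, `r0sq_prime` — through-origin determination coefficients,
#'   \eqn{R_0^2 = 1 - \sum(y - k\hat y)^2 / \sum(y - \bar y)^2} and
#'   \eqn{R'^2_0 = 1 - \sum(\hat y - k' y)^2 / \sum(\hat y - \bar{\hat y})^2};
#' * `rm2` — \eqn{r^2 (1 - \sqrt{|r^2 - R_0^2|})} (absolute-difference
#'   form; `rm2_prime` uses \eqn{R'^2_0});
#' * `q2_ext` — auxiliary \eqn{1 - \sum(y-\hat y)^2/\sum(y-\bar y)^2}
#'   (not used in the pass rules).
#'
#' Pass rules: `r2_pred > 0.6`; relative difference
#' \eqn{|(r^2 - R_0^2)/r^2| < 0.1} for either through-origin variant;
#' \eqn{0.85 \le k \le 1.15} for either slope; `rm2 > 0.5`.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3) with
#'   nonzero variance.
#' @return A list of class `qsar_external` with the statistics, a named
#'   logical `passes`, and `overall_pass` (their conjunction).
#' @examples
#' y <- c(5.1, 6.2, 5.8, 7.0, 6.4)
#' external_validate(y, y)$overall_pass
#' @export
external_validate <- function(observed, predicted) {
  y <- as.numeric(observed); yh <- as.numeric(predicted)
  if (length(y) != length(yh) || length(y) < 3L) {
    abort("observed and predicted must have equal length >= 3",
          class = "qsar_config_error")
  }
  if (sd(y) == 0 || sd(yh) == 0) {
    abort("zero variance in observed or predicted activities",
          class = "qsar_validation_error")
  }
  r2 <- cor(y, yh)^2
  k <- sum(y * yh) / sum(yh^2)
  k_prime <- sum(y * yh) / sum(y^2)
  r0sq <- 1 - sum((y - k * yh)^2) / sum((y - mean(y))^2)
  r0sq_prime <- 1 - sum((yh - k_prime * y)^2) / sum((yh - mean(yh))^2)
  # snap differences at rounding-noise level to zero: sqrt() would amplify
  # an O(1e-16) discrepancy into an O(1e-8) bias in rm2
  gap <- function(a, b) { d <- abs(a - b); if (d < 1e-12) 0 else d }
  rm2 <- r2 * (1 - sqrt(gap(r2, r0sq)))
  rm2_prime <- r2 * (1 - sqrt(gap(r2, r0sq_prime)))
  rel_diff_r0 <- (r2 - r0sq) / r2
  rel_diff_r0_prime <- (r2 - r0sq_prime) / r2
  q2_ext <- 1 - sum((y - yh)^2) / sum((y - mean(y))^2)

  passes <- c(
    r2_pred = r2 > 0.6,
    r0_close = abs(rel_diff_r0) < 0.1 || abs(rel_diff_r0_prime) < 0.1,
    slope = (k >= 0.85 && k <= 1.15) || (k_prime >= 0.85 && k_prime <= 1.15),
    rm2 = rm2 > 0.5
  )
  structure(list(r2_pred = r2, k = k, k_prime = k_prime,
                 r0sq = r0sq, r0sq_prime = r0sq_prime,
                 rm2 = rm2, rm2_prime = rm2_prime,
                 rel_diff_r0 = rel_diff_r0,
                 rel_diff_r0_prime = rel_diff_r0_prime,
                 q2_ext = q2_ext, n = length(y),
                 passes = passes, overall_pass = all(passes)),
            class = "qsar_external")
}

#' @export
print.qsar_external <- function(x, ...) {
  cat("<qsar_external> n =", x$n, "\n")
  cat(sprintf("  R2pred = %.3f  R02 = %.3f  R'02 = %.3f\n",
              x$r2_pred, x$r0sq, x$r0sq_prime))
  cat(sprintf("  k = %.3f  k' = %.3f  rm2 = %.3f (rm2' = %.3f)\n",
              x$k, x$k_prime, x$rm2, x$rm2_prime))
  cat("  pass:", paste(names(x$passes)[x$passes], collapse = ", "),
      if (!all(x$passes)) paste("| fail:",
        paste(names(x$passes)[!x$passes], collapse = ", ")) else "", "\n")
  invisible(x)
}

#' @describeIn external_validate One-row tibble of the statistics and flags.
#' @param x A `qsar_external` report.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qsar_external <- function(x, ...) {
  tibble::tibble(statistic = c("r2_pred", "r0sq", "r0sq_prime", "k",
                               "k_prime", "rm2", "rm2_prime", "q2_ext"),
                 value = c(x$r2_pred, x$r0sq, x$r0sq_prime, x$k,
                           x$k_prime, x$rm2, x$rm2_prime, x$q2_ext))
}

#' Full Tropsha predictivity decision
#'
#' Combines the internal LOO statistic with the external report:
#' (i) \eqn{Q^2 > 0.5}; (ii) \eqn{R^2_{pred} > 0.6}; (iii) a
#' through-origin \eqn{R_0^2} close to \eqn{R^2_{pred}} (relative
#' difference < 0.1, either variant); (iv) a through-origin slope in
#' [0.85, 1.15] (either variant).  The model is declared predictive when
#' all four hold.
#'
#' @param q2_train Training-set leave-one-out \eqn{Q^2}.
#' @param report A [external_validate()] result.
#' @return A tibble, one row per rule: `rule`, `pass`; attribute
#'   `"overall_pass"` carries the conjunction.
#' @export
tropsha_check <- function(q2_train, report) {
  rules <- tibble::tibble(
    rule = c("Q2 > 0.5", "R2pred > 0.6", "R02 close to R2pred",
             "slope k or k' in [0.85, 1.15]"),
    pass = c(q2_train > 0.5, unname(report$passes["r2_pred"]),
             unname(report$passes["r0_close"]),
             unname(report$passes["slope"])))
  attr(rules, "overall_pass") <- all(rules$pass)
  rules
}

#' Y-randomization (response scrambling) test
#'
#' Repeatedly shuffles the activity vector against the fixed descriptor
#' matrix, rebuilds a model each time, and records its \eqn{R^2} and
#' \eqn{Q^2}.  A robust model's scrambled statistics stay far below the
#' original ones; high scrambled values indicate chance correlation.
#'
#' @inheritParams stepwise_select
#' @param model The original `qsar_mlr` model (supplies the descriptor set
#'   for `mode = "refit_fixed"` and the reference statistics).
#' @param mode `"refit_fixed"` refits the original descriptor set on each
#'   shuffle (fast); `"rerun_stepwise"` / `"rerun_ga"` repeat the full
#'   selection per shuffle, as when the original model was built by
#'   selection.
#' @param n_repetitions Number of shuffles.
#' @param seed Integer seed for the permutations (and GA reruns).
#' @param ... Passed on to [stepwise_select()] or [ga_select()] for the
#'   rerun modes.
#' @return A list of class `qsar_yrand`: `results` (tibble: repetition,
#'   r2, q2), `original_r2`, `original_q2`, `mode`.
#' @export
y_randomize <- function(data, model,
                        mode = c("refit_fixed", "rerun_stepwise",
                                 "rerun_ga"),
                        n_repetitions = 20L, seed = 1L,
                        id = "compound_id", activity = "pIC50", ...) {
  mode <- match.arg(mode)
  n_repetitions <- check_count(n_repetitions, "n_repetitions", 1L)
  y <- activity_vector(data, activity)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  perms <- lapply(seq_len(n_repetitions),
                  function(i) sample.int(length(y)))
  ga_seeds <- sample.int(.Machine$integer.max, n_repetitions)

  rows <- purrr::map_dfr(seq_len(n_repetitions), function(i) {
    shuffled <- data
    shuffled[[activity]] <- y[perms[[i]]]
    fit <- switch(mode,
      refit_fixed = fit_mlr(shuffled, model$descriptors, id, activity),
      rerun_stepwise = stepwise_select(shuffled, id = id,
                                       activity = activity, ...),
      rerun_ga = ga_select(shuffled, seed = ga_seeds[i], id = id,
                           activity = activity, ...)$model)
    if (inherits(fit, "qsar_ga")) fit <- fit$model
    if (is.null(fit)) {
      # selection found nothing under scrambling: the null model
      return(tibble::tibble(repetition = i, r2 = 0, q2 = NA_real_))
    }
    tibble::tibble(repetition = i, r2 = fit$stats$r2, q2 = fit$stats$q2_loo)
  })
  structure(list(results = rows,
                 original_r2 = model$stats$r2,
                 original_q2 = model$stats$q2_loo,
                 mode = mode, n_repetitions = n_repetitions),
            class = "qsar_yrand")
}

#' @export
print.qsar_yrand <- function(x, ...) {
  cat("<qsar_yrand> ", x$n_repetitions, " shuffles (", x$mode, ")\n",
      sep = "")
  cat(sprintf("  shuffled R2 in [%.3f, %.3f]; original R2 = %.3f\n",
              min(x$results$r2), max(x$results$r2), x$original_r2))
  q2 <- x$results$q2[!is.na(x$results$q2)]
  if (length(q2)) {
    cat(sprintf("  shuffled Q2 in [%.3f, %.3f]; original Q2 = %.3f\n",
                min(q2), max(q2), x$original_q2))
  }
  invisible(x)
}

#' Leverage-based applicability domain
#'
#' Computes each compound's leverage \eqn{h_i = x_i (X^T X)^{-1} x_i^T}
#' against the model's stored (intercept-augmented) training design, the
#' warning threshold \eqn{h^* = 3(k+1)/n}, and domain membership
#' (\eqn{h < h^*}, strict: a compound exactly on the threshold counts as
#' outside).  For the training compounds themselves, the |standardized
#' residual| > 2.5 outlier flag is attached — together these are the
#' coordinates of the Williams plot.
#'
#' @param model A `qsar_mlr` model.
#' @param data Descriptor table to assess; defaults to the training table
#'   held by the model.
#' @param id Compound-ID column name.
#' @return A list of class `qsar_ad`: `records` (tibble: compound_id,
#'   leverage, inside, std_residual, residual_flag — residual columns are
#'   `NA` for non-training compounds), `h_star`, `n_train`, `k`.
#' @export
applicability_domain <- function(model, data = NULL, id = "compound_id") {
  k <- length(model$descriptors)
  n <- nrow(model$training_design)
  h_star <- 3 * (k + 1) / n
  if (is.null(data)) {
    h <- model$leverages
    ids <- model$training_ids
    sr <- standardized_residuals(model)
    records <- tibble::tibble(compound_id = ids, leverage = h,
                              inside = h < h_star,
                              std_residual = sr$std_residual,
                              residual_flag = sr$flagged)
  } else {
    x <- descriptor_matrix(data, model$descriptors, id, model$activity)
    X <- cbind(1, x)
    h <- unname(rowSums((X %*% model$xtx_inv) * X))
    ids <- if (id %in% names(data)) as.character(data[[id]])
           else as.character(seq_len(nrow(data)))
    records <- tibble::tibble(compound_id = ids, leverage = h,
                              inside = h < h_star,
                              std_residual = NA_real_,
                              residual_flag = NA)
  }
  structure(list(records = records, h_star = h_star, n_train = n, k = k),
            class = "qsar_ad")
}

#' @export
print.qsar_ad <- function(x, ...) {
  cat(sprintf("<qsar_ad> h* = 3(k+1)/n = %.4f (k = %d, n = %d)\n",
              x$h_star, x$k, x$n_train))
  cat("  ", sum(x$records$inside), "/", nrow(x$records),
      " compounds inside the domain\n", sep = "")
  invisible(x)
}
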