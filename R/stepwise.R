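#' Stepwise descriptor selection by partial-F probability
#'
#' Classic forward-backward stepping.  At each forward step the candidate
#' with the smallest partial-F p-value enters if that p-value is below
#' `p_enter`; at each backward step the included descriptor with the
#' largest p-value leaves if it exceeds `p_remove`.  Stepping alternates
#' until neither move applies or `max_steps` is reached; the final set is
#' refitted with [fit_mlr()].  The defaults (enter 0.05, remove 0.10) are
#' the conventional F-probability criteria.
#'
#' The partial F for one variable equals the square of its t statistic in
#' the enlarged model; p-values come from \eqn{F(1, n - k - 2)} for entry
#' into a model that already holds k descriptors.
#'
#' @inheritParams fit_mlr
#' @param candidates Descriptor names to consider (default: all descriptor
#'   columns).
#' @param p_enter,p_remove F-probabilities for inclusion/exclusion;
#'   `0 < p_enter <= p_remove < 1`.
#' @param max_steps Hard cap on forward+backward iterations.
#' @return A `qsar_mlr` model on the selected set, or `NULL` when nothing
#'   passes `p_enter` (intercept-only model: no descriptor explains the
#'   activity at the entry criterion).
#' @export
stepwise_select <- function(data, candidates = NULL,
                            p_enter = 0.05, p_remove = 0.10,
                            max_steps = 100L,
                            id = "compound_id", activity = "pIC50") {
  if (!(p_enter > 0 && p_enter <= p_remove && p_remove < 1)) {
    abort("need 0 < p_enter <= p_remove < 1", class = "qsar_config_error")
  }
  if (is.null(candidates)) candidates <- descriptor_names(data, id, activity)
  if (length(candidates) < 1L) {
    abort("no candidate descriptors", class = "qsar_config_error")
  }
  x <- descriptor_matrix(data, candidates, id, activity)
  y <- activity_vector(data, activity)
  n <- length(y)

  # p-value of the partial F test for each column of `extra` added to the
  # model holding `base` (matrix incl. intercept)
  partial_p <- function(base, xj) {
    fit0 <- stats::lm.fit(base, y)
    ss0 <- sum(fit0$residuals^2)
    X1 <- cbind(base, xj)
    if (qr(X1)$rank < ncol(X1)) return(NA_real_)
    fit1 <- stats::lm.fit(X1, y)
    ss1 <- sum(fit1$residuals^2)
    df2 <- n - ncol(X1)
    if (df2 < 1L || ss1 <= 0) return(if (ss0 > ss1) 0 else NA_real_)
    fval <- (ss0 - ss1) / (ss1 / df2)
    pf(fval, 1, df2, lower.tail = FALSE)
  }

  included <- character()
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    # forward
    pool <- setdiff(candidates, included)
    if (length(pool) > 0 && n > length(included) + 2L) {
      base <- cbind(1, x[, included, drop = FALSE])
      pvals <- vapply(pool, function(nm) partial_p(base, x[, nm]),
                      numeric(1))
      if (any(!is.na(pvals)) && min(pvals, na.rm = TRUE) < p_enter) {
        best <- pool[which.min(pvals)]
        included <- c(included, best)
        changed <- TRUE
      }
    }
    # backward
    if (length(included) > 1L) {
      pvals <- vapply(included, function(nm) {
        base <- cbind(1, x[, setdiff(included, nm), drop = FALSE])
        partial_p(base, x[, nm])
      }, numeric(1))
      worst <- which.max(pvals)
      if (!is.na(pvals[worst]) && pvals[worst] > p_remove) {
        included <- setdiff(included, included[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(included) == 0L) return(NULL)
  fit_mlr(data, included, id, activity)
}
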