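#' Screen candidate compounds with a fitted QSAR model
#'
#' Predicts the activity of every candidate, attaches its leverage and
#' applicability-domain reliability flag (leverage < h*), and ranks by
#' descending predicted activity (ties broken by candidate ID).  No
#' candidate is dropped: out-of-domain compounds are flagged, not
#' filtered, unless `keep_only_reliable = TRUE`.
#'
#' @param model A `qsar_mlr` model.
#' @param candidates Descriptor table covering every model descriptor.
#' @param keep_only_reliable Drop out-of-domain candidates from the
#'   returned table (default `FALSE`).
#' @param id Compound-ID column name.
#' @return A tibble of class `qsar_screen`: `candidate_id`,
#'   `predicted_pIC50`, `leverage`, `reliable`, sorted by descending
#'   prediction; attributes `h_star` and `model_descriptors`.
#' @examples
#' sim <- simulate_qsar_data(n_compounds = 30, n_descriptors = 5,
#'                           n_active = 2, true_coefficients = c(1, -1),
#'                           n_collinear_pairs = 0, n_constant = 0, seed = 2)
#' fit <- fit_mlr(sim$data, sim$active_names)
#' screen_candidates(fit, sim$data[1:5, ])
#' @export
screen_candidates <- function(model, candidates, keep_only_reliable = FALSE,
                              id = "compound_id") {
  pred <- predict(model, candidates)
  ad <- applicability_domain(model, candidates, id = id)
  out <- tibble::tibble(candidate_id = ad$records$compound_id,
                        predicted_pIC50 = pred,
                        leverage = ad$records$leverage,
                        reliable = ad$records$inside)
  out <- dplyr::arrange(out, dplyr::desc(.data$predicted_pIC50),
                        .data$candidate_id)
  if (keep_only_reliable) out <- dplyr::filter(out, .data$reliable)
  attr(out, "h_star") <- ad$h_star
  attr(out, "model_descriptors") <- model$descriptors
  class(out) <- c("qsar_screen", class(out))
  out
}
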