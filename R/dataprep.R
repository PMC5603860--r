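#' Remove constant and near-constant descriptors
#'
#' Drops descriptor columns with zero variance and columns whose most
#' frequent value occupies at least `near_constant_fraction` of the rows.
#' With `near_constant_fraction = 1` only exact constants are removed.
#'
#' @param data Descriptor table (tibble/data frame).
#' @param near_constant_fraction Proportion in (0, 1]; default 0.95.
#' @param id,activity Column names exempt from filtering.
#' @return The filtered tibble, with attribute `"removed"` listing the
#'   dropped descriptor names (also retrievable via [removed_descriptors()]).
#' @examples
#' d <- tibble::tibble(compound_id = c("a", "b"), x = c(1, 2),
#'                     k = c(5, 5), pIC50 = c(0, 1))
#' remove_constant(d)
#' @export
remove_constant <- function(data, near_constant_fraction = 0.95,
                            id = "compound_id", activity = "pIC50") {
  if (nrow(data) == 0L) abort("empty table", class = "qsar_config_error")
  if (near_constant_fraction <= 0 || near_constant_fraction > 1) {
    abort("near_constant_fraction must lie in (0, 1]",
          class = "qsar_config_error")
  }
  desc <- descriptor_names(data, id, activity)
  n <- nrow(data)
  drop <- vapply(desc, function(nm) {
    v <- data[[nm]]
    if (var(v) == 0) return(TRUE)
    max(table(v)) / n >= near_constant_fraction
  }, logical(1))
  removed <- desc[drop]
  if (length(removed) == length(desc)) {
    abort("all descriptor columns are (near-)constant; inspect the input",
          class = "qsar_processing_error")
  }
  out <- dplyr::select(data, -dplyr::all_of(removed))
  attr(out, "removed") <- removed
  out
}

#' Remove collinear descriptors, keeping the better activity correlate
#'
#' For every descriptor pair whose absolute Pearson correlation exceeds
#' `threshold`, the member with the lower absolute correlation to the
#' activity is dropped.  Offending pairs are processed greedily in order of
#' descending |r|, skipping pairs already resolved by an earlier removal;
#' the surviving table contains no pair above the threshold.
#'
#' @inheritParams remove_constant
#' @param threshold Correlation cut-off in (0, 1); default 0.9.
#' @return Filtered tibble with attribute `"removed"`.
#' @export
remove_collinear <- function(data, threshold = 0.9,
                             id = "compound_id", activity = "pIC50") {
  if (!activity %in% names(data)) {
    abort("collinearity filtering needs the activity column to decide which
           member of a pair to keep", class = "qsar_config_error")
  }
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must lie in (0, 1)", class = "qsar_config_error")
  }
  desc <- descriptor_names(data, id, activity)
  x <- descriptor_matrix(data, desc, id, activity)
  y <- activity_vector(data, activity)
  cx <- suppressWarnings(cor(x))
  cx[!is.finite(cx)] <- 0
  cy <- abs(suppressWarnings(cor(x, y)))
  cy[!is.finite(cy)] <- 0
  ij <- which(upper.tri(cx) & abs(cx) > threshold, arr.ind = TRUE)
  removed <- character()
  if (nrow(ij) > 0) {
    ord <- order(abs(cx[ij]), decreasing = TRUE)
    ij <- ij[ord, , drop = FALSE]
    dead <- logical(length(desc))
    for (r in seq_len(nrow(ij))) {
      a <- ij[r, 1]; b <- ij[r, 2]
      if (dead[a] || dead[b]) next
      loser <- if (cy[a] < cy[b]) a else b
      dead[loser] <- TRUE
    }
    removed <- desc[dead]
  }
  out <- dplyr::select(data, -dplyr::all_of(removed))
  attr(out, "removed") <- removed
  out
}

#' Descriptors removed by the last filtering step
#'
#' @param data A table returned by [remove_constant()] or
#'   [remove_collinear()].
#' @return Character vector of removed descriptor names.
#' @export
removed_descriptors <- function(data) attr(data, "removed") %||% character()

#' Kennard-Stone training/prediction split
#'
#' Deterministic maximum-minimum-distance sampling: descriptors are
#' autoscaled (zero mean, unit variance), the pair at maximal Euclidean
#' distance seeds the training set, and each subsequent pick is the
#' candidate whose minimum distance to the already-selected set is
#' maximal.  Remaining compounds form the prediction (test) set.  Distance
#' ties are broken by comparing standardized coordinate vectors
#' lexicographically, then by original row index, so the selected set is
#' invariant to row order.
#'
#' @inheritParams remove_constant
#' @param n_train Number of training compounds, `2 <= n_train <= n`.
#' @return A tibble with columns `compound_id`, `row` (original index) and
#'   `set` (`"train"` or `"test"`), in table row order.
#' @examples
#' d <- tibble::tibble(compound_id = letters[1:5], x = c(0, 1, 2, 3, 10))
#' kennard_stone_split(d, n_train = 3)
#' @export
kennard_stone_split <- function(data, n_train,
                                id = "compound_id", activity = "pIC50") {
  n <- nrow(data)
  n_train <- check_count(n_train, "n_train", 2L)
  if (n_train > n) {
    abort("n_train exceeds the number of compounds",
          class = "qsar_config_error")
  }
  x <- descriptor_matrix(data, id = id, activity = activity)
  x <- scale(x)
  x[, !is.finite(colSums(x))] <- 0  # constant columns contribute nothing

  # lexicographic comparison of standardized rows, for tie-breaking
  lex_less <- function(a, b) {
    d <- x[a, ] - x[b, ]
    nz <- which(abs(d) > 1e-12)
    if (length(nz) == 0L) return(a < b)
    d[nz[1]] < 0
  }
  pick_best <- function(cand, score) {
    best <- cand[1]; s <- score[1]
    for (k in seq_along(cand)[-1]) {
      if (score[k] > s + 1e-12) { best <- cand[k]; s <- score[k] }
      else if (abs(score[k] - s) <= 1e-12 && lex_less(cand[k], best)) {
        best <- cand[k]; s <- max(s, score[k])
      }
    }
    best
  }

  dm <- as.matrix(stats::dist(x))
  # seed: the globally most distant pair
  far <- which(dm == max(dm), arr.ind = TRUE)
  far <- far[far[, 1] < far[, 2], , drop = FALSE]
  # deterministic among ties: smallest lexicographic endpoint pair
  sel_pair <- far[1, ]
  if (nrow(far) > 1) {
    for (r in 2:nrow(far)) {
      cand <- far[r, ]
      a_new <- min(cand); a_old <- min(sel_pair)
      if (lex_less(a_new, a_old) ||
          (!lex_less(a_old, a_new) && lex_less(max(cand), max(sel_pair)))) {
        sel_pair <- cand
      }
    }
  }
  selected <- as.integer(sel_pair)
  remaining <- setdiff(seq_len(n), selected)
  while (length(selected) < n_train && length(remaining) > 0) {
    mind <- apply(dm[remaining, selected, drop = FALSE], 1, min)
    nxt <- pick_best(remaining, mind)
    selected <- c(selected, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  ids <- if (id %in% names(data)) as.character(data[[id]])
         else as.character(seq_len(n))
  tibble::tibble(compound_id = ids, row = seq_len(n),
                 set = ifelse(seq_len(n) %in% selected, "train", "test"))
}
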