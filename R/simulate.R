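#' Simulate a QSAR descriptor table with planted linear signal
#'
#' Generates a compound-by-descriptor matrix mimicking the shape of a
#' typical small QSAR study: a few dozen compounds, hundreds of candidate
#' descriptors, a small set of truly active descriptors driving the
#' activity linearly, plus the nuisance structure a raw descriptor matrix
#' carries — highly collinear pairs and constant columns.  The defaults
#' reproduce the study conditions the package is tested under: 46
#' compounds, 300 descriptors, an 8-descriptor signal on the pIC50 scale
#' with Gaussian noise.
#'
#' Column layout (ground truth is returned, so the layout is not load-
#' bearing): `n_active` signal columns, then `n_collinear_pairs` base +
#' partner pairs (partner = `r * base + sqrt(1 - r^2) * z`, `z` fresh
#' standard normal, so the expected correlation is exactly `collinear_r`),
#' then `n_constant` all-equal columns, then independent standard-normal
#' fillers.  Activity = intercept + signal %*% coefficients + N(0, noise_sd).
#'
#' @param n_compounds Number of compounds (rows).
#' @param n_descriptors Total number of descriptor columns.
#' @param n_active Number of descriptors carrying true signal.
#' @param true_coefficients Coefficients of the active descriptors
#'   (activity units per descriptor unit); recycled/truncated defaults are
#'   not allowed — length must equal `n_active`.
#' @param intercept Intercept on the activity (pIC50) scale.
#' @param noise_sd Standard deviation of the Gaussian activity noise
#'   (pIC50 units); `0` gives an exact linear response.
#' @param n_collinear_pairs Number of planted collinear column pairs.
#' @param collinear_r Target correlation of each pair, in (0.9, 1).
#' @param n_constant Number of constant columns.
#' @param seed Integer seed; the single source of randomness.
#' @param scale,shift Optional scale/shift applied to all random descriptor
#'   columns (robustness testing; default standard normal).
#' @return A list of class `qsar_sim` with elements `data` (tibble:
#'   `compound_id`, descriptors, `pIC50`), `active_names`,
#'   `true_coefficients`, `intercept`, `collinear_pairs` (two-column
#'   matrix of names), `constant_names`, and `noise` (the realised noise
#'   vector).
#' @examples
#' sim <- simulate_qsar_data(n_compounds = 20, n_descriptors = 10,
#'                           n_active = 2, true_coefficients = c(1, -1),
#'                           seed = 1)
#' head(sim$data)
#' @export
simulate_qsar_data <- function(n_compounds = 46,
                               n_descriptors = 300,
                               n_active = 8,
                               true_coefficients = c(0.8, -0.6, 0.7, -0.5,
                                                     0.9, 0.6, -0.7, 0.5),
                               intercept = 6,
                               noise_sd = 0.3,
                               n_collinear_pairs = 5,
                               collinear_r = 0.95,
                               n_constant = 3,
                               seed = 1,
                               scale = 1, shift = 0) {
  n <- check_count(n_compounds, "n_compounds", 1L)
  p <- check_count(n_descriptors, "n_descriptors", 1L)
  n_active <- check_count(n_active, "n_active", 0L)
  n_collinear_pairs <- check_count(n_collinear_pairs, "n_collinear_pairs", 0L)
  n_constant <- check_count(n_constant, "n_constant", 0L)
  if (n_active + 2L * n_collinear_pairs + n_constant > p) {
    abort(paste0("n_active + 2*n_collinear_pairs + n_constant (",
                 n_active + 2L * n_collinear_pairs + n_constant,
                 ") exceeds n_descriptors (", p, ")"),
          class = "qsar_config_error")
  }
  if (length(true_coefficients) != n_active) {
    abort("true_coefficients must have length n_active",
          class = "qsar_config_error")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0", class = "qsar_config_error")
  if (n_collinear_pairs > 0 && (collinear_r <= 0.9 || collinear_r >= 1)) {
    abort("collinear_r must lie in (0.9, 1)", class = "qsar_config_error")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  nm <- sprintf("X%03d", seq_len(p))
  x <- matrix(0, n, p, dimnames = list(NULL, nm))
  k <- 0L
  active_idx <- seq_len(n_active)
  if (n_active > 0) {
    x[, active_idx] <- stats::rnorm(n * n_active)
    k <- n_active
  }
  pairs <- matrix(character(), 0, 2,
                  dimnames = list(NULL, c("base", "partner")))
  if (n_collinear_pairs > 0) {
    for (q in seq_len(n_collinear_pairs)) {
      base <- stats::rnorm(n)
      z <- stats::rnorm(n)
      # empirically decorrelate z from base so the *sample* correlation of
      # the pair equals collinear_r exactly, not just in expectation
      bs <- drop(scale(base))
      zs <- stats::lm.fit(cbind(1, bs), z)$residuals
      zs <- zs / stats::sd(zs)
      partner <- collinear_r * bs + sqrt(1 - collinear_r^2) * zs
      x[, k + 1L] <- base
      x[, k + 2L] <- partner
      pairs <- rbind(pairs, nm[c(k + 1L, k + 2L)])
      k <- k + 2L
    }
  }
  const_idx <- if (n_constant > 0) k + seq_len(n_constant) else integer()
  if (n_constant > 0) {
    x[, const_idx] <- matrix(rep(seq_len(n_constant), each = n), n)
    k <- k + n_constant
  }
  if (k < p) x[, (k + 1L):p] <- stats::rnorm(n * (p - k))

  filler_or_signal <- setdiff(seq_len(p), const_idx)
  x[, filler_or_signal] <- x[, filler_or_signal] * scale + shift

  noise <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
  signal <- if (n_active > 0) {
    drop(x[, active_idx, drop = FALSE] %*% true_coefficients)
  } else rep(0, n)
  y <- intercept + signal + noise

  data <- tibble::as_tibble(as.data.frame(x))
  data <- dplyr::bind_cols(
    tibble::tibble(compound_id = sprintf("cmp%03d", seq_len(n))),
    data, tibble::tibble(pIC50 = y))

  structure(list(data = data,
                 active_names = nm[active_idx],
                 true_coefficients = as.numeric(true_coefficients),
                 intercept = intercept,
                 collinear_pairs = pairs,
                 constant_names = nm[const_idx],
                 noise = noise),
            class = "qsar_sim")
}

# Save/restore the global RNG state so generators are side-effect free.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.qsar_sim <- function(x, ...) {
  cat("<qsar_sim> ", nrow(x$data), " compounds x ",
      length(descriptor_names(x$data)), " descriptors; ",
      length(x$active_names), " active, ",
      nrow(x$collinear_pairs), " collinear pairs, ",
      length(x$constant_names), " constant\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to CSV with a JSON ground-truth sidecar
#'
#' The CSV has compound IDs first, descriptors in order, activity last;
#' the sidecar records active names, coefficients, intercept, collinear
#' pairs and constant columns.
#'
#' @param sim A [simulate_qsar_data()] result.
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".truth.json")`.
#' @return `path`, invisibly.
#' @export
write_qsar_sim <- function(sim, path) {
  write.csv(sim$data, path, row.names = FALSE)
  truth <- list(active_names = sim$active_names,
                true_coefficients = sim$true_coefficients,
                intercept = sim$intercept,
                collinear_pairs = apply(sim$collinear_pairs, 1, as.list),
                constant_names = sim$constant_names)
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
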