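#' Genetic-algorithm descriptor selection with LOO-RMScv fitness
#'
#' Chromosomes are descriptor-inclusion bitstrings; the fitness of a
#' chromosome is the leave-one-out root-mean-square error of
#' cross-validation (RMScv) of the MLR model on the encoded subset (lower
#' is better).  Selection is a size-2 tournament, recombination is uniform
#' crossover, and per-bit mutation and crossover probabilities ramp
#' linearly across generations (defaults: mutation 0% to 1%, crossover 90%
#' down to 60%).  One elite chromosome survives each generation unchanged.
#' Chromosomes encoding no descriptors, more than `max_descriptors`, or a
#' rank-deficient design receive infinite fitness.  Evolution stops when
#' `convergence_fraction` of the population shares the best fitness (to
#' 1e-12) or after `max_generations`.
#'
#' @inheritParams stepwise_select
#' @param population_size Chromosomes per generation (default 100).
#' @param max_generations Generation cap (default 200).
#' @param mutation_rate Length-2 numeric, start and end per-bit mutation
#'   probability (default `c(0, 0.01)`).
#' @param crossover_rate Length-2 numeric, start and end crossover
#'   probability (default `c(0.9, 0.6)`).
#' @param convergence_fraction Stop when this fraction of the population
#'   attains the best fitness (default 0.9).
#' @param max_descriptors Largest allowed subset; default
#'   `floor(n / 4)` (guards against overfitted chromosomes).
#' @param p_init Per-bit probability of 1 in the initial population;
#'   default seeds sparse chromosomes averaging ~4 descriptors.
#' @param seed Integer seed driving all GA randomness.
#' @return A list of class `qsar_ga`: `model` (`qsar_mlr` on the best
#'   subset), `best_fitness`, `history` (tibble: generation, best and mean
#'   finite fitness), `generations`, `converged`.
#' @examples
#' sim <- simulate_qsar_data(n_compounds = 30, n_descriptors = 12,
#'                           n_active = 2, true_coefficients = c(1.5, -1),
#'                           n_collinear_pairs = 0, n_constant = 0, seed = 3)
#' ga <- ga_select(sim$data, population_size = 20, max_generations = 15,
#'                 seed = 1)
#' ga$model$descriptors
#' @export
ga_select <- function(data, candidates = NULL,
                      population_size = 100L, max_generations = 200L,
                      mutation_rate = c(0, 0.01),
                      crossover_rate = c(0.9, 0.6),
                      convergence_fraction = 0.9,
                      max_descriptors = NULL, p_init = NULL,
                      seed = 1L,
                      id = "compound_id", activity = "pIC50") {
  population_size <- check_count(population_size, "population_size", 2L)
  max_generations <- check_count(max_generations, "max_generations", 1L)
  if (any(mutation_rate < 0 | mutation_rate > 1) ||
      any(crossover_rate < 0 | crossover_rate > 1)) {
    abort("rates must lie in [0, 1]", class = "qsar_config_error")
  }
  if (convergence_fraction <= 0 || convergence_fraction > 1) {
    abort("convergence_fraction must lie in (0, 1]",
          class = "qsar_config_error")
  }
  if (is.null(candidates)) candidates <- descriptor_names(data, id, activity)
  x <- descriptor_matrix(data, candidates, id, activity)
  y <- activity_vector(data, activity)
  n <- length(y); p <- ncol(x)
  if (is.null(max_descriptors)) max_descriptors <- max(1L, n %/% 4L)
  if (is.null(p_init)) p_init <- min(0.5, 4 / p)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  ss_tot <- sum((y - mean(y))^2)
  cache <- new.env(parent = emptyenv())
  fitness1 <- function(bits) {
    k <- sum(bits)
    if (k == 0L || k > max_descriptors || n <= k + 1L) return(Inf)
    key <- rawToChar(as.raw(bits + 48L))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    X <- cbind(1, x[, bits == 1L, drop = FALSE])
    qr_x <- qr(X)
    val <- if (qr_x$rank < ncol(X)) Inf else {
      e <- qr.resid(qr_x, y)
      h <- rowSums(qr.Q(qr_x)^2)
      if (any(h >= 1 - 1e-12)) Inf else sqrt(mean((e / (1 - h))^2))
    }
    cache[[key]] <- val
    val
  }

  pop <- matrix(stats::rbinom(population_size * p, 1, p_init),
                population_size, p)
  # never start fully empty
  empty <- rowSums(pop) == 0
  if (any(empty)) pop[empty, sample.int(p, 1)] <- 1L

  fit <- apply(pop, 1, fitness1)
  history <- vector("list", max_generations)
  converged <- FALSE
  gen_used <- max_generations

  ramp <- function(rates, g) {
    if (max_generations == 1L) rates[1]
    else rates[1] + (rates[2] - rates[1]) * (g - 1) / (max_generations - 1)
  }

  for (g in seq_len(max_generations)) {
    best <- min(fit)
    history[[g]] <- tibble::tibble(
      generation = g, best_fitness = best,
      mean_fitness = mean(fit[is.finite(fit)]))
    if (is.finite(best) &&
        mean(abs(fit - best) <= 1e-12) >= convergence_fraction) {
      converged <- TRUE; gen_used <- g
      break
    }
    if (g == max_generations) break

    pm <- ramp(mutation_rate, g)
    pc <- ramp(crossover_rate, g)

    tournament <- function() {
      a <- sample.int(population_size, 1); b <- sample.int(population_size, 1)
      if (fit[a] <= fit[b]) a else b
    }
    elite <- which.min(fit)
    newpop <- matrix(0L, population_size, p)
    newpop[1, ] <- pop[elite, ]
    r <- 2L
    while (r <= population_size) {
      p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
      if (stats::runif(1) < pc) {
        mask <- stats::rbinom(p, 1, 0.5) == 1L
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else { c1 <- p1; c2 <- p2 }
      for (child in list(c1, c2)) {
        if (r > population_size) break
        if (pm > 0) {
          flip <- stats::runif(p) < pm
          child[flip] <- 1L - child[flip]
        }
        newpop[r, ] <- child
        r <- r + 1L
      }
    }
    pop <- newpop
    fit <- apply(pop, 1, fitness1)
  }

  best_idx <- which.min(fit)
  bits <- pop[best_idx, ]
  if (!is.finite(fit[best_idx])) {
    abort("GA found no feasible descriptor subset", class = "qsar_modeling_error")
  }
  model <- fit_mlr(data, candidates[bits == 1L], id, activity)
  structure(list(model = model, best_fitness = min(fit),
                 history = dplyr::bind_rows(history[seq_len(gen_used)]),
                 generations = gen_used, converged = converged),
            class = "qsar_ga")
}

#' @export
print.qsar_ga <- function(x, ...) {
  cat("<qsar_ga> best RMScv = ", format(x$best_fitness, digits = 4),
      " after ", x$generations, " generations (",
      if (x$converged) "converged" else "generation cap", ")\n", sep = "")
  cat("  selected:", paste(x$model$descriptors, collapse = ", "), "\n")
  invisible(x)
}
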