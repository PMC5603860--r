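# Independent brute-force oracles and random fixtures.  These deliberately
# re-derive each quantity by the most literal route available (explicit
# double loops, explicit refits, stats::lm) so they share no code with the
# implementation under test.

# RDF by literal double loop over ordered pairs, halved.
oracle_rdf <- function(coords, w, r, f = 1, B = 100) {
  n <- nrow(coords)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      rij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      total <- total + w[i] * w[j] * exp(-B * (r - rij)^2)
    }
  }
  f * total / 2
}

# Moran / Geary by explicit loops over every ordered pair, given a full
# topological distance matrix.
oracle_moran <- function(d, w, lag) {
  n <- length(w)
  dev <- w - mean(w)
  num <- 0; delta <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j]) && d[i, j] == lag) {
      num <- num + dev[i] * dev[j]
      delta <- delta + 1
    }
  }
  denom <- sum(dev^2) / n
  if (delta == 0 || denom == 0) return(0)
  (num / delta) / denom
}

oracle_geary <- function(d, w, lag) {
  n <- length(w)
  num <- 0; delta <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j]) && d[i, j] == lag) {
      num <- num + (w[i] - w[j])^2
      delta <- delta + 1
    }
  }
  denom <- sum((w - mean(w))^2) / (n - 1)
  if (delta == 0 || denom == 0) return(0)
  (num / (2 * delta)) / denom
}

# Floyd-Warshall shortest paths from a bond data frame (independent of the
# igraph route used by the package).
oracle_topo_dist <- function(n, bonds) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (r in seq_len(nrow(bonds))) {
    d[bonds$i[r], bonds$j[r]] <- 1
    d[bonds$j[r], bonds$i[r]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# PRESS by n explicit leave-one-out refits with stats::lm.
oracle_press <- function(x, y) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    df <- data.frame(y = y[-i], x[-i, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = df)
    pred <- stats::predict(fit, newdata = data.frame(x[i, , drop = FALSE]))
    press <- press + (y[i] - pred)^2
  }
  unname(press)
}

# A random connected molecular graph on n atoms (random spanning tree plus
# optional extra edges), with 3D coordinates for RDF tests.
random_molecule <- function(n, extra_edges = 1, elements = NULL) {
  parents <- if (n > 1) vapply(2:n, function(k) sample.int(k - 1, 1),
                               integer(1)) else integer()
  bonds <- data.frame(i = parents, j = seq_len(n)[-1])
  for (e in seq_len(extra_edges)) {
    cand <- sample.int(n, 2)
    if (cand[1] != cand[2] &&
        !any((bonds$i == min(cand) & bonds$j == max(cand)) |
             (bonds$i == max(cand) & bonds$j == min(cand)))) {
      bonds <- rbind(bonds, data.frame(i = cand[1], j = cand[2]))
    }
  }
  if (is.null(elements)) {
    elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  }
  molecule(elements, matrix(stats::rnorm(n * 3, sd = 2), n, 3), bonds,
           id = "random")
}

# Random rigid motion: rotation from QR of a Gaussian matrix + translation.
rigid_motion <- function(coords) {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  rot <- qr.Q(qrd)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  sweep(coords %*% rot, 2, stats::rnorm(3, sd = 5), `+`)
}

# Small planted dataset used across modelling tests.
small_sim <- function(seed = 1, n = 46, p = 20, n_active = 3,
                      coefs = c(1, -0.8, 0.6), noise_sd = 0.2) {
  simulate_qsar_data(n_compounds = n, n_descriptors = p,
                     n_active = n_active, true_coefficients = coefs,
                     noise_sd = noise_sd, n_collinear_pairs = 0,
                     n_constant = 0, seed = seed)
}
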