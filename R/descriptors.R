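#' Radial distribution function (RDF) descriptor
#'
#' Computes the RDF structure code
#' \deqn{g(r) = f \sum_{i<j} A_i A_j \exp(-B (r - r_{ij})^2)}
#' over all unordered atom pairs, where \eqn{r_{ij}} is the Euclidean
#' interatomic distance, \eqn{A} an atomic property (see
#' [atomic_weights()]), \eqn{B} a smoothing parameter and \eqn{f} a scaling
#' factor.  The code is invariant to rigid rotation/translation and to atom
#' ordering; a single-atom molecule yields zeros.
#'
#' @param mol A [molecule()].
#' @param radii Numeric vector of evaluation radii (Angstrom), strictly
#'   increasing and positive.
#' @param weights Weighting scheme, see [atomic_weights()].
#' @param f Scaling factor (default 1).
#' @param B Smoothing parameter in 1/Angstrom^2 (default 100, the
#'   conventional sharp setting for discrete RDF codes).
#' @return Named numeric vector `g(r)`, one value per radius.
#' @examples
#' rdf_code(toy_molecule("pair", distance = 2), radii = c(1, 2, 3))
#' @export
rdf_code <- function(mol, radii, weights = "unweighted", f = 1, B = 100) {
  if (B <= 0) abort("B must be > 0", class = "qsar_config_error")
  radii <- as.numeric(radii)
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    abort("radii must be positive and strictly increasing",
          class = "qsar_config_error")
  }
  n <- length(mol$elements)
  out <- setNames(numeric(length(radii)), paste0("r=", radii))
  if (n < 2L) return(out)
  w <- atomic_weights(mol, weights)
  d <- as.matrix(stats::dist(mol$coordinates))
  ij <- which(upper.tri(d), arr.ind = TRUE)
  aa <- w[ij[, 1]] * w[ij[, 2]]
  rij <- d[ij]
  for (k in seq_along(radii)) {
    out[k] <- f * sum(aa * exp(-B * (radii[k] - rij)^2))
  }
  out
}

# Shared core for the two 2D autocorrelations: returns the centred weights,
# the ordered-pair indicator at the requested lag, and Delta (ordered-pair
# count).  Lags use topological (bond-path) distance.
.autocorr_parts <- function(mol, weights, lag) {
  lag <- check_count(lag, "lag", min = 1L)
  w <- atomic_weights(mol, weights)
  d <- topological_distances(mol)
  at_lag <- is.finite(d) & d == lag
  list(w = w, at_lag = at_lag, delta = sum(at_lag))
}

#' Moran autocorrelation of a molecular graph (MATS)
#'
#' \deqn{MATS_k = \frac{\frac{1}{\Delta}\sum_{d_{ij}=k} (w_i-\bar w)(w_j-\bar w)}
#'                     {\frac{1}{N}\sum_i (w_i-\bar w)^2}}
#' with \eqn{d_{ij}} the shortest bond-path length and \eqn{\Delta} the
#' number of ordered atom pairs at lag \eqn{k}.  Returns 0 when no pair sits
#' at the lag or the weights have zero variance.
#'
#' @inheritParams rdf_code
#' @param lag Topological lag (bond count), >= 1.
#' @return Scalar MATS value.
#' @examples
#' moran_autocorrelation(toy_molecule("path3"), lag = 2, weights = "custom")
#' @export
moran_autocorrelation <- function(mol, lag, weights = "unweighted") {
  p <- .autocorr_parts(mol, weights, lag)
  dev <- p$w - mean(p$w)
  denom <- sum(dev^2) / length(p$w)
  if (p$delta == 0L || denom == 0) return(0)
  num <- sum(outer(dev, dev)[p$at_lag]) / p$delta
  num / denom
}

#' Geary autocorrelation of a molecular graph (GATS)
#'
#' \deqn{GATS_k = \frac{\frac{1}{2\Delta}\sum_{d_{ij}=k} (w_i-w_j)^2}
#'                     {\frac{1}{N-1}\sum_i (w_i-\bar w)^2}}
#' with ordered-pair counting as in [moran_autocorrelation()].  Returns 0
#' when no pair sits at the lag or the weights have zero variance.
#'
#' @inheritParams moran_autocorrelation
#' @return Scalar GATS value.
#' @export
geary_autocorrelation <- function(mol, lag, weights = "unweighted") {
  p <- .autocorr_parts(mol, weights, lag)
  n <- length(p$w)
  denom <- sum((p$w - mean(p$w))^2) / (n - 1)
  if (p$delta == 0L || denom == 0) return(0)
  diffs2 <- outer(p$w, p$w, function(a, b) (a - b)^2)
  num <- sum(diffs2[p$at_lag]) / (2 * p$delta)
  num / denom
}

#' C-005 atom-centred fragment count (CH3X)
#'
#' Counts methyl carbons whose single heavy-atom neighbour is an
#' electronegative atom (O, N, S, P, Se or a halogen) — the Ghose-Crippen
#' C-005 fragment.  Hydrogens may be explicit; when the molecule carries no
#' hydrogen atoms at all, implicit hydrogen counts are inferred from
#' standard valences and bond orders.
#'
#' @inheritParams rdf_code
#' @return Integer fragment count.
#' @examples
#' c005_count(toy_molecule("methyl_probe", name = "dimethyl ether"))
#' @export
c005_count <- function(mol) {
  n <- length(mol$elements)
  if (n == 0L) return(0L)
  h <- hydrogen_counts(mol)
  electro <- c("O", "N", "S", "P", "Se", "F", "Cl", "Br", "I")
  heavy_nb <- vector("list", n)
  if (nrow(mol$bonds) > 0) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
      if (mol$elements[j] != "H") heavy_nb[[i]] <- c(heavy_nb[[i]], j)
      if (mol$elements[i] != "H") heavy_nb[[j]] <- c(heavy_nb[[j]], i)
    }
  }
  count <- 0L
  for (a in seq_len(n)) {
    if (mol$elements[a] != "C") next
    nb <- heavy_nb[[a]]
    if (length(nb) == 1L && h[a] == 3L &&
        mol$elements[nb] %in% electro) {
      count <- count + 1L
    }
  }
  count
}

# Parse a Dragon-style descriptor name into a computation recipe.
# Grammar: RDF###w (### / 10 = radius in Angstrom), MATS#w, GATS#w, C-005;
# trailing letter w in {u, m, v, e, p} selects the weighting scheme.
parse_descriptor_name <- function(name) {
  schemes <- c(u = "unweighted", m = "mass", v = "vdw_volume",
               e = "electronegativity", p = "polarizability")
  if (name == "C-005") return(list(family = "C005"))
  m <- regmatches(name, regexec("^RDF([0-9]{3})([umvep])$", name))[[1]]
  if (length(m) == 3) {
    return(list(family = "RDF", radius = as.numeric(m[2]) / 10,
                scheme = unname(schemes[m[3]])))
  }
  m <- regmatches(name, regexec("^(MATS|GATS)([0-9]+)([umvep])$", name))[[1]]
  if (length(m) == 4) {
    return(list(family = m[2], lag = as.integer(m[3]),
                scheme = unname(schemes[m[4]])))
  }
  abort(paste0("cannot parse descriptor name '", name,
               "' (expected RDF###w, MATS#w, GATS#w or C-005)"),
        class = "qsar_config_error")
}

#' Compute a descriptor table for a set of molecules
#'
#' Evaluates named descriptors — `RDF###w` (radius = code/10 Angstrom),
#' `MATS#w`, `GATS#w` (topological lag #), `C-005` — for each molecule.
#' The trailing letter selects the atomic weighting: `u` unweighted, `m`
#' mass, `v` van der Waals volume, `e` Sanderson electronegativity, `p`
#' polarizability.
#'
#' @param mols List of [molecule()] objects.
#' @param descriptors Character vector of descriptor names.
#' @param f,B RDF scaling and smoothing parameters, see [rdf_code()].
#' @return A tibble with `compound_id` and one column per requested
#'   descriptor, rows in molecule order.
#' @examples
#' compute_descriptors(list(toy_molecule("pair")), c("RDF020u", "C-005"))
#' @export
compute_descriptors <- function(mols, descriptors, f = 1, B = 100) {
  recipes <- lapply(descriptors, parse_descriptor_name)
  rows <- lapply(mols, function(mol) {
    vals <- vapply(recipes, function(rc) {
      switch(rc$family,
        C005 = as.numeric(c005_count(mol)),
        RDF  = unname(rdf_code(mol, rc$radius, rc$scheme, f = f, B = B)),
        MATS = moran_autocorrelation(mol, rc$lag, rc$scheme),
        GATS = geary_autocorrelation(mol, rc$lag, rc$scheme))
    }, numeric(1))
    setNames(as.list(vals), descriptors)
  })
  ids <- vapply(mols, function(m) m$id, character(1))
  out <- tibble::as_tibble(
    c(list(compound_id = if (length(ids)) ids else character()),
      if (length(mols)) purrr::transpose(rows) else
        setNames(rep(list(numeric()), length(descriptors)), descriptors)))
  out[] <- lapply(out, function(col)
    if (is.list(col)) unlist(col) else col)
  out
}
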