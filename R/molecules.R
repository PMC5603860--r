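#' Molecular geometry objects
#'
#' A `qsar_molecule` is a light container for everything the descriptor
#' functions need: element symbols, 3D coordinates in Angstrom, and a bond
#' list over atom indices.  Hydrogens may be explicit atoms or left implicit
#' (inferred from standard valences where a fragment count needs them).
#'
#' @param elements Character vector of element symbols (e.g. `"C"`, `"O"`).
#' @param coordinates Numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param bonds Data frame with integer columns `i`, `j` (1-based atom
#'   indices) and optionally `order` (bond order, default 1).  The graph is
#'   undirected; each bond appears once.
#' @param id Molecule identifier.
#' @return An object of class `qsar_molecule`.
#' @examples
#' m <- molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.4, 0, 0)),
#'               data.frame(i = 1, j = 2))
#' @export
molecule <- function(elements, coordinates, bonds = NULL, id = "mol") {
  elements <- as.character(elements)
  n <- length(elements)
  coordinates <- matrix(as.numeric(coordinates), ncol = 3)
  if (nrow(coordinates) != n) {
    abort("coordinates must have one row per atom", class = "qsar_config_error")
  }
  if (any(!is.finite(coordinates))) {
    abort("coordinates must be finite", class = "qsar_config_error")
  }
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer())
  bonds <- as.data.frame(bonds)
  if (is.null(bonds$order)) bonds$order <- rep(1L, nrow(bonds))
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  if (nrow(bonds) > 0 &&
      (any(bonds$i < 1 | bonds$i > n) || any(bonds$j < 1 | bonds$j > n))) {
    abort("bond indices out of range", class = "qsar_config_error")
  }
  structure(list(id = as.character(id), elements = elements,
                 coordinates = coordinates, bonds = bonds),
            class = "qsar_molecule")
}

#' @export
print.qsar_molecule <- function(x, ...) {
  cat("<qsar_molecule> ", x$id, ": ", length(x$elements), " atoms (",
      paste(unique(x$elements), collapse = ","), "), ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# Pairwise topological (bond-path) distance matrix; Inf when disconnected.
topological_distances <- function(mol) {
  n <- length(mol$elements)
  if (nrow(mol$bonds) == 0L) {
    d <- matrix(Inf, n, n); diag(d) <- 0
    return(d)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  igraph::distances(g)
}

# Heavy-atom neighbour lists and hydrogen counts (explicit + implicit).
# Implicit hydrogens for C/N/O/S/P filled up to standard valence using the
# sum of bond orders; other elements get none.
hydrogen_counts <- function(mol) {
  n <- length(mol$elements)
  deg_order <- numeric(n)
  h_explicit <- integer(n)
  if (nrow(mol$bonds) > 0) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[r]; j <- mol$bonds$j[r]; o <- mol$bonds$order[r]
      deg_order[i] <- deg_order[i] + o
      deg_order[j] <- deg_order[j] + o
      if (mol$elements[j] == "H") h_explicit[i] <- h_explicit[i] + 1L
      if (mol$elements[i] == "H") h_explicit[j] <- h_explicit[j] + 1L
    }
  }
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3)
  any_h <- any(mol$elements == "H")
  h <- h_explicit
  if (!any_h) {
    for (a in seq_len(n)) {
      v <- valence[mol$elements[a]]
      if (!is.na(v)) h[a] <- max(0, v - deg_order[a])
    }
  }
  h
}

#' Toy molecules with known descriptor values
#'
#' Small fixture geometries whose RDF, autocorrelation and fragment-count
#' values can be computed by hand, used to exercise the descriptor engine.
#'
#' * `"pair"` — two carbon atoms at `distance` Angstrom, bonded.
#' * `"path3"` — three atoms bonded in a path (1-2-3), 1.5 Angstrom spacing;
#'   `weights` (default `c(1, 2, 3)`) is attached as the `custom` atomic
#'   property for autocorrelation tests.
#' * `"methyl_probe"` — named molecules with known C-005 counts:
#'   `"methane"` (0), `"dimethyl ether"` (2), `"anisole"` (1).
#'
#' @param kind One of `"pair"`, `"path3"`, `"methyl_probe"`.
#' @param distance Interatomic distance for `"pair"` (Angstrom).
#' @param weights Atomic property vector for `"path3"`.
#' @param name Molecule name for `"methyl_probe"`.
#' @return A [molecule()] object; for `"path3"` the `custom` attribute holds
#'   the weight vector.
#' @examples
#' toy_molecule("pair", distance = 2)
#' toy_molecule("methyl_probe", name = "dimethyl ether")
#' @export
toy_molecule <- function(kind = c("pair", "path3", "methyl_probe"),
                         distance = 2, weights = c(1, 2, 3),
                         name = "methane") {
  kind <- match.arg(kind)
  if (kind == "pair") {
    return(molecule(c("C", "C"),
                    rbind(c(0, 0, 0), c(distance, 0, 0)),
                    data.frame(i = 1, j = 2), id = "pair"))
  }
  if (kind == "path3") {
    m <- molecule(c("C", "C", "C"),
                  rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)),
                  data.frame(i = c(1, 2), j = c(2, 3)), id = "path3")
    m$custom <- as.numeric(weights)
    return(m)
  }
  # methyl_probe: heavy-atom skeletons, implicit hydrogens
  probes <- list(
    "methane" = list(el = "C", xyz = rbind(c(0, 0, 0)),
                     bonds = data.frame(i = integer(), j = integer())),
    "dimethyl ether" = list(
      el = c("C", "O", "C"),
      xyz = rbind(c(-1.4, 0, 0), c(0, 0, 0), c(1.4, 0, 0)),
      bonds = data.frame(i = c(1, 2), j = c(2, 3))),
    # anisole: benzene ring (aromatic as alternating 1/2 orders) + O-CH3
    "anisole" = list(
      el = c(rep("C", 6), "O", "C"),
      xyz = {
        ang <- seq(0, 300, by = 60) * pi / 180
        ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
        rbind(ring, c(2.8, 0, 0), c(4.2, 0, 0))
      },
      bonds = data.frame(i = c(1, 2, 3, 4, 5, 6, 1, 7),
                         j = c(2, 3, 4, 5, 6, 1, 7, 8),
                         order = c(2, 1, 2, 1, 2, 1, 1, 1)))
  )
  p <- probes[[name]]
  if (is.null(p)) {
    abort(paste0("unknown methyl_probe '", name, "'"),
          class = "qsar_config_error")
  }
  molecule(p$el, p$xyz, p$bonds, id = name)
}

#' Read molecules from an SDF (V2000) file
#'
#' Parses a structure-data file via \pkg{ChemmineR} and converts each record
#' to a [molecule()].  3D coordinates are used as stored; no conformer
#' generation or geometry optimisation is attempted.
#'
#' @param path Path to an SDF file.
#' @return A list of `qsar_molecule` objects, named by the SDF molecule names.
#' @export
read_sdf_molecules <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort("ChemmineR is required to read SDF files",
          class = "qsar_config_error")
  }
  sdf <- ChemmineR::read.SDFset(path)
  out <- lapply(seq_along(sdf), function(k) {
    one <- sdf[[k]]
    ab <- ChemmineR::atomblock(one)
    bb <- ChemmineR::bondblock(one)
    elements <- gsub("_.*$", "", rownames(ab))
    bonds <- if (nrow(bb) > 0) {
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    } else NULL
    nm <- tryCatch(ChemmineR::sdfid(sdf[k]), error = function(e) NULL)
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("mol_", k)
    molecule(elements, ab[, 1:3, drop = FALSE], bonds, id = nm)
  })
  names(out) <- vapply(out, function(m) m$id, character(1))
  out
}
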