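# Carbon-scaled atomic property tables for descriptor weighting.
#
# Raw values are the commonly published ones (atomic mass in u, van der
# Waals volume in A^3, Sanderson electronegativity, dipole polarizability
# in A^3); each scheme divides by the carbon value so that carbon weighs 1.
# The tables cover the organic subset plus halogens and Se; unknown elements
# fall back to 1 with a warning.

.atomic_props <- list(
  mass = c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
           F = 18.998, Si = 28.086, P = 30.974, S = 32.066, Cl = 35.453,
           Se = 78.971, Br = 79.904, I = 126.904),
  vdw_volume = c(H = 6.709, B = 17.875, C = 22.449, N = 15.599, O = 11.494,
                 F = 9.203, Si = 38.792, P = 29.834, S = 24.429, Cl = 23.228,
                 Se = 28.730, Br = 31.954, I = 44.839),
  electronegativity = c(H = 2.592, B = 2.275, C = 2.746, N = 3.194,
                        O = 3.654, F = 4.000, Si = 2.138, P = 2.515,
                        S = 2.957, Cl = 3.475, Se = 3.014, Br = 3.219,
                        I = 2.778),
  polarizability = c(H = 0.667, B = 3.030, C = 1.760, N = 1.100, O = 0.802,
                     F = 0.557, Si = 5.380, P = 3.630, S = 2.900, Cl = 2.180,
                     Se = 3.770, Br = 3.050, I = 5.350)
)

#' Atomic weight vector for a molecule under a weighting scheme
#'
#' Returns one weight per atom, scaled so carbon = 1.  Scheme `"unweighted"`
#' gives every atom weight 1; `"custom"` uses the molecule's own `custom`
#' vector (as set by [toy_molecule()] or by the caller).
#'
#' @param mol A [molecule()].
#' @param scheme One of `"unweighted"`, `"mass"`, `"vdw_volume"`,
#'   `"electronegativity"`, `"polarizability"`, `"custom"`, or a numeric
#'   vector with one weight per atom (used as-is).
#' @return Numeric vector, one weight per atom.
#' @export
atomic_weights <- function(mol, scheme = "unweighted") {
  n <- length(mol$elements)
  if (is.numeric(scheme)) {
    if (length(scheme) != n) {
      abort("numeric weights must have one value per atom",
            class = "qsar_config_error")
    }
    return(as.numeric(scheme))
  }
  scheme <- match.arg(scheme, c("unweighted", "mass", "vdw_volume",
                                "electronegativity", "polarizability",
                                "custom"))
  if (scheme == "unweighted") return(rep(1, n))
  if (scheme == "custom") {
    if (is.null(mol$custom)) {
      abort("molecule carries no custom weight vector",
            class = "qsar_config_error")
    }
    return(as.numeric(mol$custom))
  }
  tab <- .atomic_props[[scheme]]
  w <- unname(tab[mol$elements]) / tab[["C"]]
  if (anyNA(w)) {
    warn(paste0("no ", scheme, " value for element(s) ",
                paste(unique(mol$elements[is.na(w)]), collapse = ","),
                "; using 1"))
    w[is.na(w)] <- 1
  }
  w
}
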