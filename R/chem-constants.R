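# Element isotope tables (exact masses in Da, natural abundances), residue
# elemental compositions, and the handful of physical constants the package
# relies on. Everything mass-related in the package derives from these tables
# so monoisotopic/average scales and isotope envelopes are mutually consistent.

.isotopes <- list(
  H  = list(mass = c(1.0078250319, 2.0141017780),
            abundance = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0000000, 13.0033548378),
            abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740052, 15.0001088984),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146221, 16.9991315000, 17.9991604000),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = 30.97376151,
            abundance = 1),
  S  = list(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Ca = list(mass = c(39.9625909, 41.9586183, 42.9587668, 43.9554811,
                     45.9536926, 47.9525229),
            abundance = c(0.96941, 0.00647, 0.00135, 0.02086,
                          0.00004, 0.00187))
)

# Residue (= amino acid minus water) compositions, columns C H N O S.
.residue_formula <- local({
  m <- rbind(
    G = c(2, 3, 1, 1, 0),
    A = c(3, 5, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),
    V = c(5, 9, 1, 1, 0),
    T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),
    L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0),
    E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

.water_formula <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

# Monoisotopic mass of an element = mass of its most abundant isotope.
.element_mono <- vapply(.isotopes, function(x) x$mass[which.max(x$abundance)],
                        numeric(1))
# Average mass = abundance-weighted mean over isotopes.
.element_avg <- vapply(.isotopes, function(x) sum(x$mass * x$abundance),
                       numeric(1))

#' Physical and mass-spectrometric constants
#'
#' Fixed constants used throughout the package. The proton mass is used for
#' all m/z arithmetic (electron mass neglected); the neutron-equivalent
#' isotope spacing of 1.00235 Da is the peptide/protein average spacing used
#' for charge inference and isotope-cluster walking.
#'
#' @format A named list with elements `proton` (Da), `isotope_spacing` (Da),
#'   `kb` (J/K), `e` (C), `N0` (m^-3, gas number density at standard
#'   conditions consistent with the reduced-mobility convention), `amu` (kg).
#' @export
ntdms_constants <- list(
  proton = 1.007276,
  isotope_spacing = 1.00235,
  kb = 1.380649e-23,
  e = 1.602176634e-19,
  N0 = 2.68678e25,
  amu = 1.66053906660e-27
)

# Mass of a named elemental formula (named integer/numeric vector of atom
# counts) on the requested scale.
formula_mass <- function(formula, scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  el <- names(formula)
  bad <- setdiff(el, names(.isotopes))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab <- if (scale == "monoisotopic") .element_mono else .element_avg
  sum(unlist(formula) * tab[el])
}

# Elemental formula (C H N O S [+ others]) of a residue chain given as a
# character vector of one-letter codes.
chain_formula <- function(residues) {
  bad <- which(!residues %in% rownames(.residue_formula))
  if (length(bad)) {
    stop("unknown residue code '", residues[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  counts <- colSums(.residue_formula[residues, , drop = FALSE])
  counts + .water_formula
}

# Sum two named formula vectors (missing elements treated as zero).
formula_add <- function(a, b) {
  el <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(el)), el)
  out[names(a)] <- out[names(a)] + unlist(a)
  out[names(b)] <- out[names(b)] + unlist(b)
  out
}

formula_scale <- function(a, k) {
  out <- unlist(a) * k
  stats::setNames(out, names(a))
}

# Per-residue mass table on a scale, for fast chain sums.
residue_masses <- function(scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  tab <- if (scale == "monoisotopic") .element_mono else .element_avg
  drop(.residue_formula %*% tab[colnames(.residue_formula)])
}

water_mass <- function(scale = c("monoisotopic", "average")) {
  formula_mass(.water_formula, match.arg(scale))
}
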