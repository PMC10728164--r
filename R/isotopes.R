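# Isotope envelopes. Aggregated (nucleon-resolved) isotope distributions are
# computed by exact convolution of per-element distributions on an integer
# neutron-offset grid, tracking the probability-weighted exact mass of each
# bin; this reproduces centroided isotopologue peaks at any protein size
# without enumerating fine structure. For species of unknown composition the
# averagine average-residue model supplies a surrogate formula.

# Senko averagine: average-residue composition and average mass.
.averagine <- list(
  formula = c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417),
  mass = 111.1254
)

# (prob, mass) distribution of a single atom on the integer offset grid.
atom_distribution <- function(element) {
  iso <- .isotopes[[element]]
  if (is.null(iso)) stop("unknown element symbol: ", element, call. = FALSE)
  k <- round(iso$mass - iso$mass[1])
  p <- numeric(max(k) + 1)
  m <- numeric(max(k) + 1)
  for (i in seq_along(iso$mass)) {
    p[k[i] + 1] <- p[k[i] + 1] + iso$abundance[i]
    m[k[i] + 1] <- m[k[i] + 1] + iso$abundance[i] * iso$mass[i]
  }
  nz <- p > 0
  m[nz] <- m[nz] / p[nz]
  list(p = p, m = m)
}

# Convolve two (prob, mass) distributions; drop negligible tail mass.
dist_convolve <- function(a, b, tol = 1e-15) {
  n <- length(a$p) + length(b$p) - 1L
  p <- numeric(n)
  m <- numeric(n)
  for (i in seq_along(a$p)) {
    if (a$p[i] == 0) next
    j <- seq_along(b$p) + i - 1L
    w <- a$p[i] * b$p
    p[j] <- p[j] + w
    m[j] <- m[j] + w * (a$m[i] + b$m)
  }
  nz <- p > 0
  m[nz] <- m[nz] / p[nz]
  keep <- p > tol * max(p)
  last <- max(which(keep))
  first <- min(which(keep))
  if (first > 1L) {
    # never drop the leading (monoisotopic-side) bins; they define offsets
    first <- 1L
  }
  list(p = p[first:last], m = m[first:last])
}

# Distribution of n identical atoms by binary exponentiation.
dist_power <- function(base, n) {
  result <- NULL
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base else dist_convolve(result, base)
    }
    base <- dist_convolve(base, base)
    n <- n %/% 2
  }
  if (is.null(result)) list(p = 1, m = 0) else result
}

formula_distribution <- function(formula) {
  formula <- formula[unlist(formula) != 0]
  if (!length(formula)) stop("empty formula", call. = FALSE)
  if (any(unlist(formula) < 0)) {
    stop("negative atom counts have no isotope distribution", call. = FALSE)
  }
  acc <- list(p = 1, m = 0)
  for (el in names(formula)) {
    acc <- dist_convolve(acc, dist_power(atom_distribution(el),
                                         round(formula[[el]])))
  }
  acc
}

#' Theoretical isotope envelope
#'
#' Computes the aggregated isotope distribution of an elemental formula, a
#' proteoform, or a bare mass. Bare masses (and assemblies of unknown
#' composition) use the averagine model: the canonical average-residue
#' formula is scaled to the target mass, atom counts are rounded, and
#' hydrogens are adjusted to absorb the rounding remainder. Probabilities
#' are truncated to the requested cumulative coverage and renormalized to 1.
#'
#' @param x A named formula vector (e.g. `c(C = 1)`), an `ntdms_proteoform`,
#'   an `ntdms_assembly` of sequence-backed subunits, or a single numeric
#'   mass in Da.
#' @param truncation Cumulative probability retained, in (0, 1]
#'   (default 0.9999).
#' @param model `"elemental"` (exact formula; the default whenever a formula
#'   is derivable) or `"averagine"`.
#' @return An object of class `ntdms_envelope`: list with `offsets` (Da above
#'   the monoisotopic mass), `probabilities` (summing to 1), and
#'   `monoisotopic_offset_mass` (exact mass of the first bin when the input
#'   carries a formula, else `NA`).
#' @examples
#' isotope_envelope(c(C = 1))$probabilities # 12C/13C abundances
#' @export
isotope_envelope <- function(x, truncation = 0.9999,
                             model = c("elemental", "averagine")) {
  model <- match.arg(model)
  if (!is.numeric(truncation) || truncation <= 0 || truncation > 1) {
    stop("truncation must be in (0, 1]", call. = FALSE)
  }
  formula <- NULL
  if (inherits(x, "ntdms_proteoform")) {
    formula <- proteoform_formula(x)
    if (is.null(formula)) model <- "averagine"
    mass <- neutral_mass(x)
  } else if (inherits(x, "ntdms_assembly")) {
    forms <- lapply(x$subunits, function(s)
      if (inherits(s, "ntdms_proteoform")) proteoform_formula(s) else NULL)
    if (!any(vapply(forms, is.null, logical(1))) && model == "elemental") {
      formula <- Reduce(formula_add, forms)
    } else {
      model <- "averagine"
    }
    mass <- neutral_mass(x)
  } else if (is.numeric(x) && length(x) == 1L && is.null(names(x))) {
    mass <- x
    if (mass <= 0) stop("mass must be positive", call. = FALSE)
    model <- "averagine"
  } else if (is.numeric(x) || is.list(x)) {
    formula <- unlist(x)
    if (is.null(names(formula)) || !length(formula)) {
      stop("formula must be a named vector of atom counts", call. = FALSE)
    }
    mass <- formula_mass(formula)
  } else {
    stop("cannot compute an envelope for objects of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  if (model == "averagine") formula <- averagine_formula(mass)
  d <- formula_distribution(formula)
  # truncate to requested cumulative coverage around the envelope bulk
  ord <- order(d$p, decreasing = TRUE)
  keep_n <- which(cumsum(d$p[ord]) / sum(d$p) >= truncation)[1]
  keep <- sort(ord[seq_len(keep_n)])
  p <- d$p[keep]
  offsets <- d$m[keep] - d$m[1]
  structure(list(offsets = offsets, probabilities = p / sum(p),
                 monoisotopic_offset_mass = d$m[1], model = model),
            class = "ntdms_envelope")
}

#' @export
print.ntdms_envelope <- function(x, ...) {
  cat("<ntdms_envelope> ", length(x$offsets), " isotopologue peaks (",
      x$model, " model), most probable at +",
      round(x$offsets[which.max(x$probabilities)], 3), " Da\n", sep = "")
  invisible(x)
}

#' Averagine surrogate formula for a target mass
#'
#' @param mass Target mass in Da (treated on the average scale; at envelope
#'   resolution the mono/average distinction is immaterial for shape).
#' @return Named integer vector of atom counts (C, H, N, O, S) with H
#'   adjusted so the average mass matches the target to within half a
#'   hydrogen.
#' @export
averagine_formula <- function(mass) {
  stopifnot(is.numeric(mass), mass > 0)
  n <- mass / .averagine$mass
  counts <- round(.averagine$formula * n)
  counts["H"] <- 0
  heavy <- formula_mass(counts, "average")
  counts["H"] <- max(0, round((mass - heavy) / .element_avg[["H"]]))
  counts
}

# Elemental formula of a proteoform, or NULL when a modification lacks one.
proteoform_formula <- function(p) {
  stopifnot(inherits(p, "ntdms_proteoform"))
  kept <- retained_positions(p$sequence, p$truncation)
  idx <- kept - p$sequence$numbering_origin + 1L
  f <- chain_formula(p$sequence$residues[idx])
  if (nrow(p$modifications)) {
    reg <- p$registry
    for (nm in p$modifications$name) {
      mf <- reg$formula[[match(nm, reg$name)]]
      if (is.null(mf)) return(NULL)
      f <- formula_add(f, mf)
    }
  }
  if (p$adducts$count > 0) {
    f <- formula_add(f, c(Ca = p$adducts$count))
    if (p$adducts$mode == "charge-displacement") {
      f["H"] <- f["H"] - 2 * p$adducts$count
    }
  }
  if (any(f < 0)) return(NULL)
  f[f != 0]
}
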