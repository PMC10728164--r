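# Mason-Schamps conversion between reduced ion mobility and collision cross
# section, CCS-vs-charge regression, and mobilogram conformer summarization.

#' Buffer-gas and physical parameters for mobility conversion
#'
#' @param gas_mass Buffer-gas particle mass in Da (default N2, 28.0134).
#' @param temperature Drift-region temperature in K (default 305, a typical
#'   trapped-ion-mobility drift temperature; instrument source temperatures
#'   do not apply to the drift region).
#' @param N0 Buffer-gas number density at standard conditions in m^-3
#'   (Loschmidt value consistent with the reduced-mobility convention;
#'   fixed, never recomputed from instantaneous conditions).
#' @param kb Boltzmann constant in J/K.
#' @param e Elementary charge in C.
#' @return An object of class `ntdms_gas`.
#' @export
gas_parameters <- function(gas_mass = 28.0134, temperature = 305,
                           N0 = ntdms_constants$N0,
                           kb = ntdms_constants$kb,
                           e = ntdms_constants$e) {
  vals <- c(gas_mass, temperature, N0, kb, e)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all gas parameters must be positive and finite", call. = FALSE)
  }
  structure(list(gas_mass = gas_mass, temperature = temperature,
                 N0 = N0, kb = kb, e = e), class = "ntdms_gas")
}

#' A reduced-mobility measurement
#'
#' @param inverse_K0 Reduced inverse mobility in V s/cm^2.
#' @param charge Integer ionic charge (>= 1).
#' @param ion_mass Ion mass in Da.
#' @return An object of class `ntdms_mobility`.
#' @export
mobility_measurement <- function(inverse_K0, charge, ion_mass) {
  if (any(inverse_K0 <= 0)) stop("inverse_K0 must be > 0", call. = FALSE)
  charge <- as.integer(charge)
  if (any(is.na(charge)) || any(charge < 1L)) {
    stop("charge must be >= 1", call. = FALSE)
  }
  if (any(ion_mass <= 0)) stop("ion_mass must be > 0", call. = FALSE)
  structure(list(inverse_K0 = inverse_K0, charge = charge,
                 ion_mass = ion_mass), class = "ntdms_mobility")
}

# Reduced ion-gas mass in kg.
reduced_mass_kg <- function(ion_mass, gas_mass) {
  mu_da <- ion_mass * gas_mass / (ion_mass + gas_mass)
  mu_da * ntdms_constants$amu
}

#' Collision cross section from reduced mobility (Mason-Schamps)
#'
#' CCS = (3/16) sqrt(2 pi / (mu kb T)) (z e) / (N0 K0), with the reduced
#' ion-gas mass mu = m M / (m + M), evaluated in SI units and returned in
#' square angstroms.
#'
#' @param m A [mobility_measurement()].
#' @param g A [gas_parameters()].
#' @return List of class `ntdms_ccs` with fields `ccs` (A^2), `charge`,
#'   `gas`.
#' @examples
#' mm <- mobility_measurement(1.2, 20, 77136)
#' ccs_from_mobility(mm)$ccs
#' @export
ccs_from_mobility <- function(m, g = gas_parameters()) {
  stopifnot(inherits(m, "ntdms_mobility"), inherits(g, "ntdms_gas"))
  mu <- reduced_mass_kg(m$ion_mass, g$gas_mass)
  K0 <- (1 / m$inverse_K0) * 1e-4            # cm^2/(V s) -> m^2/(V s)
  ccs_m2 <- (3 / 16) * sqrt(2 * pi / (mu * g$kb * g$temperature)) *
    (m$charge * g$e) / (g$N0 * K0)
  structure(list(ccs = ccs_m2 * 1e20, charge = m$charge, gas = g),
            class = "ntdms_ccs")
}

#' Reduced mobility from a collision cross section
#'
#' Exact algebraic inverse of [ccs_from_mobility()].
#'
#' @param ccs Collision cross section in A^2 (> 0).
#' @param charge Integer ionic charge.
#' @param ion_mass Ion mass in Da.
#' @param g A [gas_parameters()].
#' @return A [mobility_measurement()] whose forward conversion reproduces
#'   `ccs`.
#' @export
mobility_from_ccs <- function(ccs, charge, ion_mass, g = gas_parameters()) {
  if (any(ccs <= 0)) stop("CCS must be > 0", call. = FALSE)
  charge <- as.integer(charge)
  if (any(is.na(charge)) || any(charge < 1L)) {
    stop("charge must be >= 1", call. = FALSE)
  }
  mu <- reduced_mass_kg(ion_mass, g$gas_mass)
  ccs_m2 <- ccs * 1e-20
  K0 <- (3 / 16) * sqrt(2 * pi / (mu * g$kb * g$temperature)) *
    (charge * g$e) / (g$N0 * ccs_m2)         # m^2/(V s)
  mobility_measurement(1 / (K0 * 1e4), charge, ion_mass)
}

#' Ordinary least-squares fit of CCS against charge state
#'
#' Native protein conformers show a near-linear CCS-charge relationship;
#' this fits it by OLS.
#'
#' @param points Data frame with columns `charge` and `ccs` (>= 2 distinct
#'   charges).
#' @return List with `slope` (A^2 per charge), `intercept` (A^2), and `r2`.
#' @export
ccs_charge_fit <- function(points) {
  stopifnot(all(c("charge", "ccs") %in% names(points)))
  if (length(unique(points$charge)) < 2L) {
    stop("need at least two distinct charge states", call. = FALSE)
  }
  fit <- stats::lm(ccs ~ charge, data = points)
  # collinear input is legitimate here; silence the perfect-fit warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r2)) r2 <- 1  # exactly collinear two-point fit
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r2 = r2)
}

#' Construct a mobilogram
#'
#' @param inverse_K0 Ascending numeric axis in V s/cm^2.
#' @param intensity Non-negative intensities of equal length.
#' @param charge Integer charge of the monitored ion.
#' @param ion_mass Ion mass in Da.
#' @param metadata Free-form list.
#' @return An object of class `ntdms_mobilogram`.
#' @export
mobilogram <- function(inverse_K0, intensity, charge, ion_mass,
                       metadata = list()) {
  if (length(inverse_K0) != length(intensity)) {
    stop("axis and intensity must have equal length", call. = FALSE)
  }
  if (length(inverse_K0) > 1 && any(diff(inverse_K0) <= 0)) {
    stop("inverse_K0 axis must be strictly ascending", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(inverse_K0 = inverse_K0, intensity = intensity,
                 charge = as.integer(charge), ion_mass = ion_mass,
                 metadata = metadata),
            class = "ntdms_mobilogram")
}

#' Read a mobilogram from two-column text
#'
#' The data file holds (1/K0, intensity) rows; charge and ion mass come
#' either from arguments or from a YAML sidecar `<path>.meta` with keys
#' `charge`, `ion_mass` (and optionally `gas_mass`, `temperature`).
#'
#' @param path Data file.
#' @param charge,ion_mass Override/supply header values.
#' @return An `ntdms_mobilogram`.
#' @export
read_mobilogram <- function(path, charge = NULL, ion_mass = NULL) {
  meta <- list()
  sidecar <- paste0(path, ".meta")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  charge <- charge %||% meta$charge
  ion_mass <- ion_mass %||% meta$ion_mass
  if (is.null(charge) || is.null(ion_mass)) {
    stop("charge and ion_mass must come from arguments or the .meta sidecar",
         call. = FALSE)
  }
  first <- readLines(path, n = 20L)
  sep <- if (any(grepl(",", first[!grepl("^#", first)]))) "," else ""
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           comment.char = "#")
  ord <- order(tab[[1]])
  mobilogram(tab[[1]][ord], tab[[2]][ord], charge, ion_mass, metadata = meta)
}

# Peak prominence: height above the higher of the two bounding valleys,
# where a valley is the minimum between the peak and the nearest
# higher-or-equal peak (or the trace edge).
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- if (p == 1L) numeric() else y[1:(p - 1L)]
    right <- if (p == length(y)) numeric() else y[(p + 1L):length(y)]
    lv <- if (!length(left)) 0 else {
      higher <- which(left >= y[p])
      if (length(higher)) min(y[(max(higher)):(p - 1L)]) else min(left)
    }
    rv <- if (!length(right)) 0 else {
      higher <- which(right >= y[p]) + p
      if (length(higher)) min(y[(p + 1L):(min(higher))]) else min(right)
    }
    y[p] - max(lv, rv)
  }, numeric(1))
}

#' Summarize a mobilogram into conformers
#'
#' Local-maximum peak detection with prominence filtering. Each retained
#' apex defines one conformer; the trace is partitioned at the minima
#' between adjacent apexes and each conformer's share is its integrated
#' (trapezoidal) area over the total. Apex positions are refined by
#' three-point parabolic interpolation and converted to CCS.
#'
#' @param m An `ntdms_mobilogram`.
#' @param min_prominence Minimum prominence as a fraction of the maximum
#'   intensity (default 0.05).
#' @param g A [gas_parameters()].
#' @return Data frame with columns `apex_inverse_K0`, `apex_ccs` (A^2),
#'   `fwhm_inverse_K0`, `share` (summing to 1); zero rows for a flat trace.
#' @export
summarize_mobilogram <- function(m, min_prominence = 0.05,
                                 g = gas_parameters()) {
  stopifnot(inherits(m, "ntdms_mobilogram"))
  y <- m$intensity
  x <- m$inverse_K0
  out0 <- data.frame(apex_inverse_K0 = numeric(), apex_ccs = numeric(),
                     fwhm_inverse_K0 = numeric(), share = numeric())
  n <- length(y)
  if (n < 3L || max(y) <= min(y)) return(out0)
  peaks <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(peaks)) return(out0)
  prom <- peak_prominences(y, peaks)
  peaks <- peaks[prom >= min_prominence * max(y)]
  if (!length(peaks)) return(out0)
  peaks <- peaks[order(x[peaks])]
  # partition boundaries at minima between adjacent apexes
  bounds <- c(1L, vapply(seq_len(length(peaks) - 1L), function(i) {
    seg <- peaks[i]:peaks[i + 1L]
    seg[which.min(y[seg])]
  }, integer(1)), n)
  rows <- lapply(seq_along(peaks), function(i) {
    p <- peaks[i]
    # parabolic apex refinement
    delta <- 0
    if (p > 1L && p < n) {
      denom <- y[p - 1L] - 2 * y[p] + y[p + 1L]
      if (denom != 0) delta <- 0.5 * (y[p - 1L] - y[p + 1L]) / denom
      if (abs(delta) > 0.5) delta <- 0
    }
    step <- if (p > 1L && p < n) (x[p + 1L] - x[p - 1L]) / 2 else 0
    apex_x <- x[p] + delta * step
    seg <- bounds[i]:bounds[i + 1L]
    area <- sum(diff(x[seg]) * (y[seg][-1] + y[seg][-length(seg)]) / 2)
    half <- y[p] / 2
    above <- seg[y[seg] >= half]
    fwhm <- if (length(above) > 1) x[max(above)] - x[min(above)] else 0
    data.frame(apex_inverse_K0 = apex_x,
               apex_ccs = ccs_from_mobility(
                 mobility_measurement(apex_x, m$charge, m$ion_mass), g)$ccs,
               fwhm_inverse_K0 = fwhm, share = area)
  })
  res <- do.call(rbind, rows)
  total <- sum(res$share)
  if (total > 0) res$share <- res$share / total
  rownames(res) <- NULL
  res
}
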