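# Seeded ground-truth generators: isotopically resolved MS1 charge-envelope
# spectra of proteoform mixtures, CAD fragment spectra with
# position-faithful adduct retention, and Gaussian mobilograms. Every
# generator is a pure function of (config, seed) and returns a SyntheticTruth
# record sufficient to score any downstream recovery.

#' Generator configuration for synthetic MS1 spectra
#'
#' @param species List of `list(species = <proteoform|assembly|mass>,
#'   proportion = <weight>)`; proportions must be non-negative and sum to
#'   at most 1.
#' @param charge_center,charge_width Center and width of the discrete
#'   Gaussian charge envelope.
#' @param charges Integer charge support (default `charge_center` +/- 1
#'   rounded from the width).
#' @param resolving_power FWHM resolving power at the local m/z
#'   (default 150000, isotopic resolution for intact proteins).
#' @param baseline Additive baseline noise level in counts (default 0).
#' @param peak_cv Multiplicative per-peak intensity coefficient of
#'   variation (default 0).
#' @param base_intensity Height of the tallest peak in counts
#'   (default 5e4).
#' @param grid_step Profile grid spacing in m/z (default: a quarter of the
#'   narrowest peak sigma).
#' @param seed Integer seed; identical seeds give identical outputs.
#' @return An object of class `ntdms_genconfig`.
#' @export
generator_config <- function(species, charge_center = 19, charge_width = 1,
                             charges = NULL, resolving_power = 150000,
                             baseline = 0, peak_cv = 0,
                             base_intensity = 5e4, grid_step = NULL,
                             seed = 1L) {
  props <- vapply(species, function(s) s$proportion, numeric(1))
  if (any(props < 0) || sum(props) > 1 + 1e-9) {
    stop("proportions must be >= 0 and sum to at most 1", call. = FALSE)
  }
  if (resolving_power <= 0) stop("resolving_power must be > 0",
                                 call. = FALSE)
  if (is.null(charges)) {
    half <- max(1L, round(1.5 * charge_width))
    charges <- seq(max(1L, round(charge_center) - half),
                   round(charge_center) + half)
  }
  structure(list(species = species, charge_center = charge_center,
                 charge_width = charge_width, charges = as.integer(charges),
                 resolving_power = resolving_power, baseline = baseline,
                 peak_cv = peak_cv, base_intensity = base_intensity,
                 grid_step = grid_step, seed = as.integer(seed)),
            class = "ntdms_genconfig")
}

species_mass_and_envelope <- function(sp) {
  if (is.numeric(sp) && length(sp) == 1L) {
    list(mass = sp, envelope = isotope_envelope(sp), label = paste0("m", sp))
  } else {
    list(mass = neutral_mass(sp), envelope = isotope_envelope(sp),
         label = sp$label)
  }
}

#' Generate a synthetic MS1 charge-envelope spectrum
#'
#' Places each species' theoretical isotope envelope at every charge of the
#' configured envelope, with Gaussian peak shapes at the configured
#' resolving power, species proportions and discrete-Gaussian charge
#' weights, optional per-peak multiplicative noise and additive baseline
#' noise. Species pairs closer than one isotope spacing are generated
#' anyway and flagged in the truth record.
#'
#' @param config A [generator_config()].
#' @return List with `spectrum` (profile `ntdms_spectrum`) and `truth`
#'   (class `ntdms_truth`: species table with true masses and proportions,
#'   charges, seed, overlap flags).
#' @export
generate_ms1 <- function(config) {
  stopifnot(inherits(config, "ntdms_genconfig"))
  info <- lapply(config$species, function(s)
    species_mass_and_envelope(s$species))
  masses <- vapply(info, `[[`, numeric(1), "mass")
  labels <- vapply(info, `[[`, character(1), "label")
  props <- vapply(config$species, function(s) s$proportion, numeric(1))
  zs <- config$charges
  zw <- stats::dnorm(zs, config$charge_center, max(config$charge_width,
                                                  1e-6))
  zw <- zw / sum(zw)
  peaks <- do.call(rbind, lapply(seq_along(info), function(i) {
    env <- info[[i]]$envelope
    do.call(rbind, lapply(seq_along(zs), function(j) {
      data.frame(mz = (masses[i] + env$offsets) / zs[j] +
                   ntdms_constants$proton,
                 h = props[i] * zw[j] * env$probabilities)
    }))
  }))
  peaks$h <- peaks$h / max(peaks$h) * config$base_intensity
  sigma <- peaks$mz / config$resolving_power / (2 * sqrt(2 * log(2)))
  step <- config$grid_step
  if (is.null(step)) step <- min(sigma) / 4
  lo <- min(peaks$mz) - 3
  hi <- max(peaks$mz) + 3
  grid <- seq(lo, hi, by = step)
  y <- numeric(length(grid))
  sp <- withr::with_seed(config$seed, {
    h <- peaks$h * pmax(0, 1 + stats::rnorm(nrow(peaks), 0, config$peak_cv))
    for (k in seq_len(nrow(peaks))) {
      i0 <- max(1L, floor((peaks$mz[k] - 5 * sigma[k] - lo) / step) + 1L)
      i1 <- min(length(grid), ceiling((peaks$mz[k] + 5 * sigma[k] - lo) /
                                        step) + 1L)
      idx <- i0:i1
      y[idx] <- y[idx] + h[k] * exp(-(grid[idx] - peaks$mz[k])^2 /
                                      (2 * sigma[k]^2))
    }
    if (config$baseline > 0) {
      y <- y + pmax(0, stats::rnorm(length(y), config$baseline,
                                    config$baseline / 2))
    }
    y
  })
  overlap <- which(outer(masses, masses, function(a, b)
    abs(a - b) < ntdms_constants$isotope_spacing) &
      upper.tri(matrix(0, length(masses), length(masses))), arr.ind = TRUE)
  truth <- structure(list(
    species = data.frame(label = labels, mass = masses, proportion = props,
                         stringsAsFactors = FALSE),
    charges = zs, charge_weights = zw, seed = config$seed,
    overlapping_pairs = overlap), class = "ntdms_truth")
  list(spectrum = mass_spectrum(grid, sp,
                           metadata = list(generator = "generate_ms1",
                                           seed = config$seed)),
       truth = truth)
}

#' Generate a synthetic CAD fragment spectrum
#'
#' Cleaves each backbone bond independently with the stated efficiency
#' (seeded Bernoulli); every cleaved bond emits its b and y ions. A
#' fragment carries exactly those adducts whose residue position lies in
#' its span (position-faithful retention), each retained adduct being lost
#' with probability `loss_prob` (gas-phase lability; default 0). Charges
#' are drawn from a capped distribution scaled to the fragment mass.
#'
#' @param p An `ntdms_proteoform` with localized modifications.
#' @param adduct_positions True metal residue positions (length equal to
#'   the proteoform's adduct count).
#' @param efficiency Per-bond cleavage probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param loss_prob Per-adduct gas-phase loss probability (default 0).
#' @param max_charge Fragment charge cap (default 10).
#' @return List with `spectrum` (centroided `ntdms_spectrum`), `ions`
#'   (the emitted ion table) and `truth` (`ntdms_truth`: adduct positions,
#'   cleaved bonds, seed).
#' @export
generate_ms2 <- function(p, adduct_positions = integer(), efficiency = 0.6,
                         seed = 1L, loss_prob = 0, max_charge = 10L) {
  stopifnot(inherits(p, "ntdms_proteoform"))
  if (efficiency < 0 || efficiency > 1) {
    stop("efficiency must be in [0, 1]", call. = FALSE)
  }
  if (length(adduct_positions) != p$adducts$count) {
    stop("adduct_positions must match the proteoform's adduct count",
         call. = FALSE)
  }
  L <- length(p$sequence$residues)
  org <- p$sequence$numbering_origin
  withr::with_seed(seed, {
    cleaved <- which(stats::runif(L - 1L) < efficiency)
    rows <- lapply(cleaved, function(j) {
      do.call(rbind, lapply(c("b", "y"), function(series) {
        index <- if (series == "b") j else L - j
        span <- if (series == "b") seq(org, org + index - 1L)
                else seq(org + L - index, org + L - 1L)
        in_span <- adduct_positions[adduct_positions %in% span]
        kept <- in_span[stats::runif(length(in_span)) >= loss_prob]
        nm <- fragment_mass(p, series, index, adduct_count = length(kept))
        zmax <- max(1L, min(max_charge, round(nm / 1500)))
        z <- sample(seq_len(zmax), 1L)
        data.frame(series = series, index = index,
                   adduct_count = length(kept), charge = z,
                   neutral_mass = nm, mz = mz_of(nm, z),
                   intensity = stats::rlnorm(1, log(1e4), 0.5))
      }))
    })
    ions <- if (length(rows)) do.call(rbind, rows) else
      data.frame(series = character(), index = integer(),
                 adduct_count = integer(), charge = integer(),
                 neutral_mass = numeric(), mz = numeric(),
                 intensity = numeric())
    ions <- ions[order(ions$mz), , drop = FALSE]
    # merge coincident m/z (distinct ions can collide on the m/z axis)
    mzu <- ions$mz
    if (anyDuplicated(round(mzu, 6))) {
      mzu <- mzu + seq_along(mzu) * 1e-9
    }
    spec <- mass_spectrum(mzu, ions$intensity,
                     metadata = list(generator = "generate_ms2",
                                     seed = seed),
                     centroided = TRUE)
    truth <- structure(list(
      adduct_positions = adduct_positions, cleaved_bonds = cleaved,
      efficiency = efficiency, loss_prob = loss_prob, seed = seed,
      chain_length = L), class = "ntdms_truth")
    list(spectrum = spec, ions = ions, truth = truth)
  })
}

#' Generate a synthetic mobilogram
#'
#' Gaussian conformer peaks placed at the inverse mobilities implied by the
#' requested CCS values, with seeded additive noise.
#'
#' @param conformers Data frame (or list of lists) with columns `ccs`
#'   (A^2), `weight` (normalized internally), `width` (Gaussian sigma in
#'   1/K0 units, > 0).
#' @param charge,ion_mass Ion descriptors.
#' @param g A [gas_parameters()].
#' @param baseline Additive noise level (default 0).
#' @param axis Optional explicit 1/K0 axis; default spans the conformers
#'   +/- 6 widths at 1/2000 V s/cm^2 steps.
#' @param seed Integer seed.
#' @return List with `mobilogram` (`ntdms_mobilogram`) and `truth`
#'   (`ntdms_truth`: per-conformer CCS, weights, widths, seed).
#' @export
generate_mobilogram <- function(conformers, charge, ion_mass,
                                g = gas_parameters(), baseline = 0,
                                axis = NULL, seed = 1L) {
  conf <- as.data.frame(do.call(rbind, lapply(
    if (is.data.frame(conformers)) split(conformers,
                                         seq_len(nrow(conformers)))
    else conformers,
    function(x) data.frame(ccs = x$ccs, weight = x$weight,
                           width = x$width))))
  if (any(conf$width <= 0)) stop("conformer widths must be > 0",
                                 call. = FALSE)
  conf$weight <- conf$weight / sum(conf$weight)
  centers <- vapply(conf$ccs, function(cc)
    mobility_from_ccs(cc, charge, ion_mass, g)$inverse_K0, numeric(1))
  if (is.null(axis)) {
    axis <- seq(min(centers - 6 * conf$width),
                max(centers + 6 * conf$width), by = 5e-4)
  }
  y <- numeric(length(axis))
  for (i in seq_len(nrow(conf))) {
    y <- y + conf$weight[i] * stats::dnorm(axis, centers[i], conf$width[i])
  }
  y <- y / max(y)
  y <- withr::with_seed(seed, {
    if (baseline > 0) y + pmax(0, stats::rnorm(length(y), baseline,
                                               baseline / 2)) else y
  })
  truth <- structure(list(
    conformers = data.frame(ccs = conf$ccs, weight = conf$weight,
                            width = conf$width, center_inverse_K0 = centers),
    charge = charge, ion_mass = ion_mass, seed = seed),
    class = "ntdms_truth")
  list(mobilogram = mobilogram(axis, y, charge, ion_mass,
                               metadata = list(generator =
                                                 "generate_mobilogram",
                                               seed = seed)),
       truth = truth)
}

#' Emulate an EGTA titration series of mobilograms
#'
#' Chelator stripping of bound Ca2+ destabilizes a complex: with rising
#' EGTA concentration the emulation adds conformers (partially unfolded,
#' larger CCS) and broadens them, mirroring conformer enhancement under
#' titration. Conformer count is non-decreasing along the series by
#' construction.
#'
#' @param concentrations Numeric EGTA concentrations in mM
#'   (default `c(0, 25, 50, 100)`).
#' @param base_ccs Folded-complex CCS in A^2 (default 4880).
#' @param charge,ion_mass Ion descriptors (defaults 20 and 77136).
#' @param g A [gas_parameters()].
#' @param seed Integer seed.
#' @return Named list (one element per concentration) of
#'   [generate_mobilogram()] results.
#' @export
generate_egta_series <- function(concentrations = c(0, 25, 50, 100),
                                 base_ccs = 4880, charge = 20L,
                                 ion_mass = 77136, g = gas_parameters(),
                                 seed = 1L) {
  concentrations <- sort(concentrations)
  out <- lapply(seq_along(concentrations), function(i) {
    n_conf <- i  # one additional partially unfolded conformer per step
    ccs <- base_ccs * (1 + 0.06 * (seq_len(n_conf) - 1L))
    weight <- rev(seq_len(n_conf))  # folded state stays most abundant
    width <- 0.008 * (1 + 0.3 * (seq_len(n_conf) - 1L))
    generate_mobilogram(
      data.frame(ccs = ccs, weight = weight, width = width),
      charge = charge, ion_mass = ion_mass, g = g,
      seed = seed + i)
  })
  names(out) <- paste0("EGTA_", concentrations, "mM")
  out
}

#' Serialize a truth record alongside a generated artifact
#'
#' @param truth An `ntdms_truth`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
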