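# Isotopically resolved deconvolution: charge inference from isotope
# spacing, envelope fitting against theoretical distributions, and species
# quantification. The picker emulates a SNAP-style procedure: peaks are
# clustered at the 1.00235/z isotope spacing, a theoretical envelope is
# aligned to the cluster, and the monoisotopic mass is read off the fitted
# alignment. The quality factor is implemented as the fraction of
# theoretical envelope peaks (above 1% relative probability) found within
# 10 ppm — a declared surrogate for the proprietary vendor definition.

#' Peak-picker thresholds
#'
#' @param quality_factor_threshold Minimum envelope quality factor
#'   (default 0.4).
#' @param snr_threshold Minimum local signal-to-noise ratio (default 3.0).
#' @param intensity_threshold Minimum apex intensity in counts (default 500).
#' @return An object of class `ntdms_picker_settings`.
#' @export
picker_settings <- function(quality_factor_threshold = 0.4,
                            snr_threshold = 3.0,
                            intensity_threshold = 500) {
  vals <- c(quality_factor_threshold, snr_threshold, intensity_threshold)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("picker thresholds must be finite and >= 0", call. = FALSE)
  }
  structure(list(quality_factor_threshold = quality_factor_threshold,
                 snr_threshold = snr_threshold,
                 intensity_threshold = intensity_threshold),
            class = "ntdms_picker_settings")
}

#' Infer charge from isotope-cluster spacing
#'
#' @param peak_cluster Numeric vector of at least three m/z values belonging
#'   to one isotope cluster.
#' @param max_cv Maximum coefficient of variation of adjacent spacings
#'   before the call is abandoned (default 0.2).
#' @return Integer charge, or `NA_integer_` when the spacing is too
#'   non-uniform to call.
#' @examples
#' infer_charge(4060 + (0:4) * 1.00235 / 19) # 19
#' @export
infer_charge <- function(peak_cluster, max_cv = 0.2) {
  if (length(peak_cluster) < 3L) {
    stop("charge inference needs at least 3 peaks", call. = FALSE)
  }
  sp <- diff(sort(peak_cluster))
  med <- stats::median(sp)
  if (med <= 0) return(NA_integer_)
  cv <- stats::sd(sp) / mean(sp)
  if (is.finite(cv) && cv > max_cv) return(NA_integer_)
  as.integer(round(ntdms_constants$isotope_spacing / med))
}

# Cached averagine envelope lookup, quantized to `step` Da so nearby masses
# share one envelope shape.
.envelope_cache <- new.env(parent = emptyenv())
cached_averagine <- function(mass, step = 50) {
  key <- as.character(round(mass / step))
  env <- get0(key, envir = .envelope_cache)
  if (is.null(env)) {
    env <- isotope_envelope(round(mass / step) * step, truncation = 0.9999,
                            model = "averagine")
    assign(key, env, envir = .envelope_cache)
  }
  env
}

# Walk outward from a seed peak collecting cluster members at spacing d,
# tolerating `max_gap` consecutive missing isotopologues. `mz` must be
# ascending; candidate windows are tracked with an incremental pointer.
collect_cluster <- function(mz, usable, seed_idx, d, tol, max_gap = 1L) {
  members <- seed_idx
  n <- length(mz)
  for (dir in c(1, -1)) {
    gaps <- 0L
    kstep <- 0L
    p <- seed_idx
    repeat {
      # expected positions stay anchored on the seed's isotope grid: a
      # wrong-charge walk then accumulates spacing error and breaks off
      # instead of drifting along a true cluster peak by peak
      kstep <- kstep + 1L
      expect <- mz[seed_idx] + dir * kstep * d
      if (dir == 1) {
        while (p <= n && mz[p] < expect - tol) p <- p + 1L
        if (p > n) break
        q <- p
        while (q <= n && mz[q] <= expect + tol) q <- q + 1L
        hit <- if (q > p) (p:(q - 1L)) else integer()
      } else {
        while (p >= 1L && mz[p] > expect + tol) p <- p - 1L
        if (p < 1L) break
        q <- p
        while (q >= 1L && mz[q] >= expect - tol) q <- q - 1L
        hit <- if (p > q) ((q + 1L):p) else integer()
      }
      hit <- hit[usable[hit]]
      if (length(hit)) {
        hit <- hit[which.min(abs(mz[hit] - expect))]
        members <- c(members, hit)
        gaps <- 0L
      } else {
        gaps <- gaps + 1L
        if (gaps > max_gap) break
      }
    }
  }
  sort(unique(members))
}

# Score one (cluster, z, candidate mono mass) alignment. Returns the
# normalized dot product between observed intensities and theoretical
# probabilities over the union of theoretical peaks and cluster peaks, plus
# the quality factor and per-peak matches.
score_alignment <- function(mono_mass, z, cluster_mz, cluster_int, envelope,
                            match_ppm = 10) {
  theo_mz <- (mono_mass + envelope$offsets) / z + ntdms_constants$proton
  # never let the ppm window exceed a quarter isotope spacing, or high-m/z
  # matching degenerates into matching anything to anything
  tol <- pmin(theo_mz * match_ppm * 1e-6,
              0.25 * ntdms_constants$isotope_spacing / z)
  match_idx <- vapply(seq_along(theo_mz), function(j) {
    hit <- which(abs(cluster_mz - theo_mz[j]) <= tol[j])
    if (length(hit)) hit[which.min(abs(cluster_mz[hit] - theo_mz[j]))]
    else NA_integer_
  }, integer(1))
  obs <- ifelse(is.na(match_idx), 0, cluster_int[match_idx])
  theo <- envelope$probabilities
  denom <- sqrt(sum(obs^2) * sum(theo^2))
  score <- if (denom > 0) sum(obs * theo) / denom else 0
  big <- theo >= 0.01 * max(theo)
  quality <- mean(!is.na(match_idx[big]))
  list(score = score, quality = quality, match_idx = match_idx)
}

#' Deconvolve an isotopically resolved spectrum
#'
#' Finds isotope clusters, infers charge from their spacing, aligns a
#' theoretical envelope (averagine by default) to each cluster over a small
#' window of candidate monoisotopic offsets, and reports one species per
#' cluster. Off-by-one-isotope ambiguity (two candidate monoisotopic masses
#' scoring within 0.1% relative fit) is resolved deterministically toward
#' the lower mass and flagged. The tie window is deliberately narrow: for
#' smooth high-mass envelopes the fit difference between adjacent-isotope
#' alignments is itself well under 1%, so a wider window would override a
#' clear winner.
#'
#' @param s An `ntdms_spectrum` (profile spectra are centroided first).
#' @param settings A [picker_settings()].
#' @param z_range Integer charges to consider (default 1:30).
#' @param match_ppm Peak-to-envelope matching tolerance in ppm (default 10).
#' @param min_fit_score Minimum envelope fit score for a species to be
#'   reported (default 0.7; spurious charge-misassigned leftovers score far
#'   below well-fit envelopes).
#' @param max_species Stop after this many species (default 50).
#' @return Data frame of class `ntdms_species` with columns
#'   `monoisotopic_mass`, `charge`, `abundance` (summed matched cluster
#'   intensity), `fit_score` (normalized dot product in `[0, 1]`), `snr`,
#'   `quality` and `off_by_one_flag`, sorted by abundance (descending).
#'   Empty spectra yield an empty frame.
#' @export
deconvolve <- function(s, settings = picker_settings(), z_range = 1:30,
                       match_ppm = 10, min_fit_score = 0.7,
                       max_species = 50L) {
  stopifnot(inherits(s, "ntdms_spectrum"),
            inherits(settings, "ntdms_picker_settings"))
  empty <- data.frame(monoisotopic_mass = numeric(), charge = integer(),
                      abundance = numeric(), fit_score = numeric(),
                      snr = numeric(), quality = numeric(),
                      off_by_one_flag = logical())
  class(empty) <- c("ntdms_species", class(empty))
  if (!length(s$mz) || all(s$intensity == 0)) return(empty)
  cent <- centroid_spectrum(s)
  if (!length(cent$mz)) return(empty)
  # prune centroids below the global noise floor; peaks that far down carry
  # no envelope information and only slow down cluster walking
  noise_global <- stats::mad(s$intensity, constant = 1.4826)
  if (is.finite(noise_global) && noise_global > 0) {
    keep <- cent$intensity > 3 * noise_global
    cent <- mass_spectrum(cent$mz[keep], cent$intensity[keep], s$metadata,
                     centroided = TRUE)
    if (!length(cent$mz)) return(empty)
  }
  usable <- rep(TRUE, length(cent$mz))
  seeds <- order(cent$intensity, decreasing = TRUE)
  seeds <- seeds[cent$intensity[seeds] >= settings$intensity_threshold]
  snr <- rep(NA_real_, length(cent$mz))
  snr[seeds] <- local_snr(s, cent$mz[seeds], cent$intensity[seeds])
  seeds <- seeds[snr[seeds] >= settings$snr_threshold]
  out <- list()
  for (seed in seeds) {
    if (!usable[seed]) next
    best <- NULL
    for (z in sort(z_range, decreasing = TRUE)) {
      d <- ntdms_constants$isotope_spacing / z
      tol <- min(0.3 * d, max(2e-4, cent$mz[seed] * match_ppm * 1e-6))
      members <- collect_cluster(cent$mz, usable, seed, d, tol)
      if (length(members) < 3L) next
      cl_mz <- cent$mz[members]
      cl_int <- cent$intensity[members]
      apex <- which.max(cl_int)
      approx_mass <- mass_of(cl_mz[apex], z)
      if (approx_mass <= 0) next
      env <- cached_averagine(approx_mass)
      k_star <- env$offsets[which.max(env$probabilities)]
      base_mono <- approx_mass - k_star
      for (shift in -2:2) {
        mono <- base_mono + shift * ntdms_constants$isotope_spacing
        if (mono <= 0) next
        sc <- score_alignment(mono, z, cl_mz, cl_int, env, match_ppm)
        cand <- list(z = z, members = members, mono = mono, sc = sc,
                     apex_int = cl_int[apex])
        if (is.null(best)) { best <- cand; next }
        rel <- (sc$score - best$sc$score) / max(best$sc$score,
                                                .Machine$double.eps)
        if (rel > 0.001) {
          best <- cand
        } else if (abs(rel) <= 0.001 && cand$mono < best$mono) {
          cand$off_by_one <- TRUE
          best <- cand
        }
      }
    }
    if (is.null(best) || best$sc$score < min_fit_score) next
    if (best$sc$quality < settings$quality_factor_threshold) next
    # refine the monoisotopic mass as the intensity-weighted mean over
    # matched isotopologue peaks
    cl_mz <- cent$mz[best$members]
    cl_int <- cent$intensity[best$members]
    env <- cached_averagine(mass_of(cl_mz[which.max(cl_int)], best$z))
    mi <- best$sc$match_idx
    ok <- !is.na(mi)
    if (!any(ok)) next
    mono_i <- mass_of(cl_mz[mi[ok]], best$z) - env$offsets[ok]
    w <- cl_int[mi[ok]]
    mono <- sum(w * mono_i) / sum(w)
    matched_members <- best$members[unique(mi[ok])]
    usable[matched_members] <- FALSE
    out[[length(out) + 1L]] <- data.frame(
      monoisotopic_mass = mono, charge = best$z,
      abundance = sum(cl_int[unique(mi[ok])]),
      fit_score = best$sc$score, snr = snr[seed],
      quality = best$sc$quality,
      off_by_one_flag = isTRUE(best$off_by_one))
    if (length(out) >= max_species) break
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$abundance, decreasing = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ntdms_species", class(res))
  res
}

#' Quantify deconvolved species by composition group
#'
#' @param species An `ntdms_species` data frame (or anything with an
#'   `abundance` column).
#' @param group_by Character vector of composition labels, one per species
#'   row (species sharing a label are pooled).
#' @return Data frame with columns `label`, `abundance`, `proportion`;
#'   proportions sum to 1.
#' @examples
#' quantify(data.frame(abundance = c(2, 2, 5, 1)),
#'          group_by = c("0Ca", "1Ca", "2Ca", "3Ca"))
#' @export
quantify <- function(species, group_by) {
  if (!nrow(species)) stop("no species to quantify", call. = FALSE)
  stopifnot(length(group_by) == nrow(species))
  ab <- tapply(species$abundance, group_by, sum)
  total <- sum(ab)
  if (total <= 0) stop("total abundance is zero", call. = FALSE)
  data.frame(label = names(ab), abundance = as.numeric(ab),
             proportion = as.numeric(ab) / total, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Export a deconvolution report
#'
#' @param species An `ntdms_species` data frame.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_species_report <- function(species, path) {
  utils::write.csv(species, path, row.names = FALSE)
  invisible(path)
}
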