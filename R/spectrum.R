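# Spectrum container, readers/writers, centroiding, and local noise
# estimation.

#' Construct a mass spectrum
#'
#' @param mz Strictly ascending numeric vector of m/z values.
#' @param intensity Non-negative numeric vector of equal length.
#' @param metadata Free-form list of acquisition descriptors.
#' @param centroided Logical; `TRUE` when peaks are already centroided.
#' @return An object of class `ntdms_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, metadata = list(),
                          centroided = FALSE) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    stop("mz must be strictly ascending", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(mz = mz, intensity = intensity, metadata = metadata,
                 centroided = isTRUE(centroided)),
            class = "ntdms_spectrum")
}

#' @export
print.ntdms_spectrum <- function(x, ...) {
  cat("<ntdms_spectrum> ", length(x$mz), " points, m/z ",
      if (length(x$mz)) paste0(round(min(x$mz), 2), "-", round(max(x$mz), 2))
      else "-", if (x$centroided) " (centroid)" else " (profile)", "\n",
      sep = "")
  invisible(x)
}

#' Read a spectrum from disk
#'
#' Accepts two-column whitespace- or comma-separated text (m/z, intensity;
#' `#`-prefixed comment lines ignored) or mzML (through the `mzR` package
#' when available).
#'
#' @param path Input file.
#' @param scan For mzML input, the 1-based scan number (default 1).
#' @param centroided Whether the peak list is centroided.
#' @return An `ntdms_spectrum`.
#' @export
read_spectrum <- function(path, scan = 1L, centroided = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mzml", "mzxml")) {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("reading mzML requires the mzR package", call. = FALSE)
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, scan)
    hdr <- mzR::header(h, scan)
    return(mass_spectrum(pk[, 1], pk[, 2],
                    metadata = list(source = path, scan = scan,
                                    msLevel = hdr$msLevel),
                    centroided = isTRUE(hdr$centroided)))
  }
  first <- readLines(path, n = 50L)
  sep <- if (any(grepl(",", first[!grepl("^#", first)]))) "," else ""
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           comment.char = "#")
  ord <- order(tab[[1]])
  mass_spectrum(tab[[1]][ord], tab[[2]][ord], metadata = list(source = path),
           centroided = centroided)
}

#' Write a spectrum as two-column text
#'
#' @param s An `ntdms_spectrum`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "ntdms_spectrum"))
  utils::write.table(
    data.frame(mz = sprintf("%.6f", s$mz),
               intensity = sprintf("%.4f", s$intensity)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Centroid a profile spectrum
#'
#' Local maxima above zero are refined by three-point parabolic
#' interpolation in (m/z, log-free intensity) to sub-grid peak positions.
#'
#' @param s An `ntdms_spectrum` in profile mode.
#' @return A centroided `ntdms_spectrum` of peak apexes.
#' @export
centroid_spectrum <- function(s) {
  stopifnot(inherits(s, "ntdms_spectrum"))
  if (s$centroided) return(s)
  y <- s$intensity
  n <- length(y)
  if (n < 3L) return(mass_spectrum(s$mz, y, s$metadata, centroided = TRUE))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  idx <- idx[y[idx] > 0]
  if (!length(idx)) {
    return(mass_spectrum(numeric(), numeric(), s$metadata, centroided = TRUE))
  }
  y1 <- y[idx - 1L]; y2 <- y[idx]; y3 <- y[idx + 1L]
  denom <- (y1 - 2 * y2 + y3)
  delta <- ifelse(denom == 0, 0, 0.5 * (y1 - y3) / denom)
  delta[abs(delta) > 0.5] <- 0
  # local grid spacing (profile grids may be non-uniform)
  step <- (s$mz[idx + 1L] - s$mz[idx - 1L]) / 2
  mz_apex <- s$mz[idx] + delta * step
  int_apex <- y2 - 0.25 * (y1 - y3) * delta
  ord <- order(mz_apex)
  mass_spectrum(mz_apex[ord], int_apex[ord], s$metadata, centroided = TRUE)
}

# Local signal-to-noise: peak height over the median absolute deviation of
# profile/centroid intensities within +/- `window` m/z of each query.
local_snr <- function(s, query_mz, query_intensity, window = 5) {
  vapply(seq_along(query_mz), function(i) {
    i0 <- findInterval(query_mz[i] - window, s$mz) + 1L
    i1 <- findInterval(query_mz[i] + window, s$mz)
    if (i1 < i0) return(Inf)
    block <- s$intensity[i0:i1]
    # estimate noise from the lower half of the window so that dense
    # signal regions (envelope flanks) do not masquerade as noise
    block <- block[block <= stats::median(block)]
    noise <- stats::mad(block, constant = 1.4826)
    if (!is.finite(noise) || noise <= 0) {
      # all-flat window: fall back to a floor so pure signal is not divided
      # by zero
      noise <- max(.Machine$double.eps, stats::sd(block))
    }
    if (!is.finite(noise) || noise <= 0) Inf
    else query_intensity[i] / noise
  }, numeric(1))
}
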