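# Mass matching at ppm tolerance, complex-to-subunit ejection bookkeeping,
# and proteoform-landscape summarization.
#
# Per-context tolerance defaults follow the acquisition context: 2 ppm for
# intact-species assignments, 16 ppm for monomer isolation spectra, 20 ppm
# for fragments; all overridable per run and recorded in outputs.

#' Context tolerance defaults
#'
#' @return Named numeric vector of default ppm tolerances for the
#'   `intact`, `monomer`, and `fragment` matching contexts.
#' @export
tolerance_defaults <- function() {
  c(intact = 2, monomer = 16, fragment = 20)
}

#' Match deconvolved species to candidate compositions
#'
#' Each species is matched to the candidate minimizing the absolute ppm
#' error, provided it lies within tolerance (best-match-wins: a species
#' claims at most one candidate row in the output). Ties are broken by
#' lexicographic candidate label.
#'
#' @param species An `ntdms_species` data frame (or any frame with a
#'   `monoisotopic_mass` column), or a bare numeric vector of masses.
#' @param candidates A candidates data frame from [candidates_table()] (or
#'   any frame with `label` and `mass` columns), or a list of candidate
#'   objects.
#' @param tolerance_ppm Matching tolerance (> 0), default the intact-species
#'   context (2 ppm).
#' @return List with `matches` (species columns + `candidate_label`,
#'   `candidate_mass`, `ppm_error`) and `unmatched` (species rows with no
#'   candidate in tolerance). The active tolerance is recorded as an
#'   attribute.
#' @export
match_masses <- function(species, candidates,
                         tolerance_ppm = tolerance_defaults()[["intact"]]) {
  if (tolerance_ppm <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (is.numeric(species)) {
    species <- data.frame(monoisotopic_mass = species)
  }
  if (!is.data.frame(candidates)) candidates <- candidates_table(candidates)
  ord <- order(candidates$label)
  candidates <- candidates[ord, , drop = FALSE]  # lexicographic tie-break
  n <- nrow(species)
  matches <- vector("list", n)
  unmatched <- logical(n)
  for (i in seq_len(n)) {
    m <- species$monoisotopic_mass[i]
    ppm <- (m - candidates$mass) / candidates$mass * 1e6
    j <- which.min(abs(ppm))
    if (length(j) && abs(ppm[j]) <= tolerance_ppm) {
      row <- species[i, , drop = FALSE]
      row$candidate_label <- candidates$label[j]
      row$candidate_mass <- candidates$mass[j]
      row$ppm_error <- ppm[j]
      matches[[i]] <- row
    } else {
      unmatched[i] <- TRUE
    }
  }
  matches <- do.call(rbind, matches[!vapply(matches, is.null, logical(1))])
  if (is.null(matches)) {
    matches <- cbind(species[0, , drop = FALSE],
                     data.frame(candidate_label = character(),
                                candidate_mass = numeric(),
                                ppm_error = numeric()))
  }
  rownames(matches) <- NULL
  out <- list(matches = matches,
              unmatched = species[unmatched, , drop = FALSE])
  attr(out, "tolerance_ppm") <- tolerance_ppm
  out
}

#' Report the candidate nearest a mass, regardless of tolerance
#'
#' For printed masses whose composition is not itemized: reports the best
#' candidate and its signed ppm error without forcing agreement.
#'
#' @param mass Observed mass in Da.
#' @param candidates Candidates data frame or list.
#' @return One-row data frame `label`, `mass`, `ppm_error`.
#' @export
nearest_composition <- function(mass, candidates) {
  if (!is.data.frame(candidates)) candidates <- candidates_table(candidates)
  ppm <- (mass - candidates$mass) / candidates$mass * 1e6
  j <- which.min(abs(ppm))
  data.frame(label = candidates$label[j], mass = candidates$mass[j],
             ppm_error = ppm[j], row.names = NULL)
}

#' Complex-to-subunit ejection bookkeeping
#'
#' Verifies mass conservation across a subunit-ejection (complex-up)
#' experiment: the parent mass must equal the sum of product masses.
#'
#' @param parent_mass Parent complex mass in Da (> 0).
#' @param product_masses Numeric vector of ejected-product masses (>= 1
#'   product, all > 0).
#' @param tolerance_ppm Consistency tolerance in ppm of the parent
#'   (default 2).
#' @return List of class `ntdms_ejection`: `parent_mass`, `product_masses`,
#'   `residual` (Da, parent minus product sum, computed exactly),
#'   `residual_ppm`, `consistent`.
#' @examples
#' check_ejection(77136, c(42556, 34580))$residual # 0
#' @export
check_ejection <- function(parent_mass, product_masses,
                           tolerance_ppm = tolerance_defaults()[["intact"]]) {
  if (!length(product_masses)) stop("need at least one product",
                                    call. = FALSE)
  if (parent_mass <= 0 || any(product_masses <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  residual <- parent_mass - sum(product_masses)
  residual_ppm <- residual / parent_mass * 1e6
  structure(list(parent_mass = parent_mass,
                 product_masses = product_masses,
                 residual = residual, residual_ppm = residual_ppm,
                 consistent = abs(residual_ppm) <= tolerance_ppm,
                 tolerance_ppm = tolerance_ppm),
            class = "ntdms_ejection")
}

#' @export
print.ntdms_ejection <- function(x, ...) {
  cat("<ntdms_ejection> parent ", x$parent_mass, " Da vs ",
      length(x$product_masses), " products: residual ",
      signif(x$residual, 6), " Da (", signif(x$residual_ppm, 3), " ppm) — ",
      if (x$consistent) "consistent" else "inconsistent", "\n", sep = "")
  invisible(x)
}

#' Proteoform landscape across isolation levels
#'
#' Counts distinct matched species per isolation level (complex, ejected
#' dimer, ejected monomers, ...) and totals them. A species label repeated
#' within a level is counted once; the same molecular species observed at
#' two levels counts at each level, which is how a complex-up experiment
#' tallies its proteoform landscape.
#'
#' @param matches Data frame with columns `level` and `candidate_label`
#'   (e.g. row-bound [match_masses()] outputs tagged with their level), or
#'   a named list of character label vectors.
#' @return List with `per_level` (data frame `level`, `n_distinct`) and
#'   `total`.
#' @export
proteoform_landscape <- function(matches) {
  if (is.list(matches) && !is.data.frame(matches)) {
    matches <- do.call(rbind, lapply(names(matches), function(lv)
      data.frame(level = lv, candidate_label = unlist(matches[[lv]]),
                 stringsAsFactors = FALSE)))
  }
  if (is.null(matches) || !nrow(matches)) {
    return(list(per_level = data.frame(level = character(),
                                       n_distinct = integer()),
                total = 0L))
  }
  stopifnot(all(c("level", "candidate_label") %in% names(matches)))
  per <- stats::aggregate(candidate_label ~ level, data = matches,
                          FUN = function(x) length(unique(x)))
  names(per)[2] <- "n_distinct"
  per <- per[order(match(per$level, unique(matches$level))), , drop = FALSE]
  rownames(per) <- NULL
  list(per_level = per, total = sum(per$n_distinct))
}

#' Write match and landscape reports
#'
#' @param x A [match_masses()] result, `ntdms_ejection`, or
#'   [proteoform_landscape()] result.
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_match_report <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  } else {
    tab <- if (!is.null(x$matches)) x$matches
           else if (!is.null(x$per_level)) x$per_level
           else as.data.frame(unclass(x))
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
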