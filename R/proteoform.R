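# Proteoform model: sequences, modifications, metal adducts, truncations,
# non-covalent assemblies, and grammar-driven enumeration of candidate
# compositions.

#' Construct a protein sequence
#'
#' A validated container for a protein chain. Positions everywhere in the
#' package use full UniProt numbering (including Met1): `numbering_origin`
#' records the UniProt position of the first listed residue so that
#' N-terminally processed constructs keep their canonical coordinates.
#'
#' @param identifier Character scalar naming the chain (e.g. an accession).
#' @param residues Character scalar (one-letter codes) or character vector of
#'   single residues.
#' @param numbering_origin UniProt position of the first residue (default 1).
#' @return An object of class `ntdms_sequence` with fields `identifier`,
#'   `residues` (character vector) and `numbering_origin`.
#' @examples
#' protein_sequence("toy", "DFDE")
#' @export
protein_sequence <- function(identifier, residues, numbering_origin = 1L) {
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  if (length(residues) == 0L) stop("sequence must be non-empty", call. = FALSE)
  bad <- which(!residues %in% rownames(.residue_formula))
  if (length(bad)) {
    stop("unknown residue code '", residues[bad[1]], "' at position ",
         bad[1] + numbering_origin - 1L, " of '", identifier, "'",
         call. = FALSE)
  }
  numbering_origin <- as.integer(numbering_origin)
  if (is.na(numbering_origin) || numbering_origin < 1L) {
    stop("numbering_origin must be a positive integer", call. = FALSE)
  }
  structure(
    list(identifier = as.character(identifier), residues = residues,
         numbering_origin = numbering_origin),
    class = "ntdms_sequence"
  )
}

#' @export
print.ntdms_sequence <- function(x, ...) {
  cat("<ntdms_sequence> ", x$identifier, ": ", length(x$residues),
      " residues (numbering from ", x$numbering_origin, ")\n", sep = "")
  invisible(x)
}

#' @export
length.ntdms_sequence <- function(x) length(x$residues)

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning a list of
#' [protein_sequence()] objects (falls back to a plain-text parse when
#' Biostrings is unavailable).
#'
#' @param path Path to a FASTA file.
#' @return Named list of `ntdms_sequence` objects.
#' @export
read_fasta_sequences <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    seqs <- as.character(aa)
    ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop("no FASTA headers in ", path, call. = FALSE)
    grp <- cumsum(hdr)
    ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                   collapse = "")
  }
  out <- Map(protein_sequence, ids, seqs)
  names(out) <- ids
  out
}

#' The vendored human cardiac troponin C chain
#'
#' Human slow skeletal/cardiac troponin C (TNNC1, UniProt P63316; 161
#' residues), the Ca2+-sensing EF-hand subunit of the cardiac troponin
#' complex. Shipped as a plain-text FASTA fixture under `extdata`.
#'
#' @return An `ntdms_sequence` of 161 residues in full UniProt numbering.
#' @examples
#' tnc <- tnc_sequence()
#' paste(tnc$residues[73:76], collapse = "") # "DFDE", regulatory domain II
#' @export
tnc_sequence <- function() {
  path <- system.file("extdata", "P63316_TNNC1_human.fasta",
                      package = "ntdms", mustWork = TRUE)
  read_fasta_sequences(path)[[1]]
}

#' Built-in modification registry
#'
#' The covalent modifications the package knows by name: N-terminal
#' acetylation (+42.01057 Da), phosphorylation (+79.96633 Da), and excision
#' of the initiator methionine (-131.04049 Da). Deltas are computed from the
#' package's own isotope tables; elemental formulas are carried so modified
#' proteoforms still get exact elemental isotope envelopes. Additional
#' entries can be loaded from a text table with [read_modification_registry()].
#'
#' @return A data frame with columns `name`, `mono_delta`, `avg_delta`,
#'   `site_rule`, and a `formula` list-column (NULL when only a delta is
#'   known).
#' @export
modification_registry <- function() {
  reg <- data.frame(
    name = c("acetyl", "phospho", "met_excision"),
    site_rule = c("N-terminus", "any S/T/Y", "N-terminus"),
    stringsAsFactors = FALSE
  )
  forms <- list(
    acetyl = c(C = 2, H = 2, O = 1),
    phospho = c(H = 1, P = 1, O = 3),
    met_excision = -(chain_formula("M") - .water_formula)
  )
  reg$mono_delta <- vapply(forms, formula_mass, numeric(1),
                           scale = "monoisotopic")
  reg$avg_delta <- vapply(forms, formula_mass, numeric(1), scale = "average")
  reg$formula <- unname(forms)
  reg
}

#' Load additional modifications from a text table
#'
#' @param path Path to a tab- or comma-separated table with columns
#'   `name`, `mono_delta`, and `site_rule` (optional `avg_delta`, defaulting
#'   to `mono_delta`).
#' @return A registry data frame in the same shape as
#'   [modification_registry()], appended to the built-ins.
#' @export
read_modification_registry <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "mono_delta", "site_rule") %in% names(tab)))
  if (is.null(tab$avg_delta)) tab$avg_delta <- tab$mono_delta
  if (any(!is.finite(tab$mono_delta))) {
    stop("non-finite modification delta in ", path, call. = FALSE)
  }
  tab$formula <- rep(list(NULL), nrow(tab))
  rbind(modification_registry(),
        tab[, c("name", "site_rule", "mono_delta", "avg_delta", "formula")])
}

#' Describe a metal adduct set
#'
#' Non-covalently bound metal ions carried by a proteoform. Two mass
#' conventions are supported for a divalent metal observed on a neutral
#' species: `"charge-displacement"` (the bound M2+ displaces two protons;
#' per-adduct delta = metal mass - 2 x 1.007276 Da, the native-ESI default
#' for a folded acidic protein) and `"neutral-addition"` (the full neutral
#' atom mass is added). Only calcium is currently registered.
#'
#' @param count Non-negative integer number of bound metals.
#' @param element Metal element symbol (default `"Ca"`).
#' @param mode `"charge-displacement"` or `"neutral-addition"`.
#' @param max_count Cap on `count` (default 3, the number of occupiable
#'   EF-hand sites in cardiac TnC).
#' @return An object of class `ntdms_adduct`.
#' @examples
#' metal_adduct(3)$delta_per_adduct           # 37.94804 Da
#' metal_adduct(3, mode = "neutral-addition") # 39.96259 Da per Ca
#' @export
metal_adduct <- function(count = 0L, element = "Ca",
                         mode = c("charge-displacement", "neutral-addition"),
                         max_count = 3L) {
  mode <- match.arg(mode)
  count <- as.integer(count)
  if (is.na(count) || count < 0L) {
    stop("adduct count must be a non-negative integer", call. = FALSE)
  }
  if (count > max_count) {
    stop("adduct count ", count, " exceeds maximum ", max_count, call. = FALSE)
  }
  if (!element %in% names(.isotopes)) {
    stop("unknown element symbol: ", element, call. = FALSE)
  }
  delta <- adduct_delta(element, mode)
  structure(
    list(element = element, count = count, mode = mode,
         delta_per_adduct = delta, max_count = as.integer(max_count)),
    class = "ntdms_adduct"
  )
}

adduct_delta <- function(element = "Ca",
                         mode = c("charge-displacement", "neutral-addition"),
                         scale = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  m <- if (scale == "monoisotopic") .element_mono[[element]]
       else .element_avg[[element]]
  if (mode == "charge-displacement") m - 2 * ntdms_constants$proton else m
}

#' Construct a proteoform
#'
#' One neutral molecular species: a chain plus a set of localized covalent
#' modifications, a metal-adduct set, and an optional terminal truncation.
#' Modification positions and truncation bounds use full UniProt numbering.
#'
#' @param sequence An [protein_sequence()] object.
#' @param modifications Data frame with columns `name` and `position`
#'   (UniProt numbering; `NA` position allowed for composition-only
#'   bookkeeping, treated as located at the N-terminus for fragment spans),
#'   or `NULL`.
#' @param adducts An [metal_adduct()] object (default: none).
#' @param truncation `NULL` or an integer range `c(start, end)` of residues
#'   removed; only terminal truncations (touching either end of the chain)
#'   are supported.
#' @param label Optional human-readable composition label.
#' @param registry Modification registry (default [modification_registry()]).
#' @return An object of class `ntdms_proteoform`.
#' @examples
#' p <- proteoform(protein_sequence("toy", "DFDE"), adducts = metal_adduct(1))
#' neutral_mass(p)
#' @export
proteoform <- function(sequence, modifications = NULL,
                       adducts = metal_adduct(0L), truncation = NULL,
                       label = NULL, registry = modification_registry()) {
  stopifnot(inherits(sequence, "ntdms_sequence"),
            inherits(adducts, "ntdms_adduct"))
  org <- sequence$numbering_origin
  last <- org + length(sequence$residues) - 1L
  if (!is.null(truncation)) {
    truncation <- as.integer(range(truncation))
    if (truncation[1] > org && truncation[2] < last) {
      stop("only terminal truncations are supported", call. = FALSE)
    }
    if (truncation[1] < org || truncation[2] > last) {
      stop("truncation range outside the chain", call. = FALSE)
    }
  }
  kept <- retained_positions(sequence, truncation)
  if (!is.null(modifications) && nrow(modifications)) {
    stopifnot(all(c("name", "position") %in% names(modifications)))
    unknown <- setdiff(modifications$name, registry$name)
    if (length(unknown)) {
      stop("modification(s) not in registry: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    pos <- modifications$position
    off <- which(!is.na(pos) & !pos %in% kept)
    if (length(off)) {
      stop("modification position ", pos[off[1]],
           " outside the (possibly truncated) chain", call. = FALSE)
    }
    if (anyDuplicated(modifications[, c("name", "position")])) {
      stop("duplicate modification at the same position", call. = FALSE)
    }
  } else {
    modifications <- data.frame(name = character(), position = integer())
  }
  if (is.null(label)) label <- default_label(sequence, modifications, adducts,
                                             truncation)
  structure(
    list(sequence = sequence, modifications = modifications,
         adducts = adducts, truncation = truncation, label = label,
         registry = registry),
    class = "ntdms_proteoform"
  )
}

# UniProt positions retained after truncation.
retained_positions <- function(sequence, truncation) {
  org <- sequence$numbering_origin
  pos <- seq(org, org + length(sequence$residues) - 1L)
  if (is.null(truncation)) pos else setdiff(pos, seq(truncation[1],
                                                     truncation[2]))
}

default_label <- function(sequence, modifications, adducts, truncation) {
  parts <- sequence$identifier
  if (nrow(modifications)) {
    tab <- table(modifications$name)
    parts <- c(parts, paste0(names(tab), ifelse(tab > 1, paste0("x", tab), "")))
  }
  if (adducts$count > 0) {
    parts <- c(parts, paste0(adducts$count, adducts$element))
  }
  if (!is.null(truncation)) {
    parts <- c(parts, paste0("trunc", truncation[1], "-", truncation[2]))
  }
  paste(parts, collapse = "+")
}

#' @export
print.ntdms_proteoform <- function(x, ...) {
  cat("<ntdms_proteoform> ", x$label, " (", x$adducts$mode, ")\n", sep = "")
  cat("  monoisotopic mass:", format(neutral_mass(x), nsmall = 5), "Da\n")
  invisible(x)
}

#' Neutral mass of a proteoform
#'
#' Sum of residue masses over the retained chain, one water, all covalent
#' modification deltas, and `count` times the per-adduct metal delta under
#' the proteoform's adduct mode.
#'
#' @param x An `ntdms_proteoform` (or `ntdms_assembly`, via
#'   [assembly_mass()]; or a `fixed_mass_subunit`).
#' @param scale `"monoisotopic"` (default; deconvolution reports
#'   monoisotopic masses) or `"average"`.
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(x, scale = c("monoisotopic", "average")) {
  UseMethod("neutral_mass")
}

#' @export
neutral_mass.ntdms_proteoform <- function(x,
                                          scale = c("monoisotopic",
                                                    "average")) {
  scale <- match.arg(scale)
  rm <- residue_masses(scale)
  kept <- retained_positions(x$sequence, x$truncation)
  idx <- kept - x$sequence$numbering_origin + 1L
  mass <- sum(rm[x$sequence$residues[idx]]) + water_mass(scale)
  if (nrow(x$modifications)) {
    reg <- x$registry
    col <- if (scale == "monoisotopic") "mono_delta" else "avg_delta"
    mass <- mass + sum(reg[[col]][match(x$modifications$name, reg$name)])
  }
  mass + x$adducts$count * adduct_delta(x$adducts$element, x$adducts$mode,
                                        scale)
}

#' @export
neutral_mass.fixed_mass_subunit <- function(x, scale = c("monoisotopic",
                                                         "average")) {
  x$mass
}

#' A subunit known only by its measured mass
#'
#' For assembly bookkeeping when a subunit's sequence is not in hand but its
#' deconvolved mass is (e.g. printed subunit MWs used as inputs).
#'
#' @param label Subunit label.
#' @param mass Neutral mass in Da.
#' @return An object of classes `fixed_mass_subunit`.
#' @export
fixed_mass_subunit <- function(label, mass) {
  stopifnot(is.finite(mass), mass > 0)
  structure(list(label = label, mass = mass), class = "fixed_mass_subunit")
}

#' Construct a non-covalent assembly
#'
#' A multimer of proteoforms (or fixed-mass subunits). Assemblies are
#' non-covalent: the neutral mass is exactly the sum of subunit neutral
#' masses, with no condensation loss.
#'
#' @param subunits List of `ntdms_proteoform` / `fixed_mass_subunit` objects.
#' @param label Assembly label.
#' @return An object of class `ntdms_assembly`.
#' @export
assembly_species <- function(subunits, label = NULL) {
  if (!length(subunits)) stop("assembly needs at least one subunit",
                              call. = FALSE)
  ok <- vapply(subunits, function(s)
    inherits(s, "ntdms_proteoform") || inherits(s, "fixed_mass_subunit"),
    logical(1))
  if (!all(ok)) stop("subunits must be proteoforms or fixed-mass subunits",
                     call. = FALSE)
  if (is.null(label)) {
    label <- paste(vapply(subunits, function(s) s$label, character(1)),
                   collapse = "/")
  }
  structure(list(subunits = subunits, label = label),
            class = "ntdms_assembly")
}

#' Neutral mass of an assembly
#'
#' @param a An `ntdms_assembly`.
#' @param scale Mass scale, as in [neutral_mass()].
#' @return Sum of subunit neutral masses in Da; invariant under subunit
#'   reordering.
#' @examples
#' dimer <- assembly_species(list(fixed_mass_subunit("cTn(I-C)", 42556),
#'                                fixed_mass_subunit("cTnT", 34580)))
#' assembly_mass(dimer) # 77136
#' @export
assembly_mass <- function(a, scale = c("monoisotopic", "average")) {
  stopifnot(inherits(a, "ntdms_assembly"))
  scale <- match.arg(scale)
  sum(vapply(a$subunits, neutral_mass, numeric(1), scale = scale))
}

#' @export
neutral_mass.ntdms_assembly <- function(x, scale = c("monoisotopic",
                                                     "average")) {
  assembly_mass(x, scale)
}

#' m/z of a protonated ion
#'
#' @param mass Neutral mass in Da.
#' @param z Positive integer charge.
#' @return `(mass + z * 1.007276) / z`.
#' @examples
#' mz_of(77136, 19) # 4060.80, inside the 4050-4080 window of the 19+ complex
#' @export
mz_of <- function(mass, z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L)) stop("charge must be >= 1", call. = FALSE)
  (mass + z * ntdms_constants$proton) / z
}

#' Neutral mass from an observed m/z
#'
#' @param mz Observed m/z.
#' @param z Positive integer charge.
#' @return `mz * z - z * 1.007276`.
#' @export
mass_of <- function(mz, z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L)) stop("charge must be >= 1", call. = FALSE)
  mz * z - z * ntdms_constants$proton
}
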