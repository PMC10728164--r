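# Composition grammars: per-subunit allowed ranges of phosphorylation count,
# Ca occupancy, and optional acetylation / Met1-excision / terminal
# truncation flags, enumerated into concrete candidate species.

#' Describe the allowed compositions of one subunit
#'
#' @param name Subunit name used in labels.
#' @param sequence An [protein_sequence()] for exact-mass enumeration, or
#'   `NULL` when only `base_mass` is known.
#' @param base_mass Neutral mass (Da) of the unmodified, adduct-free subunit;
#'   required when `sequence` is `NULL`.
#' @param phospho Integer vector of allowed phosphorylation counts.
#' @param ca Integer vector of allowed bound-Ca counts.
#' @param ca_mode Adduct mass convention, see [metal_adduct()].
#' @param acetyl Logical vector of allowed N-terminal acetylation states.
#' @param met_excision Logical vector of allowed Met1-excision states
#'   (mass-only; reported positions keep full UniProt numbering).
#' @param truncations List of allowed truncations: `NULL` entries mean the
#'   intact chain, otherwise `c(start, end)` terminal ranges (requires
#'   `sequence`) or, for `base_mass` subunits, a named numeric mass delta.
#' @param variants Optional named list of explicit composition variants; when
#'   given it replaces the Cartesian axes (the subunit's range cardinality is
#'   then `length(variants)`). Each entry is a list with any of the fields
#'   `phospho`, `ca`, `acetyl`, `met_excision`, `truncation`. Use this for
#'   itemized composition lists that are not a full Cartesian product.
#' @return An object of class `ntdms_subunit_grammar`.
#' @export
subunit_grammar <- function(name, sequence = NULL, base_mass = NULL,
                            phospho = 0L, ca = 0L,
                            ca_mode = c("charge-displacement",
                                        "neutral-addition"),
                            acetyl = FALSE, met_excision = FALSE,
                            truncations = list(NULL), variants = NULL) {
  ca_mode <- match.arg(ca_mode)
  if (is.null(sequence) && is.null(base_mass)) {
    stop("either sequence or base_mass is required", call. = FALSE)
  }
  ranges <- list(phospho = sort(unique(as.integer(phospho))),
                 ca = sort(unique(as.integer(ca))),
                 acetyl = sort(unique(as.logical(acetyl))),
                 met_excision = sort(unique(as.logical(met_excision))))
  if (any(vapply(ranges, length, integer(1)) == 0L) || !length(truncations)) {
    stop("every grammar range must be non-empty", call. = FALSE)
  }
  if (!is.null(variants) && !length(variants)) {
    stop("variants, when given, must be non-empty", call. = FALSE)
  }
  structure(c(list(name = name, sequence = sequence, base_mass = base_mass,
                   ca_mode = ca_mode, truncations = truncations,
                   variants = variants), ranges),
            class = "ntdms_subunit_grammar")
}

#' Combine subunit grammars into a composition grammar
#'
#' @param ... One or more [subunit_grammar()] objects (one subunit yields
#'   proteoform candidates, several yield assembly candidates).
#' @param cap Maximum enumeration size (default `1e5`); exceeding it is an
#'   error reporting the would-be size.
#' @return An object of class `ntdms_grammar`.
#' @export
composition_grammar <- function(..., cap = 1e5) {
  subunits <- list(...)
  if (length(subunits) == 1L && is.list(subunits[[1]]) &&
      !inherits(subunits[[1]], "ntdms_subunit_grammar")) {
    subunits <- subunits[[1]]
  }
  ok <- vapply(subunits, inherits, logical(1), "ntdms_subunit_grammar")
  if (!length(subunits) || !all(ok)) {
    stop("composition_grammar() takes subunit_grammar objects", call. = FALSE)
  }
  structure(list(subunits = subunits, cap = cap), class = "ntdms_grammar")
}

#' Grammar cardinality
#'
#' @param g An `ntdms_grammar`.
#' @return Product over subunits of the per-subunit range cardinalities.
#' @export
grammar_size <- function(g) {
  stopifnot(inherits(g, "ntdms_grammar"))
  prod(vapply(g$subunits, function(s) {
    if (!is.null(s$variants)) return(length(s$variants))
    length(s$phospho) * length(s$ca) * length(s$acetyl) *
      length(s$met_excision) * length(s$truncations)
  }, numeric(1)))
}

# All variants of one subunit, in lexicographic (phospho, ca, acetyl,
# met_excision, truncation) order.
subunit_variants <- function(s) {
  if (!is.null(s$variants)) {
    return(lapply(seq_along(s$variants), function(i) {
      v <- s$variants[[i]]
      make_variant(s,
                   n_phospho = v$phospho %||% 0L, n_ca = v$ca %||% 0L,
                   acetyl = isTRUE(v$acetyl), met = isTRUE(v$met_excision),
                   trunc = v$truncation,
                   label_tag = names(s$variants)[i])
    }))
  }
  grid <- expand.grid(trunc = seq_along(s$truncations),
                      met = s$met_excision, ace = s$acetyl,
                      ca = s$ca, phospho = s$phospho,
                      KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first column fastest; we want phospho slowest-to-
  # fastest ordering (phospho, ca, flags, truncation), so sort explicitly.
  grid <- grid[order(grid$phospho, grid$ca, grid$ace, grid$met, grid$trunc), ,
               drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    make_variant(s, row$phospho, row$ca, row$ace, row$met,
                 s$truncations[[row$trunc]])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_variant <- function(s, n_phospho, n_ca, acetyl, met, trunc,
                         label_tag = NULL) {
  tags <- c(
    if (n_phospho > 0) paste0(n_phospho, "p"),
    if (acetyl) "ac",
    if (met) "dMet1",
    if (!is.null(trunc)) {
      if (is.numeric(trunc) && length(trunc) == 2)
        paste0("trunc", trunc[1], "-", trunc[2]) else names(trunc)
    },
    if (n_ca > 0) paste0(n_ca, "Ca")
  )
  label <- if (!is.null(label_tag) && nzchar(label_tag)) {
    paste(s$name, label_tag, sep = "+")
  } else {
    paste(c(s$name, tags), collapse = "+")
  }
  if (!is.null(s$sequence)) {
    mods <- data.frame(name = character(), position = integer())
    if (n_phospho > 0) {
      mods <- rbind(mods, data.frame(name = rep("phospho", n_phospho),
                                     position = NA_integer_))
    }
    if (acetyl) mods <- rbind(mods, data.frame(name = "acetyl",
                                               position = NA_integer_))
    if (met) mods <- rbind(mods, data.frame(name = "met_excision",
                                            position = NA_integer_))
    trunc_range <- if (is.numeric(trunc)) trunc else NULL
    proteoform(s$sequence, modifications = mods,
               adducts = metal_adduct(n_ca, mode = s$ca_mode),
               truncation = trunc_range, label = label)
  } else {
    reg <- modification_registry()
    delta <- n_phospho * reg$mono_delta[reg$name == "phospho"] +
      (if (acetyl) reg$mono_delta[reg$name == "acetyl"] else 0) +
      (if (met) reg$mono_delta[reg$name == "met_excision"] else 0) +
      (if (is.numeric(trunc) && length(trunc) == 1) trunc else 0) +
      n_ca * adduct_delta("Ca", s$ca_mode)
    fixed_mass_subunit(label, s$base_mass + delta)
  }
}

#' Enumerate candidate species from a grammar
#'
#' Expands the full Cartesian product of every subunit's allowed ranges into
#' concrete proteoforms (one subunit) or assemblies (several subunits), in
#' deterministic lexicographic order of (phosphorylation count, Ca count,
#' flags, truncation), outer subunits varying slowest.
#'
#' @param g An [composition_grammar()].
#' @return List of `ntdms_proteoform` / `fixed_mass_subunit` /
#'   `ntdms_assembly` objects, deduplicated by label.
#' @examples
#' tnc <- subunit_grammar("TnC", sequence = tnc_sequence(), ca = 0:3)
#' length(enumerate_candidates(composition_grammar(tnc))) # 4 Ca states
#' @export
enumerate_candidates <- function(g) {
  stopifnot(inherits(g, "ntdms_grammar"))
  n <- grammar_size(g)
  if (n > g$cap) {
    stop("enumeration size ", format(n, big.mark = ","), " exceeds cap ",
         format(g$cap, big.mark = ","), call. = FALSE)
  }
  per <- lapply(g$subunits, subunit_variants)
  if (length(per) == 1L) {
    out <- per[[1]]
  } else {
    idx <- expand.grid(rev(lapply(per, seq_along)), KEEP.OUT.ATTRS = FALSE)
    idx <- idx[, rev(seq_along(per)), drop = FALSE]
    idx <- idx[do.call(order, as.list(idx)), , drop = FALSE]
    out <- lapply(seq_len(nrow(idx)), function(i) {
      subs <- Map(function(vlist, j) vlist[[j]], per, as.integer(idx[i, ]))
      assembly_species(subs)
    })
  }
  labels <- vapply(out, function(x) x$label, character(1))
  out[!duplicated(labels)]
}

#' Tabulate enumerated candidates
#'
#' @param candidates List returned by [enumerate_candidates()].
#' @param scale Mass scale, as in [neutral_mass()].
#' @return Data frame with columns `label` and `mass` (Da), suitable for
#'   CSV export and for [match_masses()].
#' @export
candidates_table <- function(candidates, scale = "monoisotopic") {
  data.frame(
    label = vapply(candidates, function(x) x$label, character(1)),
    mass = vapply(candidates, neutral_mass, numeric(1), scale = scale),
    stringsAsFactors = FALSE
  )
}

#' Default cardiac troponin isolation-level grammars
#'
#' The per-isolation-level composition grammars for the endogenous cardiac
#' troponin complex, as itemized across the figure annotations of the study
#' this package emulates: the intact heterotrimer (mono-phosphorylated cTnT
#' with mono- or bis-phosphorylated cTnI and TnC carrying 2-3 Ca, four
#' compositions), the ejected cTnT monomer (unmodified, mono-phosphorylated,
#' and mono-phosphorylated with C-terminal Lys truncation), the ejected
#' cTn(I-C) dimer (cTnI phosphorylation 0-2 crossed with TnC Ca 2-3, six
#' compositions), and the ejected TnC monomer (Ca occupancy 0-3). The
#' heterotrimer/dimer/cTnT subunits enter by their deconvolved masses; TnC
#' enters by its vendored sequence. These lists are figure-derived defaults,
#' not text-itemized ground truth, and can be replaced per run.
#'
#' @param ca_mode Adduct convention for TnC, see [metal_adduct()].
#' @return Named list of [composition_grammar()] objects with levels
#'   `complex`, `ejected_cTnT`, `ejected_dimer`, `ejected_TnC`.
#' @export
ctn_level_grammars <- function(ca_mode = "charge-displacement") {
  reg <- modification_registry()
  p <- reg$mono_delta[reg$name == "phospho"]
  lysK <- -(residue_masses()[["K"]])
  tnc <- tnc_sequence()
  # Anchors: the printed deconvolved MWs are inputs. The most abundant
  # heterotrimer (77,136 Da) anchors the (pcTnT, ppcTnI, 3 Ca) corner of the
  # complex grammar; the dimer grammar anchors its unphosphorylated 3-Ca
  # corner to the printed 42,556 Da by solving for the cTnI base mass.
  tnc_3ca <- neutral_mass(proteoform(tnc, adducts = metal_adduct(
    3L, mode = ca_mode)))
  list(
    complex = composition_grammar(
      subunit_grammar("cTn(pT)", base_mass = 77136 - 2 * p -
                        3 * adduct_delta("Ca", ca_mode),
                      phospho = 1:2, ca = 2:3, ca_mode = ca_mode)
    ),
    ejected_cTnT = composition_grammar(
      subunit_grammar("cTnT", base_mass = 34580 - p, variants = list(
        "unmod" = list(),
        "1p" = list(phospho = 1L),
        "1p+dLys287" = list(phospho = 1L, truncation = c(dLys = lysK))
      ))
    ),
    ejected_dimer = composition_grammar(
      subunit_grammar("cTnI", base_mass = 42556 - tnc_3ca, phospho = 0:2),
      subunit_grammar("TnC", sequence = tnc, ca = 2:3, ca_mode = ca_mode)
    ),
    ejected_TnC = composition_grammar(
      subunit_grammar("TnC", sequence = tnc, ca = 0:3, ca_mode = ca_mode)
    )
  )
}
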