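# Shared fixtures built in code.

tnc <- tnc_sequence()

tnc_ca_states <- function(mode = "charge-displacement") {
  lapply(0:3, function(k)
    proteoform(tnc, adducts = metal_adduct(k, mode = mode)))
}

# The standard synthetic TnC Ca-state mixture: proportions 0.2/0.2/0.5/0.1
# over 0/1/2/3 bound Ca, charge envelope 6-8, moderate noise.
tnc_mixture_config <- function(seed = 1L, baseline = 20, peak_cv = 0.05) {
  generator_config(
    Map(function(s, p) list(species = s, proportion = p),
        tnc_ca_states(), c(0.2, 0.2, 0.5, 0.1)),
    charge_center = 7, charge_width = 1, charges = 6:8,
    baseline = baseline, peak_cv = peak_cv, seed = seed)
}

tnc_grammar <- function(ca = 0:3) {
  composition_grammar(subunit_grammar("TnC", sequence = tnc, ca = ca))
}

# Random sequence of canonical residues.
random_chain <- function(n, seed = NULL) {
  codes <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q",
             "K", "E", "M", "H", "F", "R", "Y", "W")
  if (!is.null(seed)) withr::with_seed(seed, paste(sample(codes, n,
                                                          TRUE),
                                                   collapse = ""))
  else paste(sample(codes, n, TRUE), collapse = "")
}

# Position-faithful adduct-count evidence built by arithmetic alone
# (independent of the localization code): count on b_i is the number of
# true sites <= i, on y_n the number of true sites > L - n.
evidence_from_sites <- function(sites, L, b_idx, y_idx) {
  adduct_evidence(rbind(
    data.frame(series = "b", index = b_idx,
               adduct_count = vapply(b_idx, function(i)
                 sum(sites <= i), numeric(1))),
    data.frame(series = "y", index = y_idx,
               adduct_count = vapply(y_idx, function(n)
                 sum(sites > L - n), numeric(1)))
  ), chain_length = L)
}
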