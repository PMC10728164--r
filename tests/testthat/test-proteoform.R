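# Exact-mass chemistry of sequences, modifications, adducts, assemblies,
# and grammar enumeration.

test_that("neutral mass reproduces elemental sums", {
  g <- proteoform(protein_sequence("gly", "G"))
  expect_equal(neutral_mass(g), 75.03203, tolerance = 1e-6)

  # y1-style sanity on lysine as a free amino acid
  k <- proteoform(protein_sequence("lys", "K"))
  expect_equal(neutral_mass(k), 146.10553, tolerance = 1e-6)

  # unknown residue reported with its position
  expect_error(protein_sequence("bad", "GAXK"), "position 3")
})

test_that("metal adduct deltas follow the declared conventions", {
  dfde <- protein_sequence("dfde", "DFDE")
  apo <- proteoform(dfde)
  disp <- proteoform(dfde, adducts = metal_adduct(1))
  add <- proteoform(dfde, adducts = metal_adduct(1,
                                                 mode = "neutral-addition"))
  # charge displacement: Ca minus two protons
  expect_equal(neutral_mass(disp) - neutral_mass(apo),
               39.9625909 - 2 * 1.007276, tolerance = 1e-6)
  expect_equal(neutral_mass(add) - neutral_mass(apo), 39.9625909,
               tolerance = 1e-6)
  # mode irrelevant at zero adducts
  z1 <- proteoform(dfde, adducts = metal_adduct(0))
  z2 <- proteoform(dfde, adducts = metal_adduct(0,
                                                mode = "neutral-addition"))
  expect_identical(neutral_mass(z1), neutral_mass(z2))
  # count capped
  expect_error(metal_adduct(4), "exceeds maximum")
})

test_that("adduct mass additivity is exact for 0..3 Ca", {
  for (mode in c("charge-displacement", "neutral-addition")) {
    masses <- vapply(0:3, function(k)
      neutral_mass(proteoform(tnc, adducts = metal_adduct(k, mode = mode))),
      numeric(1))
    deltas <- diff(masses)
    expect_equal(deltas, rep(adduct_delta("Ca", mode), 3), tolerance = 1e-12)
  }
})

test_that("monoisotopic mass is below average mass (elemental oracle)", {
  withr::with_seed(11, {
    for (i in 1:50) {
      chain <- random_chain(sample(5:60, 1))
      p <- proteoform(protein_sequence("r", chain))
      mono <- neutral_mass(p)
      avg <- neutral_mass(p, "average")
      expect_lt(mono, avg)
      # dual route: residue-table sum must agree with the elemental
      # composition oracle
      f <- ntdms:::chain_formula(strsplit(chain, "")[[1]])
      expect_equal(mono, ntdms:::formula_mass(f), tolerance = 1e-9)
      expect_equal(avg, ntdms:::formula_mass(f, "average"),
                   tolerance = 1e-9)
    }
  })
})

test_that("modification registry carries the canonical deltas", {
  reg <- modification_registry()
  expect_equal(reg$mono_delta[reg$name == "acetyl"], 42.01057,
               tolerance = 1e-5)
  expect_equal(reg$mono_delta[reg$name == "phospho"], 79.96633,
               tolerance = 1e-5)
  expect_equal(reg$mono_delta[reg$name == "met_excision"], -131.04049,
               tolerance = 1e-5)
})

test_that("modifications and truncations are validated", {
  p <- proteoform(tnc,
                  modifications = data.frame(name = "phospho",
                                             position = 22L))
  expect_equal(neutral_mass(p) - neutral_mass(proteoform(tnc)), 79.96633,
               tolerance = 1e-5)
  expect_error(proteoform(tnc, modifications = data.frame(name = "phospho",
                                                          position = 200L)),
               "outside")
  expect_error(proteoform(tnc, modifications = data.frame(
    name = c("phospho", "phospho"), position = c(22L, 22L))), "duplicate")
  # internal truncation rejected; terminal accepted and mass-effective
  expect_error(proteoform(tnc, truncation = c(50, 60)), "terminal")
  tr <- proteoform(tnc, truncation = c(161, 161))
  expect_equal(neutral_mass(proteoform(tnc)) - neutral_mass(tr),
               ntdms:::residue_masses()[["E"]], tolerance = 1e-9)
})

test_that("assembly mass is an exact commutative sum", {
  dimer <- assembly_species(list(fixed_mass_subunit("cTn(I-C)", 42556),
                                 fixed_mass_subunit("cTnT", 34580)))
  expect_identical(assembly_mass(dimer), 77136)

  single <- assembly_species(list(proteoform(tnc)))
  expect_equal(assembly_mass(single), neutral_mass(proteoform(tnc)))

  subs <- list(fixed_mass_subunit("a", 101.5), fixed_mass_subunit("b", 202.5),
               proteoform(tnc))
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  masses <- vapply(perms, function(p)
    assembly_mass(assembly_species(subs[p])), numeric(1))
  expect_true(all(masses == masses[1]))
  expect_error(assembly_species(list()), "at least one")
})

test_that("m/z arithmetic places printed charge states in their windows", {
  expect_equal(mz_of(77136, 19), (77136 + 19 * 1.007276) / 19)
  expect_gt(mz_of(77136, 19), 4050)
  expect_lt(mz_of(77136, 19), 4080)
  expect_gt(mz_of(18520, 7), 2600)
  expect_lt(mz_of(18520, 7), 3100)
  expect_equal(mz_of(500, 1), 501.007276)
  expect_error(mz_of(500, 0), ">= 1")
  expect_equal(mass_of(mz_of(12345.6, 9), 9), 12345.6, tolerance = 1e-9)
})

test_that("grammar enumeration matches its cardinality product", {
  dimer <- composition_grammar(
    subunit_grammar("cTnI", base_mass = 24000, phospho = 0:2),
    subunit_grammar("TnC", sequence = tnc, ca = 2:3))
  cand <- enumerate_candidates(dimer)
  expect_length(cand, 6)

  expect_length(enumerate_candidates(tnc_grammar(0:3)), 4)
  # all-singleton grammar enumerates one species
  expect_length(enumerate_candidates(composition_grammar(
    subunit_grammar("x", base_mass = 1000))), 1)

  # cardinality property for a family of small grammars
  withr::with_seed(5, {
    for (i in 1:10) {
      g <- composition_grammar(
        subunit_grammar("a", base_mass = 5000,
                        phospho = 0:sample(0:3, 1), ca = 0:sample(0:3, 1),
                        acetyl = c(FALSE, TRUE)[1:sample(1:2, 1)]),
        subunit_grammar("b", base_mass = 7000,
                        phospho = 0:sample(0:2, 1)))
      expect_lte(grammar_size(g), 100)
      expect_length(enumerate_candidates(g), grammar_size(g))
    }
  })
  # enumeration cap
  big <- composition_grammar(subunit_grammar("x", base_mass = 1e4,
                                             phospho = 0:9, ca = 0:3),
                             cap = 10)
  expect_error(enumerate_candidates(big), "exceeds cap")
})

test_that("enumeration order is deterministic and labels are stable", {
  g <- tnc_grammar(0:3)
  t1 <- candidates_table(enumerate_candidates(g))
  t2 <- candidates_table(enumerate_candidates(g))
  expect_identical(t1, t2)
  expect_identical(t1$label, c("TnC", "TnC+1Ca", "TnC+2Ca", "TnC+3Ca"))
})

test_that("FASTA fixture matches the printed sequence anchors", {
  expect_length(tnc$residues, 161)
  expect_identical(paste(tnc$residues[73:76], collapse = ""), "DFDE")
  expect_identical(paste(tnc$residues[113:115], collapse = ""), "DLD")
  expect_identical(paste(tnc$residues[141:145], collapse = ""), "DKNND")
  expect_identical(paste(tnc$residues[65:76], collapse = ""),
                   "DEDGSGTVDFDE")
  expect_identical(paste(tnc$residues[105:116], collapse = ""),
                   "DKNADGYIDLDE")
})
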