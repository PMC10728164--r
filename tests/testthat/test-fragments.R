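# b/y fragment masses, MS2 matching, adduct localization, and coverage.

test_that("b/y complementarity holds with mods and adducts partitioned", {
  p <- proteoform(tnc,
                  modifications = data.frame(name = c("phospho", "acetyl"),
                                             position = c(84L, 1L)),
                  adducts = metal_adduct(2))
  sites <- c(114L, 143L)
  precursor <- neutral_mass(p)
  for (i in c(1, 2, 50, 84, 113, 160)) {
    b <- fragment_mass(p, "b", i, adduct_positions = sites)
    y <- fragment_mass(p, "y", 161 - i, adduct_positions = sites)
    expect_equal(b + y, precursor, tolerance = 1e-8)
  }
})

test_that("fragment spans follow the b/y convention", {
  # y1 of a chain ending in K is lysine plus water
  chain <- protein_sequence("x", "GAVLK")
  expect_equal(fragment_mass(proteoform(chain), "y", 1), 146.10553,
               tolerance = 1e-5)
  # y16 of the 161-residue TnC spans residues 146..161
  y16 <- fragment_mass(proteoform(tnc), "y", 16)
  manual <- sum(ntdms:::residue_masses()[tnc$residues[146:161]]) +
    ntdms:::water_mass()
  expect_equal(y16, manual, tolerance = 1e-9)
  expect_error(fragment_mass(proteoform(tnc), "b", 161), "index")
})

test_that("fragment matching is a nearest-neighbor assignment at 20 ppm", {
  p <- proteoform(protein_sequence("pep", random_chain(30, seed = 41)))
  theo <- fragment_ions(p, charges = 1:2)
  # noiseless roundtrip: every generated ion matches at < 1 ppm
  peaks <- data.frame(mz = theo$mz, intensity = 100)
  m <- match_fragments(peaks, theo)
  expect_identical(nrow(m), nrow(theo))
  expect_true(all(abs(m$ppm_error) < 1))
  # a 30-ppm displaced peak stays unmatched
  one <- theo[1, , drop = FALSE]
  far <- data.frame(mz = one$mz * (1 + 30e-6), intensity = 1)
  expect_identical(nrow(match_fragments(far, one)), 0L)
  expect_error(match_fragments(far, one, tolerance_ppm = 0), "> 0")
})

test_that("competing ions resolve to the lower-|ppm| assignment", {
  withr::with_seed(43, {
    for (i in 1:20) {
      mz0 <- stats::runif(1, 300, 3000)
      ions <- data.frame(series = "b", index = 1:2, adduct_count = 0,
                         charge = 1,
                         neutral_mass = 0,
                         mz = c(mz0, mz0 * (1 + stats::runif(1, 2e-6,
                                                             15e-6))))
      peak_mz <- mz0 * (1 + stats::runif(1, -1e-6, 1e-6))
      m <- match_fragments(data.frame(mz = peak_mz, intensity = 1), ions)
      oracle <- which.min(abs(peak_mz - ions$mz) / ions$mz)
      expect_identical(m$index[1], ions$index[oracle])
    }
  })
})

test_that("the printed evidence sets localize to the printed motifs", {
  ev <- tnc_ca_evidence()
  iii <- localize_adducts(ev$domain_III, tnc)
  best3 <- iii[which.min(iii$width), ]
  expect_identical(c(best3$raw_start, best3$raw_end), c(110L, 115L))
  expect_identical(c(best3$trimmed_start, best3$trimmed_end), c(113L, 115L))
  expect_identical(best3$motif, "DLD")

  iv <- localize_adducts(ev$domain_IV, tnc)
  best4 <- iv[which.min(iv$width), ]
  expect_identical(c(best4$raw_start, best4$raw_end), c(141L, 145L))
  expect_identical(best4$motif, "DKNND")

  ii <- localize_adducts(ev$domain_II, tnc)
  best2 <- ii[which.min(ii$width), ]
  expect_identical(c(best2$raw_start, best2$raw_end), c(68L, 76L))
  expect_identical(c(best2$trimmed_start, best2$trimmed_end), c(73L, 76L))
  expect_identical(best2$motif, "DFDE")
})

test_that("adjacent b evidence gives a single-residue interval", {
  e <- adduct_evidence(data.frame(series = c("b", "b"), index = c(80, 81),
                                  adduct_count = c(0, 1)),
                       chain_length = 161)
  loc <- localize_adducts(e, tnc)
  expect_identical(c(loc$raw_start, loc$raw_end), c(81L, 81L))
})

test_that("inconsistent or acid-free evidence is handled explicitly", {
  # b50 + Ca says the site is N-terminal of 51; y100 + Ca says it is
  # C-terminal of 61 — impossible for a single adduct
  bad <- adduct_evidence(data.frame(series = c("b", "y"),
                                    index = c(50, 100),
                                    adduct_count = c(1, 1)),
                         chain_length = 161)
  expect_error(localize_adducts(bad, tnc), "does not intersect")

  # interval without D/E stays untrimmed and flagged
  seq_noacid <- protein_sequence("na", "GGGGKGGGGG")
  e <- adduct_evidence(data.frame(series = c("b", "b"),
                                  index = c(3, 7),
                                  adduct_count = c(0, 1)),
                       chain_length = 10)
  loc <- localize_adducts(e, seq_noacid)
  expect_false(loc$trimmed)
  expect_identical(c(loc$raw_start, loc$raw_end),
                   c(loc$trimmed_start, loc$trimmed_end))

  # non-monotone counts are flagged, not silently dropped
  nonmono <- adduct_evidence(
    data.frame(series = c("b", "b"), index = c(10, 20),
               adduct_count = c(1, 0)), 30)
  expect_identical(nonmono$violations$b, 20L)
  expect_warning(
    try(localize_adducts(nonmono,
                         protein_sequence("x", random_chain(30, seed = 1))),
        silent = TRUE),
    "non-monotone")
})

test_that("raw intervals always contain the true site (200 random draws)", {
  withr::with_seed(47, {
    for (i in 1:200) {
      L <- sample(40:80, 1)
      chain <- random_chain(L)
      n_sites <- sample(1:3, 1)
      sites <- sort(sample(seq(2, L - 1), n_sites))
      b_idx <- sort(sample(seq_len(L - 1), 8))
      y_idx <- sort(sample(seq_len(L - 1), 8))
      e <- evidence_from_sites(sites, L, b_idx, y_idx)
      loc <- localize_adducts(e, protein_sequence("r", chain),
                              n_adducts = n_sites)
      for (k in seq_len(n_sites)) {
        row <- loc[loc$adduct_ordinal == k, ]
        expect_lte(row$raw_start, sites[k])
        expect_gte(row$raw_end, sites[k])
        if (substr(chain, sites[k], sites[k]) %in% c("D", "E")) {
          expect_lte(row$trimmed_start, sites[k])
          expect_gte(row$trimmed_end, sites[k])
        }
      }
    }
  })
})

test_that("adding consistent evidence never widens a raw interval", {
  withr::with_seed(53, {
    for (i in 1:25) {
      L <- 60
      sites <- sort(sample(2:59, 2))
      b1 <- sort(sample(seq_len(L - 1), 4))
      y1 <- sort(sample(seq_len(L - 1), 4))
      extra_b <- setdiff(sort(sample(seq_len(L - 1), 8)), b1)
      e1 <- evidence_from_sites(sites, L, b1, y1)
      e2 <- evidence_from_sites(sites, L, sort(c(b1, extra_b)), y1)
      chain <- protein_sequence("r", random_chain(L))
      l1 <- localize_adducts(e1, chain, n_adducts = 2)
      l2 <- localize_adducts(e2, chain, n_adducts = 2)
      expect_true(all(l2$raw_end - l2$raw_start <=
                        l1$raw_end - l1$raw_start))
    }
  })
})

test_that("bond coverage counts cleaved backbone bonds", {
  all_b <- data.frame(series = "b", index = 1:160)
  expect_equal(bond_coverage(all_b, 161)$percent, 100)
  expect_equal(bond_coverage(NULL, 161)$percent, 0)
  expect_equal(bond_coverage(all_b[0, ], 161)$percent, 0)

  # 101 of 160 TnC bonds
  m <- data.frame(series = "b", index = 1:101)
  expect_equal(bond_coverage(m, 161)$percent, 63.1)

  # brute-force equality on random match sets (b and y mixed, duplicated)
  withr::with_seed(59, {
    for (i in 1:50) {
      L <- sample(20:100, 1)
      n <- sample(1:40, 1)
      m <- data.frame(series = sample(c("b", "y"), n, TRUE),
                      index = sample(seq_len(L - 1), n, TRUE))
      got <- bond_coverage(m, L)
      bonds <- rep(FALSE, L - 1)
      for (j in seq_len(n)) {
        bd <- if (m$series[j] == "b") m$index[j] else L - m$index[j]
        if (bd >= 1 && bd <= L - 1) bonds[bd] <- TRUE
      }
      expect_identical(got$cleaved_bonds, sum(bonds))
      expect_equal(got$percent, round(100 * sum(bonds) / (L - 1), 1))
    }
  })
})
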