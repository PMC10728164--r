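# Ground-truth generators: determinism, analytic totals, and roundtrips.

test_that("generators are pure functions of (config, seed)", {
  cfg <- tnc_mixture_config(seed = 12)
  a <- generate_ms1(cfg)
  b <- generate_ms1(cfg)
  expect_identical(a$spectrum$mz, b$spectrum$mz)
  expect_identical(a$spectrum$intensity, b$spectrum$intensity)
  c <- generate_ms1(tnc_mixture_config(seed = 13))
  expect_false(identical(a$spectrum$intensity, c$spectrum$intensity))

  p <- proteoform(tnc, adducts = metal_adduct(3))
  m1 <- generate_ms2(p, c(74, 114, 143), efficiency = 0.5, seed = 4)
  m2 <- generate_ms2(p, c(74, 114, 143), efficiency = 0.5, seed = 4)
  expect_identical(m1$spectrum$mz, m2$spectrum$mz)

  g1 <- generate_mobilogram(data.frame(ccs = 4880, weight = 1,
                                       width = 0.008), 20, 77136,
                            baseline = 0.02, seed = 9)
  g2 <- generate_mobilogram(data.frame(ccs = 4880, weight = 1,
                                       width = 0.008), 20, 77136,
                            baseline = 0.02, seed = 9)
  expect_identical(g1$mobilogram$intensity, g2$mobilogram$intensity)
})

test_that("noiseless MS1 total ion current matches the analytic sum", {
  cfg <- tnc_mixture_config(seed = 2, baseline = 0, peak_cv = 0)
  gen <- generate_ms1(cfg)
  s <- gen$spectrum
  step <- s$mz[2] - s$mz[1]
  tic <- sum(s$intensity) * step
  # quadrature oracle: each Gaussian peak integrates to h * sigma * sqrt(2pi)
  env <- lapply(tnc_ca_states(), isotope_envelope)
  zs <- 6:8
  zw <- stats::dnorm(zs, 7, 1); zw <- zw / sum(zw)
  props <- c(0.2, 0.2, 0.5, 0.1)
  peaks <- do.call(rbind, lapply(1:4, function(i) {
    mass <- neutral_mass(tnc_ca_states()[[i]])
    do.call(rbind, lapply(seq_along(zs), function(j)
      data.frame(mz = (mass + env[[i]]$offsets) / zs[j] + 1.007276,
                 h = props[i] * zw[j] * env[[i]]$probabilities)))
  }))
  peaks$h <- peaks$h / max(peaks$h) * cfg$base_intensity
  sigma <- peaks$mz / cfg$resolving_power / (2 * sqrt(2 * log(2)))
  analytic <- sum(peaks$h * sigma * sqrt(2 * pi))
  expect_lt(abs(tic - analytic) / analytic, 0.005)
})

test_that("MS2 generation honours efficiency and retention", {
  p <- proteoform(tnc, adducts = metal_adduct(3))
  sites <- c(74, 114, 143)

  none <- generate_ms2(p, sites, efficiency = 0, seed = 1)
  expect_identical(nrow(none$ions), 0L)
  expect_error(generate_ms2(p, sites, efficiency = 1.2), "\\[0, 1\\]")
  expect_error(generate_ms2(p, c(74), efficiency = 1), "adduct count")

  full <- generate_ms2(p, sites, efficiency = 1, seed = 2)
  expect_identical(sort(unique(full$ions$index[full$ions$series == "b"])),
                   1:160)
  # position-faithful retention: b-ion adduct counts equal sites in span
  b <- full$ions[full$ions$series == "b", ]
  expect_equal(b$adduct_count[order(b$index)],
               vapply(sort(b$index), function(i) sum(sites <= i),
                      numeric(1)))
  # bond coverage reports the generated cleavage fraction exactly
  part <- generate_ms2(p, sites, efficiency = 0.63, seed = 3)
  cov <- bond_coverage(part$ions, 161)
  expect_identical(cov$cleaved_bonds, length(part$truth$cleaved_bonds))
  expect_equal(cov$percent,
               round(100 * length(part$truth$cleaved_bonds) / 160, 1))
})

test_that("full-efficiency MS2 localizes adducts back to their sites", {
  p <- proteoform(tnc, adducts = metal_adduct(3))
  sites <- c(74, 114, 143)
  gen <- generate_ms2(p, sites, efficiency = 1, seed = 11)
  ev <- gen$ions[!duplicated(gen$ions[, c("series", "index")]),
                 c("series", "index", "adduct_count")]
  loc <- localize_adducts(adduct_evidence(ev, 161), tnc)
  expect_identical(nrow(loc), 3L)
  for (k in 1:3) {
    expect_lte(loc$raw_start[k], sites[k])
    expect_gte(loc$raw_end[k], sites[k])
  }
})

test_that("mobilogram truth records reproduce the generating conformers", {
  conf <- data.frame(ccs = c(4600, 5100), weight = c(0.7, 0.3),
                     width = c(0.007, 0.007))
  gen <- generate_mobilogram(conf, charge = 20, ion_mass = 77136, seed = 21)
  expect_equal(gen$truth$conformers$ccs, conf$ccs)
  s <- summarize_mobilogram(gen$mobilogram)
  expect_identical(nrow(s), 2L)
  expect_equal(sort(s$apex_ccs), sort(conf$ccs), tolerance = 2e-3)
  expect_equal(sort(s$share), sort(conf$weight), tolerance = 0.02)
  expect_error(generate_mobilogram(
    data.frame(ccs = 4880, weight = 1, width = 0), 20, 77136), "> 0")
})

test_that("the EGTA series emulation has non-decreasing conformer counts", {
  series <- generate_egta_series(seed = 31)
  counts <- vapply(series, function(x)
    nrow(summarize_mobilogram(x$mobilogram)), integer(1))
  expect_identical(length(counts), 4L)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], counts[1])
})

test_that("truth sidecars serialize enough to score a recovery", {
  gen <- generate_ms1(tnc_mixture_config(seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(gen$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$species$mass, gen$truth$species$mass, tolerance = 1e-9)
  expect_equal(back$species$proportion, gen$truth$species$proportion)
  expect_identical(as.integer(back$seed), gen$truth$seed)
})
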