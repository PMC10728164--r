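# Mason-Schamps conversion, CCS-charge regression, mobilogram conformers.

test_that("forward and inverse Mason-Schamps are exact inverses", {
  g <- gas_parameters()
  withr::with_seed(61, {
    for (i in 1:20) {
      ccs <- stats::runif(1, 1000, 8000)
      z <- sample(5:25, 1)
      mass <- stats::runif(1, 1e4, 1e5)
      m <- mobility_from_ccs(ccs, z, mass, g)
      back <- ccs_from_mobility(m, g)$ccs
      expect_equal(back, ccs, tolerance = 1e-9)
    }
  })
  m <- mobility_from_ccs(4880, 20, 77136, g)
  expect_equal(ccs_from_mobility(m, g)$ccs, 4880, tolerance = 1e-9)
  # the implied inverse mobility sits in the locked TIMS range
  expect_gt(m$inverse_K0, 1.05)
  expect_lt(m$inverse_K0, 1.55)
})

test_that("conversion matches an independent constant-by-constant oracle", {
  # z = 1, K0 = 1 cm^2/(V s), ion mass large enough that mu -> M
  g <- gas_parameters()
  v <- ccs_from_mobility(mobility_measurement(1, 1, 1e9), g)$ccs
  mu <- 28.0134 * 1.66053906660e-27
  oracle <- (3 / 16) * sqrt(2 * pi / (mu * 1.380649e-23 * 305)) *
    1.602176634e-19 / (2.68678e25 * 1e-4) * 1e20
  expect_equal(v, oracle, tolerance = 1e-6)  # 6 significant figures
})

test_that("CCS obeys its dimensional scalings", {
  g <- gas_parameters()
  base <- ccs_from_mobility(mobility_measurement(1.2, 10, 5e4), g)$ccs
  # linear in z
  expect_equal(ccs_from_mobility(mobility_measurement(1.2, 20, 5e4), g)$ccs,
               2 * base, tolerance = 1e-12)
  # linear in 1/K0
  expect_equal(ccs_from_mobility(mobility_measurement(2.4, 10, 5e4), g)$ccs,
               2 * base, tolerance = 1e-12)
  # T^(-1/2) at fixed mu
  g2 <- gas_parameters(temperature = 4 * 305)
  expect_equal(ccs_from_mobility(mobility_measurement(1.2, 10, 5e4),
                                 g2)$ccs,
               base / 2, tolerance = 1e-12)
  # halving CCS doubles K0 (i.e. halves 1/K0)
  m1 <- mobility_from_ccs(4000, 10, 5e4, g)
  m2 <- mobility_from_ccs(2000, 10, 5e4, g)
  expect_equal(m1$inverse_K0 / m2$inverse_K0, 2, tolerance = 1e-12)
  # mu -> M limit for very heavy ions
  heavy <- ccs_from_mobility(mobility_measurement(1.2, 10, 1e7), g)$ccs
  mu_inf <- g$gas_mass * ntdms_constants$amu
  limit <- (3 / 16) * sqrt(2 * pi / (mu_inf * g$kb * g$temperature)) *
    (10 * g$e) / (g$N0 * (1 / 1.2) * 1e-4) * 1e20
  expect_equal(heavy, limit, tolerance = 1e-4)  # < 0.01%
  expect_error(mobility_measurement(-1, 10, 5e4), "> 0")
  expect_error(mobility_from_ccs(-5, 10, 5e4), "> 0")
})

test_that("CCS-charge regression recovers linear structure", {
  pts <- data.frame(charge = 6:9, ccs = 1000 + 120 * (6:9))
  fit <- ccs_charge_fit(pts)
  expect_equal(fit$slope, 120, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  two <- ccs_charge_fit(data.frame(charge = c(7, 8), ccs = c(1800, 1900)))
  expect_equal(two$slope, 100, tolerance = 1e-9)

  expect_error(ccs_charge_fit(data.frame(charge = c(7, 7),
                                         ccs = c(1, 2))), "distinct")

  # symmetric noise leaves the slope unbiased (< 1%)
  withr::with_seed(67, {
    slopes <- replicate(1000, {
      x <- 15:21
      y <- 3000 + 80 * x + stats::rnorm(length(x), 0, 30)
      ccs_charge_fit(data.frame(charge = x, ccs = y))$slope
    })
    expect_lt(abs(mean(slopes) - 80) / 80, 0.01)
  })
})

test_that("mobilogram summarization recovers generated conformers", {
  g <- gas_parameters()
  one <- generate_mobilogram(data.frame(ccs = 4880, weight = 1,
                                        width = 0.008),
                             charge = 20, ion_mass = 77136, seed = 3)
  s <- summarize_mobilogram(one$mobilogram, g = g)
  expect_identical(nrow(s), 1L)
  expect_lt(abs(s$apex_ccs - 4880) / 4880, 0.001)  # within 0.1%

  # well-separated conformers recover count and shares
  three <- generate_mobilogram(
    data.frame(ccs = c(4400, 4880, 5400), weight = c(0.25, 0.5, 0.25),
               width = c(0.006, 0.006, 0.006)),
    charge = 20, ion_mass = 77136, seed = 4)
  s3 <- summarize_mobilogram(three$mobilogram, g = g)
  expect_identical(nrow(s3), 3L)
  expect_equal(sort(s3$share), sort(c(0.25, 0.5, 0.25)), tolerance = 0.02)
  expect_equal(sum(s3$share), 1, tolerance = 1e-9)

  # equal halves
  half <- generate_mobilogram(
    data.frame(ccs = c(4500, 5300), weight = c(0.5, 0.5),
               width = c(0.006, 0.006)),
    charge = 20, ion_mass = 77136, seed = 5)
  sh <- summarize_mobilogram(half$mobilogram, g = g)
  expect_equal(sh$share, c(0.5, 0.5), tolerance = 0.02)

  # merged below the prominence threshold: one conformer
  merged <- generate_mobilogram(
    data.frame(ccs = c(4870, 4890), weight = c(0.5, 0.5),
               width = c(0.02, 0.02)),
    charge = 20, ion_mass = 77136, seed = 6)
  expect_identical(nrow(summarize_mobilogram(merged$mobilogram, g = g)), 1L)

  # flat trace: empty
  flat <- mobilogram(seq(1, 1.5, 0.001), rep(2, 501), 20, 77136)
  expect_identical(nrow(summarize_mobilogram(flat)), 0L)

  # shares invariant under uniform rescaling
  m <- three$mobilogram
  m10 <- mobilogram(m$inverse_K0, m$intensity * 10, m$charge, m$ion_mass)
  expect_equal(summarize_mobilogram(m10, g = g)$share, s3$share,
               tolerance = 1e-12)
})

test_that("mobilograms round-trip through two-column text + sidecar", {
  gen <- generate_mobilogram(data.frame(ccs = 4880, weight = 1,
                                        width = 0.008),
                             charge = 20, ion_mass = 77136, seed = 8)
  path <- withr::local_tempfile(fileext = ".txt")
  m <- gen$mobilogram
  utils::write.table(data.frame(m$inverse_K0, m$intensity), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  yaml::write_yaml(list(charge = 20L, ion_mass = 77136),
                   paste0(path, ".meta"))
  r <- read_mobilogram(path)
  expect_identical(r$charge, 20L)
  expect_equal(summarize_mobilogram(r)$apex_ccs,
               summarize_mobilogram(m)$apex_ccs, tolerance = 1e-6)
})
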