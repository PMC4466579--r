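# One short reference trajectory shared across observable tests.
obsFixture <- local({
  tc <- NULL
  function() {
    if (is.null(tc)) {
      p <- applyStudyConfig(defaultParameters(), "other", vegf_ng_ml = 20)
      prot <- makeProtocol(p, mode = "immobilized", vegf_ng_ml = 20,
                           duration_s = 600, grid_s = seq(0, 600, by = 10))
      tc <<- simulateProtocol(prot, network = fullNet())
    }
    tc
  }
})

test_that("normalization anchors the pre-stimulus total at 100 percent", {
  tot <- totalR2Series(obsFixture())
  expect_equal(tot@values[1], 100)
  # mass balance surfaced as observables: live + degraded = 100 + produced
  tc <- obsFixture()
  degr <- degradedR2Series(tc)
  produced <- 100 * tc@protocol@params@trafficking[["s.R2"]] * tc@times /
    tc@baselineR2
  expect_equal(tot@values + degr@values, 100 + produced, tolerance = 1e-8)
})

test_that("pR2 is the union of the site series", {
  tc <- obsFixture()
  pr2 <- pR2Series(tc)@values
  p951 <- phosphoSeries(tc, "Y951")@values
  p1175 <- phosphoSeries(tc, "Y1175")@values
  p1214 <- phosphoSeries(tc, "Y1214")@values
  expect_true(all(pr2 >= pmax(p951, p1175, p1214) - 1e-9))
  expect_true(all(pr2 <= p951 + p1175 + p1214 + 1e-9))
  expect_error(phosphoSeries(tc, "Y9999"), "unknown residue")
})

test_that("with phosphorylation disabled every phospho series is zero", {
  p <- applyStudyConfig(defaultParameters(), "other", vegf_ng_ml = 20)
  kp <- grep("^kp\\.", names(p@phospho), value = TRUE)
  p@phospho[kp] <- 0
  prot <- makeProtocol(p, mode = "soluble", vegf_ng_ml = 20,
                       duration_s = 300, grid_s = seq(0, 300, by = 60))
  tc <- simulateProtocol(prot, network = fullNet())
  expect_equal(max(pR2Series(tc)@values), 0)
  expect_true(is.na(ligatedFractionPhosphorylated(tc, 300)) ||
              ligatedFractionPhosphorylated(tc, 300) == 0)
})

test_that("single-residue parameterization collapses pR2 onto that site", {
  p <- applyStudyConfig(defaultParameters(), "other", vegf_ng_ml = 20)
  off <- grep("^kp\\.(Y951|Y1175)\\.", names(p@phospho), value = TRUE)
  p@phospho[off] <- 0
  prot <- makeProtocol(p, mode = "soluble", vegf_ng_ml = 20,
                       duration_s = 300, grid_s = seq(0, 300, by = 60))
  tc <- simulateProtocol(prot, network = fullNet())
  expect_equal(pR2Series(tc)@values, phosphoSeries(tc, "Y1214")@values,
               tolerance = 1e-10)
})

test_that("rab11 phospho pools are negligible under the fast rab11 phosphatase", {
  tc <- obsFixture()
  expect_lt(max(pR2Series(tc, "rab11")@values),
            0.05 * max(pR2Series(tc)@values))
})

test_that("AUC reproduces closed-form areas", {
  tri <- new("ObservableSeries", name = "tri",
             times = c(0, 1800, 3600), values = c(0, 10, 0),
             filter = "total")
  expect_equal(aucSeries(tri, c(0, 3600)), 0.5 * 60 * 10, tolerance = 1e-3)
  const <- new("ObservableSeries", name = "c", times = c(0, 3600),
               values = c(4, 4), filter = "total")
  expect_equal(aucSeries(const, c(0, 3600)), 60 * 4, tolerance = 1e-6)
  zero <- new("ObservableSeries", name = "z", times = c(0, 3600),
              values = c(0, 0), filter = "total")
  expect_identical(aucSeries(zero, c(0, 3600)), 0)
})

test_that("ratios guard their denominator and self-ratio is one", {
  a <- new("ObservableSeries", name = "a", times = 0:10 * 60,
           values = c(0, 1:10), filter = "total")
  r <- ratioSeries(a, a)
  expect_true(all(r@values[-1] == 1))
  expect_true(is.na(r@values[1]))  # below floor at t = 0
})

test_that("peaks of monotone series sit at the window edge", {
  dec <- new("ObservableSeries", name = "d", times = 0:10 * 60,
             values = 10 - 0:10, filter = "total")
  pk <- peakSeries(dec, c(0, 600))
  expect_identical(pk[["t_peak"]], 0)
  expect_identical(pk[["value"]], 10)
})

test_that("the ligated fraction is a proper fraction tied to its pools", {
  tc <- obsFixture()
  f <- ligatedFractionPhosphorylated(tc, c(60, 300, 600))
  expect_true(all(f >= 0 & f <= 1))
  # manual recomputation at one time point
  sp <- tc@network@species
  live <- sp$compartment %in% c("surf", "rab45", "rab11")
  lig <- sp$has_R2 & sp$has_V & live
  i <- which(tc@times == 300)
  num <- sum(tc@states[i, lig & (sp$p951 | sp$p1175 | sp$p1214)])
  den <- sum(tc@states[i, lig])
  expect_equal(f[2], num / den, tolerance = 1e-12)
})
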