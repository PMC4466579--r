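test_that("printed dissociation constants round-trip as koff/kon", {
  kd <- dissociationConstants(defaultParameters())
  printed <- c(KD.V.R2.surf = 1.0e-10, KD.M.VR2.surf = 2.4e-8,
               KD.VM.R2.surf = 1.0e-10, KD.V.N1.surf = 2.1e-9,
               KD.N1.VR2.surf = 3.2e-17, KD.VN1.R2.surf = 1.0e-17,
               KD.V.R2.int = 1.0e-10, KD.V.N1.int = 2.1e-9,
               KD.N1.VR2.int = 3.2e-17, KD.VN1.R2.int = 1.0e-17)
  for (nm in names(printed))
    expect_equal(kd[[nm]], printed[[nm]], tolerance = 0.05, label = nm)
})

test_that("bulk-to-endosomal on-rate conversion is dimensional", {
  geo <- defaultParameters()@geometry
  expect_identical(convertBulkToInternalKon(0, geo, "rab45"), 0)
  # doubling the endosomal volume halves the per-density rate
  geo2 <- geo
  geo2[["endoVol.rab45"]] <- 2 * geo[["endoVol.rab45"]]
  expect_equal(convertBulkToInternalKon(1e7, geo2, "rab45"),
               convertBulkToInternalKon(1e7, geo, "rab45") / 2)
  # hand value: 1e7 / (6.022e23 x 1e-10 L/cm2) ~ 1.66e-7 per (#/cm2) per s
  expect_equal(convertBulkToInternalKon(1e7, geo, "rab45"), 1.6606e-7,
               tolerance = 1e-4)
  geo3 <- geo
  geo3[["endoVol.rab11"]] <- -1
  expect_error(convertBulkToInternalKon(1e7, geo3, "rab11"), "volume")
})

test_that("receptor surface densities scale with cell density", {
  geo <- defaultParameters()@geometry  # 1e5 cells/cm2
  expect_identical(receptorsPerCellToDensity(0, geo), 0)
  expect_equal(receptorsPerCellToDensity(6000, geo), 6e8)
  expect_equal(receptorsPerCellToDensity(35000, geo), 3.5e9)
})

test_that("study specialization applies the degradation and internalization rules", {
  base <- defaultParameters()
  other <- applyStudyConfig(base, "other", vegf_ng_ml = 20)
  # all degradation rates x 2.4; dose of 20 ng/mL keeps the original k_int
  expect_equal(other@trafficking[["kdegr.V.R2"]], 3.6e-5 * 2.4)
  expect_equal(other@trafficking[["kdegr.N1"]], 1.6e-4 * 2.4)
  expect_equal(other@trafficking[["kint.V.R2"]],
               base@trafficking[["kint.V.R2"]])
  # high-dose study divides ligated internalization by 6
  p2010 <- applyStudyConfig(base, "presentation_2010")
  expect_equal(p2010@trafficking[["kint.V.R2"]], 3.12e-2 / 6)
  expect_equal(p2010@trafficking[["kint.V.N1.R2"]], 3.12e-2 / 6)
  expect_equal(p2010@kinetic[["koff.V.M"]], 1e-2)
  expect_equal(p2010@kinetic[["kon.V.M"]], 4e3)
  # at exactly the 50 ng/mL threshold the original rate is kept
  p50 <- applyStudyConfig(base, "other", vegf_ng_ml = 50)
  expect_equal(p50@trafficking[["kint.V.R2"]], 3.12e-2)
  # the PAEC column applies no degradation scale and no matrix kinetics
  ts <- applyStudyConfig(base, "trafficking_study")
  expect_equal(ts@trafficking[["kdegr.V.R2"]], 3.6e-5)
  expect_identical(ts@kinetic[["kon.V.M"]], 0)
  expect_error(applyStudyConfig(base, "huvec_typo"), "unknown study")
})

test_that("a specialized set refuses a second specialization", {
  p <- applyStudyConfig(defaultParameters(), "other")
  expect_error(applyStudyConfig(p, "other"), "already specialized")
})

test_that("production rates make the unligated subsystem stationary", {
  p <- applyStudyConfig(defaultParameters(), "trafficking_study")
  trf <- p@trafficking
  ss <- p@study$ss
  # production balances degradation out of the early endosome
  expect_equal(trf[["s.R2"]], trf[["kdegr.R2"]] * ss$R2[["rab45"]])
  expect_equal(trf[["s.N1"]], trf[["kdegr.N1"]] * ss$N1[["rab45"]])
  # hand value at the representative rates and 6e8 receptors/cm2
  pr <- computeProductionRates(defaultParameters(), r2_surface = 6e8,
                               n1_surface = 0)
  expect_equal(pr@trafficking[["s.R2"]], 3.6e-6 * 0.6818 * 6e8,
               tolerance = 1e-3)
  expect_identical(pr@trafficking[["s.N1"]], 0)
  # zero internalization needs zero production
  z <- setParameters(defaultParameters(), c(kint.R2 = 0))
  expect_identical(computeProductionRates(z, r2_surface = 6e8,
                                          n1_surface = 0)@trafficking[["s.R2"]],
                   0)
})

test_that("the computed steady state persists under long integration", {
  p <- applyStudyConfig(defaultParameters(), "trafficking_study")
  net <- noPhosphoNet()
  prot <- makeProtocol(p, mode = "soluble", vegf_ng_ml = 0,
                       duration_s = 1e5, grid_s = seq(0, 1e5, length.out = 21))
  tc <- simulateProtocol(prot, network = net)
  live <- tc@network@species$compartment != "degr"
  x0 <- tc@states[1, live]
  drift <- apply(tc@states[, live, drop = FALSE], 1,
                 function(x) max(abs(x - x0) / pmax(x0, 1)))
  expect_lt(max(drift), 1e-6)
})

test_that("unit conversions for ligand and matrix doses", {
  geo <- defaultParameters()@geometry
  expect_equal(vegfNgMlToMolar(45, geo), 1e-9)   # 45 kDa dimer
  expect_equal(matrixMgMlToMolar(3, geo), 1e-4)  # 30 kDa site default
})
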