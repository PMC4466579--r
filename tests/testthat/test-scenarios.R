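test_that("named scenarios install their study columns", {
  p2010 <- makeScenario("presentation_2010", mode = "immobilized")
  expect_equal(p2010@params@kinetic[["koff.V.M"]], 1e-2)
  kd <- p2010@params@kinetic[["koff.V.M"]] / p2010@params@kinetic[["kon.V.M"]]
  expect_equal(kd, 2.5e-6)
  expect_equal(p2010@params@trafficking[["kint.V.R2"]], 3.12e-2 / 6)
  ts <- makeScenario("trafficking_study", mode = "soluble")
  expect_equal(ts@params@study$r2_per_cell, 108000)
  expect_equal(ts@params@study$n1_per_cell, 113000)
  tr <- makeScenario("trafficking_study_r2only", mode = "soluble")
  expect_equal(tr@params@study$r2_per_cell, 37400)
  expect_error(makeScenario("nope"), "unknown study")
})

test_that("a zero-dose scenario is a null stimulus", {
  prot <- makeScenario("other", mode = "soluble", vegf_ng_ml = 0,
                       duration_s = 600)
  tc <- simulateProtocol(prot, network = noPhosphoNet())
  expect_lt(max(abs(totalR2Series(tc)@values - 100)), 1e-6)
})

test_that("perturbations are pure and invertible", {
  p <- otherParams()
  id <- applyPerturbation(p, "surface_phosphatase_overexpression",
                          magnitude = 1)
  expect_identical(id@phospho, p@phospho)
  up <- applyPerturbation(p, "surface_phosphatase_overexpression",
                          magnitude = 5)
  back <- applyPerturbation(up, "surface_phosphatase_overexpression",
                            magnitude = 1 / 5)
  expect_equal(back@phospho, p@phospho, tolerance = 1e-14)
  # an exactly representable factor inverts bitwise
  up2 <- applyPerturbation(p, "surface_phosphatase_overexpression",
                           magnitude = 4)
  back2 <- applyPerturbation(up2, "surface_phosphatase_overexpression",
                             magnitude = 0.25)
  expect_identical(back2@phospho, p@phospho)
  expect_error(applyPerturbation(p, "unknown_kind"), "unknown perturbation")
})

test_that("phosphatase perturbations touch the intended rates only", {
  p <- otherParams()
  ve <- applyPerturbation(p, "veptp_sirna")
  expect_equal(ve@phospho[["kdp.Y951.V.R2.surf"]], 0.043 / 5)
  expect_equal(ve@phospho[["kdp.Y1175.V.N1.R2.surf"]], 5 / 5)
  expect_equal(ve@phospho[["kdp.Y1214.V.R2.surf"]],
               p@phospho[["kdp.Y1214.V.R2.surf"]])
  expect_equal(ve@phospho[["kdp.Y951.V.R2.rab45"]],
               p@phospho[["kdp.Y951.V.R2.rab45"]])
  tc <- applyPerturbation(p, "tcptp_active")
  expect_equal(tc@phospho[["kdp.Y951.V.R2.surf"]], 30)
  expect_equal(tc@phospho[["kdp.Y1214.V.N1.R2.rab45"]], 30)
  expect_equal(tc@phospho[["kdp.Y1175.V.R2.surf"]],
               p@phospho[["kdp.Y1175.V.R2.surf"]])
  rb <- applyPerturbation(p, "rab11_kdp_equals_rab45")
  expect_equal(rb@phospho[["kdp.Y1175.V.R2.rab11"]],
               p@phospho[["kdp.Y1175.V.R2.rab45"]])
})

test_that("NRP1 knockout and an NRP1-blind ligand agree on every VEGFR2 species", {
  net <- fullNet()
  p <- otherParams()
  mk <- function(pert) {
    prot <- makeProtocol(p, mode = "soluble", vegf_ng_ml = 20,
                         duration_s = 600, grid_s = seq(0, 600, by = 120),
                         perturbations = list(list(kind = pert)))
    simulateProtocol(prot, network = net)
  }
  ko <- mk("nrp1_knockout")
  vb <- mk("v165b_ligand")
  r2 <- net@species$has_R2
  expect_equal(vb@states[, r2], ko@states[, r2], tolerance = 1e-10)
  # they differ in the NRP1 pools themselves (knockout removes them)
  n1 <- net@species$form == "N1"
  expect_gt(max(vb@states[, n1]), 0)
  expect_equal(max(ko@states[, n1]), 0)
})

test_that("the matrix off-rate sweep varies exactly one constant", {
  prots <- koffVmSweep(c(1e-4, 1e-3, 1e-2))
  expect_length(prots, 3)
  ps <- lapply(prots, function(pr) {
    pp <- pr@params
    for (q in pr@perturbations) pp <- do.call(applyPerturbation,
                                              c(list(params = pp), q))
    pp
  })
  expect_equal(vapply(ps, function(p) p@kinetic[["koff.V.M"]], 1),
               c(1e-4, 1e-3, 1e-2))
  # all other kinetic entries identical
  rest <- setdiff(names(ps[[1]]@kinetic),
                  c("koff.V.M", "koff.M.VR2.surf"))
  expect_identical(ps[[1]]@kinetic[rest], ps[[3]]@kinetic[rest])
  expect_error(koffVmSweep(c(-1)), "values > 0")
})

test_that("a fast-releasing matrix approaches the soluble response", {
  solP <- makeScenario("other", mode = "soluble", vegf_ng_ml = 20,
                       duration_s = 900)
  fast <- makeScenario("other", mode = "immobilized", vegf_ng_ml = 20,
                       duration_s = 900,
                       perturbations = list(list(kind = "koff_vm",
                                                 magnitude = 1)))
  net <- noPhosphoNet()
  a <- seriesAt(ligatedR2Series(simulateProtocol(solP, network = net)), 600)
  b <- seriesAt(ligatedR2Series(simulateProtocol(fast, network = net)), 600)
  expect_lt(abs(a - b) / a, 0.05)
})

test_that("figure registry bundles have the declared shape", {
  expect_setequal(figureIds(),
                  c("fig2", "fig4ef", "fig5", "fig6", "fig7", "fig8",
                    "s4", "s5"))
  expect_error(runFigureScenario("fig99"), "unknown figure")
  out <- runFigureScenario("s5", duration_s = 600)
  expect_length(out$runs, 1)
  lf <- out$runs[[1]]$series$ligatedFraction
  expect_true(all(lf$fraction >= 0 & lf$fraction <= 1, na.rm = TRUE))
})
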