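test_that("the assembled derivative vanishes on the empty system", {
  params <- defaultParameters()  # production rates zero in the base set
  model <- assembleModel(fullNet(), params)
  expect_true(all(model$rhs(numeric(97)) == 0))
})

test_that("a lone ligand-receptor pair produces the single mass-action flux", {
  params <- defaultParameters()
  net <- minimalNet()
  model <- assembleModel(net, params)
  x <- setNames(numeric(12), net@species$name)
  vMolar <- 1e-9
  depthL <- params@geometry[["depth.cm"]] * 1e-3
  x["ext:V"] <- vMolar * 6.02214076e23 * depthL  # #/cm2 basis
  x["surf:R2"] <- 6e8
  d <- model$rhs(unname(x))
  names(d) <- net@species$name
  # d[V.R2]/dt = kon [V] [R2] with [V] in molar
  expect_equal(d[["surf:V.R2"]], 1e7 * vMolar * 6e8, tolerance = 1e-12)
  expect_equal(d[["ext:V"]], -d[["surf:V.R2"]], tolerance = 1e-12)
  # internalization of R2 also drains the surface pool
  expect_equal(d[["surf:R2"]],
               -d[["surf:V.R2"]] - 2.6e-3 * 6e8, tolerance = 1e-12)
})

test_that("the generic assembler matches the hand-coded minimal-system oracle", {
  params <- applyStudyConfig(defaultParameters(), "trafficking_study_r2only")
  net <- minimalNet()
  model <- assembleModel(net, params)
  oracle <- minimalOracleRhs(params)
  set.seed(7)
  for (i in 1:100) {
    x <- 10^runif(12, 0, 10)
    a <- model$rhs(x)
    b <- oracle(x)
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-9)), 1e-12)
  }
})

test_that("the analytic Jacobian matches a numerical one", {
  params <- applyStudyConfig(defaultParameters(), "trafficking_study_r2only")
  net <- minimalNet()
  model <- assembleModel(net, params)
  set.seed(11)
  x <- 10^runif(12, 2, 8)
  J <- model$jac(0, x, NULL)
  h <- 1e-4
  for (j in seq_along(x)) {
    dx <- x; dx[j] <- dx[j] * (1 + h)
    num <- (model$rhs(dx) - model$rhs(x)) / (x[j] * h)
    expect_equal(J[, j], num, tolerance = 1e-5)
  }
})

test_that("no-VEGF steady state has the analytic surface fractions", {
  p <- applyStudyConfig(defaultParameters(), "trafficking_study")
  ss <- p@study$ss
  expect_equal(ss$R2[["surf"]] / sum(ss$R2), 0.578, tolerance = 1e-3)
  expect_equal(ss$N1[["surf"]] / sum(ss$N1), 0.758, tolerance = 1e-3)
  # rab11 NRP1 pool exceeds its rab45 pool (fast transfer, slow return)
  expect_gt(ss$N1[["rab11"]], ss$N1[["rab45"]])
  # and the state satisfies the derivative-norm contract
  x <- steadyStateNoVegf(noPhosphoNet(), p)
  expect_true(all(x >= 0))
})

test_that("a zero-dose protocol leaves every pool constant", {
  p <- applyStudyConfig(defaultParameters(), "other", vegf_ng_ml = 0)
  prot <- makeProtocol(p, mode = "soluble", vegf_ng_ml = 0,
                       duration_s = 3600,
                       grid_s = seq(0, 3600, by = 300))
  tc <- simulateProtocol(prot, network = noPhosphoNet())
  live <- tc@network@species$compartment != "degr"
  x0 <- tc@states[1, live]
  expect_lt(max(abs(t(tc@states[, live]) - x0) / pmax(x0, 1)), 1e-7)
})

test_that("total VEGFR2 declines monotonically after soluble stimulation", {
  p <- applyStudyConfig(defaultParameters(), "other", vegf_ng_ml = 20)
  prot <- makeProtocol(p, mode = "soluble", vegf_ng_ml = 20,
                       duration_s = 1800, grid_s = seq(0, 1800, by = 60))
  tc <- simulateProtocol(prot, network = noPhosphoNet())
  tot <- totalR2Series(tc)
  expect_equal(tot@values[1], 100)
  expect_true(all(diff(tot@values) < 0))
})

test_that("VEGFR2 mass balance holds exactly and VEGF is conserved", {
  p <- applyStudyConfig(defaultParameters(), "other", vegf_ng_ml = 20)
  prot <- makeProtocol(p, mode = "immobilized", vegf_ng_ml = 20,
                       duration_s = 1800, grid_s = seq(0, 1800, by = 120))
  tc <- simulateProtocol(prot, network = fullNet())
  sp <- tc@network@species
  totR2 <- rowSums(tc@states[, sp$has_R2])
  pred <- totR2[1] + p@trafficking[["s.R2"]] * tc@times
  expect_lt(max(abs(totR2 - pred) / pred), 1e-6)
  totV <- rowSums(tc@states[, sp$has_V])
  expect_lt(max(abs(totV - totV[1])) / totV[1], 1e-9)
})

test_that("halving the solver tolerances leaves observables unchanged to 0.1%", {
  p <- applyStudyConfig(defaultParameters(), "other", vegf_ng_ml = 20)
  prot <- makeProtocol(p, mode = "soluble", vegf_ng_ml = 20,
                       duration_s = 900, grid_s = seq(0, 900, by = 60))
  a <- simulateProtocol(prot, network = noPhosphoNet())
  b <- simulateProtocol(prot, network = noPhosphoNet(),
                        rtol = 5e-9, atol = 5e-7)
  ligA <- ligatedR2Series(a)@values[-1]
  ligB <- ligatedR2Series(b)@values[-1]
  expect_lt(max(abs(ligA - ligB) / ligB), 1e-3)
})

test_that("states stay nonnegative within solver tolerance", {
  p <- applyStudyConfig(defaultParameters(), "other", vegf_ng_ml = 200)
  prot <- makeProtocol(p, mode = "immobilized", vegf_ng_ml = 200,
                       duration_s = 900, grid_s = seq(0, 900, by = 60))
  expect_silent(tc <- simulateProtocol(prot, network = fullNet()))
  expect_true(all(tc@states >= 0))
})

test_that("time courses export tidy data with unit-correct extracellular rows", {
  p <- applyStudyConfig(defaultParameters(), "other", vegf_ng_ml = 20)
  prot <- makeProtocol(p, mode = "soluble", vegf_ng_ml = 20,
                       duration_s = 60, grid_s = c(0, 30, 60))
  tc <- simulateProtocol(prot, network = minimalNet())
  df <- timeCourseToDataFrame(tc)
  expect_setequal(unique(df$unit[df$compartment == "ext"]), "M")
  v0 <- df$value[df$species == "ext:V" & df$time_s == 0]
  expect_equal(v0, vegfNgMlToMolar(20, p@geometry), tolerance = 1e-9)
})
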