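# A small fit problem shared across tests: both trafficking arms, short
# horizon, zero-noise observations generated from the table values.
estFixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$arms)) {
      env$arms <- traffickingArms(duration_s = 1800)
      env$truth <- c(krec4.R2 = 3.8e-3, krec11.N1 = 1.4e-2,
                     k4to11.N1 = 1.9e-2, kdegr.V.R2 = 3.6e-5,
                     kdegr.N1 = 1.6e-4, kdegr.V.N1.R2 = 6.8e-4)
      env$obs0 <- synthTraffickingObservations(env$arms, noiseCV = 0,
                                               seed = 1)
      env$problem <- traffickingFitProblem(env$obs0, arms = env$arms)
    }
    env
  }
})

test_that("tie expansion reproduces the held-equal trafficking structure", {
  fx <- estFixture()
  full <- expandTies(fx$truth, traffickingTies())
  tab <- defaultParameters()@trafficking
  # held-equal ties (ratio 1) must reproduce the table bitwise; scaled ties
  # agree to floating-point rounding of the printed values
  ties <- traffickingTies()
  for (i in seq_len(nrow(ties))) {
    nm <- ties$name[i]
    if (ties$ratio[i] == 1)
      expect_identical(unname(full[nm]), unname(tab[nm]), label = nm)
    else
      expect_equal(unname(full[nm]), unname(tab[nm]), tolerance = 1e-14,
                   label = nm)
  }
  for (nm in names(fx$truth))
    expect_identical(unname(full[nm]), unname(tab[nm]), label = nm)
})

test_that("zero-noise observations reproduce the model exactly", {
  fx <- estFixture()
  # fraction triplets sum to 100 per molecule and time point
  fr <- fx$obs0[grep("^frac", fx$obs0$observable), ]
  sums <- tapply(fr$value,
                 paste(fr$arm, fr$time_s, sub(".*\\.", "", fr$observable)),
                 sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # residuals at truth are zero apart from the steady-state penalty
  r <- costResiduals(fx$problem, fx$truth)
  n <- nrow(fx$obs0)
  expect_lt(max(abs(r[seq_len(n)])), 1e-4)
  # the penalty term carries the documented analytic value
  expect_equal(r[n + 1], 100 * (0.57790 - 0.60), tolerance = 1e-3)
})

test_that("fraction normalization survives noise", {
  arms <- estFixture()$arms
  obs <- synthTraffickingObservations(arms, noiseCV = 0.3, seed = 9)
  fr <- obs[grep("^frac", obs$observable), ]
  sums <- tapply(fr$value,
                 paste(fr$arm, fr$time_s, sub(".*\\.", "", fr$observable)),
                 sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("residuals scale linearly in the weights and ignore row order", {
  fx <- estFixture()
  start <- fx$truth * 2
  r1 <- costResiduals(fx$problem, start)
  p2 <- fx$problem
  p2@observations$weight <- 2 * p2@observations$weight
  r2 <- costResiduals(p2, start)
  n <- nrow(fx$obs0)
  expect_equal(r2[seq_len(n)], 2 * r1[seq_len(n)], tolerance = 1e-9)
  p3 <- fx$problem
  perm <- rev(seq_len(n))
  p3@observations <- p3@observations[perm, ]
  expect_equal(costValue(p3, start), costValue(fx$problem, start),
               tolerance = 1e-9)
})

test_that("an unsimulatable parameter set yields finite penalty residuals", {
  fx <- estFixture()
  bad <- fx$truth
  bad[] <- NA_real_
  r <- costResiduals(fx$problem, bad)
  expect_true(all(is.finite(r)))
  expect_true(all(r == 1e3))
})

test_that("multistart optimization is deterministic and anchored at truth", {
  fx <- estFixture()
  e1 <- multistartLM(fx$problem, nStarts = 2, seed = 31, maxiter = 3)
  e2 <- multistartLM(fx$problem, nStarts = 2, seed = 31, maxiter = 3)
  expect_identical(e1@starts, e2@starts)
  expect_identical(e1@estimates, e2@estimates)
  # the ensemble's best cost never exceeds a perturbed start's initial cost
  expect_lte(min(e1@starts$cost), costValue(fx$problem, fx$truth * 3))
})

test_that("a start at truth converges to a near-zero data cost", {
  fx <- estFixture()
  prob <- fx$problem
  prob@ssWeight <- 0  # isolate the data term
  fit <- minpack.lm::nls.lm(
    par = log10(fx$truth),
    lower = log10(prob@lower[prob@free]),
    upper = log10(prob@upper[prob@free]),
    fn = function(lt) costResiduals(prob, setNames(10^lt, prob@free)),
    control = minpack.lm::nls.lm.control(maxiter = 5))
  expect_lt(fit$deviance, 1e-6 * sum(fx$obs0$value^2))
})

test_that("the plausibility filter vetoes low-phospho parameter sets", {
  fx <- estFixture()
  ens <- multistartLM(fx$problem, nStarts = 2, seed = 5, maxiter = 2,
                      plausibility = function(v) FALSE)
  expect_false(any(ens@starts$accepted))
  ens2 <- multistartLM(fx$problem, nStarts = 2, seed = 5, maxiter = 2)
  expect_true(any(ens2@starts$accepted))
})

test_that("ensembles export a JSON summary and the accepted parameter cloud", {
  fx <- estFixture()
  ens <- multistartLM(fx$problem, nStarts = 2, seed = 5, maxiter = 2)
  d <- withr::local_tempdir()
  writeEnsemble(ens, d)
  j <- jsonlite::read_json(file.path(d, "ensemble.json"))
  expect_identical(j$nStarts, 2L)
  expect_named(j$best, fx$problem@free, ignore.order = TRUE)
  cloud <- read.csv(file.path(d, "accepted_parameters.csv"))
  expect_identical(nrow(cloud), sum(ens@starts$accepted))
})

test_that("peak phospho receptor counts per cell are computed from trajectories", {
  p <- otherParams()
  prot <- makeProtocol(p, mode = "soluble", vegf_ng_ml = 20,
                       duration_s = 300, grid_s = seq(0, 300, by = 60))
  tc <- simulateProtocol(prot, network = fullNet())
  n <- peakPhosphoPerCell(tc)
  expect_gt(n, 10)  # the representative set is far above the veto line
  expect_lt(n, 6000 + 1)
})
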