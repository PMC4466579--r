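# Fitting machinery: weighted least squares on normalized observables, tie
# constraints reproducing the "held equal" parameter structure, bounded
# multi-start Levenberg-Marquardt in log10-parameter space, acceptance bands,
# and the synthetic-observation generator that stands in for the original
# (unavailable) trafficking data.

# --- fitting observables ------------------------------------------------

# Internal-distribution fractions are normalized so Rab4/5 + Rab11 + degraded
# sum to 100% of the internal population of that receptor; surface and total
# time courses are percent of their own t=0 value.
.fitObservableSeries <- function(tc, name) {
  sp <- tc@network@species
  part <- strsplit(name, ".", fixed = TRUE)[[1]]
  mol <- part[length(part)]  # "R2" or "N1"
  carrier <- if (mol == "R2") sp$has_R2 else sp$has_N1
  sumOf <- function(mask)
    if (any(mask)) rowSums(tc@states[, mask, drop = FALSE])
    else numeric(length(tc@times))
  if (part[1] == "frac") {
    comp <- part[2]
    pools <- cbind(rab45 = sumOf(carrier & sp$compartment == "rab45"),
                   rab11 = sumOf(carrier & sp$compartment == "rab11"),
                   degr = sumOf(carrier & sp$compartment == "degr"))
    tot <- rowSums(pools)
    100 * pools[, comp] / ifelse(tot > 0, tot, NA_real_)
  } else if (part[1] == "surface") {
    v <- sumOf(carrier & sp$compartment == "surf")
    100 * v / v[1]
  } else if (part[1] == "total") {
    v <- sumOf(carrier & sp$compartment != "degr")
    100 * v / v[1]
  } else stop("unknown fitting observable: ", name)
}

.fitObservableAt <- function(tc, name, time_s)
  approx(tc@times, .fitObservableSeries(tc, name), time_s)$y

#' Fitting observable names
#'
#' \code{frac.rab45.R2} / \code{frac.rab11.R2} / \code{frac.degr.R2} (and
#' \code{.N1}): percent of the internal receptor population in Rab4/5,
#' Rab11, and the degraded pool, normalized to sum to 100 (the merged Rab4/5
#' pool plays the role of the larger of the Rab4- and Rab5-style
#' colocalization measures, which in a single-pool model is the pool itself);
#' \code{surface.N1}, \code{total.R2}, \code{total.N1}: percent of the
#' pre-stimulus value.
#' @export
fitObservableNames <- function()
  c(paste0("frac.", rep(c("rab45", "rab11", "degr"), 2), ".",
           rep(c("R2", "N1"), each = 3)),
    "surface.N1", "total.R2", "total.N1")

# --- tie constraints ----------------------------------------------------

#' Default trafficking tie structure
#'
#' Reproduces the held-equal rows of the trafficking table: Rab4-route
#' recycling equal for free and ligated VEGFR2 and 100-fold slower for the
#' NRP1 family; Rab11-route recycling equal within the NRP1 family and
#' 100-fold slower for VEGFR2; early-to-recycling transfer equal within the
#' NRP1 family; free-receptor degradation 10-fold slower than ligated.
#'
#' @return data.frame with columns name, source, ratio.
#' @export
traffickingTies <- function() {
  data.frame(
    name = c("krec4.V.R2", "krec4.N1", "krec4.V.N1", "krec4.V.N1.R2",
             "krec11.V.N1", "krec11.V.N1.R2", "krec11.R2", "krec11.V.R2",
             "k4to11.V.N1", "k4to11.V.N1.R2",
             "kdegr.R2", "kdegr.V.N1"),
    source = c("krec4.R2", "krec4.R2", "krec4.R2", "krec4.R2",
               "krec11.N1", "krec11.N1", "krec11.N1", "krec11.N1",
               "k4to11.N1", "k4to11.N1",
               "kdegr.V.R2", "kdegr.N1"),
    ratio = c(1, 0.01, 0.01, 0.01, 1, 1, 0.01, 0.01, 1, 1, 0.1, 1),
    stringsAsFactors = FALSE)
}

#' Expand free parameters through tie constraints
#' @param values named numeric of free parameters.
#' @param ties data.frame (name, source, ratio).
#' @return named numeric including the tied parameters.
#' @export
expandTies <- function(values, ties) {
  if (!nrow(ties)) return(values)
  tied <- setNames(values[ties$source] * ties$ratio, ties$name)
  c(values, tied)
}

# --- problem construction -----------------------------------------------

#' Default experimental arms of the trafficking fit
#'
#' Three soluble-VEGF arms mirroring the underlying colocalization
#' experiment: cells expressing both receptors, cells expressing VEGFR2
#' only (which makes the ligated-VEGFR2 degradation rate identifiable,
#' since with NRP1 present nearly all ligated receptor is NRP1-bound), and
#' cells expressing NRP1 only (which exposes NRP1's own degradation,
#' otherwise masked by the ternary-complex route). All use the reduced
#' no-phospho network and a 1-minute output grid (fitting only needs the
#' observation times).
#'
#' @param duration_s arm duration.
#' @return list of arms (protocol + network).
#' @export
traffickingArms <- function(duration_s = 3600) {
  network <- buildNetwork(includePhospho = FALSE)
  mk <- function(study) {
    prot <- makeScenario(study, mode = "soluble", duration_s = duration_s)
    prot@grid_s <- seq(0, duration_s, by = 60)
    prot
  }
  list(list(protocol = mk("trafficking_study"), network = network),
       list(protocol = mk("trafficking_study_r2only"), network = network),
       list(protocol = mk("trafficking_study_n1only"), network = network))
}

#' Construct the trafficking fit problem
#'
#' Free parameters are the six directly-fit trafficking rates (Rab4-route
#' recycling of VEGFR2, Rab11-route recycling and early-to-recycling
#' transfer of NRP1, and the degradation rates of ligated VEGFR2, NRP1, and
#' the ternary complex); the remaining trafficking rates follow by tie.
#' Bounds are [1e-5, 1] 1/s. A steady-state penalty keeps the no-VEGF
#' surface fraction of VEGFR2 near 60%. The trafficking observables are
#' independent of phosphorylation state, so the reduced no-phospho network
#' is used for speed (the marginalization property guarantees identical
#' trajectories).
#'
#' @param observations data.frame (observable, time_s, value, weight, arm).
#' @param arms list of arms (default \code{\link{traffickingArms}}).
#' @param ssWeight steady-state penalty weight (0 disables).
#' @return a \code{\linkS4class{FitProblem}}.
#' @export
traffickingFitProblem <- function(observations, arms = NULL,
                                  ssWeight = 100) {
  if (is.null(arms)) arms <- traffickingArms()
  if (is.null(observations$arm)) observations$arm <- 1L
  free <- c("krec4.R2", "krec11.N1", "k4to11.N1",
            "kdegr.V.R2", "kdegr.N1", "kdegr.V.N1.R2")
  new("FitProblem", free = free, ties = traffickingTies(),
      lower = setNames(rep(1e-5, length(free)), free),
      upper = setNames(rep(1, length(free)), free),
      observations = observations, arms = arms,
      ssTarget = 0.60, ssWeight = ssWeight)
}

# analytic no-VEGF surface fraction of VEGFR2 from trafficking rates
.surfaceFractionR2 <- function(trf) {
  den <- trf[["krec4.R2"]] + trf[["k4to11.R2"]] + trf[["kdegr.R2"]]
  e45 <- trf[["kint.R2"]] / den
  e11 <- trf[["k4to11.R2"]] * e45 / trf[["krec11.R2"]]
  1 / (1 + e45 + e11)
}

#' Weighted residual vector of a fit problem
#'
#' Installs the (tie-expanded) free parameter values, recomputes production
#' rates, simulates the problem's protocol, and returns weighted residuals
#' (observation minus model) with the steady-state surface-fraction penalty
#' appended. A failed simulation yields large finite penalty residuals
#' (1e3 per observation) rather than an exception, so the optimizer can
#' retreat.
#'
#' @param problem a \code{FitProblem}.
#' @param freeValues named numeric of the free parameters (natural scale).
#' @param rtol,atol solver tolerances used inside the cost evaluation;
#'   looser than the reporting defaults because the residuals are compared
#'   against percent-scale observations.
#' @return numeric residual vector of length nrow(observations) + 1.
#' @export
costResiduals <- function(problem, freeValues, rtol = 1e-6, atol = 1e-3) {
  obs <- problem@observations
  vals <- expandTies(freeValues[problem@free], problem@ties)
  res <- tryCatch({
    model <- rep(NA_real_, nrow(obs))
    ptr <- NULL
    for (a in seq_along(problem@arms)) {
      sel <- obs$arm == a
      if (!any(sel)) next
      arm <- problem@arms[[a]]
      p <- setParameters(arm$protocol@params, vals)
      p <- computeProductionRates(p)
      if (is.null(ptr)) ptr <- p@trafficking
      prot <- arm$protocol
      prot@params <- p
      tc <- simulateProtocol(prot, network = arm$network,
                             rtol = rtol, atol = atol)
      model[sel] <- vapply(which(sel), function(i)
        .fitObservableAt(tc, obs$observable[i], obs$time_s[i]), numeric(1))
    }
    r <- obs$weight * (obs$value - model)
    ssres <- if (problem@ssWeight > 0)
      problem@ssWeight * (.surfaceFractionR2(ptr) - problem@ssTarget)
    else 0
    c(r, ssres)
  }, error = function(e) rep(1e3, nrow(obs) + 1L))
  res[!is.finite(res)] <- 1e3
  res
}

#' Total cost (sum of squared residuals)
#' @inheritParams costResiduals
#' @export
costValue <- function(problem, freeValues)
  sum(costResiduals(problem, freeValues)^2)

# --- multistart Levenberg-Marquardt -------------------------------------

#' Multi-start bounded Levenberg-Marquardt fit
#'
#' Starts are drawn log-uniformly within \code{initRange}; each is optimized
#' with Levenberg-Marquardt in log10-parameter space under the problem's box
#' bounds. A converged set is accepted when its cost is within \code{band}
#' of the lowest cost found (relative) and the plausibility filter (if any)
#' passes. Fully deterministic for a given seed.
#'
#' @param problem a \code{FitProblem}.
#' @param nStarts number of starts (>= 1).
#' @param seed integer seed.
#' @param band relative acceptance band on the cost (0.15 for trafficking,
#'   0.65 for phosphorylation fits).
#' @param initRange c(low, high) of the log-uniform start distribution, 1/s.
#' @param plausibility optional function(freeValues) returning TRUE/FALSE;
#'   sets failing it are rejected regardless of cost (used to exclude fits
#'   predicting fewer than 10 phospho-receptors per cell at peak).
#' @param maxiter LM iteration cap per start.
#' @return a \code{\linkS4class{FitEnsemble}}.
#' @export
multistartLM <- function(problem, nStarts, seed, band = 0.15,
                         initRange = c(1e-4, 1e-2), plausibility = NULL,
                         maxiter = 25) {
  stopifnot(nStarts >= 1)
  set.seed(seed)
  nf <- length(problem@free)
  inits <- matrix(runif(nStarts * nf, log10(initRange[1]),
                        log10(initRange[2])),
                  nrow = nStarts, dimnames = list(NULL, problem@free))
  lo <- log10(problem@lower[problem@free])
  hi <- log10(problem@upper[problem@free])
  fits <- lapply(seq_len(nStarts), function(i) {
    # nls.lm warns when it stops on maxiter; the info code is recorded in
    # the ensemble, so the warning is redundant noise here
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = inits[i, ], lower = lo, upper = hi,
        fn = function(lt) costResiduals(problem, setNames(10^lt, problem@free)),
        # epsfcn keeps the forward-difference step (~sqrt(epsfcn) in log10
        # units) well above the integration error of a cost evaluation
        control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                             ftol = 1e-8, ptol = 1e-8,
                                             epsfcn = 1e-6))),
      error = function(e) NULL)
    if (is.null(fit))
      return(list(par = inits[i, ], cost = Inf, converged = FALSE,
                  info = -1L))
    list(par = unlist(fit$par), cost = fit$deviance,
         converged = fit$info %in% 1:4, info = fit$info)
  })
  costs <- vapply(fits, `[[`, numeric(1), "cost")
  est <- do.call(rbind, lapply(fits, function(f) 10^f$par))
  colnames(est) <- problem@free
  minCost <- min(costs)
  accepted <- costs <= (1 + band) * minCost
  if (!is.null(plausibility))
    accepted <- accepted & vapply(seq_len(nStarts), function(i)
      isTRUE(plausibility(setNames(est[i, ], problem@free))), logical(1))
  starts <- data.frame(
    start = seq_len(nStarts),
    cost = costs,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    info = vapply(fits, function(f) as.integer(f$info), integer(1)),
    accepted = accepted)
  starts <- cbind(starts,
                  setNames(as.data.frame(inits),
                           paste0("init.", problem@free)))
  best <- setNames(est[which.min(costs), ], problem@free)
  new("FitEnsemble", starts = starts, estimates = est, best = best,
      band = band, problem = problem)
}

#' Peak phospho-receptor count per cell
#'
#' The plausibility measure behind the ensemble filter: the maximum over the
#' trajectory of VEGFR2 molecules phosphorylated on at least one residue,
#' per cell.
#'
#' @param tc a \code{TimeCourse} from a full (phospho) network.
#' @export
peakPhosphoPerCell <- function(tc) {
  s <- pR2Series(tc)
  dens <- max(s@values) / 100 * tc@baselineR2  # #/cm2
  dens / tc@protocol@params@geometry[["cellDensity"]]
}

# --- synthetic observations ---------------------------------------------

#' Generate synthetic observations from known parameters
#'
#' Simulates the protocol under \code{params}, samples the trafficking
#' observable set (internal compartment-distribution fractions of VEGFR2 and
#' NRP1 at the colocalization time points, the surface-NRP1 and total
#' receptor time courses), applies multiplicative Gaussian noise with the
#' given coefficient of variation, and renormalizes each fraction triplet to
#' sum to 100% — exactly the normalization applied to the real
#' colocalization data.
#'
#' @param params true \code{ParameterSet}.
#' @param protocol stimulation protocol.
#' @param noiseCV coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param seed integer seed.
#' @param network network to simulate (default reduced no-phospho).
#' @param fracTimes times (s) of the compartment-distribution observations.
#' @param tcTimes times (s) of the time-course observations.
#' @param arm arm index recorded on the observations.
#' @return data.frame (observable, time_s, value, weight, arm).
#' @export
synthObservations <- function(params, protocol, noiseCV = 0.1, seed = 1,
                              network = NULL,
                              fracTimes = c(600, 1800, 3600),
                              tcTimes = c(300, 900, 1800, 3600),
                              arm = 1L) {
  stopifnot(noiseCV >= 0)
  if (is.null(network)) network <- buildNetwork(includePhospho = FALSE)
  fracTimes <- fracTimes[fracTimes <= protocol@duration_s]
  tcTimes <- tcTimes[tcTimes <= protocol@duration_s]
  prot <- protocol
  prot@params <- computeProductionRates(params)
  tc <- simulateProtocol(prot, network = network)
  set.seed(seed)
  noisy <- function(v) v * (1 + noiseCV * rnorm(length(v)))
  hasN1 <- !is.null(params@study$n1_per_cell) && params@study$n1_per_cell > 0
  hasR2 <- is.null(params@study$r2_per_cell) || params@study$r2_per_cell > 0
  mols <- c(if (hasR2) "R2", if (hasN1) "N1")
  tcNames <- c(if (hasR2) "total.R2",
               if (hasN1) c("surface.N1", "total.N1"))
  rows <- list()
  for (mol in mols) for (t in fracTimes) {
    v <- vapply(c("rab45", "rab11", "degr"), function(cc)
      .fitObservableAt(tc, paste0("frac.", cc, ".", mol), t), numeric(1))
    v <- pmax(noisy(v), 0)
    v <- 100 * v / sum(v)
    rows[[length(rows) + 1L]] <- data.frame(
      observable = paste0("frac.", c("rab45", "rab11", "degr"), ".", mol),
      time_s = t, value = v, weight = 1, arm = arm)
  }
  for (nm in tcNames) {
    v <- vapply(tcTimes, function(t) .fitObservableAt(tc, nm, t), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      observable = nm, time_s = tcTimes, value = pmax(noisy(v), 0),
      weight = 1, arm = arm)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-arm synthetic trafficking data set
#'
#' Applies \code{\link{synthObservations}} to each default trafficking arm
#' with truth values taken from the arm protocols themselves (optionally
#' overridden), giving the complete synthetic data set the recovery
#' experiment fits.
#'
#' @param arms arms list (default \code{\link{traffickingArms}}).
#' @param truth optional named numeric of trafficking rates installed as
#'   ground truth in every arm before simulating.
#' @param noiseCV,seed noise level and seed (seed offsets per arm).
#' @return data.frame of observations across the arms.
#' @export
synthTraffickingObservations <- function(arms = NULL, truth = NULL,
                                         noiseCV = 0.1, seed = 1) {
  if (is.null(arms)) arms <- traffickingArms()
  do.call(rbind, lapply(seq_along(arms), function(a) {
    p <- arms[[a]]$protocol@params
    if (!is.null(truth)) p <- setParameters(p, truth)
    synthObservations(p, arms[[a]]$protocol, noiseCV = noiseCV,
                      seed = seed * 1000L + a, network = arms[[a]]$network,
                      arm = a)
  }))
}

#' @export
setMethod("show", "FitEnsemble", function(object) {
  cat("FitEnsemble:", nrow(object@starts), "starts,",
      sum(object@starts$accepted), "accepted (band",
      object@band, ")\n")
  cat("  best cost:", signif(min(object@starts$cost), 5), "\n")
  print(signif(object@best, 4))
})
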