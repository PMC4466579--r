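# Readouts computed on trajectories: site-specific phospho pools, pR2,
# per-compartment splits, ligated-fraction-phosphorylated, AUCs, ratios,
# peaks. All normalized series are percent of the baseline (pre-stimulus)
# total VEGFR2 in the system, which maps to 100.

.residueCol <- c(Y951 = "p951", Y1175 = "p1175", Y1214 = "p1214")

.compFilter <- function(sp, compartments) {
  if (identical(compartments, "total"))
    sp$compartment %in% c("surf", "rab45", "rab11")
  else sp$compartment %in% compartments
}

.seriesFromMask <- function(tc, mask, name, filterTag) {
  vals <- if (any(mask)) rowSums(tc@states[, mask, drop = FALSE]) else
    numeric(length(tc@times))
  new("ObservableSeries", name = name, times = tc@times,
      values = 100 * vals / tc@baselineR2, filter = filterTag)
}

#' Site-specific phosphorylated VEGFR2 series
#'
#' Sums every VEGFR2-containing species (free and ligated) whose
#' phosphorylation state has the residue set, in the filtered compartments,
#' normalized to baseline total VEGFR2 (100%).
#'
#' @param tc a \code{TimeCourse}.
#' @param residue "Y951", "Y1175" or "Y1214".
#' @param compartments "total" or a subset of c("surf","rab45","rab11").
#' @return an \code{\linkS4class{ObservableSeries}}.
#' @export
phosphoSeries <- function(tc, residue, compartments = "total") {
  if (!residue %in% RESIDUES) stop("unknown residue: ", residue)
  sp <- tc@network@species
  mask <- sp$has_R2 & sp[[.residueCol[[residue]]]] == 1 &
    .compFilter(sp, compartments)
  .seriesFromMask(tc, mask, paste0("p", sub("^Y", "Y", residue)),
                  paste(compartments, collapse = "+"))
}

#' Total phosphorylated VEGFR2 (pR2) series
#'
#' VEGFR2 phosphorylated on at least one of Y951, Y1175, Y1214 (the union,
#' not the sum of the site-specific series).
#'
#' @inheritParams phosphoSeries
#' @export
pR2Series <- function(tc, compartments = "total") {
  sp <- tc@network@species
  mask <- sp$has_R2 & (sp$p951 | sp$p1175 | sp$p1214) &
    .compFilter(sp, compartments)
  .seriesFromMask(tc, mask, "pR2", paste(compartments, collapse = "+"))
}

#' Total VEGFR2 series (excluding degraded pools)
#' @inheritParams phosphoSeries
#' @export
totalR2Series <- function(tc, compartments = "total") {
  sp <- tc@network@species
  mask <- sp$has_R2 & .compFilter(sp, compartments)
  .seriesFromMask(tc, mask, "totalR2", paste(compartments, collapse = "+"))
}

#' Ligated VEGFR2 series
#'
#' VEGF-bound VEGFR2 (V.R2, M.V.R2 or V.N1.R2) regardless of phospho-state.
#' @inheritParams phosphoSeries
#' @export
ligatedR2Series <- function(tc, compartments = "total") {
  sp <- tc@network@species
  mask <- sp$has_R2 & sp$has_V & .compFilter(sp, compartments)
  .seriesFromMask(tc, mask, "ligatedR2", paste(compartments, collapse = "+"))
}

#' Degraded VEGFR2 series
#' @param tc a \code{TimeCourse}.
#' @export
degradedR2Series <- function(tc) {
  sp <- tc@network@species
  .seriesFromMask(tc, sp$has_R2 & sp$compartment == "degr",
                  "degradedR2", "degr")
}

#' Fraction of ligated VEGFR2 phosphorylated on at least one residue
#'
#' At time \code{t}: (ligated VEGFR2 species with >= 1 residue set) /
#' (all ligated VEGFR2), across surface + Rab4/5 + Rab11.
#'
#' @param tc a \code{TimeCourse}.
#' @param t time in seconds (interpolated on the trajectory grid).
#' @param floor ligated pools below this many molecules/cm2 yield NA.
#' @return fraction in [0, 1], or NA when the ligated pool is below floor.
#' @export
ligatedFractionPhosphorylated <- function(tc, t, floor = 1e-6) {
  sp <- tc@network@species
  live <- .compFilter(sp, "total")
  lig <- sp$has_R2 & sp$has_V & live
  ligP <- lig & (sp$p951 | sp$p1175 | sp$p1214)
  num <- approx(tc@times, rowSums(tc@states[, ligP, drop = FALSE]), t)$y
  den <- approx(tc@times, rowSums(tc@states[, lig, drop = FALSE]), t)$y
  ifelse(den < floor, NA_real_, num / den)
}

.resample <- function(series, window, dt = 1) {
  tt <- seq(window[1], window[2], by = dt)
  list(times = tt, values = approx(series@times, series@values, tt)$y)
}

#' Area under an observable curve
#'
#' Trapezoidal integral over the window on a 1 s resampled grid, in
#' percent-minutes (the total-activation measure for the first hour).
#'
#' @param series an \code{ObservableSeries}.
#' @param window c(start, end) in seconds, within the series range.
#' @export
aucSeries <- function(series, window = c(0, 3600)) {
  stopifnot(window[1] >= min(series@times), window[2] <= max(series@times))
  r <- .resample(series, window)
  v <- r$values
  sum((v[-1] + v[-length(v)]) / 2 * diff(r$times)) / 60
}

#' Pointwise ratio of two observable series
#'
#' Resamples both onto the shared 1 s grid; denominators below the floor
#' (1e-3 percent of baseline by default) yield NA rather than a blow-up.
#'
#' @param a,b \code{ObservableSeries} on overlapping time ranges.
#' @param floor denominator floor (same units as \code{b}).
#' @export
ratioSeries <- function(a, b, floor = 1e-3) {
  window <- c(max(min(a@times), min(b@times)), min(max(a@times), max(b@times)))
  ra <- .resample(a, window)
  rb <- .resample(b, window)
  vals <- ifelse(rb$values < floor, NA_real_, ra$values / rb$values)
  new("ObservableSeries", name = paste0(a@name, "/", b@name),
      times = ra$times, values = vals, filter = a@filter)
}

#' Peak of an observable series
#'
#' Maximum over a 1 s resampled grid within the window (default the first
#' 60 minutes).
#'
#' @param series an \code{ObservableSeries}.
#' @param window c(start, end) seconds.
#' @return named numeric c(t_peak, value).
#' @export
peakSeries <- function(series, window = c(0, 3600)) {
  window[2] <- min(window[2], max(series@times))
  r <- .resample(series, window)
  ok <- !is.na(r$values)
  i <- which.max(r$values[ok])
  c(t_peak = r$times[ok][i], value = r$values[ok][i])
}

#' Value of a series at a time point
#' @param series an \code{ObservableSeries}.
#' @param t seconds.
#' @export
seriesAt <- function(series, t) approx(series@times, series@values, t)$y

#' @export
setMethod("show", "ObservableSeries", function(object) {
  cat("ObservableSeries", object@name, "[", object@filter, "]:",
      length(object@times), "points,",
      "range", signif(min(object@values, na.rm = TRUE), 4), "-",
      signif(max(object@values, na.rm = TRUE), 4), "\n")
})
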