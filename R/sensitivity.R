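# Local one-at-a-time sensitivity analysis: each parameter is doubled and
# halved, the absolute percent change of each panel output is computed
# against the unperturbed run, and the two directions are averaged.

#' Default sensitivity output panel
#'
#' pY1175, pY1214, and the pY1214/pY1175 ratio at 5, 15, and 30 minutes, for
#' soluble and immobilized VEGF at 2 and 200 ng/mL.
#'
#' @param modes presentation modes.
#' @param concs VEGF doses (ng/mL).
#' @param times_min readout times (minutes).
#' @return data.frame of panel conditions.
#' @export
sensitivityPanel <- function(modes = c("soluble", "immobilized"),
                             concs = c(2, 200),
                             times_min = c(5, 15, 30)) {
  expand.grid(output = c("pY1175", "pY1214", "ratio1214.1175"),
              time_min = times_min, mode = modes, vegf = concs,
              stringsAsFactors = FALSE)
}

.panelOutputs <- function(tc, panel, floor = 1e-3) {
  y1175 <- phosphoSeries(tc, "Y1175")
  y1214 <- phosphoSeries(tc, "Y1214")
  vapply(seq_len(nrow(panel)), function(i) {
    t <- panel$time_min[i] * 60
    a <- seriesAt(y1214, t)
    b <- seriesAt(y1175, t)
    switch(panel$output[i],
      pY1175 = b, pY1214 = a,
      ratio1214.1175 = if (is.na(b) || b < floor) NA_real_ else a / b)
  }, numeric(1))
}

# tied parameter families perturbed as a unit (the published held-equal
# structure is preserved under perturbation)
.tieGroups <- function() {
  ties <- traffickingTies()
  split(ties$name, ties$source)
}

#' Local sensitivity analysis
#'
#' For each parameter (tied families move as a unit): simulate with the
#' parameter multiplied and divided by \code{factor}, compute the absolute
#' percent change of every panel output relative to the unperturbed run at
#' the same time point, and average the two directions. Outputs whose
#' unperturbed value lies below the ratio floor are excluded from averages
#' and counted.
#'
#' @param params specialized \code{ParameterSet} (study applied).
#' @param parameters character vector of parameter names to perturb.
#' @param panel data.frame from \code{\link{sensitivityPanel}}.
#' @param factor fold-change (default 2).
#' @param network optional \code{ReactionNetwork}.
#' @param duration_s simulation span (covers the latest panel time).
#' @return a \code{\linkS4class{SensitivityResult}}.
#' @export
localSensitivity <- function(params, parameters, panel = sensitivityPanel(),
                             factor = 2, network = NULL, duration_s = NULL) {
  if (is.null(network)) network <- .defaultNetwork()
  if (is.null(duration_s)) duration_s <- max(panel$time_min) * 60
  conds <- unique(panel[, c("mode", "vegf")])
  groups <- .tieGroups()
  runCond <- function(p, mode, vegf) {
    prot <- makeProtocol(p, mode = mode, vegf_ng_ml = vegf,
                         duration_s = duration_s)
    simulateProtocol(prot, network = network)
  }
  baseVals <- rep(NA_real_, nrow(panel))
  for (j in seq_len(nrow(conds))) {
    sel <- panel$mode == conds$mode[j] & panel$vegf == conds$vegf[j]
    tc <- runCond(params, conds$mode[j], conds$vegf[j])
    baseVals[sel] <- .panelOutputs(tc, panel[sel, , drop = FALSE])
  }
  flat <- flattenParameters(params)
  perturbOne <- function(nm, f) {
    keys <- c(nm, groups[[nm]])
    keys <- intersect(keys, names(flat))
    upd <- setNames(flat[keys] * f, keys)
    p <- setParameters(params, upd)
    computeProductionRates(p)
  }
  mat <- matrix(NA_real_, nrow = length(parameters), ncol = nrow(panel),
                dimnames = list(parameters, NULL))
  excluded <- 0L
  for (nm in parameters) {
    changes <- matrix(NA_real_, 2, nrow(panel))
    for (d in 1:2) {
      f <- if (d == 1) factor else 1 / factor
      p <- tryCatch(perturbOne(nm, f), error = function(e) NULL)
      if (is.null(p)) next
      for (j in seq_len(nrow(conds))) {
        sel <- panel$mode == conds$mode[j] & panel$vegf == conds$vegf[j]
        tc <- tryCatch(runCond(p, conds$mode[j], conds$vegf[j]),
                       error = function(e) NULL)
        if (is.null(tc)) next
        vals <- .panelOutputs(tc, panel[sel, , drop = FALSE])
        base <- baseVals[sel]
        ok <- !is.na(base) & abs(base) > 1e-3
        excluded <- excluded + sum(!ok)
        pc <- rep(NA_real_, length(vals))
        pc[ok] <- abs(100 * (vals[ok] - base[ok]) / base[ok])
        changes[d, sel] <- pc
      }
    }
    mat[nm, ] <- colMeans(changes, na.rm = TRUE)
  }
  mat[is.nan(mat)] <- NA_real_
  new("SensitivityResult", matrix = mat, panel = panel,
      excluded = as.integer(excluded))
}

#' Aggregate a sensitivity result over the panel
#'
#' @param result a \code{SensitivityResult}.
#' @param subset optional logical/integer index into the panel rows.
#' @return named numeric: mean |percent change| per parameter.
#' @export
sensitivitySummary <- function(result, subset = NULL) {
  m <- result@matrix
  if (!is.null(subset)) m <- m[, subset, drop = FALSE]
  rowMeans(m, na.rm = TRUE)
}

#' Heatmap-ready data.frame (parameter x condition)
#' @param result a \code{SensitivityResult}.
#' @export
sensitivityToDataFrame <- function(result) {
  p <- result@panel
  cond <- paste0(p$output, "@", p$time_min, "min:", p$mode, ":", p$vegf,
                 "ng/mL")
  out <- as.data.frame(result@matrix)
  names(out) <- cond
  cbind(parameter = rownames(result@matrix), out, row.names = NULL)
}

#' @export
setMethod("show", "SensitivityResult", function(object) {
  cat("SensitivityResult:", nrow(object@matrix), "parameters x",
      ncol(object@matrix), "panel outputs;", object@excluded,
      "outputs excluded (below floor)\n")
})
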