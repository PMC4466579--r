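# Declarative scenario and perturbation constructors: every simulation
# condition used in the study is reproducible from a name plus options.

#' Construct a named scenario protocol
#'
#' Builds the protocol for one study column: initial receptor densities,
#' geometry, degradation scale, internalization rule, and V-matrix kinetics.
#'
#' @param name one of \code{\link{studyNames}} ("trafficking_study",
#'   "trafficking_study_r2only", "presentation_2011", "presentation_2010",
#'   "other").
#' @param mode "soluble" or "immobilized".
#' @param vegf_ng_ml dose override (the "other" study varies its dose;
#'   defaults to each study's column value).
#' @param duration_s simulated span.
#' @param perturbations list of perturbation descriptors.
#' @param base optional base \code{ParameterSet} (geometry overrides).
#' @return a \code{\linkS4class{Protocol}}.
#' @export
makeScenario <- function(name, mode = c("soluble", "immobilized"),
                         vegf_ng_ml = NULL, duration_s = 3600,
                         perturbations = list(), base = NULL) {
  mode <- match.arg(mode)
  if (is.null(base)) base <- defaultParameters()
  params <- applyStudyConfig(base, name, vegf_ng_ml = vegf_ng_ml)
  makeProtocol(params, mode = mode,
               vegf_ng_ml = params@study$vegf_ng_ml,
               duration_s = duration_s, perturbations = perturbations,
               label = paste0(name, ":", mode))
}

.ligatedForms <- c("V.R2", "M.V.R2", "V.N1.R2")

.kdpKeys <- function(residues, forms, comps) {
  as.vector(outer(residues, as.vector(outer(forms, comps, paste, sep = ".")),
                  function(r, fc) paste0("kdp.", r, ".", fc)))
}

#' Apply a perturbation to a parameter set
#'
#' Pure function; composable (apply in order). Kinds:
#' \describe{
#'   \item{nrp1_knockout}{NRP1 density and production set to zero (all NRP1
#'     reactions become inert).}
#'   \item{v165b_ligand}{the ligand cannot bind NRP1: every V-NRP1 coupling
#'     on-rate set to zero.}
#'   \item{veptp_sirna}{surface dephosphorylation of Y951 and Y1175 on
#'     ligated receptor divided by \code{magnitude} (default 5), mimicking
#'     phosphatase knockdown.}
#'   \item{tcptp_active}{dephosphorylation of Y951 and Y1214 raised to the
#'     unligated-receptor rate (30/s) in all compartments.}
#'   \item{surface_phosphatase_overexpression}{surface dephosphorylation of
#'     all three residues on ligated receptor multiplied by
#'     \code{magnitude}.}
#'   \item{rab11_kdp_equals_rab45}{Rab11 ligated dephosphorylation rates set
#'     equal to the Rab4/5 values.}
#'   \item{koff_vm}{V-matrix off-rate set to \code{magnitude} (on-rate kept,
#'     so K_D co-varies).}
#' }
#' Phosphatase perturbations act on ligated-form rates only (the unligated
#' forms already sit at the 30/s ceiling).
#'
#' @param params a \code{ParameterSet}.
#' @param kind perturbation kind (see above).
#' @param magnitude scalar where applicable.
#' @return modified \code{ParameterSet}.
#' @export
applyPerturbation <- function(params, kind, magnitude = NULL) {
  p <- params
  switch(kind,
    nrp1_knockout = {
      p@study$n1_per_cell <- 0
      p <- computeProductionRates(p)
    },
    v165b_ligand = {
      keys <- c("kon.V.N1.surf", "kon.V.N1.int",
                "kon.N1.VR2.surf", "kon.N1.VR2.int",
                "kon.VN1.R2.surf", "kon.VN1.R2.int")
      p@kinetic[keys] <- 0
      # NRP1 pools persist but never couple to VEGF or VEGFR2
      p@study$n1_inert <- TRUE
    },
    veptp_sirna = {
      f <- if (is.null(magnitude)) 5 else magnitude
      keys <- .kdpKeys(c("Y951", "Y1175"), .ligatedForms, "surf")
      keys <- intersect(keys, names(p@phospho))
      p@phospho[keys] <- p@phospho[keys] / f
    },
    tcptp_active = {
      keys <- .kdpKeys(c("Y951", "Y1214"), .ligatedForms,
                       c("surf", "rab45", "rab11"))
      keys <- intersect(keys, names(p@phospho))
      p@phospho[keys] <- 30
    },
    surface_phosphatase_overexpression = {
      if (is.null(magnitude)) stop("magnitude required")
      keys <- .kdpKeys(RESIDUES, .ligatedForms, "surf")
      keys <- intersect(keys, names(p@phospho))
      p@phospho[keys] <- p@phospho[keys] * magnitude
    },
    rab11_kdp_equals_rab45 = {
      for (f in c("V.R2", "V.N1.R2")) for (r in RESIDUES) {
        src <- paste0("kdp.", r, ".", f, ".rab45")
        dst <- paste0("kdp.", r, ".", f, ".rab11")
        p@phospho[[dst]] <- p@phospho[[src]]
      }
    },
    koff_vm = {
      if (is.null(magnitude)) stop("magnitude required")
      p@kinetic[["koff.V.M"]] <- magnitude
      p@kinetic[["koff.M.VR2.surf"]] <- magnitude
    },
    stop("unknown perturbation kind: ", kind))
  p
}

#' Immobilized-VEGF protocols sweeping the matrix off-rate
#'
#' Identical protocols differing only in k_off,V.M (K_D co-varies at fixed
#' k_on).
#'
#' @param values off-rates in 1/s (all > 0).
#' @param name study name (default "other").
#' @param vegf_ng_ml dose.
#' @param duration_s span.
#' @return list of \code{Protocol}s.
#' @export
koffVmSweep <- function(values, name = "other", vegf_ng_ml = 20,
                        duration_s = 3600) {
  stopifnot(all(values > 0))
  lapply(values, function(v)
    makeScenario(name, mode = "immobilized", vegf_ng_ml = vegf_ng_ml,
                 duration_s = duration_s,
                 perturbations = list(list(kind = "koff_vm", magnitude = v))))
}

# Registry of figure-style scenario bundles (values, not images).
.figureRegistry <- function() {
  concs <- c(2, 20, 200)
  list(
    fig2 = list(desc = "VEGFR2 distribution after stimulation",
                runs = lapply(concs, function(v)
                  list(name = "other", mode = "soluble", vegf = v)),
                outputs = c("totalR2", "ligatedR2")),
    fig4ef = list(desc = "phosphatase perturbation validation",
                  runs = list(
                    list(name = "other", mode = "soluble", vegf = 50,
                         perturbations = list(list(kind = "veptp_sirna"))),
                    list(name = "other", mode = "soluble", vegf = 50,
                         perturbations = list(list(kind = "tcptp_active")))),
                  outputs = c("pY951", "pY1175", "pY1214", "pR2")),
    fig5 = list(desc = "soluble vs immobilized response panel",
                runs = do.call(c, lapply(c("soluble", "immobilized"),
                  function(m) lapply(concs, function(v)
                    list(name = "other", mode = m, vegf = v)))),
                outputs = c("ligatedR2", "pR2", "pY1175", "pY1214")),
    fig6 = list(desc = "AUC decomposition at 2 ng/mL",
                runs = lapply(c("soluble", "immobilized"), function(m)
                  list(name = "other", mode = m, vegf = 2)),
                outputs = c("pR2", "pY1175", "pY1214")),
    fig7 = list(desc = "NRP1 knockout comparison",
                runs = do.call(c, lapply(c("soluble", "immobilized"),
                  function(m) list(
                    list(name = "other", mode = m, vegf = 20),
                    list(name = "other", mode = m, vegf = 20,
                         perturbations = list(list(kind = "nrp1_knockout")))))),
                outputs = c("ligatedR2", "pR2", "pY1175", "pY1214",
                            "totalR2")),
    fig8 = list(desc = "matrix off-rate sweep",
                runs = lapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(k)
                  list(name = "other", mode = "immobilized", vegf = 20,
                       perturbations = list(list(kind = "koff_vm",
                                                 magnitude = k)))),
                outputs = c("pR2", "pY1175", "pY1214")),
    s4 = list(desc = "uniform endosomal dephosphorylation",
              runs = lapply(c("soluble", "immobilized"), function(m)
                list(name = "other", mode = m, vegf = 20,
                     perturbations = list(
                       list(kind = "rab11_kdp_equals_rab45")))),
              outputs = c("pR2", "pY1175", "pY1214")),
    s5 = list(desc = "ligated-fraction-phosphorylated decomposition",
              runs = list(list(name = "other", mode = "immobilized",
                               vegf = 20)),
              outputs = c("ligatedFraction")))
}

#' Figure scenario ids
#' @export
figureIds <- function() names(.figureRegistry())

#' Run a registered figure scenario
#'
#' Executes the registered protocol set for a figure panel and returns the
#' observable values replicating the panel structure (series and summary
#' numbers, not images).
#'
#' @param id a figure id from \code{\link{figureIds}}.
#' @param duration_s simulated span per run.
#' @param network optional network (defaults to the full network).
#' @return list with elements \code{runs} (per-run observable series) and
#'   \code{summary} (peaks/AUCs data.frame).
#' @export
runFigureScenario <- function(id, duration_s = 1800, network = NULL) {
  reg <- .figureRegistry()
  if (!id %in% names(reg)) stop("unknown figure id: ", id)
  fig <- reg[[id]]
  runs <- lapply(fig$runs, function(r) {
    prot <- makeScenario(r$name, mode = r$mode, vegf_ng_ml = r$vegf,
                         duration_s = duration_s,
                         perturbations = if (is.null(r$perturbations))
                           list() else r$perturbations)
    tc <- simulateProtocol(prot, network = network)
    series <- list()
    for (out in fig$outputs) {
      series[[out]] <- switch(out,
        pR2 = pR2Series(tc),
        pY951 = phosphoSeries(tc, "Y951"),
        pY1175 = phosphoSeries(tc, "Y1175"),
        pY1214 = phosphoSeries(tc, "Y1214"),
        totalR2 = totalR2Series(tc),
        ligatedR2 = ligatedR2Series(tc),
        ligatedFraction = data.frame(
          time_min = c(5, 30),
          fraction = ligatedFractionPhosphorylated(tc, c(300, 1800))))
    }
    list(run = r, series = series)
  })
  summ <- do.call(rbind, lapply(seq_along(runs), function(i) {
    s <- runs[[i]]$series
    do.call(rbind, lapply(names(s), function(nm) {
      if (!methods::is(s[[nm]], "ObservableSeries")) return(NULL)
      pk <- peakSeries(s[[nm]], c(0, duration_s))
      data.frame(run = i, observable = nm, peak_t_s = pk[["t_peak"]],
                 peak = pk[["value"]],
                 auc = aucSeries(s[[nm]], c(0, min(3600, duration_s))))
    }))
  }))
  list(id = id, description = fig$desc, runs = runs, summary = summ)
}
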