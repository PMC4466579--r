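#' @import methods
#' @importFrom stats approx rnorm runif setNames
#' @importFrom utils head modifyList write.csv read.csv
NULL

# Compartment codes used throughout. "ext" holds bulk-phase species (media and
# matrix), "surf" the plasma membrane, "rab45" merged Rab4/Rab5 early
# endosomes, "rab11" recycling endosomes, "degr" the degraded pool
# (late/Rab7 endosomes and lysosomes, retained for mass balance).
COMPARTMENTS <- c("ext", "surf", "rab45", "rab11", "degr")

RESIDUES <- c("Y951", "Y1175", "Y1214")

#' Reaction network for the VEGF-VEGFR2-NRP1 trafficking model
#'
#' Holds the programmatically enumerated molecular species and mass-action
#' reactions. Species are rows of a data.frame with composition flags
#' (\code{has_V}, \code{has_M}, \code{has_R2}, \code{has_N1}), a compartment
#' code, and a three-bit phosphorylation state (\code{p951}, \code{p1175},
#' \code{p1214}). Reactions reference species by index and a named rate
#' parameter; bimolecular rates carry a unit tag resolved at assembly time.
#'
#' @slot species data.frame of species (one row per state variable).
#' @slot reactions data.frame of unidirectional reactions.
#' @slot index named integer vector mapping species name to row.
#' @export
setClass("ReactionNetwork",
  representation(species = "data.frame",
                 reactions = "data.frame",
                 index = "integer"))

setValidity("ReactionNetwork", function(object) {
  msgs <- character(0)
  sp <- object@species
  rx <- object@reactions
  if (anyDuplicated(sp$name)) msgs <- c(msgs, "duplicate species names")
  if (!all(sp$compartment %in% COMPARTMENTS))
    msgs <- c(msgs, "unknown compartment code")
  bad <- sp$has_M & sp$has_N1
  if (any(bad))
    msgs <- c(msgs, "matrix site and NRP1 present in the same complex")
  idx <- c(rx$r1, rx$r2, rx$p1, rx$p2)
  idx <- idx[!is.na(idx)]
  if (length(idx) && (min(idx) < 1L || max(idx) > nrow(sp)))
    msgs <- c(msgs, "reaction references a species outside the list")
  if (length(msgs)) msgs else TRUE
})

#' Complete parameter set for the model
#'
#' Kinetic (binding) constants, trafficking rates, phosphorylation and
#' dephosphorylation rates, geometry, and the study-specific configuration.
#' All rate slots are flat named numeric vectors; see
#' \code{\link{defaultParameters}} for the naming scheme.
#'
#' @slot kinetic named numeric; on/off rate constants per binding pair and
#'   compartment class (fluid-phase in 1/M/s, membrane-coupling in
#'   1/(mol/cm2)/s, off rates in 1/s).
#' @slot trafficking named numeric; first-order trafficking rates (1/s) and
#'   the calculated production rates \code{s.R2}, \code{s.N1} (#/cm2/s).
#' @slot phospho named numeric; site-specific phosphorylation and
#'   dephosphorylation rates (1/s).
#' @slot geometry named numeric; surface area (cm2), bulk fluid depth (cm),
#'   endosomal volume per unit surface area (cm3/cm2), cell density
#'   (cells/cm2), and molecular weights (g/mol).
#' @slot study list describing the study configuration this set has been
#'   specialized to (empty for the representative base set).
#' @export
setClass("ParameterSet",
  representation(kinetic = "numeric", trafficking = "numeric",
                 phospho = "numeric", geometry = "numeric",
                 study = "list"))

setValidity("ParameterSet", function(object) {
  msgs <- character(0)
  if (any(object@trafficking < 0)) msgs <- c(msgs, "negative trafficking rate")
  if (any(object@phospho < 0)) msgs <- c(msgs, "negative phospho rate")
  geo <- object@geometry
  need <- c("area.cm2", "depth.cm", "endoVol.rab45", "endoVol.rab11",
            "cellDensity", "mw.V", "mw.Msite")
  if (!all(need %in% names(geo))) {
    msgs <- c(msgs, "incomplete geometry")
  } else if (any(geo[need] <= 0)) {
    msgs <- c(msgs, "geometry values must be strictly positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Stimulation protocol
#'
#' A fully specified simulation: parameter set (already specialized to a
#' study), VEGF presentation mode and dose, duration and output grid, and an
#' ordered list of perturbations applied to the parameters before assembly.
#'
#' @slot params a \code{ParameterSet}.
#' @slot mode "soluble" or "immobilized".
#' @slot vegf_ng_ml VEGF dose in ng/mL.
#' @slot duration_s simulated time span in seconds.
#' @slot grid_s output time grid in seconds.
#' @slot perturbations list of perturbation descriptors (see
#'   \code{\link{applyPerturbation}}).
#' @slot label human-readable protocol name.
#' @export
setClass("Protocol",
  representation(params = "ParameterSet", mode = "character",
                 vegf_ng_ml = "numeric", duration_s = "numeric",
                 grid_s = "numeric", perturbations = "list",
                 label = "character"))

setValidity("Protocol", function(object) {
  msgs <- character(0)
  if (!object@mode %in% c("soluble", "immobilized"))
    msgs <- c(msgs, "mode must be 'soluble' or 'immobilized'")
  if (object@vegf_ng_ml < 0) msgs <- c(msgs, "VEGF dose must be >= 0")
  if (object@duration_s <= 0) msgs <- c(msgs, "duration must be positive")
  g <- object@grid_s
  if (length(g) < 2 || any(diff(g) <= 0) || min(g) < 0 ||
      max(g) > object@duration_s)
    msgs <- c(msgs, "output grid must be increasing within [0, duration]")
  if (length(msgs)) msgs else TRUE
})

#' Simulated time course
#'
#' Trajectory of all species on the protocol's output grid. States are stored
#' in molecules per cm2 of total cell surface for every species (extracellular
#' bulk species are converted to this basis via Avogadro's number and the
#' fluid depth, which makes total mass balance exact); use
#' \code{\link{statesMolar}} for extracellular rows in molar.
#'
#' @slot times numeric vector of seconds.
#' @slot states matrix (time x species) in #/cm2.
#' @slot network the \code{ReactionNetwork} simulated.
#' @slot protocol the \code{Protocol} that produced it.
#' @slot baselineR2 baseline (pre-stimulus) total VEGFR2 in #/cm2, the 100%
#'   reference of all normalized observables.
#' @slot solver list of solver metadata (method, tolerances, step counts).
#' @export
setClass("TimeCourse",
  representation(times = "numeric", states = "matrix",
                 network = "ReactionNetwork", protocol = "Protocol",
                 baselineR2 = "numeric", solver = "list"))

setValidity("TimeCourse", function(object) {
  msgs <- character(0)
  if (any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (nrow(object@states) != length(object@times))
    msgs <- c(msgs, "states/time dimension mismatch")
  if (ncol(object@states) != nrow(object@network@species))
    msgs <- c(msgs, "states/species dimension mismatch")
  if (length(msgs)) msgs else TRUE
})

#' A named, normalized observable time series
#'
#' @slot name observable name.
#' @slot times seconds.
#' @slot values percent of baseline total VEGFR2 (or dimensionless for
#'   ratios); may contain NA where a ratio denominator fell below the floor.
#' @slot filter compartment filter tag ("total", "surf", "rab45", "rab11").
#' @export
setClass("ObservableSeries",
  representation(name = "character", times = "numeric", values = "numeric",
                 filter = "character"))

#' Parameter-estimation problem
#'
#' Free parameters (optimized in log10 space), multiplicative tie constraints
#' reproducing the "held equal" structure of the trafficking table, box
#' bounds, weighted observations, and a steady-state penalty keeping the
#' no-VEGF surface fraction of VEGFR2 near its target.
#'
#' @slot free character vector of free parameter names.
#' @slot ties data.frame with columns \code{name}, \code{source},
#'   \code{ratio}: after each update, \code{name <- ratio * source}.
#' @slot lower,upper named numeric bounds on the free parameters (1/s).
#' @slot observations data.frame: \code{observable}, \code{time_s},
#'   \code{value}, \code{weight}, \code{arm} (index into \code{arms}).
#' @slot arms list of experimental arms, each a list with elements
#'   \code{protocol} and \code{network} (reduced networks are legitimate
#'   when the observables are phospho-independent).
#' @slot ssTarget,ssWeight steady-state surface-fraction penalty (fraction in
#'   [0,1] and its weight; weight 0 disables the term).
#' @export
setClass("FitProblem",
  representation(free = "character", ties = "data.frame",
                 lower = "numeric", upper = "numeric",
                 observations = "data.frame", arms = "list",
                 ssTarget = "numeric", ssWeight = "numeric"))

setValidity("FitProblem", function(object) {
  msgs <- character(0)
  if (!all(object@free %in% names(object@lower)) ||
      !all(object@free %in% names(object@upper)))
    msgs <- c(msgs, "every free parameter needs lower and upper bounds")
  if (nrow(object@ties) &&
      !all(object@ties$source %in% object@free))
    msgs <- c(msgs, "tie sources must be free parameters")
  obs <- object@observations
  need <- c("observable", "time_s", "value", "weight", "arm")
  if (!all(need %in% names(obs)))
    msgs <- c(msgs, "observations need observable/time_s/value/weight/arm")
  else {
    if (any(obs$weight < 0)) msgs <- c(msgs, "negative observation weight")
    if (any(!obs$arm %in% seq_along(object@arms)))
      msgs <- c(msgs, "observation arm index out of range")
  }
  if (!length(object@arms) ||
      !all(vapply(object@arms, function(a)
        all(c("protocol", "network") %in% names(a)), logical(1))))
    msgs <- c(msgs, "arms must each carry a protocol and a network")
  if (length(msgs)) msgs else TRUE
})

#' Multi-start fit ensemble
#'
#' @slot starts data.frame with one row per start: initial and converged
#'   values (log10), cost, convergence flag, acceptance flag.
#' @slot estimates matrix of converged parameter values (natural scale), one
#'   row per start.
#' @slot best named numeric, the lowest-cost parameter vector.
#' @slot band relative acceptance band on the cost.
#' @slot problem the \code{FitProblem}.
#' @export
setClass("FitEnsemble",
  representation(starts = "data.frame", estimates = "matrix",
                 best = "numeric", band = "numeric", problem = "FitProblem"))

#' Local sensitivity result
#'
#' @slot matrix numeric matrix (parameter x output-condition) of mean
#'   absolute percent changes, averaged over the twofold up and down
#'   perturbations.
#' @slot panel data.frame describing the output panel columns.
#' @slot excluded integer count of panel entries excluded because the
#'   unperturbed output was below the ratio floor.
#' @export
setClass("SensitivityResult",
  representation(matrix = "matrix", panel = "data.frame",
                 excluded = "integer"))
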