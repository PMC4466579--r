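# Parameter tables, geometry, unit conversions, study specialization.
#
# Unit conventions: fluid-phase on-rates in 1/M/s, membrane-coupling on-rates
# in 1/(mol/cm2)/s, all off/first-order rates in 1/s. The assembler converts
# everything to a per-(#/cm2) basis at compile time using the geometry
# (Avogadro's number with bulk fluid depth or endosomal volume per area).

AVOGADRO <- 6.02214076e23

#' Representative model parameters
#'
#' The literature/fit parameter set: binding kinetics for every legal pair in
#' every compartment class, first-order trafficking rates (internalization,
#' Rab4-route and Rab11-route recycling, early-to-recycling transfer,
#' degradation) per species form, site-specific phosphorylation and
#' dephosphorylation rates per VEGFR2-containing form and compartment, and
#' geometry. Phosphorylation requires ligation (k_p = 0 for free VEGFR2,
#' 1/s for ligated); dephosphorylation of free receptor, and of every complex
#' in Rab11 endosomes, is fast (30/s). Matrix-anchored M.V.R2 uses the
#' surface V.R2 phosphorylation rates (immobilization does not change the
#' intrinsic kinetics). The V-matrix binding constants default to zero and
#' are installed per study by \code{\link{applyStudyConfig}}.
#'
#' @param cellDensity cells per cm2 of culture surface.
#' @param endoVol endosomal volume per unit cell-surface area (cm3/cm2),
#'   applied to both Rab4/5 and Rab11 compartments.
#' @param depth bulk fluid (solution/matrix) depth in cm.
#' @param area total culture surface area in cm2.
#' @return a \code{\linkS4class{ParameterSet}}.
#' @export
defaultParameters <- function(cellDensity = 1e5, endoVol = 1e-7,
                              depth = 0.5, area = 1) {
  kin <- c(
    # extracellular V + matrix site (study-specific; zero until installed)
    kon.V.M = 0, koff.V.M = 0,
    # surface
    kon.V.R2.surf = 1.0e7,  koff.V.R2.surf = 1.0e-3,
    kon.M.VR2.surf = 4.2e5, koff.M.VR2.surf = 1.0e-2,
    kon.VM.R2.surf = 1.0e7, koff.VM.R2.surf = 1.0e-3,
    kon.V.N1.surf = 4.8e4,  koff.V.N1.surf = 1.0e-4,
    kon.N1.VR2.surf = 3.1e13, koff.N1.VR2.surf = 1.0e-3,
    kon.VN1.R2.surf = 1.0e14, koff.VN1.R2.surf = 1.0e-3,
    # internal (same in Rab4/5 and Rab11; unit conversion at assembly)
    kon.V.R2.int = 1.0e7,   koff.V.R2.int = 1.0e-3,
    kon.V.N1.int = 4.8e4,   koff.V.N1.int = 1.0e-4,
    kon.N1.VR2.int = 3.1e13, koff.N1.VR2.int = 1.0e-3,
    kon.VN1.R2.int = 1.0e14, koff.VN1.R2.int = 1.0e-3)
  trf <- c(
    kint.R2 = 2.6e-3, kint.V.R2 = 3.12e-2, kint.N1 = 2.6e-3,
    kint.V.N1 = 2.6e-3, kint.V.N1.R2 = 3.12e-2,
    krec4.R2 = 3.8e-3, krec4.V.R2 = 3.8e-3, krec4.N1 = 3.8e-5,
    krec4.V.N1 = 3.8e-5, krec4.V.N1.R2 = 3.8e-5,
    krec11.R2 = 1.4e-4, krec11.V.R2 = 1.4e-4, krec11.N1 = 1.4e-2,
    krec11.V.N1 = 1.4e-2, krec11.V.N1.R2 = 1.4e-2,
    k4to11.R2 = 1.0e-5, k4to11.V.R2 = 1.0e-5, k4to11.N1 = 1.9e-2,
    k4to11.V.N1 = 1.9e-2, k4to11.V.N1.R2 = 1.9e-2,
    kdegr.R2 = 3.6e-6, kdegr.V.R2 = 3.6e-5, kdegr.V = 1.2e-2,
    kdegr.N1 = 1.6e-4, kdegr.V.N1 = 1.6e-4, kdegr.V.N1.R2 = 6.8e-4,
    s.R2 = 0, s.N1 = 0)
  kdp <- c(
    # free receptor: fast everywhere
    kdp.Y951.R2.surf = 30, kdp.Y1175.R2.surf = 30, kdp.Y1214.R2.surf = 30,
    kdp.Y951.R2.rab45 = 30, kdp.Y1175.R2.rab45 = 30, kdp.Y1214.R2.rab45 = 30,
    kdp.Y951.R2.rab11 = 30, kdp.Y1175.R2.rab11 = 30, kdp.Y1214.R2.rab11 = 30,
    # ligated, surface
    kdp.Y951.V.R2.surf = 0.043, kdp.Y1175.V.R2.surf = 4.98,
    kdp.Y1214.V.R2.surf = 1.06,
    kdp.Y951.M.V.R2.surf = 0.043, kdp.Y1175.M.V.R2.surf = 4.98,
    kdp.Y1214.M.V.R2.surf = 1.06,
    kdp.Y951.V.N1.R2.surf = 6, kdp.Y1175.V.N1.R2.surf = 5,
    kdp.Y1214.V.N1.R2.surf = 1,
    # ligated, Rab4/5
    kdp.Y951.V.R2.rab45 = 75.0, kdp.Y1175.V.R2.rab45 = 0.00972,
    kdp.Y1214.V.R2.rab45 = 0.0307,
    kdp.Y951.V.N1.R2.rab45 = 15, kdp.Y1175.V.N1.R2.rab45 = 0.01,
    kdp.Y1214.V.N1.R2.rab45 = 6,
    # ligated, Rab11: fast
    kdp.Y951.V.R2.rab11 = 30, kdp.Y1175.V.R2.rab11 = 30,
    kdp.Y1214.V.R2.rab11 = 30,
    kdp.Y951.V.N1.R2.rab11 = 30, kdp.Y1175.V.N1.R2.rab11 = 30,
    kdp.Y1214.V.N1.R2.rab11 = 30)
  kp <- numeric(0)
  for (comp in c("surf", "rab45", "rab11")) {
    forms <- if (comp == "surf") c("R2", "V.R2", "M.V.R2", "V.N1.R2")
             else c("R2", "V.R2", "V.N1.R2")
    for (f in forms) for (res in RESIDUES)
      kp[paste0("kp.", res, ".", f, ".", comp)] <- if (f == "R2") 0 else 1
  }
  geo <- c(area.cm2 = area, depth.cm = depth,
           endoVol.rab45 = endoVol, endoVol.rab11 = endoVol,
           cellDensity = cellDensity, mw.V = 45000, mw.Msite = 30000)
  new("ParameterSet", kinetic = kin, trafficking = trf,
      phospho = c(kp, kdp), geometry = geo, study = list())
}

#' Flatten a ParameterSet to one named numeric vector
#' @param params a \code{ParameterSet}.
#' @export
flattenParameters <- function(params)
  c(params@kinetic, params@trafficking, params@phospho, params@geometry)

#' Update named rates in a ParameterSet
#'
#' @param params a \code{ParameterSet}.
#' @param values named numeric; names must exist in the kinetic, trafficking
#'   or phospho slots.
#' @return modified copy.
#' @export
setParameters <- function(params, values) {
  for (nm in names(values)) {
    hit <- FALSE
    for (slot in c("kinetic", "trafficking", "phospho", "geometry")) {
      v <- slot(params, slot)
      if (nm %in% names(v)) {
        v[nm] <- values[[nm]]
        slot(params, slot) <- v
        hit <- TRUE
        break
      }
    }
    if (!hit) stop("unknown parameter: ", nm)
  }
  params
}

#' Derived equilibrium dissociation constants
#'
#' K_D = k_off / k_on for each binding pair with a nonzero on-rate, in the
#' on-rate's unit system (M for fluid-phase pairs, mol/cm2 for
#' membrane-coupling pairs).
#'
#' @param params a \code{ParameterSet}.
#' @export
dissociationConstants <- function(params) {
  kin <- params@kinetic
  on <- kin[grep("^kon\\.", names(kin))]
  off <- kin[sub("^kon\\.", "koff.", names(on))]
  kd <- ifelse(on > 0, off / on, NA_real_)
  names(kd) <- sub("^kon\\.", "KD.", names(on))
  kd
}

#' Convert a bulk molar on-rate to a per-areal-density rate
#'
#' Endosomal bimolecular reactions run between species measured in molecules
#' per cm2 of cell surface; a literature on-rate in 1/M/s is divided by
#' (Avogadro x endosomal volume per area in L/cm2) so that k' x y with x, y
#' in #/cm2 reproduces the molar-rate flux.
#'
#' @param konMolar on-rate in 1/M/s.
#' @param geometry named geometry vector (see \code{defaultParameters}).
#' @param compartment "rab45" or "rab11".
#' @return rate in 1/(#/cm2)/s.
#' @export
convertBulkToInternalKon <- function(konMolar, geometry, compartment) {
  stopifnot(compartment %in% c("rab45", "rab11"))
  vol <- geometry[[paste0("endoVol.", compartment)]]
  if (is.null(vol) || is.na(vol) || vol <= 0)
    stop("endosomal volume per area unset for ", compartment)
  konMolar / (AVOGADRO * vol * 1e-3)  # cm3/cm2 -> L/cm2
}

#' Receptors per cell to surface density
#'
#' @param count receptors per cell.
#' @param geometry named geometry vector.
#' @return molecules per cm2 of culture surface.
#' @export
receptorsPerCellToDensity <- function(count, geometry) {
  stopifnot(count >= 0)
  count * geometry[["cellDensity"]]
}

#' VEGF mass concentration to molar
#' @param ng_ml ng/mL of VEGF dimer.
#' @param geometry named geometry vector (uses \code{mw.V}).
#' @export
vegfNgMlToMolar <- function(ng_ml, geometry)
  ng_ml * 1e-6 / geometry[["mw.V"]]  # ng/mL = 1e-6 g/L

#' Matrix-site mass concentration to molar
#' @param mg_ml mg/mL of matrix protein.
#' @param geometry named geometry vector (uses \code{mw.Msite}).
#' @export
matrixMgMlToMolar <- function(mg_ml, geometry)
  mg_ml / geometry[["mw.Msite"]]  # mg/mL = g/L

# Registry of the study columns: initial conditions, geometry, and parameter
# overrides per experimental protocol.
.studyTable <- function() {
  list(
    trafficking_study = list(
      cell = "PAEC", vegf_ng_ml = 50, matrix_mg_ml = 0,
      r2_per_cell = 108000, n1_per_cell = 113000,
      area = 1, depth = 0.5, kdegr_scale = 1,
      koff.V.M = NA, kon.V.M = NA),
    trafficking_study_r2only = list(
      cell = "PAEC", vegf_ng_ml = 50, matrix_mg_ml = 0,
      r2_per_cell = 37400, n1_per_cell = 0,
      area = 1, depth = 0.5, kdegr_scale = 1,
      koff.V.M = NA, kon.V.M = NA),
    trafficking_study_n1only = list(
      cell = "PAEC", vegf_ng_ml = 50, matrix_mg_ml = 0,
      r2_per_cell = 0, n1_per_cell = 113000,
      area = 1, depth = 0.5, kdegr_scale = 1,
      koff.V.M = NA, kon.V.M = NA),
    presentation_2011 = list(
      cell = "HUVEC", vegf_ng_ml = 2, matrix_mg_ml = 1.5e-3, # 1500 ng/mL
      r2_per_cell = 6000, n1_per_cell = 35000,
      area = 3, depth = 0.05, kdegr_scale = 2.4,
      koff.V.M = 3.3e-3, kon.V.M = 4.2e5),
    presentation_2010 = list(
      cell = "HUVEC", vegf_ng_ml = 200, matrix_mg_ml = 3,
      r2_per_cell = 6000, n1_per_cell = 35000,
      area = 1, depth = 0.5, kdegr_scale = 2.4,
      koff.V.M = 1.0e-2, kon.V.M = 4.0e3),
    other = list(
      cell = "HUVEC", vegf_ng_ml = 20, matrix_mg_ml = 3,
      r2_per_cell = 6000, n1_per_cell = 35000,
      area = 1, depth = 0.5, kdegr_scale = 2.4,
      koff.V.M = 1.0e-2, kon.V.M = 4.0e3))
}

#' List available study configurations
#' @export
studyNames <- function() names(.studyTable())

#' Specialize a parameter set to a study configuration
#'
#' Installs the study column: receptor numbers per cell, geometry, V-matrix
#' binding constants, the degradation scale factor (2.4 for HUVEC studies),
#' and the internalization rule — the ligated-receptor internalization rate
#' is divided by 6 when the VEGF dose exceeds 50 ng/mL (at exactly 50 ng/mL
#' the original rate is kept). Production rates are recomputed for the new
#' surface targets. Refuses to specialize an already-specialized set, so the
#' degradation factor can never be applied twice.
#'
#' @param base a complete representative \code{ParameterSet}.
#' @param study a study name from \code{\link{studyNames}}.
#' @param vegf_ng_ml optional dose override (ng/mL); the "other" study varies
#'   its dose.
#' @return a specialized \code{ParameterSet}.
#' @export
applyStudyConfig <- function(base, study, vegf_ng_ml = NULL) {
  if (length(base@study) && isTRUE(base@study$applied))
    stop("parameter set is already specialized to a study; start from the base set")
  tab <- .studyTable()
  if (!study %in% names(tab)) stop("unknown study: ", study)
  cfg <- tab[[study]]
  if (!is.null(vegf_ng_ml)) cfg$vegf_ng_ml <- vegf_ng_ml
  p <- base
  p@geometry[["area.cm2"]] <- cfg$area
  p@geometry[["depth.cm"]] <- cfg$depth
  # degradation scale applies to every molecular species
  kd <- grep("^kdegr\\.", names(p@trafficking))
  p@trafficking[kd] <- p@trafficking[kd] * cfg$kdegr_scale
  # dose-dependent internalization of ligated receptor
  if (cfg$vegf_ng_ml > 50) {
    p@trafficking[["kint.V.R2"]] <- p@trafficking[["kint.V.R2"]] / 6
    p@trafficking[["kint.V.N1.R2"]] <- p@trafficking[["kint.V.N1.R2"]] / 6
  }
  if (!is.na(cfg$koff.V.M)) {
    p@kinetic[["kon.V.M"]] <- cfg$kon.V.M
    p@kinetic[["koff.V.M"]] <- cfg$koff.V.M
    # M anchoring V.R2, and V.M capturing R2, share the V.M chemistry class
    p@kinetic[["kon.M.VR2.surf"]] <- cfg$kon.V.M
    p@kinetic[["koff.M.VR2.surf"]] <- cfg$koff.V.M
  }
  p@study <- c(cfg, list(name = study, applied = TRUE))
  computeProductionRates(p)
}

#' Receptor production rates balancing the no-VEGF steady state
#'
#' For each receptor the unligated surface/Rab4/5/Rab11 subsystem is linear;
#' with the surface pool held at its configured density S the stationary
#' endosomal pools are E45 = k_int S / (k_rec4 + k_4to11 + k_degr) and
#' E11 = k_4to11 E45 / k_rec11, and the unique production rate making the
#' system stationary is s = k_int S - k_rec4 E45 - k_rec11 E11, which equals
#' k_degr E45 (production balances degradation).
#'
#' @param params a \code{ParameterSet} whose study slot provides the surface
#'   receptor targets (per cell).
#' @param r2_surface,n1_surface optional explicit surface densities (#/cm2),
#'   overriding the study configuration.
#' @return the parameter set with \code{s.R2}, \code{s.N1} filled in.
#' @export
computeProductionRates <- function(params, r2_surface = NULL,
                                   n1_surface = NULL) {
  st <- params@study
  if (is.null(r2_surface))
    r2_surface <- receptorsPerCellToDensity(
      if (length(st)) st$r2_per_cell else 0, params@geometry)
  if (is.null(n1_surface))
    n1_surface <- receptorsPerCellToDensity(
      if (length(st)) st$n1_per_cell else 0, params@geometry)
  trf <- params@trafficking
  sFor <- function(form, S) {
    ki <- trf[[paste0("kint.", form)]]
    if (ki == 0 || S == 0) return(c(s = 0, E45 = 0, E11 = 0))
    den <- trf[[paste0("krec4.", form)]] + trf[[paste0("k4to11.", form)]] +
           trf[[paste0("kdegr.", form)]]
    if (den == 0) stop("degenerate trafficking rates for ", form)
    E45 <- ki * S / den
    kr11 <- trf[[paste0("krec11.", form)]]
    if (kr11 == 0) stop("zero Rab11 recycling rate for ", form)
    E11 <- trf[[paste0("k4to11.", form)]] * E45 / kr11
    c(s = ki * S - trf[[paste0("krec4.", form)]] * E45 - kr11 * E11,
      E45 = E45, E11 = E11)
  }
  r2 <- sFor("R2", r2_surface)
  n1 <- sFor("N1", n1_surface)
  params@trafficking[["s.R2"]] <- r2[["s"]]
  params@trafficking[["s.N1"]] <- n1[["s"]]
  params@study$ss <- list(
    R2 = c(surf = r2_surface, rab45 = r2[["E45"]], rab11 = r2[["E11"]]),
    N1 = c(surf = n1_surface, rab45 = n1[["E45"]], rab11 = n1[["E11"]]))
  params
}

#' @export
setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet:", length(object@kinetic), "kinetic,",
      length(object@trafficking), "trafficking,",
      length(object@phospho), "phospho parameters\n")
  if (length(object@study))
    cat("  study:", object@study$name, "| cell:", object@study$cell,
        "| [V] =", object@study$vegf_ng_ml, "ng/mL\n")
  else cat("  study: representative base set (not specialized)\n")
})
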