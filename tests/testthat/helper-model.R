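# Shared fixtures: networks are pure values, built once per test run.

.fixtures <- new.env()

fullNet <- function() {
  if (is.null(.fixtures$full)) .fixtures$full <- buildNetwork()
  .fixtures$full
}

noPhosphoNet <- function() {
  if (is.null(.fixtures$nop)) .fixtures$nop <- buildNetwork(includePhospho = FALSE)
  .fixtures$nop
}

# Minimal ligand-receptor system: no NRP1, no matrix, no phospho states.
minimalNet <- function() {
  if (is.null(.fixtures$min))
    .fixtures$min <- buildNetwork(includeNRP1 = FALSE, includeMatrix = FALSE,
                                  includePhospho = FALSE)
  .fixtures$min
}

otherParams <- function(vegf = 20)
  applyStudyConfig(defaultParameters(), "other", vegf_ng_ml = vegf)

# Independently hand-coded derivative of the minimal system, written
# directly from the rate tables (not via the generic assembler). State order
# must match minimalNet()'s species order:
#   ext:V, surf:R2, surf:V.R2, rab45:R2, rab45:V.R2, rab45:V,
#   rab11:R2, rab11:V.R2, rab11:V, degr:V, degr:R2, degr:V.R2
minimalOracleRhs <- function(params) {
  k <- flattenParameters(params)
  geo <- params@geometry
  fluid <- 1 / (6.02214076e23 * geo[["depth.cm"]] * 1e-3)
  endo45 <- 1 / (6.02214076e23 * geo[["endoVol.rab45"]] * 1e-3)
  endo11 <- 1 / (6.02214076e23 * geo[["endoVol.rab11"]] * 1e-3)
  function(x) {
    V <- x[1]; R2 <- x[2]; VR2 <- x[3]
    R2e <- x[4]; VR2e <- x[5]; Ve <- x[6]
    R2r <- x[7]; VR2r <- x[8]; Vr <- x[9]
    bSurf <- k[["kon.V.R2.surf"]] * fluid * V * R2 -
      k[["koff.V.R2.surf"]] * VR2
    bE <- k[["kon.V.R2.int"]] * endo45 * Ve * R2e -
      k[["koff.V.R2.int"]] * VR2e
    bR <- k[["kon.V.R2.int"]] * endo11 * Vr * R2r -
      k[["koff.V.R2.int"]] * VR2r
    c(-bSurf,
      -bSurf - k[["kint.R2"]] * R2 + k[["krec4.R2"]] * R2e +
        k[["krec11.R2"]] * R2r + k[["s.R2"]],
      bSurf - k[["kint.V.R2"]] * VR2 + k[["krec4.V.R2"]] * VR2e +
        k[["krec11.V.R2"]] * VR2r,
      -bE + k[["kint.R2"]] * R2 -
        (k[["krec4.R2"]] + k[["k4to11.R2"]] + k[["kdegr.R2"]]) * R2e,
      bE + k[["kint.V.R2"]] * VR2 -
        (k[["krec4.V.R2"]] + k[["k4to11.V.R2"]] + k[["kdegr.V.R2"]]) * VR2e,
      -bE - k[["kdegr.V"]] * Ve,
      -bR + k[["k4to11.R2"]] * R2e - k[["krec11.R2"]] * R2r,
      bR + k[["k4to11.V.R2"]] * VR2e - k[["krec11.V.R2"]] * VR2r,
      -bR,
      k[["kdegr.V"]] * Ve,
      k[["kdegr.R2"]] * R2e,
      k[["kdegr.V.R2"]] * VR2e)
  }
}
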