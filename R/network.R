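# Species and reaction enumeration.
#
# The network is generated, never hand-listed: species come from composition
# rules (which molecules can co-occur in a complex, and where), reactions from
# pairing rules replicated over the eight phosphorylation states of any
# VEGFR2-containing participant. Binding and trafficking preserve the
# phospho-state; degradation clears it.

# Canonical complex names keyed by composition flags (M, V, N1, R2).
.formName <- function(v, m, r2, n1) {
  key <- paste0(as.integer(v), as.integer(m), as.integer(r2), as.integer(n1))
  switch(key,
    "1000" = "V", "0100" = "M", "1100" = "V.M",
    "0010" = "R2", "1010" = "V.R2", "1110" = "M.V.R2",
    "0001" = "N1", "1001" = "V.N1", "1011" = "V.N1.R2",
    stop("illegal composition: ", key))
}

.phosphoStates <- function() {
  g <- expand.grid(p951 = 0:1, p1175 = 0:1, p1214 = 0:1)
  # order: unphosphorylated first, then single, double, triple sites
  g[order(g$p951 + g$p1175 + g$p1214, 8 - (4 * g$p951 + 2 * g$p1175 + g$p1214)), ]
}

.speciesName <- function(comp, form, p951 = 0, p1175 = 0, p1214 = 0,
                         bracket = FALSE) {
  base <- paste0(comp, ":", form)
  if (bracket)
    base <- paste0(base, "[p951=", p951, ",p1175=", p1175, ",p1214=", p1214, "]")
  base
}

.speciesRow <- function(comp, form, p951 = 0, p1175 = 0, p1214 = 0,
                        bracket = FALSE) {
  data.frame(name = .speciesName(comp, form, p951, p1175, p1214, bracket),
             compartment = comp, form = form,
             has_V = form %in% c("V", "V.M", "V.R2", "M.V.R2", "V.N1", "V.N1.R2"),
             has_M = form %in% c("M", "V.M", "M.V.R2"),
             has_R2 = form %in% c("R2", "V.R2", "M.V.R2", "V.N1.R2"),
             has_N1 = form %in% c("N1", "V.N1", "V.N1.R2"),
             p951 = p951, p1175 = p1175, p1214 = p1214,
             stringsAsFactors = FALSE)
}

.enumForm <- function(comp, form, phospho) {
  hasR2 <- form %in% c("R2", "V.R2", "M.V.R2", "V.N1.R2")
  # degraded pools are phospho-free: phosphorylation is lost on degradation
  if (hasR2 && phospho && comp != "degr") {
    ps <- .phosphoStates()
    do.call(rbind, lapply(seq_len(nrow(ps)), function(i)
      .speciesRow(comp, form, ps$p951[i], ps$p1175[i], ps$p1214[i],
                  bracket = TRUE)))
  } else {
    .speciesRow(comp, form)
  }
}

#' Enumerate the molecular species of the model
#'
#' Applies the composition rules: NRP1 and the matrix site bind the same
#' heparin-binding domain of VEGF and never co-occur in a complex; VEGFR2 and
#' NRP1 only couple through VEGF; matrix-anchored complexes exist only
#' extracellularly or on the surface (M.V.R2 is surface-only and is never
#' internalized); degraded pools are phospho-free. Every VEGFR2-containing
#' species in a live compartment carries one of the eight phosphorylation
#' patterns of (Y951, Y1175, Y1214). The full enumeration has 97 species.
#'
#' @param includeNRP1,includeMatrix,includePhospho logical switches producing
#'   reduced networks (used for oracles and phospho-independent fitting).
#' @return data.frame of species.
#' @export
enumerateSpecies <- function(includeNRP1 = TRUE, includeMatrix = TRUE,
                             includePhospho = TRUE) {
  blocks <- list()
  add <- function(comp, form) {
    if (!includeNRP1 && grepl("N1", form)) return()
    if (!includeMatrix && grepl("M", form)) return()
    blocks[[length(blocks) + 1L]] <<- .enumForm(comp, form, includePhospho)
  }
  add("ext", "V"); add("ext", "M"); add("ext", "V.M")
  for (f in c("R2", "V.R2", "M.V.R2", "V.N1.R2", "N1", "V.N1")) add("surf", f)
  for (comp in c("rab45", "rab11"))
    for (f in c("R2", "V.R2", "V.N1.R2", "N1", "V.N1", "V")) add(comp, f)
  for (f in c("V", "R2", "N1", "V.R2", "V.N1", "V.N1.R2")) add("degr", f)
  sp <- do.call(rbind, blocks)
  rownames(sp) <- NULL
  attr(sp, "includeNRP1") <- includeNRP1
  attr(sp, "includeMatrix") <- includeMatrix
  attr(sp, "includePhospho") <- includePhospho
  sp
}

# Legal binding pairs. Each row: compartment of the complex, reactant forms A
# and B (with their compartments), product form, kinetic key, and the unit
# class of the on-rate ("fluid" = 1/M/s against the bulk volume, "endo" =
# 1/M/s against the endosomal volume, "areal" = 1/(mol/cm2)/s).
.bindingTable <- function() {
  rbind(
    data.frame(comp = "ext",  compA = "ext", formA = "V",    compB = "ext", formB = "M",    prod = "V.M",      key = "V.M",       unit = "fluid"),
    data.frame(comp = "surf", compA = "ext", formA = "V",    compB = "surf", formB = "R2",   prod = "V.R2",     key = "V.R2.surf", unit = "fluid"),
    data.frame(comp = "surf", compA = "ext", formA = "V.M",  compB = "surf", formB = "R2",   prod = "M.V.R2",   key = "VM.R2.surf", unit = "fluid"),
    data.frame(comp = "surf", compA = "ext", formA = "M",    compB = "surf", formB = "V.R2", prod = "M.V.R2",   key = "M.VR2.surf", unit = "fluid"),
    data.frame(comp = "surf", compA = "ext", formA = "V",    compB = "surf", formB = "N1",   prod = "V.N1",     key = "V.N1.surf", unit = "fluid"),
    data.frame(comp = "surf", compA = "surf", formA = "N1",  compB = "surf", formB = "V.R2", prod = "V.N1.R2",  key = "N1.VR2.surf", unit = "areal"),
    data.frame(comp = "surf", compA = "surf", formA = "V.N1", compB = "surf", formB = "R2",  prod = "V.N1.R2",  key = "VN1.R2.surf", unit = "areal"),
    do.call(rbind, lapply(c("rab45", "rab11"), function(cc) rbind(
      data.frame(comp = cc, compA = cc, formA = "V",    compB = cc, formB = "R2",   prod = "V.R2",    key = "V.R2.int",  unit = "endo"),
      data.frame(comp = cc, compA = cc, formA = "V",    compB = cc, formB = "N1",   prod = "V.N1",    key = "V.N1.int",  unit = "endo"),
      data.frame(comp = cc, compA = cc, formA = "N1",   compB = cc, formB = "V.R2", prod = "V.N1.R2", key = "N1.VR2.int", unit = "areal"),
      data.frame(comp = cc, compA = cc, formA = "V.N1", compB = cc, formB = "R2",   prod = "V.N1.R2", key = "VN1.R2.int", unit = "areal")))))
}

# Trafficking rate table: process, species form, rate key. Forms with a zero
# rate in the source table (free V internalization/recycling, M.V.R2
# internalization) have no reaction at all.
.traffickingTable <- function() {
  forms5 <- c("R2", "V.R2", "N1", "V.N1", "V.N1.R2")
  rbind(
    data.frame(kind = "internalize", form = forms5,
               rate = paste0("kint.", forms5)),
    data.frame(kind = "recycle_rab4", form = forms5,
               rate = paste0("krec4.", forms5)),
    data.frame(kind = "recycle_rab11", form = forms5,
               rate = paste0("krec11.", forms5)),
    data.frame(kind = "transfer_4to11", form = forms5,
               rate = paste0("k4to11.", forms5)),
    data.frame(kind = "degrade", form = c("R2", "V.R2", "V", "N1", "V.N1", "V.N1.R2"),
               rate = paste0("kdegr.", c("R2", "V.R2", "V", "N1", "V.N1", "V.N1.R2"))))
}

.rxRow <- function(kind, r1, r2, p1, p2, rate, unit = "none",
                   residue = NA_character_, family = NA_character_) {
  data.frame(kind = kind, r1 = r1, r2 = r2, p1 = p1, p2 = p2, rate = rate,
             unit = unit, residue = residue, family = family,
             stringsAsFactors = FALSE)
}

#' Enumerate all reactions over a species list
#'
#' Generates binding on/off pairs for every legal pair-compartment
#' combination, trafficking reactions for every species form with a rate row
#' (degradation maps to the phospho-cleared degraded pool), reversible
#' site-specific phosphorylation for every VEGFR2-containing form in live
#' compartments, and zeroth-order production of surface VEGFR2 and NRP1. All
#' reactions replicated over phosphorylation states share one rate parameter
#' per family.
#'
#' @param species data.frame from \code{\link{enumerateSpecies}}.
#' @return a \code{\linkS4class{ReactionNetwork}}.
#' @export
enumerateReactions <- function(species) {
  idx <- setNames(seq_len(nrow(species)), species$name)
  phospho <- isTRUE(attr(species, "includePhospho"))
  look <- function(name) {
    i <- idx[name]
    if (is.na(i)) stop("reaction references unknown species: ", name)
    unname(i)
  }
  hasSpecies <- function(name) !is.na(idx[name])
  variantsOf <- function(comp, form) {
    sel <- species$compartment == comp & species$form == form
    which(sel)
  }
  rx <- list()
  push <- function(df) rx[[length(rx) + 1L]] <<- df

  # --- binding ---
  bt <- .bindingTable()
  for (i in seq_len(nrow(bt))) {
    b <- bt[i, ]
    aAll <- variantsOf(b$compA, b$formA)
    bAll <- variantsOf(b$compB, b$formB)
    pAll <- variantsOf(b$comp, b$prod)
    if (!length(aAll) || !length(bAll) || !length(pAll)) next
    fam <- paste0("bind:", b$comp, ":", b$formA, "+", b$formB)
    # pair each phospho variant of the R2 carrier with the matching product
    combos <- expand.grid(a = aAll, b2 = bAll)
    for (j in seq_len(nrow(combos))) {
      ia <- combos$a[j]; ib <- combos$b2[j]
      st <- species[if (species$has_R2[ia]) ia else ib,
                    c("p951", "p1175", "p1214")]
      pm <- pAll[species$p951[pAll] == st$p951 &
                 species$p1175[pAll] == st$p1175 &
                 species$p1214[pAll] == st$p1214]
      if (length(pm) != 1L) stop("no unique product for ", fam)
      push(.rxRow("binding_on", ia, ib, pm, NA, paste0("kon.", b$key),
                  unit = b$unit, family = fam))
      push(.rxRow("binding_off", pm, NA, ia, ib, paste0("koff.", b$key),
                  family = fam))
    }
  }

  # --- trafficking ---
  tt <- .traffickingTable()
  moves <- c(internalize = "surf>rab45", recycle_rab4 = "rab45>surf",
             recycle_rab11 = "rab11>surf", transfer_4to11 = "rab45>rab11",
             degrade = "rab45>degr")
  for (i in seq_len(nrow(tt))) {
    kind <- tt$kind[i]; form <- tt$form[i]
    mv <- strsplit(moves[[kind]], ">")[[1]]
    from <- variantsOf(mv[1], form)
    if (!length(from)) next
    fam <- paste0(kind, ":", form)
    for (ia in from) {
      if (kind == "degrade") {
        tgt <- which(species$compartment == "degr" & species$form == form)
      } else {
        toAll <- variantsOf(mv[2], form)
        tgt <- toAll[species$p951[toAll] == species$p951[ia] &
                     species$p1175[toAll] == species$p1175[ia] &
                     species$p1214[toAll] == species$p1214[ia]]
      }
      if (length(tgt) != 1L) stop("no unique trafficking target for ", fam)
      push(.rxRow(kind, ia, NA, tgt, NA, tt$rate[i], family = fam))
    }
  }

  # --- production (new receptor is unphosphorylated) ---
  r2new <- variantsOf("surf", "R2")
  r2new <- r2new[species$p951[r2new] == 0 & species$p1175[r2new] == 0 &
                 species$p1214[r2new] == 0]
  push(.rxRow("produce", NA, NA, r2new, NA, "s.R2", family = "produce:R2"))
  if (hasSpecies("surf:N1"))
    push(.rxRow("produce", NA, NA, look("surf:N1"), NA, "s.N1",
                family = "produce:N1"))

  # --- phosphorylation ---
  if (phospho) {
    pforms <- rbind(
      expand.grid(comp = "surf", form = c("R2", "V.R2", "M.V.R2", "V.N1.R2"),
                  stringsAsFactors = FALSE),
      expand.grid(comp = c("rab45", "rab11"), form = c("R2", "V.R2", "V.N1.R2"),
                  stringsAsFactors = FALSE))
    pcols <- c(Y951 = "p951", Y1175 = "p1175", Y1214 = "p1214")
    for (i in seq_len(nrow(pforms))) {
      comp <- pforms$comp[i]; form <- pforms$form[i]
      vs <- variantsOf(comp, form)
      if (!length(vs)) next
      for (res in RESIDUES) {
        col <- pcols[[res]]
        fam <- paste0("phospho:", comp, ":", form, ":", res)
        src <- vs[species[[col]][vs] == 0]
        for (ia in src) {
          tgt <- vs[species$p951[vs] == (species$p951[ia] + (col == "p951")) &
                    species$p1175[vs] == (species$p1175[ia] + (col == "p1175")) &
                    species$p1214[vs] == (species$p1214[ia] + (col == "p1214"))]
          if (length(tgt) != 1L) stop("no unique phospho target for ", fam)
          push(.rxRow("phosphorylate", ia, NA, tgt, NA,
                      paste0("kp.", res, ".", form, ".", comp),
                      residue = res, family = fam))
          push(.rxRow("dephosphorylate", tgt, NA, ia, NA,
                      paste0("kdp.", res, ".", form, ".", comp),
                      residue = res, family = fam))
        }
      }
    }
  }

  reactions <- do.call(rbind, rx)
  rownames(reactions) <- NULL
  new("ReactionNetwork", species = species, reactions = reactions,
      index = idx)
}

#' Build the model's reaction network
#'
#' @inheritParams enumerateSpecies
#' @return a validated \code{\linkS4class{ReactionNetwork}}; the full default
#'   network has 97 species.
#' @export
buildNetwork <- function(includeNRP1 = TRUE, includeMatrix = TRUE,
                         includePhospho = TRUE) {
  enumerateReactions(enumerateSpecies(includeNRP1, includeMatrix,
                                      includePhospho))
}

#' @describeIn buildNetwork number of species.
#' @param object,x a \code{ReactionNetwork}.
#' @export
speciesNames <- function(x) x@species$name

#' Count reversible reaction families
#'
#' Binding families collapse the phospho-replicates of one legal
#' pair-compartment combination; phosphorylation pairs are counted with
#' replicates (one per source state), matching the published bookkeeping.
#'
#' @param net a \code{ReactionNetwork}.
#' @return named integer vector.
#' @export
reactionCounts <- function(net) {
  rx <- net@reactions
  c(species = nrow(net@species),
    binding_reversible_types =
      length(unique(rx$family[rx$kind == "binding_on"])),
    phospho_reversible = sum(rx$kind == "phosphorylate"),
    trafficking = sum(rx$kind %in% c("internalize", "recycle_rab4",
                                     "recycle_rab11", "transfer_4to11",
                                     "degrade")),
    trafficking_families =
      length(unique(rx$family[rx$kind %in% c("internalize", "recycle_rab4",
                                             "recycle_rab11", "transfer_4to11",
                                             "degrade", "produce")])),
    total_unidirectional = nrow(rx))
}

.reachable <- function(net, sources) {
  rx <- net@reactions
  n <- nrow(net@species)
  seen <- rep(FALSE, n)
  seen[sources] <- TRUE
  repeat {
    before <- sum(seen)
    prem <- !is.na(rx$r1) & seen[pmax(rx$r1, 1)] |
            is.na(rx$r1)  # production has no reactant
    # bimolecular needs both reactants live
    both <- ifelse(is.na(rx$r2), TRUE, seen[pmax(rx$r2, 1, na.rm = TRUE)])
    both[is.na(rx$r2)] <- TRUE
    fire <- prem & both
    for (col in c("p1", "p2")) {
      tgt <- rx[[col]][fire]
      tgt <- tgt[!is.na(tgt)]
      seen[tgt] <- TRUE
    }
    if (sum(seen) == before) break
  }
  seen
}

#' Validate a reaction network's structural invariants
#'
#' Runs all structural checks and returns a report rather than failing on the
#' first violation: species counts (per compartment and total), exclusion
#' rules, compartment legality of matrix-bound complexes, phospho-clearing on
#' degradation, phospho-preservation elsewhere, phospho-uniform trafficking
#' rates, reversible reaction counts, and graph reachability from the
#' extracellular VEGF pools and produced receptors. The published totals of
#' 277 reactions and 31 trafficking reactions are reported as informational
#' values only (their counting convention is not reconstructible).
#'
#' @param net a \code{ReactionNetwork}.
#' @return data.frame with columns \code{check}, \code{pass}, \code{detail}.
#' @export
validateNetwork <- function(net) {
  sp <- net@species
  rx <- net@reactions
  full <- isTRUE(attr(sp, "includeNRP1")) && isTRUE(attr(sp, "includeMatrix")) &&
          isTRUE(attr(sp, "includePhospho"))
  out <- list()
  add <- function(check, pass, detail = "") {
    out[[length(out) + 1L]] <<- data.frame(check = check, pass = pass,
                                           detail = as.character(detail),
                                           stringsAsFactors = FALSE)
  }
  cnt <- reactionCounts(net)
  if (full) {
    add("species_count_97", cnt[["species"]] == 97L, cnt[["species"]])
    byComp <- table(sp$compartment)
    add("compartment_counts_3_34_27_27_6",
        identical(as.integer(byComp[c("ext", "surf", "rab45", "rab11", "degr")]),
                  c(3L, 34L, 27L, 27L, 6L)),
        paste(byComp, collapse = "/"))
    add("binding_types_15", cnt[["binding_reversible_types"]] == 15L,
        cnt[["binding_reversible_types"]])
    add("phospho_reversible_120", cnt[["phospho_reversible"]] == 120L,
        cnt[["phospho_reversible"]])
    add("reported_total_reactions", NA, cnt[["total_unidirectional"]])
    add("reported_trafficking_reactions", NA, cnt[["trafficking"]])
  }
  add("no_M_and_N1_cooccur", !any(sp$has_M & sp$has_N1),
      sum(sp$has_M & sp$has_N1))
  add("N1_R2_requires_V", !any(sp$has_N1 & sp$has_R2 & !sp$has_V), "")
  add("M_R2_requires_V", !any(sp$has_M & sp$has_R2 & !sp$has_V), "")
  okM <- sp$compartment[sp$has_M] %in% c("ext", "surf")
  add("M_species_ext_or_surf_only", all(okM), sum(!okM))
  mvr2 <- sp$has_M & sp$has_R2
  add("MVR2_surface_only", all(sp$compartment[mvr2] == "surf"), "")
  degr <- sp$compartment == "degr"
  add("degraded_phospho_free",
      !any(sp$p951[degr] | sp$p1175[degr] | sp$p1214[degr]), "")
  add("MVR2_not_internalized",
      !any(rx$kind == "internalize" & sp$has_M[rx$r1]), "")
  # stoichiometry of binding
  bon <- rx[rx$kind == "binding_on", ]
  add("binding_on_2reactants_1product",
      all(!is.na(bon$r1) & !is.na(bon$r2) & !is.na(bon$p1) & is.na(bon$p2)), "")
  # phospho preservation (binding + trafficking except degrade)
  keep <- rx$kind %in% c("binding_on", "binding_off", "internalize",
                         "recycle_rab4", "recycle_rab11", "transfer_4to11")
  pres <- vapply(which(keep), function(i) {
    ids <- c(rx$r1[i], rx$r2[i], rx$p1[i], rx$p2[i])
    ids <- ids[!is.na(ids)]
    r2ids <- ids[sp$has_R2[ids]]
    if (!length(r2ids)) return(TRUE)
    length(unique(paste(sp$p951[r2ids], sp$p1175[r2ids], sp$p1214[r2ids]))) == 1L
  }, logical(1))
  add("phospho_preserved_by_binding_and_trafficking", all(pres), sum(!pres))
  dg <- rx[rx$kind == "degrade", ]
  cleared <- !sp$p951[dg$p1] & !sp$p1175[dg$p1] & !sp$p1214[dg$p1]
  add("degradation_clears_phospho", all(cleared), sum(!cleared))
  # one shared rate name per trafficking family (phospho-uniform)
  tr <- rx[rx$kind %in% c("internalize", "recycle_rab4", "recycle_rab11",
                          "transfer_4to11", "degrade"), ]
  uni <- tapply(tr$rate, tr$family, function(z) length(unique(z)) == 1L)
  add("trafficking_rates_phospho_uniform", all(uni), sum(!uni))
  # reachability
  srcNames <- intersect(c("ext:V", "ext:M", "surf:N1"), sp$name)
  src <- net@index[srcNames]
  r2zero <- which(sp$compartment == "surf" & sp$form == "R2" &
                  !sp$p951 & !sp$p1175 & !sp$p1214)
  seen <- .reachable(net, c(src, r2zero))
  live <- sp$compartment != "degr"
  add("all_live_species_reachable", all(seen[live]),
      paste(sp$name[live & !seen], collapse = ","))
  if ("rab11:V" %in% sp$name) {
    iv11 <- net@index[["rab11:V"]]
    prod11 <- which(rx$p1 == iv11 | (!is.na(rx$p2) & rx$p2 == iv11))
    add("rab11_free_V_only_from_dissociation",
        all(rx$kind[prod11] == "binding_off"), "")
  }
  do.call(rbind, out)
}

#' Deterministic plain-text dump of a network
#'
#' One line per species (sorted as enumerated) followed by one line per
#' reaction; stable across runs and platforms, suitable as a golden file.
#'
#' @param net a \code{ReactionNetwork}.
#' @return character vector of lines.
#' @export
networkDump <- function(net) {
  sp <- net@species
  rx <- net@reactions
  rname <- function(i) ifelse(is.na(i), "", sp$name[i])
  lhs <- trimws(paste(rname(rx$r1),
                      ifelse(is.na(rx$r2), "", paste("+", rname(rx$r2)))))
  rhs <- trimws(paste(rname(rx$p1),
                      ifelse(is.na(rx$p2), "", paste("+", rname(rx$p2)))))
  c(paste0("species\t", sp$name),
    sort(paste0("reaction\t", rx$kind, "\t", trimws(lhs), " -> ", rhs,
                "\t@", rx$rate)))
}

#' @rdname validateNetwork
#' @export
setMethod("show", "ReactionNetwork", function(object) {
  cnt <- reactionCounts(object)
  cat("ReactionNetwork:", cnt[["species"]], "species,",
      cnt[["total_unidirectional"]], "unidirectional reactions\n")
  cat("  reversible binding types:", cnt[["binding_reversible_types"]],
      "| reversible phospho:", cnt[["phospho_reversible"]],
      "| trafficking:", cnt[["trafficking"]], "\n")
})
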