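# Configuration files, CSV/JSON input-output, run manifests.

.configDefaults <- function() {
  list(study = "other", mode = "soluble", vegf_ng_ml = 20,
       duration_min = 60, solver = "stiff", rtol = 1e-8, atol = 1e-6,
       geometry = list(cellDensity = 1e5, endoVol = 1e-7),
       perturbations = list())
}

#' Load and validate a run configuration
#'
#' YAML (or JSON) mapping with keys study, mode, vegf_ng_ml, duration_min,
#' solver, rtol, atol, geometry (cellDensity, endoVol), perturbations.
#' Missing keys take defaults; unknown keys are rejected with their path;
#' invalid values are listed with their field path. An empty file yields the
#' full default configuration for the "other" study.
#'
#' @param path file path.
#' @return validated configuration list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defs <- .configDefaults()
  bad <- setdiff(names(raw), names(defs))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- modifyList(defs, raw)
  errs <- character(0)
  if (!cfg$study %in% studyNames())
    errs <- c(errs, paste0("study: unknown study '", cfg$study, "'"))
  if (!cfg$mode %in% c("soluble", "immobilized"))
    errs <- c(errs, "mode: must be soluble or immobilized")
  if (!is.numeric(cfg$vegf_ng_ml) || cfg$vegf_ng_ml < 0)
    errs <- c(errs, "vegf_ng_ml: must be >= 0")
  if (!is.numeric(cfg$duration_min) || cfg$duration_min <= 0)
    errs <- c(errs, "duration_min: must be > 0")
  if (!cfg$solver %in% c("stiff", "rk45"))
    errs <- c(errs, "solver: must be stiff or rk45")
  for (g in c("cellDensity", "endoVol"))
    if (!is.numeric(cfg$geometry[[g]]) || cfg$geometry[[g]] <= 0)
      errs <- c(errs, paste0("geometry.", g, ": must be > 0"))
  for (i in seq_along(cfg$perturbations))
    if (is.null(cfg$perturbations[[i]]$kind))
      errs <- c(errs, paste0("perturbations[", i, "].kind: required"))
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

#' Build a protocol from a configuration
#' @param cfg list from \code{\link{loadConfig}}.
#' @export
protocolFromConfig <- function(cfg) {
  base <- defaultParameters(cellDensity = cfg$geometry$cellDensity,
                            endoVol = cfg$geometry$endoVol)
  makeScenario(cfg$study, mode = cfg$mode, vegf_ng_ml = cfg$vegf_ng_ml,
               duration_s = cfg$duration_min * 60,
               perturbations = cfg$perturbations, base = base)
}

#' Serialize a parameter set to a flat configuration file
#'
#' Writes all kinetic, trafficking, phosphorylation, and geometry values as
#' flat dotted keys (YAML mapping), with the study configuration nested
#' under \code{study}. \code{readParameters} applies such a file on top of
#' a base set, so a partial file acts as an override layer.
#'
#' @param params a \code{ParameterSet}.
#' @param path output file.
#' @export
writeParameters <- function(params, path) {
  out <- list(kinetic = as.list(params@kinetic),
              trafficking = as.list(params@trafficking),
              phospho = as.list(params@phospho),
              geometry = as.list(params@geometry))
  if (length(params@study))
    out$study <- params@study[setdiff(names(params@study), "ss")]
  yaml::write_yaml(out, path, precision = 15)
  invisible(params)
}

#' @rdname writeParameters
#' @param base base \code{ParameterSet} the file's values are applied onto.
#' @export
readParameters <- function(path, base = defaultParameters()) {
  raw <- yaml::read_yaml(path)
  p <- base
  for (slotName in c("kinetic", "trafficking", "phospho", "geometry")) {
    v <- raw[[slotName]]
    if (is.null(v)) next
    cur <- slot(p, slotName)
    unknown <- setdiff(names(v), names(cur))
    if (length(unknown))
      stop("unknown ", slotName, " keys: ", paste(unknown, collapse = ", "))
    cur[names(v)] <- unlist(v)
    slot(p, slotName) <- cur
  }
  if (!is.null(raw$study)) p@study <- raw$study
  if (length(p@study)) p <- computeProductionRates(p)
  p
}

#' Write a time course as tidy CSV
#'
#' Long format (time_s, species, compartment, value, unit) with the protocol
#' echoed as a JSON header comment line. Numbers are written at full double
#' precision.
#'
#' @param tc a \code{TimeCourse}.
#' @param path output file.
#' @param wide write one column per species (time_s first) instead of the
#'   long format; the wide form is not read back by
#'   \code{\link{readTimeCourseCsv}}.
#' @export
writeTimeCourseCsv <- function(tc, path, wide = FALSE) {
  prot <- tc@protocol
  hdr <- jsonlite::toJSON(list(label = prot@label, mode = prot@mode,
                               vegf_ng_ml = prot@vegf_ng_ml,
                               duration_s = prot@duration_s,
                               depth_cm = prot@params@geometry[["depth.cm"]],
                               baselineR2 = tc@baselineR2,
                               solver = tc@solver),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  if (wide) {
    m <- statesMolar(tc)
    df <- data.frame(time_s = tc@times)
    for (j in seq_len(ncol(m)))
      df[[tc@network@species$name[j]]] <-
        format(m[, j], digits = 17, scientific = TRUE, trim = TRUE)
    write.csv(df, con, row.names = FALSE, quote = TRUE)
  } else {
    df <- timeCourseToDataFrame(tc)
    df$value <- format(df$value, digits = 17, scientific = TRUE, trim = TRUE)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
}

#' Read a time course back from tidy CSV
#'
#' Inverse of \code{\link{writeTimeCourseCsv}}: rebuilds the state matrix
#' (extracellular rows converted back to the molecules-per-cm2 basis using
#' the fluid depth echoed in the header), reconstructs the matching network
#' from the species names present, and restores the normalization baseline.
#' The embedded protocol carries the echoed mode/dose/duration over the
#' default parameter set; it documents provenance rather than enabling
#' re-simulation.
#'
#' @param path CSV written by \code{writeTimeCourseCsv}.
#' @return a \code{\linkS4class{TimeCourse}}.
#' @export
readTimeCourseCsv <- function(path) {
  hdrLine <- readLines(path, n = 1)
  if (!startsWith(hdrLine, "# "))
    stop("missing protocol header comment in ", path)
  hdr <- jsonlite::fromJSON(sub("^# ", "", hdrLine))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  net <- buildNetwork(
    includeNRP1 = any(grepl("N1", df$species)),
    includeMatrix = any(df$species == "ext:M"),
    includePhospho = any(grepl("[p951=", df$species, fixed = TRUE)))
  times <- sort(unique(df$time_s))
  states <- matrix(NA_real_, length(times), nrow(net@species),
                   dimnames = list(NULL, net@species$name))
  for (nm in unique(df$species)) {
    sel <- df$species == nm
    states[, nm] <- df$value[sel][order(df$time_s[sel])]
  }
  if (anyNA(states)) stop("species in file do not match the network")
  ext <- net@species$compartment == "ext"
  states[, ext] <- states[, ext] * AVOGADRO * hdr$depth_cm * 1e-3
  params <- defaultParameters(depth = hdr$depth_cm)
  prot <- makeProtocol(params, mode = hdr$mode, vegf_ng_ml = hdr$vegf_ng_ml,
                       duration_s = hdr$duration_s,
                       grid_s = times, label = hdr$label)
  new("TimeCourse", times = times, states = unname(states), network = net,
      protocol = prot, baselineR2 = hdr$baselineR2,
      solver = as.list(hdr$solver))
}

#' Read observations from CSV
#' @param path CSV with columns observable, time_s, value, weight.
#' @export
readObservations <- function(path) {
  obs <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("observable", "time_s", "value", "weight")
  if (!all(need %in% names(obs)))
    stop("observations CSV needs columns: ", paste(need, collapse = ", "))
  obs
}

#' Write a fit ensemble
#'
#' JSON summary plus a CSV of the accepted parameter vectors.
#'
#' @param ens a \code{FitEnsemble}.
#' @param dir output directory (created).
#' @export
writeEnsemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(nStarts = nrow(ens@starts), band = ens@band,
         bestCost = min(ens@starts$cost),
         accepted = sum(ens@starts$accepted),
         best = as.list(ens@best)),
    file.path(dir, "ensemble.json"), auto_unbox = TRUE, digits = NA)
  acc <- ens@estimates[ens@starts$accepted, , drop = FALSE]
  write.csv(as.data.frame(acc), file.path(dir, "accepted_parameters.csv"),
            row.names = FALSE)
  invisible(ens)
}

#' Run manifest
#'
#' Deterministic description of a run: command, configuration hash, seeds,
#' package version, solver settings, output files.
#'
#' @param command character.
#' @param config list used for the run.
#' @param seed integer or NULL.
#' @param outputs character vector of output paths.
#' @param path optional file to write the manifest JSON to.
#' @export
runManifest <- function(command, config, seed = NULL, outputs = character(0),
                        path = NULL) {
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  man <- list(command = command,
              config_hash = sprintf("%08x",
                sum(utf8ToInt(as.character(cfgJson)) *
                    (seq_len(nchar(cfgJson)) %% 97 + 1)) %% .Machine$integer.max),
              seed = seed,
              package_version = as.character(utils::packageVersion("vegfr2traffic")),
              outputs = outputs)
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  man
}
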