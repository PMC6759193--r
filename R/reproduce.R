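#' Default configuration for the reproduce-all pipeline
#'
#' @return list of stage parameters: master `seed`, number of sampled
#'   parameterisations for the empirical influence stage
#'   (`empiricalSeeds`), the critical-gain verification grid
#'   (`prop1Theta`, `prop1Tau`, `prop1Ratio`), the propensity-surface
#'   settings (`surfaceN`, `surfaceNGrid`, `surfaceTheta`,
#'   `surfacePairs`) and whether PNG plots are written (`plots`).
#' @export
defaultConfig <- function() {
  list(seed = 1L,
       empiricalSeeds = 50L,
       prop1Theta = c(0, 0.5, 1),
       prop1Tau = c(2, 3, 4),
       prop1Ratio = c(0.2, 0.5, 0.8),
       surfaceN = 41L,
       surfaceNGrid = 2e4,
       surfaceTheta = 0.5,
       surfacePairs = list(c(0.5, 0.5), c(0.4, 0.6), c(0.3, 0.7),
                           c(0.2, 0.8)),
       plots = TRUE)
}

#' Load a pipeline configuration from YAML
#'
#' Fields present in the file override [defaultConfig()] entries.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
loadConfig <- function(path) {
  cfg <- defaultConfig()
  user <- yaml::read_yaml(path)
  if (!is.null(user$surfacePairs))
    user$surfacePairs <- lapply(user$surfacePairs, as.numeric)
  utils::modifyList(cfg, user)
}

stageLog <- function(stage, t0, seed) {
  message(sprintf("[%s] done in %.2fs (seed %d)", stage,
                  as.numeric(proc.time()[3] - t0), seed))
}

#' Regenerate every headline analysis into a report bundle
#'
#' Runs, in order: fixture construction and cycle/gauge analysis of the
#' bundled networks; structural influence matrices of the two AAR
#' regulation schemes with their sampling-oracle cross-check; the
#' empirical (simulated) influence experiment over sampled
#' parameterisations; the critical-gain verification table; and the
#' four oscillation-propensity surfaces.  All results land in CSV/JSON
#' files under `outDir`, together with a run manifest (seed,
#' configuration, package and R versions) sufficient to regenerate the
#' bundle.
#'
#' @param outDir output directory (created if needed).
#' @param config configuration list (see [defaultConfig()],
#'   [loadConfig()]).
#' @param seed master seed overriding `config$seed`.
#' @return invisibly, a list with `ok` (all internal consistency checks
#'   passed), `checks` (named logical vector) and `files`.
#' @export
runReproduceAll <- function(outDir, config = defaultConfig(),
                            seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  checks <- c()
  files <- character(0)
  emit <- function(name) {
    p <- file.path(outDir, name)
    files <<- c(files, p)
    p
  }

  ## -- cycles and gauges ----------------------------------------------
  t0 <- proc.time()[3]
  aav <- aavGraph()
  cyc <- enumerateCycles(aav)
  cycDF <- data.frame(
    cycle = vapply(cyc, function(cy) paste(cy$nodes, collapse = ">"), ""),
    length = lengths(lapply(cyc, `[[`, "nodes")),
    sign = vapply(cyc, `[[`, numeric(1), "sign"))
  cycDF$contains_x1 <- grepl("(^|>)x_1(>|$)", cycDF$cycle)
  utils::write.csv(cycDF, emit("cycles_aav.csv"), row.names = FALSE,
                   quote = FALSE)
  checks["all_aav_cycles_negative"] <- all(cycDF$sign == -1)
  checks["all_aav_cycles_through_x1"] <- all(cycDF$contains_x1)
  checks["aav_internal_dag"] <- isInternalDag(aav, paste0("x_", 1:15))
  gaugeAAR <- findCooperativeGauge(aarReducedGraph(),
                                   c("ACO", "JGC", "HMY", "SPN"))
  gaugeAAV <- findCooperativeGauge(aav, paste0("x_", 1:15))
  checks["aar_core_balanceable"] <- !is.null(gaugeAAR)
  checks["aav_cell_balanceable"] <- !is.null(gaugeAAV)
  gaugeDF <- data.frame(
    subsystem = c(rep("AAR_core", length(gaugeAAR)),
                  rep("AAV_cell", length(gaugeAAV))),
    node = c(names(gaugeAAR), names(gaugeAAV)),
    sigma = c(gaugeAAR, gaugeAAV))
  utils::write.csv(gaugeDF, emit("gauge_report.csv"), row.names = FALSE,
                   quote = FALSE)
  stageLog("cycles+gauges", t0, seed)

  ## -- structural influence -------------------------------------------
  t0 <- proc.time()[3]
  Mdtc <- structuralInfluenceMatrix(sigmaDTC())
  Mvsm <- structuralInfluenceMatrix(sigmaVSM())
  writeInfluenceCSV(Mdtc, emit("influence_dtc.csv"))
  writeInfluenceCSV(Mvsm, emit("influence_vsm.csv"))
  checks["det_dtc_positive"] <- structuralDeterminantSign(sigmaDTC()) == "+"
  checks["det_vsm_positive"] <- structuralDeterminantSign(sigmaVSM()) == "+"
  oracleOK <- TRUE
  for (sig in list(sigmaDTC(), sigmaVSM())) {
    ex <- influenceClasses(structuralInfluenceMatrix(sig))
    or <- influenceClasses(samplingOracleInfluence(sig, 2000L, seed))
    oracleOK <- oracleOK && all(or[ex != "?"] == ex[ex != "?"])
  }
  checks["influence_oracle_consistent"] <- oracleOK
  stageLog("structural influence", t0, seed)

  ## -- empirical influence --------------------------------------------
  t0 <- proc.time()[3]
  agree <- TRUE
  counts <- list(dtc = NULL, vsm = NULL)
  exact <- list(dtc = influenceClasses(Mdtc), vsm = influenceClasses(Mvsm))
  for (k in seq_len(config$empiricalSeeds)) {
    sc <- sampleAARSchemes(seed + k)
    for (nm in c("dtc", "vsm")) {
      emp <- empiricalInfluence(sc[[nm]], seed = seed + k)
      ex <- exact[[nm]][rownames(emp), colnames(emp)]
      agree <- agree &&
        !any(emp == "+" & ex == "-") && !any(emp == "-" & ex == "+") &&
        !any(emp != "0" & ex == "0")
      if (is.null(counts[[nm]]))
        counts[[nm]] <- matrix(0L, nrow(emp), ncol(emp),
                               dimnames = dimnames(emp))
      counts[[nm]] <- counts[[nm]] + (emp == "+")
    }
  }
  for (nm in c("dtc", "vsm"))
    utils::write.csv(as.data.frame(counts[[nm]]),
                     emit(sprintf("empirical_positive_counts_%s.csv", nm)),
                     quote = FALSE)
  checks["empirical_within_structural"] <- agree
  stageLog("empirical influence", t0, seed)

  ## -- critical-gain table --------------------------------------------
  t0 <- proc.time()[3]
  grid <- expand.grid(theta = config$prop1Theta, tau1 = config$prop1Tau,
                      tau2 = config$prop1Tau, ratio = config$prop1Ratio)
  grid$s_star <- mapply(function(th, t1, t2, r)
    criticalGain(th, t1, t2, r)$gain,
    grid$theta, grid$tau1, grid$tau2, grid$ratio)
  utils::write.csv(grid, emit("critical_gain_table.csv"),
                   row.names = FALSE, quote = FALSE)
  eqDelay <- grid$theta == 0 & grid$tau1 == grid$tau2
  checks["critical_gain_floor"] <- all(grid$s_star >= 1 - 1e-9)
  checks["critical_gain_unity_at_theta0"] <-
    all(abs(grid$s_star[eqDelay] - 1) < 1e-6)
  checks["critical_gain_above_unity_otherwise"] <-
    all(grid$s_star[!eqDelay] > 1 + 1e-9)
  stageLog("critical gains", t0, seed)

  ## -- propensity surfaces --------------------------------------------
  t0 <- proc.time()[3]
  diagMax <- TRUE
  pairs <- config$surfacePairs
  if (is.matrix(pairs))      # e.g. round-tripped through JSON
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.numeric(pairs[i, ]))
  for (pq in pairs) {
    surf <- propensitySurface(config$surfaceTheta, pq[1], pq[2],
                              n = config$surfaceN,
                              nGrid = config$surfaceNGrid)
    tag <- sprintf("p%02.0f", 100 * pq[1])
    writeSurfaceCSV(surf, emit(sprintf("surface_%s.csv", tag)))
    if (isTRUE(config$plots)) {
      png <- emit(sprintf("surface_%s.png", tag))
      grDevices::png(png, width = 720, height = 640)
      plotSurface(surf)
      grDevices::dev.off()
    }
    J <- surf@jstar
    diagMax <- diagMax && max(diag(J)) >= max(J) - 1e-9
  }
  checks["surface_diagonal_maximal"] <- diagMax
  stageLog("propensity surfaces", t0, seed)

  manifest <- list(seed = seed,
                   config = config[setdiff(names(config), "plots")],
                   package = as.character(utils::packageVersion("vasoloop")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  jsonlite::write_json(manifest, emit("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ok <- all(checks)
  if (!ok)
    warning("consistency checks failed: ",
            paste(names(checks)[!checks], collapse = ", "))
  invisible(list(ok = ok, checks = checks, files = files))
}
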