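#' Default pipeline configuration
#'
#' Returns the demo configuration driving [runPipeline()]: 33 synthetic
#' sausage phantoms, both spectral domains with the ten standard
#' pretreatment chains, a two-thirds row-wise calibration split,
#' leave-one-out cross-validation, 12 feature wavelengths and the
#' response-surface stage. Any subset of the list can be overridden via
#' the \code{config} argument of [runPipeline()].
#'
#' @return nested configuration list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    grid = list(start_nm = 350, stop_nm = 1100, step_nm = 5),
    simulate = list(n_samples = 33L, nrow = 48L, ncol = 72L,
                    pH_range = c(4.44, 6.46), gain_sd = 0.05,
                    offset_sd = 0.005, noise_sd = 0.002),
    segmentation = list(band_index = 70L, threshold = 0.075, k = 5L),
    domains = c("reflectance", "absorbance"),
    chains = tableChains(),
    split = list(fraction = 2 / 3, seed = 1L, by = "row"),
    model = list(n_latent = 8L, cv_scheme = "loo"),
    feature_selection = list(k = 12L, min_separation_bands = 2L,
                             use_preset = FALSE,
                             from = list(domain = "reflectance",
                                         chain = "Raw")),
    map = list(scale = c(4.4, 6.5)),
    rsm = list(enabled = TRUE, alpha = 2, n_center = 6L, noise_sd = 0.15,
               hold = c(X2 = 1.78, X4 = 19.5, X5 = 75),
               vary = c("X1", "X3"))
  )
}

## Recursively overlay user values onto the default config.
.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks the configuration against the pipeline's schema -- known keys,
#' value ranges, and recognised chain names -- before any stage runs, so a
#' bad configuration fails fast rather than mid-pipeline.
#'
#' @param config configuration list (see [defaultConfig()]).
#' @return the validated config, invisibly; errors on violation.
#' @export
validateConfig <- function(config) {
  known <- names(defaultConfig())
  extra <- setdiff(names(config), known)
  if (length(extra))
    stopf("unknown config key(s): %s", paste(extra, collapse = ", "))
  g <- config$grid
  wavelengthGrid(g$start_nm, g$stop_nm, g$step_nm)  # validates divisibility
  if (config$split$fraction <= 0 || config$split$fraction >= 1)
    stopf("split fraction must be in (0, 1)")
  if (!all(config$domains %in% c("reflectance", "absorbance")))
    stopf("domains must be reflectance and/or absorbance")
  for (ch in config$chains)
    pretreatmentChain(ch)  # errors on unknown chain names
  if (config$segmentation$k < 1L) stopf("segmentation k must be >= 1")
  if (config$model$n_latent < 1L) stopf("n_latent must be >= 1")
  invisible(config)
}

#' Run the end-to-end pipeline
#'
#' Executes the full workflow on synthetic phantoms: simulate one hypercube
#' per sausage (latent pH drawn uniformly from the configured range),
#' segment at band 70 / 0.075, split each sausage into five equal-area
#' regions and extract the region mean spectra into one table; derive the
#' absorbance table; for every configured domain x chain fit a full-band
#' PLSR and record the six-number metric row (full-model metrics table);
#' select feature wavelengths from the coefficient profile of the
#' configured reference model (or use the published preset); refit reduced
#' models per domain x chain (reduced-model metrics table); produce a
#' pixel-wise pH map of the first phantom from the reduced raw-reflectance
#' model; and run the CCD/response-surface stage against the published
#' surface. Outputs (metrics CSVs, model JSONs, design/ANOVA CSVs, mask and
#' map images) are written under \code{output_dir} with a manifest recording
#' seeds, versions and output checksums.
#'
#' @param config full or partial configuration list, or a path to a YAML
#'   file with the same structure; merged over [defaultConfig()].
#' @param verbose print stage progress.
#' @return the manifest list, invisibly; its \code{tables} element holds the
#'   in-memory results (spectra table, metrics data frames, models, ANOVA).
#' @export
runPipeline <- function(config = list(), verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validateConfig(.mergeConfig(defaultConfig(), config))
  outDir <- cfg$output_dir
  if (is.null(outDir)) outDir <- tempfile("hyperpH_run_")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  grid <- wavelengthGrid(cfg$grid$start_nm, cfg$grid$stop_nm,
                         cfg$grid$step_nm)
  sim <- cfg$simulate

  ## --- simulate + segment + extract -------------------------------------
  say("simulate/segment/extract: %d phantoms", sim$n_samples)
  pHs <- withSeed(cfg$seed,
                  stats::runif(sim$n_samples, sim$pH_range[1],
                               sim$pH_range[2]))
  rows <- vector("list", sim$n_samples)
  firstCube <- NULL; firstMask <- NULL
  for (i in seq_len(sim$n_samples)) {
    spec <- phantomSpec(nrow = sim$nrow, ncol = sim$ncol, grid = grid,
                        pH = pHs[i], gainSd = sim$gain_sd,
                        offsetSd = sim$offset_sd, noiseSd = sim$noise_sd,
                        seed = cfg$seed * 1000L + i)
    ph <- generatePhantomHypercube(spec)
    m <- segmentCube(ph$cube, cfg$segmentation$band_index,
                     cfg$segmentation$threshold)
    lab <- splitRegions(m, cfg$segmentation$k)
    rows[[i]] <- extractMeanSpectra(ph$cube, lab, sprintf("S%03d", i),
                                    pHs[i])
    if (i == 1L) { firstCube <- ph$cube; firstMask <- m }
  }
  tabR <- spectraSet(do.call(rbind, lapply(rows, spectraMatrix)), grid,
                     unlist(lapply(rows, sampleCode)),
                     unlist(lapply(rows, regionId)),
                     unlist(lapply(rows, pHRef)),
                     domain = "reflectance")
  tabA <- replaceSpectra(tabR, toAbsorbance(spectraMatrix(tabR),
                                            clip = TRUE),
                         domain = "absorbance")
  writeSpectraTable(tabR, file.path(outDir, "spectra_reflectance.csv"))

  ## --- full-band models per domain x chain ------------------------------
  split <- splitCalibrationPrediction(tabR, cfg$split$fraction,
                                      cfg$split$seed, cfg$split$by)
  fullMetrics <- list()
  fullModels <- list()
  for (dom in cfg$domains) {
    tab <- if (dom == "reflectance") tabR else tabA
    for (ch in cfg$chains) {
      say("full model: %s / %s", dom, ch)
      chain <- pretreatmentChain(ch, dom)
      fullMetrics[[paste(dom, ch)]] <-
        chainMetrics(tab, chain, split, cfg$model$n_latent,
                     cvScheme = cfg$model$cv_scheme)
      pre <- applyChain(tab, chain, calibrationRows = split$calibration)
      M <- spectraMatrix(pre)
      fullModels[[paste(dom, ch)]] <-
        fitPLSR(M[split$calibration, , drop = FALSE],
                pHRef(tab)[split$calibration],
                min(cfg$model$n_latent, length(split$calibration) - 1L),
                wavelengthsNm = wavelengths(grid), chain = ch)
    }
  }
  fullMetrics <- do.call(rbind, c(fullMetrics, make.row.names = FALSE))
  utils::write.csv(fullMetrics, file.path(outDir, "metrics_full.csv"),
                   row.names = FALSE)

  ## --- feature selection + reduced models --------------------------------
  fs <- cfg$feature_selection
  fw <- if (isTRUE(fs$use_preset)) presetFeatureWavelengths()
        else selectFeatureWavelengths(
          fullModels[[paste(fs$from$domain, fs$from$chain)]], grid,
          k = fs$k, minSeparationBands = fs$min_separation_bands)
  say("feature wavelengths: %s", paste(fw, collapse = ", "))
  reducedMetrics <- list()
  reducedLinear <- NULL
  for (dom in cfg$domains) {
    tab <- if (dom == "reflectance") tabR else tabA
    for (ch in cfg$chains) {
      red <- buildReducedModel(tab, fw, split, cfg$model$n_latent,
                               chain = pretreatmentChain(ch, dom),
                               cvScheme = cfg$model$cv_scheme)
      reducedMetrics[[paste(dom, ch)]] <- red$metrics
      if (dom == "reflectance" && ch == "Raw") reducedLinear <- red$linear
    }
  }
  reducedMetrics <- do.call(rbind, c(reducedMetrics,
                                     make.row.names = FALSE))
  utils::write.csv(reducedMetrics, file.path(outDir, "metrics_reduced.csv"),
                   row.names = FALSE)
  writeLinearModelJSON(reducedLinear,
                       file.path(outDir, "reduced_model.json"))

  ## --- prediction map -----------------------------------------------------
  say("prediction map")
  pm <- predictMap(firstCube, reducedLinear, firstMask,
                   scale = cfg$map$scale)
  renderMap(pm, file.path(outDir, "prediction_map.png"))
  writeMapCSV(pm, file.path(outDir, "prediction_map.csv"))
  writeMaskPNG(firstMask, file.path(outDir, "mask.png"))

  ## --- response-surface stage ---------------------------------------------
  anova <- NULL; surface <- NULL
  if (isTRUE(cfg$rsm$enabled)) {
    say("response surface")
    design <- generateCCD(alpha = cfg$rsm$alpha, nCenter = cfg$rsm$n_center,
                          seed = cfg$seed)
    y <- generateRSMResponses(presetSurface(), design,
                              noiseSd = cfg$rsm$noise_sd,
                              seed = cfg$seed + 1L)
    surface <- fitQuadraticSurface(design, y)
    anova <- anovaQuadratic(design, y)
    utils::write.csv(cbind(run = seq_len(nrow(codedMatrix(design))),
                           as.data.frame(uncodedMatrix(design)),
                           point_type = design@pointType, pH = y),
                     file.path(outDir, "ccd_design.csv"), row.names = FALSE)
    utils::write.csv(anova, file.path(outDir, "rsm_anova.csv"),
                     row.names = FALSE)
    writeSurfaceJSON(surface, file.path(outDir, "rsm_surface.json"))
  }

  ## --- manifest -----------------------------------------------------------
  outputs <- list.files(outDir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package = "hyperpH",
    version = as.character(utils::packageVersion("hyperpH")),
    r_version = R.version.string,
    seed = cfg$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    config = cfg,
    feature_wavelengths = fw,
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$output_dir <- outDir
  manifest$tables <- list(spectra = tabR, full_metrics = fullMetrics,
                          reduced_metrics = reducedMetrics,
                          reduced_model = reducedLinear, anova = anova,
                          surface = surface)
  invisible(manifest)
}
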