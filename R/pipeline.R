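## End-to-end orchestration: simulate -> fit -> report, driven by a YAML/list
## config. Stages communicate only through serialized artifacts; every
## output JSON embeds the package version, config hash and master seed, and
## the run manifest lists every artifact with its md5 checksum so that
## identical config + seed reruns are checksum-identical.

.pipelineStages <- c("simulate", "exsy", "rex", "cluster", "popfit", "shifts")

## internal: md5 of the canonical JSON form of a config list; the output
## location is excluded so the hash identifies the scientific configuration
.configHash <- function(config) {
  config$outDir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

## internal: write an artifact JSON with the standard provenance header
.writeArtifact <- function(x, path, meta) {
  jsonlite::write_json(c(list(tool = "ligandconf",
                              version = meta$version,
                              configHash = meta$configHash,
                              seed = meta$seed), x),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}

#' Validate a pipeline run configuration
#'
#' Checks the config against the expected schema before any computation:
#' known stage names, required per-stage parameters, stage dependencies
#' (e.g. the population fit needs an ensemble, from the simulate stage or
#' from files), and existence of every referenced input file. Errors name
#' the offending stage.
#'
#' @param config a list, or path to a YAML file
#' @return the normalized config list, invisibly; errors on invalid input
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$stages) || !length(config$stages))
    stop("config must select at least one stage")
  bad <- setdiff(config$stages, .pipelineStages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1
  if (is.null(config$outDir)) stop("config must set outDir")
  has <- function(s) s %in% config$stages
  if (has("exsy") && !has("simulate") && is.null(config$exsy$inputFile))
    stop("stage 'exsy': needs the simulate stage or exsy$inputFile")
  if (has("popfit") && !has("simulate") &&
      (is.null(config$popfit$ensembleFile) ||
       is.null(config$popfit$observedFile)))
    stop("stage 'popfit': needs the simulate stage or ",
         "popfit$ensembleFile + popfit$observedFile")
  for (f in c(config$exsy$inputFile, config$popfit$ensembleFile,
              config$popfit$observedFile, config$shifts$file)) {
    if (!is.null(f) && !file.exists(f))
      stop("referenced input file does not exist: ", f)
  }
  invisible(config)
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order, writing every
#' intermediate and final result under \code{outDir}:
#' \describe{
#'   \item{simulate}{synthetic EXSY dataset (CSV + JSON) and a synthetic
#'     conformer ensemble with observed data (JSON), from ground truth in
#'     the config}
#'   \item{exsy}{per-temperature rate fits and the Arrhenius barrier}
#'   \item{rex}{replica-exchange torsional sampling and its profile /
#'     ergodicity report, plus histogram and radial plot-data CSVs}
#'   \item{cluster}{representative-conformer clustering report}
#'   \item{popfit}{simplex-constrained population fit against the observed
#'     data}
#'   \item{shifts}{shift-list parsing and rotamer-fraction accounting}
#' }
#'
#' @param config list or YAML path accepted by
#'   \code{\link{validateRunConfig}}
#' @param quiet suppress per-stage log lines
#' @return the run manifest (list), invisibly; also written as
#'   \code{manifest.json}
#' @export
runPipeline <- function(config, quiet = FALSE) {
  config <- validateRunConfig(config)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(version = as.character(utils::packageVersion("ligandconf")),
               configHash = .configHash(config), seed = config$seed)
  artifacts <- character(0)
  completed <- character(0)
  logline <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  out <- function(name) file.path(config$outDir, name)
  runStage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    logline("[%s] start", stage)
    fun()
    logline("[%s] done (%.2f s)", stage, proc.time()[["elapsed"]] - t0)
    completed <<- c(completed, stage)
  }
  has <- function(s) s %in% config$stages

  if (has("simulate")) runStage("simulate", function() {
    sc <- config$simulate
    truth <- arrheniusTruth(
      ea = if (is.null(sc$ea)) 19.9 else sc$ea,
      kRef = if (is.null(sc$kRef)) 1.386 else sc$kRef,
      tRef = if (is.null(sc$tRef)) 300 else sc$tRef,
      temperatures = if (is.null(sc$temperatures)) c(300, 305, 310)
                     else sc$temperatures)
    ds <- genExsyDataset(truth,
                         sigma = if (is.null(sc$sigma)) 0.02 else sc$sigma,
                         seed = config$seed)
    writeEXSYCsv(ds, out("exsy_data.csv"))
    writeEXSYJson(ds, out("exsy_data.json"))
    pc <- config$popfit
    tw <- if (is.null(pc$trueWeights)) c(0.7, 0.3) else pc$trueWeights
    syn <- genConformerEnsemble(
      tw, nConformers = if (is.null(pc$nConformers)) length(tw)
                        else pc$nConformers,
      sigma = if (is.null(pc$sigma)) 0 else pc$sigma, seed = config$seed)
    writeEnsembleJson(syn$ensemble, out("ensemble.json"))
    .writeArtifact(list(observables = syn$observed@observables,
                        provenance = syn$provenance),
                   out("observed.json"), meta)
    artifacts <<- c(artifacts, out("exsy_data.csv"), out("exsy_data.json"),
                    out("ensemble.json"), out("observed.json"))
  })

  if (has("exsy")) runStage("exsy", function() {
    src <- if (!is.null(config$exsy$inputFile)) config$exsy$inputFile
           else out("exsy_data.csv")
    ds <- readEXSYCsv(src)
    fits <- fitRates(ds)
    arr <- withCallingHandlers(
      fitArrhenius(fits),
      warning = function(w) invokeRestart("muffleWarning"))
    .writeArtifact(list(
      rates = data.frame(
        temperature_K = vapply(fits, function(f) f@temperature, numeric(1)),
        k = vapply(fits, function(f) f@k, numeric(1)),
        t_half_s = vapply(fits, function(f) f@tHalf, numeric(1))),
      arrhenius = list(ea_kcal_mol = arr@ea, lnA = arr@lnA,
                       rSquared = arr@rSquared,
                       narrowSpan = arr@narrowSpan),
      eyring_dG_kcal_mol = eyringBarrier(fits[[1]]@k, fits[[1]]@temperature)),
      out("exsy_fit.json"), meta)
    artifacts <<- c(artifacts, out("exsy_fit.json"))
  })

  if (has("rex")) runStage("rex", function() {
    rc <- config$rex
    pot <- genTorsionPotential(
      if (is.null(rc$preset)) "hindered_biaryl" else rc$preset)
    ladder <- buildLadder(if (is.null(rc$tMin)) 300 else rc$tMin,
                          if (is.null(rc$tMax)) 3302 else rc$tMax,
                          if (is.null(rc$replicas)) 12 else rc$replicas)
    traj <- runRex(pot, ladder,
                   sweeps = if (is.null(rc$sweeps)) 20000 else rc$sweeps,
                   startAngle = if (is.null(rc$startAngle)) 90
                                else rc$startAngle,
                   seed = config$seed)
    rep <- rexReport(traj, pot)
    utils::write.csv(rep@histogram, out("rex_histogram.csv"),
                     row.names = FALSE)
    utils::write.csv(radialSeries(traj, burnIn = 0.1), out("rex_radial.csv"),
                     row.names = FALSE)
    .writeArtifact(list(minima = rep@minima, barriers = rep@barriers,
                        occupancies = rep@occupancies,
                        transitions = rep@transitions,
                        ergodic = rep@ergodic,
                        ladder = as.numeric(ladder)),
                   out("rex_report.json"), meta)
    artifacts <<- c(artifacts, out("rex_histogram.csv"),
                    out("rex_radial.csv"), out("rex_report.json"))
  })

  if (has("cluster")) runStage("cluster", function() {
    cc <- config$cluster
    ens <- if (!is.null(cc$ensembleFile)) readEnsembleJson(cc$ensembleFile)
           else genWellEnsemble(n = if (is.null(cc$n)) 300 else cc$n,
                                seed = config$seed)
    cl <- clusterConformers(ens,
      threshold = if (is.null(cc$threshold)) 30 else cc$threshold)
    .writeArtifact(list(nConformers = nConformers(ens),
                        nClusters = max(cl$assignment),
                        representativeIds = cl$representativeIds),
                   out("cluster_report.json"), meta)
    artifacts <<- c(artifacts, out("cluster_report.json"))
  })

  if (has("popfit")) runStage("popfit", function() {
    pc <- config$popfit
    ensFile <- if (!is.null(pc$ensembleFile)) pc$ensembleFile
               else out("ensemble.json")
    obsFile <- if (!is.null(pc$observedFile)) pc$observedFile
               else out("observed.json")
    ens <- readEnsembleJson(ensFile)
    oj <- jsonlite::read_json(obsFile, simplifyVector = TRUE)
    od <- as.data.frame(oj$observables)
    obs <- ObservedData(od$name, od$kind, od$value, od$weight, od$unit)
    fit <- fitPopulations(ens, obs)
    .writeArtifact(list(weights = as.list(fitWeights(fit)), ssd = fit@ssd,
                        pruned = fit@pruned,
                        rms = as.list(goodnessReport(fit, obs)$rms)),
                   out("population_fit.json"), meta)
    artifacts <<- c(artifacts, out("population_fit.json"))
  })

  if (has("shifts")) runStage("shifts", function() {
    src <- if (!is.null(config$shifts$file)) config$shifts$file
           else shiftListFixture(2)
    sl <- suppressWarnings(parseShiftList(readLines(src, warn = FALSE)))
    fr <- tryCatch(suppressWarnings(rotamerFractions(sl)),
                   error = function(e) NULL)
    .writeArtifact(list(
      nEntries = nrow(sl@entries), totalProtons = totalProtons(sl),
      frequencyMHz = sl@frequencyMHz, solvent = sl@solvent,
      rotamerFractions = if (is.null(fr)) NULL else as.list(fr),
      imbalance = if (is.null(fr)) NULL else attr(fr, "imbalance")),
      out("shifts.json"), meta)
    artifacts <<- c(artifacts, out("shifts.json"))
  })

  manifest <- list(tool = "ligandconf", version = meta$version,
                   configHash = meta$configHash, seed = meta$seed,
                   stages = completed,
                   artifacts = data.frame(
                     path = basename(artifacts),
                     md5 = unname(tools::md5sum(artifacts))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
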