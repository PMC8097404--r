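#' Build a run configuration for the site-mapping pipeline
#'
#' @param input either `list(synthetic = <SyntheticSystemSpec>)` to analyse a
#'   generated system, or `list(topology = <path>, coordinates = <path or
#'   NULL>, rules = <annotationRules>, dt = <ns>)` for file input
#' @param species primary lipid species to map
#' @param speciesPair two species for the fold-enrichment comparison
#' @param stages analysis toggles, any of `"contacts"`, `"binders"`, `"maps"`,
#'   `"clustering"`, `"chemistry"`
#' @param config an [analysisConfig()]
#' @param outputDir output directory (created if missing)
#' @param maxPoses frame subsample size for pose clustering
#' @param seed integer seed governing every stochastic step
#' @return list of class `RunConfig`
#' @export
runConfig <- function(input, species = "LIN", speciesPair = c("LIN", "STE"),
                      stages = c("contacts", "binders", "maps", "clustering"),
                      config = analysisConfig(), outputDir = tempfile("run"),
                      maxPoses = 200L, seed = 1L) {
  structure(list(input = input, species = species, speciesPair = speciesPair,
                 stages = stages, config = config, outputDir = outputDir,
                 maxPoses = as.integer(maxPoses), seed = as.integer(seed)),
            class = "RunConfig")
}

#' Load a run configuration from YAML
#'
#' File inputs only; the YAML maps directly onto [runConfig()] arguments, with
#' `input.topology`, `input.coordinates`, `input.dt`, and annotation rules
#' under `input.rules` (`lipids`, `proteinResnames`).
#'
#' @param path YAML file
#' @return a `RunConfig`
#' @export
runConfigFromYAML <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- do.call(annotationRules, c(
    list(lipids = lapply(y$input$rules$lipids, function(l)
      list(resnames = l$resnames, headAtoms = l$headAtoms))),
    y$input$rules[setdiff(names(y$input$rules), "lipids")]))
  cfgArgs <- if (is.null(y$config)) list() else y$config
  runConfig(input = list(topology = y$input$topology,
                         coordinates = y$input$coordinates,
                         rules = rules,
                         dt = if (is.null(y$input$dt)) NA_real_ else y$input$dt),
            species = if (is.null(y$species)) "LIN" else y$species,
            speciesPair = if (is.null(y$speciesPair)) c("LIN", "STE")
                          else y$speciesPair,
            stages = if (is.null(y$stages))
                       c("contacts", "binders", "maps", "clustering")
                     else y$stages,
            config = do.call(analysisConfig, cfgArgs),
            outputDir = if (is.null(y$outputDir)) tempfile("run")
                        else y$outputDir,
            seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Validate a run configuration
#'
#' Checks paths, species names, stage names and parameter ranges; errors are
#' returned (not raised) as an aggregated list.
#'
#' @param rc a `RunConfig`
#' @return list with `valid` (logical) and `errors` (character vector)
#' @export
validateConfig <- function(rc) {
  errs <- character(0)
  known <- c("contacts", "binders", "maps", "clustering", "chemistry")
  bad <- setdiff(rc$stages, known)
  if (length(bad))
    errs <- c(errs, paste("unknown stage(s):", paste(bad, collapse = ", ")))
  cfg <- rc$config
  cuts <- c(contactCutoff = cfg$contactCutoff,
            hydrophobicCutoff = cfg$hydrophobicCutoff,
            hbondCutoff = cfg$hbondCutoff,
            saltbridgeCutoff = cfg$saltbridgeCutoff,
            gridResolution = cfg$gridResolution,
            slabThickness = cfg$slabThickness, shellCutoff = cfg$shellCutoff)
  for (nm in names(cuts))
    if (!is.numeric(cuts[[nm]]) || cuts[[nm]] <= 0)
      errs <- c(errs, paste0(nm, " must be positive (got ", cuts[[nm]], ")"))
  if (any(cfg$occupancyThresholds <= 0 | cfg$occupancyThresholds >= 1))
    errs <- c(errs, "occupancy thresholds must lie in (0, 1)")
  if (!is.null(rc$input$synthetic)) {
    avail <- names(rc$input$synthetic$nLipidsPerSpecies)
  } else {
    for (p in c(rc$input$topology, rc$input$coordinates))
      if (!is.null(p) && !file.exists(p))
        errs <- c(errs, paste("input path does not exist:", p))
    avail <- if (!is.null(rc$input$rules)) names(rc$input$rules$lipids)
             else character(0)
  }
  for (sp in unique(c(rc$species, rc$speciesPair)))
    if (!sp %in% avail)
      errs <- c(errs, paste0("species '", sp, "' not available (available: ",
                             paste(avail, collapse = ", "), ")"))
  list(valid = length(errs) == 0, errors = errs)
}

#' Run the end-to-end site-mapping workflow
#'
#' load/generate -> contact tensor -> per-residue statistics (symmetry
#' averaging + Tukey-fence classification) -> per-lipid statistics (UQ /
#' constant binders) -> binder-residue roles -> occupancy grid, slab profiles,
#' species fold enrichment, lateral RDF -> pose clustering of the primary
#' species' head groups -> JSON report plus CSV/OpenDX/PDB outputs in
#' `outputDir`. Deterministic given the seed; stage failures abort with the
#' failing stage named and a `FAILED` marker file retained.
#'
#' @param rc a `RunConfig`
#' @return the report, invisibly (also written as `report.json`)
#' @export
runSiteMapping <- function(rc) {
  val <- validateConfig(rc)
  if (!val$valid)
    stop("invalid configuration:\n  ", paste(val$errors, collapse = "\n  "))
  dir.create(rc$outputDir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(rc$outputDir, "FAILED")
  file.create(marker)
  stage <- "load"
  report <- list(provenance = list(
    package = as.character(utils::packageVersion("LipidSites")),
    seed = rc$seed, species = rc$species, stages = rc$stages,
    config = rc$config[setdiff(names(rc$config), "seed")]))
  tryCatch({
    set.seed(rc$seed)
    if (!is.null(rc$input$synthetic)) {
      spec <- rc$input$synthetic
      spec$seed <- rc$seed
      sim <- simulateLipidTrajectory(spec)
      traj <- sim$trajectory
      report$provenance$input <- "synthetic"
    } else {
      traj <- loadTrajectory(rc$input$topology, rc$input$coordinates,
                             rc$input$rules, dt = rc$input$dt)
      report$provenance$input <- rc$input$topology
    }
    cfg <- rc$config
    a <- atoms(traj)
    dur <- duration(traj)

    siteResidues <- NULL
    if ("contacts" %in% rc$stages) {
      stage <- "contacts"
      tensor <- computeContactTensor(traj, rc$species, cutoff = cfg$contactCutoff)
      rs <- residueStats(tensor)
      avg <- symmetryAverage(rs, traj@topology@subunitMap)
      cls <- classifyContactResidues(rs, cfg$quantileType)
      clsAvg <- classifyContactResidues(avg, cfg$quantileType)
      writeResidueStatsCSV(rs, traj, file.path(rc$outputDir, "residue_stats.csv"))
      writeResidueStatsCSV(avg, traj,
                           file.path(rc$outputDir, "residue_stats_averaged.csv"),
                           averaged = TRUE)
      writeBFactorPDB(traj, stats::setNames(rs$totalTime, rs$resid),
                      file.path(rc$outputDir, "total_time_heatmap.pdb"))
      siteResidues <- sort(union(cls$highContact, cls$stableContact))
      report$contacts <- list(
        highContact = cls$highContact, stableContact = cls$stableContact,
        highContactAveraged = clsAvg$highContact,
        stableContactAveraged = clsAvg$stableContact,
        fences = cls$fences)
    }

    if ("binders" %in% rc$stages) {
      stage <- "binders"
      if (!exists("tensor", inherits = FALSE))
        tensor <- computeContactTensor(traj, rc$species,
                                       cutoff = cfg$contactCutoff)
      ls <- lipidInteractionStats(tensor)
      uq <- identifyUQBinders(ls, cfg$quantileType)
      cb <- identifyConstantBinders(ls, dur)
      utils::write.csv(ls, file.path(rc$outputDir, "lipid_stats.csv"),
                       row.names = FALSE)
      roles <- NULL
      if (length(cb$constantBinders) && length(siteResidues)) {
        roles <- classifyBinderResidues(traj, cb$constantBinders[1],
                                        siteResidues, cfg)
        utils::write.csv(roles, file.path(rc$outputDir, "binder_roles.csv"),
                         row.names = FALSE)
      }
      report$binders <- list(uqBinders = uq$uqBinders,
                             uqThreshold = uq$uqThreshold,
                             constantBinders = cb$constantBinders,
                             roles = roles)
    }

    if ("maps" %in% rc$stages) {
      stage <- "maps"
      heads <- selectAtoms(traj@topology, species = rc$species,
                           role = "lipid_head", label = rc$species)
      grid <- occupancyGrid(traj, heads, cfg$gridResolution)
      writeOpenDX(grid, file.path(rc$outputDir,
                                  paste0("occupancy_", rc$species, ".dx")))
      masks <- lapply(cfg$occupancyThresholds, function(th)
        sum(thresholdContour(grid, th)))
      rdf <- lateralRDF(traj, heads)
      utils::write.csv(rdf, file.path(rc$outputDir,
                                      paste0("rdf_", rc$species, ".csv")),
                       row.names = FALSE)
      report$maps <- list(maxOccupancy = max(grid@occupancy),
                          thresholdVoxels = stats::setNames(
                            masks, paste0("t", cfg$occupancyThresholds)),
                          rdfPeakR = rdf$r[which.max(rdf$g)])
      if (length(siteResidues)) {
        profs <- lapply(rc$speciesPair, function(sp)
          slabContactProfile(traj,
                             selectAtoms(traj@topology, species = sp,
                                         role = "lipid_head", label = sp),
                             siteResidues, cfg$shellCutoff,
                             cfg$slabThickness))
        fe <- foldEnrichment(profs[[1]], profs[[2]])
        utils::write.csv(fe, file.path(rc$outputDir, "fold_enrichment.csv"),
                         row.names = FALSE)
        tot <- c(sum(profs[[1]]$counts), sum(profs[[2]]$counts))
        report$maps$foldEnrichmentTotal <-
          if (tot[2] > 0) tot[1] / tot[2] else NA_real_
      }
    }

    if ("clustering" %in% rc$stages) {
      stage <- "clustering"
      heads <- selectAtoms(traj@topology, species = rc$species,
                           role = "lipid_head", label = rc$species)
      nf <- nFrames(traj)
      frames <- unique(round(seq(1, nf, length.out = min(rc$maxPoses, nf))))
      poses <- extractPoses(traj, heads, frames)
      dm <- poseRMSDMatrix(poses, superpose = FALSE)
      jp <- jarvisPatrickCluster(dm)
      gr <- gromosCluster(dm, cutoff = 5)
      report$clustering <- list(
        jarvisPatrick = list(populations = as.list(clusterPopulations(jp)),
                             parameters = jp@parameters),
        gromos = list(populations = as.list(clusterPopulations(gr)),
                      representatives = as.list(gr@representatives),
                      parameters = gr@parameters))
    }

    if ("chemistry" %in% rc$stages) {
      stage <- "chemistry"
      if (!any(a$elem == "H")) {
        report$chemistry <- list(
          skipped = "no hydrogens in topology (coarse-grained system)")
      } else {
        heads <- selectAtoms(traj@topology, species = rc$species)
        prot <- selectAtoms(traj@topology, role = "protein")
        hb <- detectHBonds(traj, prot, heads,
                           bondCriteria(hbond = cfg$hbondCutoff))
        report$chemistry <- list(hbonds = bondTimeStats(hb, union = TRUE))
      }
    }

    stage <- "report"
    report$warnings <- character(0)
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, null = "null")
    writeLines(json, file.path(rc$outputDir, "report.json"))
    writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               file.path(rc$outputDir, "timestamp.txt"))
    unlink(marker)
    invisible(report)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
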