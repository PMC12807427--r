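.CONFIG_KEYS <- list(
  top = c("reference", "systems", "pcaSystem", "selection", "cutoff",
          "countLevel", "temperature", "reweight", "outDir", "seed",
          "logLevel", "frameSpacing"),
  reference = c("path", "model"),
  system = c("trajectories", "energyLog"),
  selection = c("name", "class", "heavy", "resno"),
  reweight = c("method", "maclaurinOrder"))

.checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
}

#' Validate and complete a pipeline run configuration
#'
#' Reads a YAML (or JSON) config, rejects unknown keys, reports all missing
#' required keys together, checks ranges and path existence, and fills the
#' defaults (cutoff 6.0 Angstrom, temperature 300 K, protein C-alpha
#' selection, exponential reweighting, frame spacing 1 ns, seed 1) explicitly
#' into the returned object.
#'
#' @param config path to a YAML/JSON file, or an equivalent nested list.
#' @return a validated `RunConfig` list.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  .checkKeys(config, .CONFIG_KEYS$top, "top level")
  required <- c("reference", "systems", "pcaSystem", "outDir")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("missing required config key(s): ", paste(missing, collapse = ", "))
  .checkKeys(config$reference, .CONFIG_KEYS$reference, "reference")
  if (is.null(config$reference$path)) stop("reference$path is required")
  if (!file.exists(config$reference$path))
    stop("reference$path does not exist: ", config$reference$path)
  config$reference$model <- config$reference$model %||% 1L
  if (!length(config$systems)) stop("systems must name at least one system")
  for (nm in names(config$systems)) {
    sys <- config$systems[[nm]]
    .checkKeys(sys, .CONFIG_KEYS$system, paste0("systems$", nm))
    if (is.null(sys$trajectories) || !length(sys$trajectories))
      stop("systems$", nm, "$trajectories must list at least one file")
    bad <- sys$trajectories[!file.exists(unlist(sys$trajectories))]
    if (length(bad))
      stop("systems$", nm, "$trajectories: file(s) not found: ",
           paste(unlist(bad), collapse = ", "))
    if (!is.null(sys$energyLog) && !file.exists(sys$energyLog))
      stop("systems$", nm, "$energyLog does not exist: ", sys$energyLog)
  }
  if (!config$pcaSystem %in% names(config$systems))
    stop("pcaSystem '", config$pcaSystem, "' is not a named system")
  sel <- config$selection %||% list(name = "CA", class = "protein")
  .checkKeys(sel, .CONFIG_KEYS$selection, "selection")
  config$selection <- sel
  config$cutoff <- config$cutoff %||% 6.0
  if (config$cutoff <= 0) stop("cutoff must be positive")
  config$countLevel <- config$countLevel %||% "residue"
  if (!config$countLevel %in% c("residue", "atom_pair"))
    stop("countLevel must be 'residue' or 'atom_pair'")
  config$temperature <- config$temperature %||% 300
  if (config$temperature <= 0) stop("temperature must be positive")
  rw <- config$reweight %||% list()
  .checkKeys(rw, .CONFIG_KEYS$reweight, "reweight")
  rw$method <- rw$method %||% "exponential"
  if (!rw$method %in% c("exponential", "maclaurin"))
    stop("reweight$method must be 'exponential' or 'maclaurin'")
  rw$maclaurinOrder <- rw$maclaurinOrder %||% 10L
  config$reweight <- rw
  config$seed <- as.integer(config$seed %||% 1L)
  config$logLevel <- config$logLevel %||% "info"
  config$frameSpacing <- config$frameSpacing %||% 1
  class(config) <- "RunConfig"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.loadTrajectory <- function(path, template, frameSpacing, replicaId) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE))
    readPDBTrajectory(path, frameSpacing, replicaId)
  else readCoordTable(path, template, frameSpacing, replicaId)
}

.readEnergyLog <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("frame", "V_tot", "V_dih", "deltaV_tot", "deltaV_dih")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("energy log ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' Run the full analysis pipeline
#'
#' Orchestrates, from one validated config: per-system RMSD series with
#' replica summaries; Cartesian PCA on the defining system (replicas
#' combined) with cross-projection of every system onto its essential
#' subspace, extreme conformations and mode arrows; native contacts of the
#' reference with per-frame minimum-distance series and per-nucleotide
#' contact counts; contact PCA with ranked components and representative
#' frames; and, when boost-energy logs are supplied, a reweighted
#' free-energy surface over the essential-subspace projections. All outputs
#' are CSV/PDB files registered in a JSON manifest; the same config and seed
#' reproduce byte-identical numeric outputs.
#'
#' @param config a `RunConfig` from [validateConfig()], or a path/list
#'   accepted by it.
#' @return (invisibly) the report bundle: `manifest` path, named `files`
#'   vector, `log` path.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "RunConfig")) config <- validateConfig(config)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(config$outDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  info <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
    writeLines(line, logCon)
    if (identical(config$logLevel, "info")) message(line)
  }
  files <- character()
  register <- function(name, path) files[[name]] <<- path
  out <- function(...) file.path(config$outDir, paste0(...))
  writeManifest <- function(status) {
    cfg <- unclass(config)
    manifest <- list(package = "amdtools",
                     version = as.character(utils::packageVersion("amdtools")),
                     seed = config$seed, status = status, config = cfg,
                     files = lapply(files, function(p)
                       list(path = p, md5 = unname(tools::md5sum(p)))))
    mpath <- out("manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    mpath
  }
  stage <- function(name, expr) {
    info("stage: ", name)
    tryCatch(expr, error = function(e) {
      writeManifest(paste0("failed at stage ", name))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  set.seed(config$seed)

  ref <- NULL; sel <- NULL; trajsBySystem <- list()
  stage("load", {
    ref <- readPDB(config$reference$path, config$reference$model)
    sel <- selectAtoms(ref, name = config$selection$name,
                        class = config$selection$class,
                        heavy = isTRUE(config$selection$heavy),
                        resno = config$selection$resno)
    for (nm in names(config$systems)) {
      paths <- unlist(config$systems[[nm]]$trajectories)
      trajsBySystem[[nm]] <- lapply(seq_along(paths), function(r)
        .loadTrajectory(paths[r], ref, config$frameSpacing, r))
    }
  })
  info("reference: ", nAtoms(ref), " atoms; selection '", sel@label, "': ",
       length(sel@indices), " atoms; systems: ",
       paste(names(config$systems), collapse = ", "))

  stage("rmsd", {
    for (nm in names(config$systems)) {
      series <- lapply(trajsBySystem[[nm]], function(tr) {
        rmsdSeries(tr, ref, sel)
      })
      for (r in seq_along(series)) {
        tab <- data.frame(frame_index = seq_along(series[[r]]),
                          time = seq_along(series[[r]]) * config$frameSpacing,
                          rmsd_A = series[[r]])
        p <- out("rmsd_", nm, "_rep", r, ".csv")
        write.csv(tab, p, row.names = FALSE)
        register(paste0("rmsd_", nm, "_rep", r), p)
      }
      summ <- replicaSummary(series, allowSingle = TRUE)
      p <- out("rmsd_", nm, "_summary.csv")
      write.csv(summ, p, row.names = FALSE)
      register(paste0("rmsd_", nm, "_summary"), p)
    }
  })

  pca <- NULL; projections <- list()
  stage("pca", {
    cov <- buildCovariance(trajsBySystem[[config$pcaSystem]], sel, ref)
    pca <- eigenDecompose(cov)
    ev <- pmax(eigenvalues(pca), 0)
    tab <- data.frame(mode = seq_along(ev), eigenvalue_A2 = eigenvalues(pca),
                      fraction = ev / sum(ev))
    p <- out("pca_eigenvalues.csv")
    write.csv(tab, p, row.names = FALSE)
    register("pca_eigenvalues", p)
    projTabs <- list()
    for (nm in names(config$systems)) {
      for (r in seq_along(trajsBySystem[[nm]])) {
        pr <- projectTrajectory(trajsBySystem[[nm]][[r]], pca, 1:2, ref)
        projTabs[[paste(nm, r)]] <- data.frame(
          system = nm, replica = r, frame = seq_len(nrow(pr)),
          PC1 = pr[, 1], PC2 = pr[, 2])
      }
      projections[[nm]] <- do.call(rbind,
        projTabs[paste(nm, seq_along(trajsBySystem[[nm]]))])
    }
    p <- out("projections.csv")
    write.csv(do.call(rbind, projTabs), p, row.names = FALSE)
    register("projections", p)
    comb <- projections[[config$pcaSystem]]
    ext <- extremeConformations(as.matrix(comb[, c("PC1", "PC2")]), 1L)
    pick <- comb[ext, , drop = FALSE]
    frames <- lapply(seq_len(2), function(i)
      coords(trajsBySystem[[config$pcaSystem]][[pick$replica[i]]],
             pick$frame[i]))
    arr <- array(NA_real_, dim = c(2, nAtoms(ref), 3))
    arr[1, , ] <- frames[[1]]; arr[2, , ] <- frames[[2]]
    extTraj <- Trajectory(arr, ref)
    p <- out("pc1_extremes.pdb")
    writePDB(extTraj, p)
    register("pc1_extremes", p)
    arrows <- modeArrows(pca, 1L)
    p <- out("pc1_arrows.csv")
    write.csv(data.frame(atom = sel@indices, arrows), p, row.names = FALSE)
    register("pc1_arrows", p)
  })

  contacts <- NULL
  hasRNA <- any(ref@atoms$moleculeClass == "nucleotide")
  if (!hasRNA) {
    info("contacts: reference has no nucleotides; contact stages skipped")
  } else {
    seriesBySystem <- list()
    stage("contacts", {
      contacts <- nativeContacts(ref, cutoff = config$cutoff,
                                  referenceId = config$reference$path)
      p <- out("native_contacts.csv")
      write.csv(contactPairs(contacts), p, row.names = FALSE)
      register("native_contacts", p)
      nucs <- sort(unique(ref@atoms$resno[
        ref@atoms$moleculeClass == "nucleotide"]))
      countRows <- list()
      for (nm in names(config$systems)) {
        D <- do.call(rbind, lapply(trajsBySystem[[nm]], function(tr)
          minDistanceSeries(tr, contacts)@distances))
        seriesBySystem[[nm]] <- new("ContactDistanceSeries",
                                     distances = D, contacts = contacts)
        p <- out("contact_distances_", nm, ".csv")
        write.csv(data.frame(frame = seq_len(nrow(D)), D, check.names = FALSE),
                  p, row.names = FALSE)
        register(paste0("contact_distances_", nm), p)
        for (nu in nucs) {
          cc <- unlist(lapply(trajsBySystem[[nm]], function(tr)
            contactCountSeries(tr, nu, cutoff = config$cutoff,
                               level = config$countLevel)$counts))
          countRows[[paste(nm, nu)]] <- data.frame(
            system = nm, nucleotide = nu, mean_contacts = mean(cc),
            std = stats::sd(cc))
        }
      }
      p <- out("contact_counts.csv")
      write.csv(do.call(rbind, countRows), p, row.names = FALSE)
      register("contact_counts", p)
    })

    stage("conpca", {
      for (nm in names(config$systems)) {
        modes <- conpcaModes(contactCovariance(seriesBySystem[[nm]]))
        rc <- rankComponents(modes, 1L)
        p <- out("conpca_components_", nm, ".csv")
        write.csv(rc, p, row.names = FALSE)
        register(paste0("conpca_components_", nm), p)
      }
    })
  }

  stage("fes", {
    for (nm in names(config$systems)) {
      logFile <- config$systems[[nm]]$energyLog
      if (is.null(logFile)) next
      en <- .readEnergyLog(logFile)
      proj <- projections[[nm]]
      if (nrow(en) != nrow(proj))
        stop("energy log rows (", nrow(en), ") do not match frames (",
             nrow(proj), ") for system ", nm)
      w <- reweightFrames(en$deltaV_tot + en$deltaV_dih,
                          temperature = config$temperature,
                          method = config$reweight$method,
                          k = config$reweight$maclaurinOrder)
      fes <- freeEnergySurface(as.matrix(proj[, c("PC1", "PC2")]),
                               weights = w, breaks = 40,
                               temperature = config$temperature)
      ctr <- fesBinCenters(fes)
      grid <- expand.grid(PC1 = ctr[[1]], PC2 = ctr[[2]])
      grid$G_kcal_mol <- as.vector(fes@G)
      p <- out("fes_", nm, ".csv")
      write.csv(grid, p, row.names = FALSE)
      register(paste0("fes_", nm), p)
    }
    if (!any(vapply(config$systems, function(s) !is.null(s$energyLog),
                    logical(1))))
      info("fes: no energy logs supplied; stage skipped")
  })

  mpath <- writeManifest("complete")
  info("done: ", length(files), " output files registered")
  invisible(list(manifest = mpath, files = unlist(files), log = logPath))
}
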