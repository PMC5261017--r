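## One orchestrated entry point: dispatches a validated run configuration to
## the analysis modules, echoes the configuration, and writes a manifest with
## checksums so that identical configurations provably produce identical
## artifacts. The `exec/cytoskel` script is a thin command-line wrapper over
## runPipeline().

pipelineSubcommands <- c("simulate", "contacts", "neighbors", "msd",
                         "persistence", "omics")

#' Run a configured analysis pipeline
#'
#' `config` is a named list (or path to a YAML file holding one) with at
#' least `subcommand` (one of simulate, contacts, neighbors, msd,
#' persistence, omics) plus the subcommand's fields; see the package vignette
#' for the full schema. Every run writes `config_echo.json` and
#' `manifest.json` (artifact list with md5 checksums) into `outDir`. Reruns
#' with identical configuration and inputs produce identical artifacts.
#'
#' @param config named list or YAML path.
#' @param outDir output directory (created if missing); defaults to
#'   `config$out`.
#' @param seed optional seed overriding `config$seed`.
#' @return the manifest, invisibly (list with `subcommand` and `outputs`,
#'   a named md5 vector).
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$subcommand))
    stop("config must be a named list (or YAML file) with a 'subcommand' field")
  sub <- config$subcommand
  if (!sub %in% pipelineSubcommands)
    stop(sprintf("unknown subcommand '%s' (expected one of %s)", sub,
                 paste(pipelineSubcommands, collapse = ", ")))
  if (is.null(outDir)) outDir <- config$out
  if (is.null(outDir)) stop("no output directory: set outDir or config$out")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) config$seed <- seed
  config$out <- NULL

  files <- switch(sub,
    simulate = pipeSimulate(config, outDir),
    contacts = pipeContacts(config, outDir),
    neighbors = pipeNeighbors(config, outDir),
    msd = pipeMsd(config, outDir),
    persistence = pipePersistence(config, outDir),
    omics = pipeOmics(config, outDir))

  echoPath <- file.path(outDir, "config_echo.json")
  jsonlite::write_json(config, echoPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, echoPath)
  sums <- vapply(files, fileChecksum, character(1L))
  names(sums) <- basename(files)
  manifest <- list(subcommand = sub, outputs = as.list(sums))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

writeCsv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE)
  path
}

cfgOrDefault <- function(config, field, default) {
  if (is.null(config[[field]])) default else config[[field]]
}

peakParamsFromConfig <- function(config) {
  pk <- cfgOrDefault(config, "peak", list())
  do.call(peakParams, pk)
}

pipeSimulate <- function(config, outDir) {
  what <- cfgOrDefault(config, "what", "scene")
  params <- cfgOrDefault(config, "params", list())
  if (!is.null(config$seed)) params$seed <- config$seed
  switch(what,
    scene = {
      sc <- do.call(simulateContactScene, params)
      imgPath <- file.path(outDir, "image.tif")
      writeImageTIFF(sc$image, imgPath)
      reg <- sc$truth$regions
      segs <- data.frame(region_id = reg$region_id,
                         row0 = reg$row_px, col0 = reg$x0_px,
                         row1 = reg$row_px, col1 = reg$x1_px,
                         width_px = 15, gap_um = reg$gap_um)
      out <- c(imgPath,
               writeCsv(segs, file.path(outDir, "segments.csv")),
               writeCsv(reg, file.path(outDir, "truth_regions.csv")),
               writeCsv(sc$truth$contacts,
                        file.path(outDir, "truth_contacts.csv")))
      sidecar <- paste0(imgPath, ".json")
      if (file.exists(sidecar)) out <- c(out, sidecar)
      out
    },
    trajectories = {
      tr <- do.call(simulateTrajectories, params)
      writeTrajectoryCSV(tr, file.path(outDir, "tracks.csv"))
      file.path(outDir, "tracks.csv")
    },
    filaments = {
      fs <- do.call(simulateWLCFilaments, params)
      writeFilamentCSV(fs, file.path(outDir, "filaments.csv"))
      file.path(outDir, "filaments.csv")
    },
    points = {
      pp <- do.call(simulatePointPattern, params)
      maskPath <- file.path(outDir, "mask.tif")
      writeImageTIFF(pp$mask * 1, maskPath)
      c(maskPath,
        writeCsv(pp$truth, file.path(outDir, "truth_centers.csv")))
    },
    de = {
      de <- do.call(simulateDETables, params)
      out <- writeCsv(de$tables[[1L]], file.path(outDir, "de_a.csv"))
      if (length(de$tables) > 1L)
        out <- c(out, writeCsv(de$tables[[2L]], file.path(outDir, "de_b.csv")))
      c(out,
        writeCsv(data.frame(gene = de$truth$up),
                 file.path(outDir, "truth_up.csv")),
        writeCsv(data.frame(gene = de$truth$down),
                 file.path(outDir, "truth_down.csv")))
    },
    stop(sprintf("unknown simulate target '%s'", what)))
}

pipeContacts <- function(config, outDir) {
  img <- readImageTIFF(config$image)
  segs <- utils::read.csv(config$segments, stringsAsFactors = FALSE)
  px <- config$pixel_size
  if (is.null(px)) stop("contacts: 'pixel_size' is required")
  pk <- peakParamsFromConfig(config)
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    seg <- LineSegment(c(segs$row0[i], segs$col0[i]),
                       c(segs$row1[i], segs$col1[i]),
                       widthPx = cfgOrDefault(segs, "width_px", 1)[i])
    prof <- extractProfile(img, seg, px, sourceId = segs$region_id[i])
    reg <- contactRegion(prof, cellGapUm = segs$gap_um[i],
                         regionId = segs$region_id[i], params = pk)
    data.frame(region_id = reg@regionId, gap_um = reg@cellGapUm,
               n_contacts = reg@nContacts,
               length_um = profileLength(prof), density = reg@density)
  })
  writeCsv(do.call(rbind, rows), file.path(outDir, "regions.csv"))
}

pipeNeighbors <- function(config, outDir) {
  img <- readImageTIFF(config$image)
  px <- config$pixel_size
  if (is.null(px)) stop("neighbors: 'pixel_size' is required")
  method <- cfgOrDefault(config, "binarize", "otsu")
  mask <- if (method == "none") img > 0
          else binarizeImage(img, method = method,
                             threshold = config$threshold)
  field <- labelComponents(mask,
                           connectivity = cfgOrDefault(config, "connectivity", 8L),
                           pixelSize = px)
  nd <- firstNeighborDistances(field)
  c(writeCsv(objectTable(field), file.path(outDir, "objects.csv")),
    writeCsv(data.frame(distance_um = nd@distances,
                        normalized = nd@normalized),
             file.path(outDir, "distances.csv")))
}

pipeMsd <- function(config, outDir) {
  trajs <- readTrajectoryCSV(config$tracks)
  curve <- computeMSD(trajs, maxLag = config$max_lag)
  fit <- fitMSD(curve, model = cfgOrDefault(config, "model", "linear"))
  fitPath <- file.path(outDir, "msd_fit.json")
  jsonlite::write_json(fit[setdiff(names(fit), c("lagsUsed"))], fitPath,
                       auto_unbox = TRUE, digits = NA)
  c(writeCsv(msdTable(curve), file.path(outDir, "msd.csv")), fitPath)
}

pipePersistence <- function(config, outDir) {
  fils <- readFilamentCSV(config$filaments)
  nMax <- cfgOrDefault(config, "n_max", 10L)
  modes <- cfgOrDefault(config, "modes_used", 1:5)
  sp <- filamentModeSpectrum(fils, nMax = nMax,
                             resampleStep = config$resample_step)
  fit <- fitPersistenceLength(sp, modesUsed = modes)
  fitPath <- file.path(outDir, "lp_fit.json")
  jsonlite::write_json(list(lp_star = fit@lpStar, se = fit@fitSe,
                            modes_used = fit@modesUsed,
                            converged = fit@converged),
                       fitPath, auto_unbox = TRUE, digits = NA)
  c(writeCsv(data.frame(mode = sp@modes, q = sp@q, variance = sp@variance),
             file.path(outDir, "spectrum.csv")), fitPath)
}

pipeOmics <- function(config, outDir) {
  action <- cfgOrDefault(config, "action", "threshold")
  cutoffs <- cfgOrDefault(config, "cutoffs", c(2, 3, 5, 8))
  pMax <- cfgOrDefault(config, "p_max", 0.05)
  switch(action,
    threshold = {
      sets <- thresholdDE(readDETable(config$table), cutoffs, pMax)
      long <- do.call(rbind, lapply(names(sets$up), function(k) {
        rbind(if (length(sets$up[[k]]))
                data.frame(cutoff = k, direction = "up", gene = sets$up[[k]]),
              if (length(sets$down[[k]]))
                data.frame(cutoff = k, direction = "down",
                           gene = sets$down[[k]]))
      }))
      if (is.null(long))
        long <- data.frame(cutoff = character(), direction = character(),
                           gene = character())
      writeCsv(long, file.path(outDir, "gene_sets.csv"))
    },
    overlap = {
      a <- thresholdDE(readDETable(config$table_a), cutoffs, pMax)
      b <- thresholdDE(readDETable(config$table_b), cutoffs, pMax)
      ov <- overlapComparisons(a, b)
      ovPath <- file.path(outDir, "overlap.json")
      jsonlite::write_json(ov$sets, ovPath, auto_unbox = FALSE)
      c(writeCsv(ov$summary, file.path(outDir, "overlap_summary.csv")),
        ovPath)
    },
    netfilter = {
      net <- readSIF(config$network)
      keep <- cfgOrDefault(config, "types", "physical")
      writeSIF(filterEdges(net, keep), file.path(outDir, "filtered.sif"))
      file.path(outDir, "filtered.sif")
    },
    domainnet = {
      domains <- utils::read.csv(config$domains, stringsAsFactors = FALSE)
      pd <- split(domains[[2L]], domains[[1L]])
      net <- domainNetwork(pd, readDomainMap(config$domain_map))
      writeSIF(net, file.path(outDir, "domain_network.sif"))
      file.path(outDir, "domain_network.sif")
    },
    stop(sprintf("unknown omics action '%s'", action)))
}
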