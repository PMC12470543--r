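# Pipeline orchestration: YAML run configuration, logging, and the
# subcommands binding all stages (simulate -> screen -> extract ->
# train-ae -> encode -> cluster -> fit-ellipse -> apply-labels ->
# augment -> report).

.subcommands <- c("simulate", "screen", "extract", "train-ae", "encode",
                  "cluster", "fit-ellipse", "apply-labels", "augment",
                  "report")

#' Default run configuration
#'
#' @return nested list with one section per stage; see the YAML config
#'   documented in the package vignette.
#' @export
defaultConfig <- function() {
  list(
    pixel_size_um = 0.1658,
    seed = 1L,
    out = "rbcmorph_out",
    synth = list(width_px = 800L, height_px = 600L, n_cells = 25L,
                 noise_sigma = 3, overlap_fraction = 0,
                 border_cells = 0L, debris_count = 0L),
    extract = list(spatial_radius = 10L, range_radius = 20,
                   mean_shift = TRUE, tolerance = 0.5, ext = 1L,
                   min_region_px = 25L),
    ae = list(arch = "dense", input_side = 128L, latent_dim = 64L,
              epochs = 200L, batch_size = 64L, val_fraction = 0.2,
              lr = 1e-3),
    cluster = list(k_list = c(2L, 3L, 4L, 5L), export_k = NULL),
    ellipse = list(er_min = 0.5, annotate = FALSE),
    labels = list(assignment = NULL),
    augment = list(scales = 1.0, rotations = 5L,
                   flips = c("vertical", "horizontal", "both"),
                   canvas = 128L))
}

.loadConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(defaultConfig(), config)
}

.logger <- function(outDir) {
  logFile <- file.path(outDir, "run.log")
  function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    message(msg)
    cat(msg, "\n", file = logFile, append = TRUE)
  }
}

#' Run one pipeline subcommand
#'
#' Dispatches to the module behind each stage, writes the stage's
#' artifacts under the configured output directory together with the
#' exact configuration that produced them (`config.yaml`) and an
#' INFO-level `run.log`. Downstream commands check for their upstream
#' artifacts and name the producing subcommand when one is missing.
#'
#' @param name subcommand, one of
#'   `r paste(rbcmorph:::.subcommands, collapse = ", ")`.
#' @param config YAML file path or config list (merged over
#'   [defaultConfig()]).
#' @param overrides named list merged over the config last (e.g.
#'   `list(seed = 7, out = "run2")`).
#' @return invisibly, the stage's main result object.
#' @export
runSubcommand <- function(name, config = list(), overrides = list()) {
  if (!name %in% .subcommands) {
    stop("unknown subcommand '", name, "'; available: ",
         paste(.subcommands, collapse = ", "))
  }
  cfg <- utils::modifyList(.loadConfig(config), overrides)
  out <- cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  log <- .logger(out)
  log("subcommand: ", name, " (seed ", cfg$seed, ")")

  need <- function(path, producer) {
    if (!file.exists(path) && !dir.exists(path)) {
      stop("missing upstream artifact '", path,
           "'; run the '", producer, "' subcommand first")
    }
    path
  }

  result <- switch(
    name,
    "simulate" = {
      s <- cfg$synth
      scene <- smearScene(
        widthPx = s$width_px, heightPx = s$height_px, nCells = s$n_cells,
        pixelSizeUm = cfg$pixel_size_um, noiseSigma = s$noise_sigma,
        overlapFraction = s$overlap_fraction,
        borderCells = s$border_cells, debrisCount = s$debris_count,
        seed = cfg$seed)
      sc <- generateScene(scene)
      writeImage8(sc$image, file.path(out, "scene.png"))
      writeTruthCsv(sc$truth, file.path(out, "truth.csv"))
      log("rendered ", nrow(sc$truth), " cells at ",
          s$width_px, " x ", s$height_px, " px")
      sc
    },
    "screen" = {
      img <- readImage8(need(cfg$image %||% file.path(out, "scene.png"),
                             "simulate"))
      rep <- roiScreen(img)
      write.csv(as.data.frame(rep[c("widthPx", "heightPx",
                                    "artifactFraction", "clumpFraction",
                                    "passed")]),
                file.path(out, "roi_screen.csv"), row.names = FALSE)
      log("screen ", if (rep$passed) "PASSED" else "REJECTED",
          " (artifact ", round(rep$artifactFraction, 3), ", clump ",
          round(rep$clumpFraction, 3), ")")
      rep
    },
    "extract" = {
      img <- readImage8(need(cfg$image %||% file.path(out, "scene.png"),
                             "simulate"))
      e <- cfg$extract
      res <- extractCells(
        img, config = list(spatialRadius = e$spatial_radius,
                           rangeRadius = e$range_radius,
                           meanShift = e$mean_shift,
                           tolerance = e$tolerance, ext = e$ext,
                           minRegionPx = e$min_region_px),
        outDir = file.path(out, "patches"))
      log("extracted: ",
          paste(names(res$summary), res$summary, sep = "=",
                collapse = ", "))
      res
    },
    "train-ae" = {
      pdir <- need(cfg$ae$patches_dir %||%
                     file.path(out, "patches", "single"), "extract")
      patches <- .readPatchDir(pdir, cfg$ae$input_side)
      aeCfg <- aeConfig(arch = cfg$ae$arch, inputSide = cfg$ae$input_side,
                        latentDim = cfg$ae$latent_dim,
                        epochs = cfg$ae$epochs,
                        batchSize = cfg$ae$batch_size, lr = cfg$ae$lr,
                        valFraction = cfg$ae$val_fraction,
                        seed = cfg$seed)
      dir.create(file.path(out, "models"), showWarnings = FALSE)
      fit <- trainAutoencoder(patches, aeCfg,
                              historyCsv = file.path(out, "history.csv"))
      saveRDS(fit$model, file.path(out, "models", "autoencoder.rds"))
      log("trained ", cfg$ae$arch, " AE for ", cfg$ae$epochs,
          " epochs; final train loss ",
          round(utils::tail(fit$history$train_loss, 1), 4))
      fit
    },
    "encode" = {
      model <- readRDS(need(file.path(out, "models", "autoencoder.rds"),
                            "train-ae"))
      pdir <- need(cfg$ae$patches_dir %||%
                     file.path(out, "patches", "single"), "extract")
      patches <- .readPatchDir(pdir, model@config$inputSide)
      latent <- encodeLatent(model, patches)
      df <- data.frame(file = attr(patches, "files"), latent)
      write.csv(df, file.path(out, "latent.csv"), row.names = FALSE)
      log("encoded ", nrow(latent), " patches into ", ncol(latent),
          "-d latent vectors")
      latent
    },
    "cluster" = {
      lat <- read.csv(need(file.path(out, "latent.csv"), "encode"))
      latent <- as.matrix(lat[, -1, drop = FALSE])
      sw <- sweepK(latent, cfg$cluster$k_list, seed = cfg$seed,
                   scoresCsv = file.path(out, "cluster_scores.csv"))
      kBest <- cfg$cluster$export_k %||%
        sw$scores$k[which.max(sw$scores$silhouette)]
      run <- sw$runs[[as.character(kBest)]]
      pdir <- cfg$ae$patches_dir %||% file.path(out, "patches", "single")
      paths <- file.path(pdir, lat$file)
      exportClusterDirs(clusterLabels(run), paths,
                        file.path(out, "clusters"), k = run@k)
      if (nrow(latent) >= 10L) {
        emb <- project2D(latent, seed = cfg$seed,
                         labels = clusterLabels(run),
                         plotFile = file.path(out, "umap.png"))
        write.csv(data.frame(id = lat$file, x = emb[, 1], y = emb[, 2],
                             label = clusterLabels(run)),
                  file.path(out, "embedding.csv"), row.names = FALSE)
      }
      log("swept k in {", paste(cfg$cluster$k_list, collapse = ", "),
          "}; exported k = ", kBest)
      sw
    },
    "fit-ellipse" = {
      dirs <- cfg$ellipse$input_dirs %||%
        file.path(out, "patches", "single",
                  list.files(file.path(out, "patches", "single")))
      dirs <- dirs[dir.exists(dirs)]
      if (!length(dirs)) need(file.path(out, "patches"), "extract")
      met <- runEllipsePipeline(dirs, outDir = file.path(out, "classified"),
                                pixelSizeUm = cfg$pixel_size_um,
                                erMin = cfg$ellipse$er_min,
                                annotate = isTRUE(cfg$ellipse$annotate))
      log("fitted ", nrow(met), " contours; kept ", sum(met$kept))
      met
    },
    "apply-labels" = {
      apath <- cfg$labels$assignment
      if (is.null(apath)) stop("config labels$assignment is required")
      assignment <- loadAssignment(need(apath, "expert review"))
      res <- applyAssignment(need(file.path(out, "clusters"), "cluster"),
                             assignment, file.path(out, "classes"))
      summarizeClasses(file.path(out, "classes"),
                       csv = file.path(out, "class_summary.csv"))
      log("applied ", nrow(assignment), " cluster assignments")
      res
    },
    "augment" = {
      a <- cfg$augment
      plan <- augmentPlan(scales = a$scales, rotations = a$rotations,
                          flips = a$flips, canvas = a$canvas)
      classRoot <- a$class_root %||% file.path(out, "classes")
      need(classRoot, "apply-labels")
      dirs <- list.dirs(classRoot, recursive = FALSE)
      dirs <- dirs[basename(dirs) != "_review"]
      rows <- lapply(dirs, function(d) {
        augmentClass(d, plan, file.path(out, "augmented"))
      })
      report <- do.call(rbind, rows)
      write.csv(report, file.path(out, "augment_report.csv"),
                row.names = FALSE)
      log("augmented ", nrow(report), " classes, ",
          sum(report$output_count), " files")
      report
    },
    "report" = {
      pieces <- list()
      for (f in c("summary.csv", "cluster_scores.csv",
                  "class_summary.csv", "augment_report.csv")) {
        p <- file.path(out, if (f == "summary.csv") "patches" else ".", f)
        if (file.exists(p)) pieces[[f]] <- read.csv(p, check.names = FALSE)
      }
      if ("class_summary.csv" %in% names(pieces)) {
        cs <- pieces[["class_summary.csv"]]
        recomputed <- summarizeClasses(
          stats::setNames(cs$count, cs$class_name))
        pieces[["class_summary.csv"]]$percentage <- recomputed$percentage
      }
      rf <- file.path(out, "report")
      dir.create(rf, showWarnings = FALSE)
      for (nm in names(pieces)) {
        write.csv(pieces[[nm]], file.path(rf, nm), row.names = FALSE)
      }
      log("collated ", length(pieces), " tables into ", rf)
      pieces
    })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# read every PNG under a directory (recursively) as flattened patches;
# files shorter or longer than side x side are resized
.readPatchDir <- function(dir, side) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE,
                      recursive = TRUE)
  files <- files[!basename(files) %in% c("montage.png", "qc_montage.png")]
  if (!length(files)) stop("no PNG patches under ", dir)
  X <- t(vapply(files, function(f) {
    m <- readImage8(f)
    if (!all(dim(m) == side)) {
      m <- .fromEBI(EBImage::resize(.toEBI(m), w = side, h = side))
    }
    as.vector(m) / 255
  }, numeric(side^2)))
  attr(X, "files") <- sub(paste0("^", dir, "/?"), "", files)
  X
}
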