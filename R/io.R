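#' @include AllClasses.R utils.R
NULL

#' Write an ImageVolume as NIfTI with a JSON sidecar
#'
#' The voxel data go to `<prefix>.nii.gz` (floating point, lossless); the
#' acquisition metadata, world origin and spacing go to `<prefix>.json`.
#' The sidecar is authoritative for timing metadata (TR/TE/TI/flip), which
#' NIfTI headers cannot carry.
#'
#' @param volume an [ImageVolume-class].
#' @param prefix path prefix (without extension).
#' @return the NIfTI path, invisibly.
#' @export
writeVolume <- function(volume, prefix) {
  nii <- RNifti::asNifti(imageData(volume),
                         pixdim = voxelSpacing(volume))
  path <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(nii, path)
  side <- c(list(spacing_mm = voxelSpacing(volume),
                 origin_mm = imageOrigin(volume)),
            acqMeta(volume))
  jsonlite::write_json(side, paste0(prefix, ".json"), digits = I(17),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read one NIfTI + sidecar volume
#'
#' @param path path to the `.nii`/`.nii.gz` file (sidecar `.json` expected
#'   alongside).
#' @return an [ImageVolume-class].
#' @export
readVolume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read ", path, ": ",
                                           conditionMessage(e)))
  d <- dim(img)
  if (length(d) < 3) d <- c(d, rep(1L, 3 - length(d)))  # single-slice images
  arr <- array(as.numeric(img), d)
  side_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side_path))
    stop("missing sidecar for ", path,
         ": timing metadata (TR/TE/TI/flip) unavailable")
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  spacing <- as.numeric(side$spacing_mm)
  origin <- as.numeric(side$origin_mm)
  meta <- side[setdiff(names(side), c("spacing_mm", "origin_mm"))]
  imageVolume(arr, spacing, origin, meta = meta)
}

#' Write a series of volumes
#'
#' @param volumes list of [ImageVolume-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of NIfTI paths, invisibly.
#' @export
writeSeries <- function(volumes, dir, prefix = "vol") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(volumes), function(i) {
    writeVolume(volumes[[i]],
                file.path(dir, sprintf("%s_%03d", prefix, i)))
  }, "")
  invisible(paths)
}

#' Read an image series from a directory
#'
#' Reads every NIfTI volume (with its JSON sidecar) in a directory, checks
#' that the geometry is consistent across the series, and sorts by TI, TE
#' then flip angle, then replicate — so the result is independent of file
#' order. A file that fails to read aborts with an error naming it.
#'
#' @param dir directory containing `.nii`/`.nii.gz` + `.json` pairs.
#' @return list of [ImageVolume-class], series-sorted.
#' @export
readSeries <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) stop("no NIfTI volumes found in ", dir)
  vols <- lapply(files, readVolume)
  sp <- voxelSpacing(vols[[1]]); dm <- dim(imageData(vols[[1]]))
  for (i in seq_along(vols)) {
    if (!isTRUE(all.equal(voxelSpacing(vols[[i]]), sp)) ||
        !all(dim(imageData(vols[[i]])) == dm))
      stop("mixed geometry within series: ", files[i])
  }
  key <- vapply(vols, function(v) {
    m <- acqMeta(v)
    num <- function(x) if (is.null(x)) 0 else as.numeric(x)[1]
    num(m$TI_ms) * 1e9 + num(m$TE_ms) * 1e6 + num(m$flip_deg) * 1e3 +
      num(m$rep)
  }, 0)
  vols[order(key)]
}

#' Run a named analysis protocol from a configuration
#'
#' Thin driver tying the modules together: `simulate` renders and writes a
#' series; the analysis tasks read a series (or take volumes directly) and
#' produce an analysis report written as JSON + CSV. Deterministic given
#' the same configuration and seed (timestamps excluded from outputs).
#'
#' @param config a named list (or path to a YAML/JSON file) with at least
#'   `task` (one of "simulate", "fiducial", "t1-ir", "t1-vfa", "t2",
#'   "pd-snr"), plus task arguments: `preset`, `seed`, `input`, `out`,
#'   `array`, `mode`.
#' @return list of class "AnalysisReport": module, parameters, results,
#'   summary.
#' @export
runProtocol <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  task <- config$task
  if (is.null(task)) stop("config must name a task")
  layout <- if (!is.null(config$layout)) layoutFromJSON(config$layout)
            else phantomLayout()
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- config$out

  report <- switch(task,
    simulate = {
      preset <- if (is.null(config$preset)) "isotropic3D" else config$preset
      cfg <- simulationConfig(
        layout = layout,
        acquisition = acquisitionPreset(preset),
        noise = list(sigma = if (is.null(config$sigma)) 0 else config$sigma,
                     kind = if (is.null(config$noise_kind)) "rician"
                            else config$noise_kind,
                     seed = seed))
      vols <- renderSeries(cfg)
      if (!is.null(out)) writeSeries(vols, out, prefix = preset)
      list(module = "simulate",
           parameters = list(preset = preset, seed = seed),
           results = data.frame(n_volumes = length(vols)),
           summary = list(n_volumes = length(vols)))
    },
    fiducial = {
      vols <- if (!is.null(config$volumes)) config$volumes
              else readSeries(config$input)
      fa <- fiducialAnalysis(vols[[1]], layout)
      list(module = "fiducial",
           parameters = list(seed = seed),
           results = fa$distortion$per_sphere,
           summary = list(scale = fa$distortion$scale,
                          rms_mm = fa$distortion$rms_mm,
                          translation_mm = fa$distortion$translation))
    },
    `t1-ir` = .relaxTask(config, layout, "NiCl2", "t1_ir"),
    `t1-vfa` = .relaxTask(config, layout, "NiCl2", "t1_vfa"),
    t2 = .relaxTask(config, layout, "MnCl2", "t2_se"),
    `pd-snr` = {
      vols <- if (!is.null(config$volumes)) config$volumes
              else readSeries(config$input)
      if (length(vols) < 2) stop("pd-snr needs two replicate volumes")
      arr <- parameterArray(layout, "PD")
      pd <- measurePD(vols[[1]], layout)
      snr <- estimateSNR(vols[[1]], vols[[2]],
                         as.matrix(arr[, c("x", "y", "z")]))
      res <- cbind(pd, SNR = snr$SNR, noise = snr$noise)
      list(module = "pd_snr", parameters = list(seed = seed),
           results = res,
           summary = list(max_abs_error_pp = max(abs(pd$error_pp)),
                          sd_error_pp = stats::sd(pd$error_pp)))
    },
    stop("unknown protocol task: ", task)
  )
  class(report) <- "AnalysisReport"
  if (!is.null(out) && task != "simulate") writeAnalysisReport(report, out)
  report
}

.relaxTask <- function(config, layout, default_array, model) {
  vols <- if (!is.null(config$volumes)) config$volumes
          else readSeries(config$input)
  kind <- if (is.null(config$array)) default_array else config$array
  mode <- if (is.null(config$mode)) "roi_mean" else config$mode
  TRms <- acqMeta(vols[[1]], "TR_ms")
  res <- relaxometryAnalysis(vols, layout, kind, model, mode = mode,
                             TR_ms = TRms)
  list(module = paste0("relaxometry_", model),
       parameters = list(array = kind, mode = mode),
       results = res,
       summary = list(mean_abs_deviation_pct =
                        mean(abs(res$deviation_pct), na.rm = TRUE)))
}

#' Write an analysis report as JSON + CSV
#'
#' @param report an "AnalysisReport" from [runProtocol()].
#' @param prefix output path prefix.
#' @return invisibly, the JSON path.
#' @export
writeAnalysisReport <- function(report, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$results, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(module = report$module, parameters = report$parameters,
         summary = report$summary),
    paste0(prefix, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(paste0(prefix, ".json"))
}
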