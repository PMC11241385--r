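## Image and configuration I/O. Rasters go through EBImage (PNG, JPEG,
## TIFF); ROI/threshold configuration comes from YAML or JSON.

#' Read an ultrasound raster from disk
#'
#' Reads a PNG, JPEG or TIFF file into an [UltrasoundImage-class].
#' Grayscale files yield one channel; color files are truncated to the
#' three RGB channels (an alpha channel, if present, is dropped). Sample
#' depth beyond 8 bits is rejected.
#'
#' @param path file path.
#' @return An [UltrasoundImage-class] in RGB colorspace.
#' @export
readUltrasound <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  px <- EBImage::imageData(img)
  if (length(d) == 2L) {
    px <- array(px, c(d, 1L))
  } else if (d[3L] > 3L) {
    px <- px[, , 1:3, drop = FALSE]
  }
  px <- px * 255
  if (max(abs(px - round(px))) > 1e-6)
    stop("depth error: ", path, " does not hold 8-bit samples")
  ## EBImage stores x (width) first; transpose to row/col
  px <- aperm(round(px), c(2L, 1L, 3L))
  ultrasoundImage(px, colorspace = "RGB", sourcePath = path)
}

#' Write an RGB/grayscale ultrasound raster to disk
#'
#' @param img an RGB [UltrasoundImage-class].
#' @param path output path; format follows the extension (png, jpg,
#'   tiff). PNG is lossless and is what the phantom writer uses.
#' @return `path`, invisibly.
#' @export
writeUltrasound <- function(img, path) {
  stopifnot(is(img, "UltrasoundImage"))
  if (!identical(img@colorspace, "RGB"))
    stop("only RGB images can be written")
  px <- aperm(img@pixels / 255, c(2L, 1L, 3L))
  out <- if (dim(px)[3L] == 1L) EBImage::Image(px[, , 1L]) else
    EBImage::Image(px, colormode = "Color")
  EBImage::writeImage(out, path)
  invisible(path)
}

#' Read ROI/threshold configuration from YAML or JSON
#'
#' The file must hold `roi_parenchyma` and `roi_plexus` blocks with keys
#' `row_start`, `row_end`, `col_start`, `col_end` (1-based inclusive
#' pixel bounds) and may hold a `thresholds` block with `t_intensive`
#' and `t_normal` (defaults 10 and 40).
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return List with `roiParenchyma`, `roiPlexus` ([RegionSpec-class])
#'   and `thresholds` ([ThresholdSet-class]).
#' @export
readRegionConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path)
  .regionFrom <- function(block, name) {
    need <- c("row_start", "row_end", "col_start", "col_end")
    if (is.null(block) || !all(need %in% names(block)))
      stop("config block ", name, " must define ",
           paste(need, collapse = ", "))
    regionSpec(block$row_start, block$row_end, block$col_start,
               block$col_end)
  }
  th <- if (is.null(cfg$thresholds)) thresholdSet() else
    thresholdSet(
      if (is.null(cfg$thresholds$t_intensive)) 10 else
        cfg$thresholds$t_intensive,
      if (is.null(cfg$thresholds$t_normal)) 40 else
        cfg$thresholds$t_normal)
  list(roiParenchyma = .regionFrom(cfg$roi_parenchyma, "roi_parenchyma"),
       roiPlexus = .regionFrom(cfg$roi_plexus, "roi_plexus"),
       thresholds = th)
}

#' Flatten a DensityAssessment to a one-row data.frame
#'
#' @param assessment a [DensityAssessment-class].
#' @param id optional identifier for the record.
#' @return One-row data.frame with the score, grade, per-region Lab
#'   means and the thresholds used.
#' @export
assessmentRecord <- function(assessment, id = NA_character_) {
  stopifnot(is(assessment, "DensityAssessment"))
  p <- assessment@parenchyma; q <- assessment@plexus
  data.frame(id = id,
             deltaE = assessment@deltaE,
             grade = as.character(assessment@grade),
             parenchymaL = p@LMean, parenchymaA = p@aMean,
             parenchymaB = p@bMean,
             plexusL = q@LMean, plexusA = q@aMean, plexusB = q@bMean,
             tIntensive = assessment@thresholds@tIntensive,
             tNormal = assessment@thresholds@tNormal,
             stringsAsFactors = FALSE)
}

#' Write a phantom dataset as class-folder PNGs plus a manifest
#'
#' Writes one PNG per composite under `Normal/`, `Moderate/` and
#' `Intensive/` subdirectories of `dir` and a `manifest.csv` describing
#' every sample.
#'
#' @param dataset a [CompositeDataset-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeDatasetPNGs <- function(dataset, dir) {
  stopifnot(is(dataset, "CompositeDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lev in gradeLevels())
    dir.create(file.path(dir, lev), showWarnings = FALSE)
  man <- dataset@manifest
  files <- character(length(dataset))
  for (i in seq_len(length(dataset))) {
    img <- ultrasoundImage(dataset@pixels[, , , i])
    files[i] <- file.path(dir, as.character(dataset@labels[i]),
                          paste0(man$id[i], ".png"))
    writeUltrasound(img, files[i])
  }
  man$file <- files
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a class-folder dataset of composite PNGs
#'
#' Inverse of [writeDatasetPNGs()]: reads every PNG under the
#' `Normal/`, `Moderate/`, `Intensive/` subdirectories of `dir` into a
#' [CompositeDataset-class], labels taken from the folder names.
#'
#' @param dir dataset directory.
#' @return A [CompositeDataset-class].
#' @export
readDatasetPNGs <- function(dir) {
  files <- character(); labs <- character()
  for (lev in gradeLevels()) {
    f <- sort(list.files(file.path(dir, lev), pattern = "\\.png$",
                         full.names = TRUE))
    files <- c(files, f)
    labs <- c(labs, rep(lev, length(f)))
  }
  if (!length(files)) stop("no class-folder PNGs under ", dir)
  imgs <- lapply(files, readUltrasound)
  d <- dim(imgs[[1L]]@pixels)
  px <- array(0, c(d[1L], d[2L], 3L, length(imgs)))
  for (i in seq_along(imgs)) {
    p <- imgs[[i]]@pixels
    if (dim(p)[3L] == 1L) p <- array(p, c(d[1L], d[2L], 3L))
    px[, , , i] <- p
  }
  man <- data.frame(id = tools::file_path_sans_ext(basename(files)),
                    label = labs, file = files, stringsAsFactors = FALSE)
  new("CompositeDataset", pixels = px, labels = .gradeFactor(labs),
      manifest = man)
}

#' Export an evaluation report as CSV and JSON
#'
#' Writes `<prefix>_metrics.csv` (per-class rows plus the macro
#' `Overall` row, in percent) and `<prefix>_confusion.csv` (row-percent
#' confusion matrix), plus a single `<prefix>.json` holding counts,
#' per-class metrics and the overall row at full precision.
#'
#' @param report an [EvaluationReport-class].
#' @param prefix output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
exportReport <- function(report, prefix) {
  stopifnot(is(report, "EvaluationReport"))
  per <- round(report@perClass * 100, 2)
  per <- rbind(per, Overall = round(report@overall * 100, 2))
  metricsPath <- paste0(prefix, "_metrics.csv")
  utils::write.csv(cbind(class = rownames(per), per), metricsPath,
                   row.names = FALSE)
  confPath <- paste0(prefix, "_confusion.csv")
  utils::write.csv(round(rowPercent(report@confusion), 2), confPath)
  jsonPath <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(confusion = report@confusion,
         perClass = cbind(class = rownames(report@perClass),
                          report@perClass),
         overall = as.list(report@overall)),
    jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(metricsPath, confPath, jsonPath))
}
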