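# Readers and writers for the public brain-tumor dataset dialect: MAT v7.3
# files are HDF5 containers holding a `cjdata` group with `image`, `label`,
# `PID` and optionally `tumorMask`/`tumorBorder`.  Plus dataset manifests,
# delimited feature IO and PNG export.

#' Default label map of the three-class brain-tumor dataset
#'
#' @return named character vector mapping the stored integer codes to tumor
#'   type names.
#' @export
defaultLabelMap <- function() {
  c("1" = "meningioma", "2" = "glioma", "3" = "pituitary")
}

#' Load one record in the cjdata dialect
#'
#' Reads a MAT v7.3 / HDF5 file holding a `cjdata` group and returns the
#' parsed record.  `PID` stored as numeric character codes (the MAT string
#' convention) is decoded to a character id; the image is cast to a float
#' matrix; `tumorMask` and `tumorBorder` are optional.
#'
#' @param path file path.
#' @param labelMap named vector mapping stored integer labels to class
#'   names; [defaultLabelMap()] by default.
#' @return list with `image` (numeric matrix), `label` (integer code),
#'   `labelName`, `subjectId`, `tumorMask` (logical matrix or `NULL`),
#'   `tumorBorder` (numeric vector or `NULL`).
#' @export
loadCjdataMat <- function(path, labelMap = defaultLabelMap()) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  contents <- tryCatch(rhdf5::h5ls(path),
                       error = function(e)
                         stop("unreadable HDF5/MAT file '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  inGroup <- contents$name[contents$group == "/cjdata"]
  if (!any(contents$name == "cjdata" & contents$group == "/"))
    stop("format error in '", path, "': missing group 'cjdata'",
         call. = FALSE)
  for (fld in c("image", "label", "PID"))
    if (!fld %in% inGroup)
      stop("format error in '", path, "': missing field '", fld, "'",
           call. = FALSE)
  readF <- function(name) rhdf5::h5read(path, paste0("cjdata/", name))
  image <- readF("image")
  storage.mode(image) <- "double"
  label <- as.integer(as.vector(readF("label"))[1])
  pid <- readF("PID")
  subjectId <- if (is.character(pid)) paste(pid, collapse = "")
               else intToUtf8(as.integer(as.vector(pid)))
  rec <- list(image = image, label = label,
              labelName = unname(labelMap[as.character(label)]),
              subjectId = subjectId, tumorMask = NULL, tumorBorder = NULL)
  if ("tumorMask" %in% inGroup) {
    m <- readF("tumorMask")
    if (!all(dim(m) == dim(image)))
      stop("format error in '", path,
           "': tumorMask shape differs from image", call. = FALSE)
    rec$tumorMask <- matrix(as.logical(m), nrow(m))
  }
  if ("tumorBorder" %in% inGroup)
    rec$tumorBorder <- as.numeric(as.vector(readF("tumorBorder")))
  rec
}

#' Write one record in the cjdata dialect
#'
#' Writes a synthetic record as an HDF5 file with the same group/field
#' layout the loader expects; used for fixtures and for exporting phantom
#' datasets.
#'
#' @param path destination path.
#' @param image numeric matrix.
#' @param label integer class code.
#' @param subjectId subject/patient identifier string.
#' @param tumorMask optional logical matrix, same shape as `image`.
#' @param tumorBorder optional numeric coordinate vector.
#' @return `path`, invisibly.
#' @export
writeCjdataMat <- function(path, image, label, subjectId,
                           tumorMask = NULL, tumorBorder = NULL) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "cjdata")
  rhdf5::h5write(image, path, "cjdata/image")
  rhdf5::h5write(as.numeric(label), path, "cjdata/label")
  rhdf5::h5write(as.numeric(utf8ToInt(subjectId)), path, "cjdata/PID")
  if (!is.null(tumorMask))
    rhdf5::h5write(tumorMask * 1, path, "cjdata/tumorMask")
  if (!is.null(tumorBorder))
    rhdf5::h5write(as.numeric(tumorBorder), path, "cjdata/tumorBorder")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Manifest of a cjdata dataset directory
#'
#' Walks a directory (recursively) of `.mat` records, counting records per
#' class and distinct subjects.  The acquisition plane is not stored
#' per-record in this dialect, so plane counts report "unknown".  Counts are
#' independent of file order.
#'
#' @param dir dataset directory.
#' @param labelMap label map, see [loadCjdataMat()].
#' @return list with `total`, `perClass` (named vector), `perPlane`,
#'   `nSubjects`.
#' @export
datasetManifest <- function(dir, labelMap = defaultLabelMap()) {
  files <- sort(list.files(dir, pattern = "\\.mat$", recursive = TRUE,
                           full.names = TRUE))
  if (!length(files)) {
    warning("no .mat records under '", dir, "'", call. = FALSE)
    return(list(total = 0L, perClass = integer(0),
                perPlane = c(unknown = 0L), nSubjects = 0L))
  }
  labels <- character(length(files))
  subjects <- character(length(files))
  for (i in seq_along(files)) {
    rec <- loadCjdataMat(files[i], labelMap)
    labels[i] <- if (is.na(rec$labelName)) as.character(rec$label)
                 else rec$labelName
    subjects[i] <- rec$subjectId
  }
  perClass <- table(labels)
  list(total = length(files),
       perClass = stats::setNames(as.integer(perClass), names(perClass)),
       perPlane = c(unknown = length(files)),
       nSubjects = length(unique(subjects)))
}

#' Read / write grayscale images and feature tables
#'
#' Thin wrappers over the standard format libraries: PNG via EBImage,
#' feature matrices and labels as headered CSV.
#'
#' @param path file path.
#' @param image numeric matrix (values clipped to `[0, 1]` on write).
#' @return `readImagePNG` returns a numeric matrix; writers return the path
#'   invisibly.
#' @export
readImagePNG <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) d <- d[, , 1]
  as.matrix(d)
}

#' @rdname readImagePNG
#' @export
writeImagePNG <- function(image, path) {
  EBImage::writeImage(EBImage::Image(pmin(pmax(image, 0), 1)), path)
  invisible(path)
}

#' @rdname readImagePNG
#' @param features numeric matrix, rows = samples.
#' @param labels optional label vector written as a `label` column.
#' @export
writeFeatureCSV <- function(features, path, labels = NULL) {
  df <- as.data.frame(features)
  if (is.null(colnames(features)))
    colnames(df) <- sprintf("f%03d", seq_len(ncol(features)))
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname readImagePNG
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% colnames(df)) {
    labels <- df$label
    df$label <- NULL
  }
  list(features = as.matrix(df), labels = labels)
}

#' Write a selection result as JSON
#'
#' Serializes a [SelectionResult-class] (selected indices, fitness, trace
#' and the optimizer configuration) to a JSON report.
#'
#' @param result a [SelectionResult-class].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeSelectionJSON <- function(result, path) {
  cfg <- result@config
  jsonlite::write_json(list(
    selected = which(result@mask),
    fitness = result@fitness,
    trace = result@trace,
    config = list(popSize = cfg@popSize, iterations = cfg@iterations,
                  alpha = cfg@alpha, hMax = cfg@hMax,
                  pThreshold = cfg@pThreshold, pHybrid = cfg@pHybrid,
                  seed = cfg@seed)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export phantom images as a cjdata-style dataset
#'
#' Writes each phantom as one `.mat` record plus a `manifest.json` carrying
#' the ground truth, so the loader/manifest machinery can be exercised on a
#' fully synthetic directory.
#'
#' @param phantoms result of [makePhantomImages()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportPhantomDataset <- function(phantoms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(phantoms$images))
    writeCjdataMat(file.path(dir, sprintf("%04d.mat", i)),
                   phantoms$images[[i]], phantoms$labels[i],
                   phantoms$subjectIds[i])
  jsonlite::write_json(
    list(total = length(phantoms$images),
         labels = phantoms$labels, subjects = phantoms$subjectIds),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
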