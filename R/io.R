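## NIfTI-1 is the interchange image format; acquisition metadata that the
## NIfTI header cannot carry (TE, TR, b, N, sigma, seed, sensitivities)
## lives in a JSON sidecar next to the image with fixed key names.

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

.niftiPath <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) path else paste0(path, ".nii")
}

#' Write a magnitude image as NIfTI plus JSON sidecar
#'
#' Pixel data are stored as a single 2-D slice in a NIfTI-1 file (double
#' precision, so values round-trip bit-identically) with the in-plane
#' pixel size in the header; slice thickness and the acquisition metadata
#' go in a JSON sidecar with the same base name (NIfTI drops the
#' through-plane spacing of a single slice).
#'
#' @param img a [MagnitudeImage-class].
#' @param path output path; `.nii` is appended if absent.
#' @return invisibly, a character vector of the two paths written.
#' @seealso [readMagnitudeImage()]
#' @export
writeMagnitudeImage <- function(img, path) {
  stopifnot(is(img, "MagnitudeImage"))
  niiPath <- .niftiPath(path)
  arr <- pixels(img)
  attr(arr, "pixdim") <- c(img@pixelSize, img@pixelSize)
  RNifti::writeNifti(arr, niiPath, datatype = "double")
  p <- acqParams(img)
  meta <- list(
    phantomId = img@phantomId,
    tr = p@tr, te = p@te, bValue = p@bValue,
    nChannels = p@nChannels, noiseSigma = p@noiseSigma,
    seed = p@seed, quantize16bit = p@quantize16bit,
    coilSensitivitiesRe = Re(p@coilSensitivities),
    coilSensitivitiesIm = Im(p@coilSensitivities),
    pixelSize = img@pixelSize, sliceThickness = img@sliceThickness)
  scPath <- .sidecarPath(niiPath)
  jsonlite::write_json(meta, scPath, auto_unbox = TRUE, digits = NA)
  invisible(c(niiPath, scPath))
}

#' Read a magnitude image written by [writeMagnitudeImage()]
#'
#' @param path path to the `.nii` file (the JSON sidecar is located next to
#'   it).
#' @return a [MagnitudeImage-class].
#' @export
readMagnitudeImage <- function(path) {
  niiPath <- .niftiPath(path)
  if (!file.exists(niiPath)) stop("no such image: ", niiPath, call. = FALSE)
  scPath <- .sidecarPath(niiPath)
  if (!file.exists(scPath)) stop("missing sidecar: ", scPath, call. = FALSE)
  arr <- RNifti::readNifti(niiPath)
  px <- array(as.numeric(arr), dim = dim(arr))
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  meta <- jsonlite::read_json(scPath, simplifyVector = TRUE)
  sens <- complex(real = meta$coilSensitivitiesRe,
                  imaginary = meta$coilSensitivitiesIm)
  params <- SequenceParams(tr = meta$tr, te = meta$te, bValue = meta$bValue,
                           nChannels = meta$nChannels,
                           noiseSigma = meta$noiseSigma,
                           coilSensitivities = sens, seed = meta$seed,
                           quantize16bit = meta$quantize16bit)
  new("MagnitudeImage", pixels = px, params = params,
      phantomId = meta$phantomId, pixelSize = meta$pixelSize,
      sliceThickness = meta$sliceThickness)
}

#' Write a map set as NIfTI files
#'
#' Writes the signal, noise and SNR maps and the validity mask as four
#' NIfTI files `<prefix>_signal.nii`, `<prefix>_noise.nii`,
#' `<prefix>_snr.nii` and `<prefix>_valid.nii`, plus `<prefix>_maps.json`
#' recording the window size. Invalid border pixels are stored as NaN
#' (mask 0).
#'
#' @param maps a [MapSet-class].
#' @param prefix output path prefix.
#' @param pixelSize,sliceThickness geometry for the NIfTI headers.
#' @return invisibly, the paths written.
#' @export
writeMapSet <- function(maps, prefix, pixelSize = 1, sliceThickness = 1) {
  stopifnot(is(maps, "MapSet"))
  writeOne <- function(m, suffix) {
    p <- paste0(prefix, "_", suffix, ".nii")
    arr <- m
    attr(arr, "pixdim") <- c(pixelSize, pixelSize)
    RNifti::writeNifti(arr, p, datatype = "double")
    p
  }
  paths <- c(writeOne(signalMap(maps), "signal"),
             writeOne(noiseMap(maps), "noise"),
             writeOne(snrMap(maps), "snr"),
             writeOne(validMask(maps) + 0, "valid"))
  metaPath <- paste0(prefix, "_maps.json")
  jsonlite::write_json(list(window = windowSize(maps),
                            pixelSize = pixelSize,
                            sliceThickness = sliceThickness),
                       metaPath, auto_unbox = TRUE)
  invisible(c(paths, metaPath))
}

#' Read a run configuration from JSON or YAML
#'
#' JSON is read with jsonlite; `.yaml`/`.yml` files are read with the yaml
#' package when available.
#'
#' @param path configuration file path.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Read an ROI specification from JSON
#'
#' Accepts either `{"kind": "circular", "center": [r, c], "pixelCount": k}`
#' or `{"kind": "mask", "pixels": [[r, c], ...]}`.
#'
#' @param path JSON file path.
#' @return an [ROISpec-class].
#' @export
readROISpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  roiFromList(x)
}

#' Build an ROI specification from a plain list
#'
#' @param x list with fields as in [readROISpec()].
#' @return an [ROISpec-class].
#' @export
roiFromList <- function(x) {
  kind <- x$kind
  if (identical(kind, "circular")) {
    circularROI(unlist(x$center), x$pixelCount)
  } else if (identical(kind, "mask")) {
    px <- x$pixels
    if (is.list(px)) px <- do.call(rbind, lapply(px, unlist))
    maskROI(matrix(as.integer(px), ncol = 2))
  } else stop("ROI kind must be 'circular' or 'mask'", call. = FALSE)
}

## deterministic 31-bit checksum of a config object (djb2 over its
## canonical JSON serialization); recorded in outputs for provenance
configHash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  b <- utf8ToInt(as.character(s))
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}
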