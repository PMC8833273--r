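#' Construct tissue properties
#'
#' @param t1 longitudinal relaxation time in ms (> 0).
#' @param t2 transverse relaxation time in ms (> 0).
#' @param d apparent diffusion coefficient in mm^2/s (>= 0).
#' @param protonDensity relative proton density (>= 0), default 1.
#' @return a [TissueProperties-class] object.
#'
#' @examples
#' water <- TissueProperties(t1 = 3505, t2 = 2390, d = 2.1e-3)
#' oil   <- TissueProperties(t1 = 196, t2 = 75, d = 0.04e-3)
#' @export
TissueProperties <- function(t1, t2, d, protonDensity = 1) {
  new("TissueProperties", t1 = as.numeric(t1), t2 = as.numeric(t2),
      d = as.numeric(d), protonDensity = as.numeric(protonDensity))
}

#' Construct sequence parameters
#'
#' @param tr repetition time in ms (> 0).
#' @param te echo time in ms (>= 0).
#' @param bValue diffusion weighting in s/mm^2 (>= 0), default 0.
#' @param nChannels number of receive coil channels (>= 1), default 1.
#' @param noiseSigma per-channel, per-component Gaussian noise SD in
#'   intensity units (>= 0), default 0.
#' @param coilSensitivities complex per-channel gains; default all 1.
#' @param seed integer seed for the simulated noise stream, default 1.
#' @param quantize16bit round simulated pixels to a signed 16-bit scale,
#'   default FALSE.
#' @return a [SequenceParams-class] object.
#'
#' @examples
#' SequenceParams(tr = 3000, te = 37, bValue = 0, nChannels = 16,
#'                noiseSigma = 1, seed = 7)
#' @export
SequenceParams <- function(tr, te, bValue = 0, nChannels = 1L,
                           noiseSigma = 0, coilSensitivities = NULL,
                           seed = 1L, quantize16bit = FALSE) {
  n <- .checkChannels(nChannels)
  if (is.null(coilSensitivities)) coilSensitivities <- rep(1 + 0i, n)
  new("SequenceParams", tr = as.numeric(tr), te = as.numeric(te),
      bValue = as.numeric(bValue), nChannels = n,
      noiseSigma = as.numeric(noiseSigma),
      coilSensitivities = as.complex(coilSensitivities),
      seed = as.integer(seed), quantize16bit = isTRUE(quantize16bit))
}

#' Construct a phantom specification from a region map
#'
#' @param regionMap integer matrix of region labels; 0 is background
#'   (signal-free).
#' @param regions named list of [TissueProperties-class], names being the
#'   non-zero labels as character.
#' @param pixelSize in-plane pixel size in mm, default 2.
#' @param sliceThickness slice thickness in mm, default 5.
#' @return a [PhantomSpec-class] object.
#' @seealso [cylindricalPhantom()]
#' @export
PhantomSpec <- function(regionMap, regions, pixelSize = 2, sliceThickness = 5) {
  storage.mode(regionMap) <- "integer"
  new("PhantomSpec", regionMap = regionMap, regions = regions,
      pixelSize = as.numeric(pixelSize),
      sliceThickness = as.numeric(sliceThickness))
}

#' Uniform cylindrical phantom on a square grid
#'
#' Builds the digital analogue of a uniform cylindrical phantom imaged in
#' cross-section: a centered disc of one material surrounded by signal-free
#' background.
#'
#' @param matrixSize image matrix side length in pixels, default 128.
#' @param tissue [TissueProperties-class] of the filling material.
#' @param diameter physical disc diameter in mm, default 100 (a 10-cm
#'   cylinder).
#' @param pixelSize in-plane pixel size in mm, default 2 (a 256-mm field of
#'   view at matrix 128).
#' @param sliceThickness slice thickness in mm, default 5.
#' @return a [PhantomSpec-class] with region label 1 inside the disc.
#'
#' @examples
#' ph <- cylindricalPhantom(64, TissueProperties(3505, 2390, 2.1e-3))
#' table(regionMap(ph))
#' @export
cylindricalPhantom <- function(matrixSize = 128L, tissue,
                               diameter = 100, pixelSize = 2,
                               sliceThickness = 5) {
  n <- as.integer(matrixSize)
  if (n < 4L) stop("matrixSize must be >= 4", call. = FALSE)
  ctr <- (n + 1) / 2
  rad <- diameter / 2 / pixelSize
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  map <- matrix(0L, n, n)
  map[(rr - ctr)^2 + (cc - ctr)^2 <= rad^2] <- 1L
  PhantomSpec(map, list("1" = tissue), pixelSize = pixelSize,
              sliceThickness = sliceThickness)
}

#' Region map of a phantom
#' @param x a [PhantomSpec-class].
#' @return the integer label matrix.
#' @export
regionMap <- function(x) {
  stopifnot(is(x, "PhantomSpec"))
  x@regionMap
}

#' Tissue properties of one phantom region
#' @param x a [PhantomSpec-class].
#' @param label region label (integer or character).
#' @return the [TissueProperties-class] of that region; label 0 returns the
#'   implicit signal-free background.
#' @export
regionTissue <- function(x, label) {
  stopifnot(is(x, "PhantomSpec"))
  lab <- as.character(as.integer(label))
  if (identical(lab, "0"))
    return(TissueProperties(t1 = 1, t2 = 1, d = 0, protonDensity = 0))
  out <- x@regions[[lab]]
  if (is.null(out)) stop("no region with label ", lab, call. = FALSE)
  out
}
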