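#' Read a single-channel TIFF image
#'
#' Accepts 8/16-bit integer or 32-bit float, single channel. Integer data
#' are returned in counts (0..255 / 0..65535); float data are returned
#' as stored (NaN preserved, used for disparity/depth maps).
#'
#' @param path TIFF file path.
#' @return numeric matrix.
#' @export
readImageTiff <- function(path) {
  im <- tiff::readTIFF(path, info = TRUE)
  info <- attributes(im)
  if (!identical(info$sample.format, "float")) {
    # integer TIFF: undo the [0,1] scaling back to counts
    bits <- if (is.null(info$bits.per.sample)) 16L else info$bits.per.sample
    im <- round(im * (2^bits - 1))
  }
  attributes(im) <- list(dim = dim(im))
  if (length(dim(im)) == 3) {
    if (dim(im)[3] == 1) im <- im[, , 1]
    else stop("multi-channel TIFF not supported: ", path,
              " has ", dim(im)[3], " channels; supply a single-channel ",
              "grayscale image")
  }
  im
}

#' Write a single-channel TIFF image
#'
#' `type = "uint16"` (or "uint8") writes integer counts; `type = "float"`
#' writes 32-bit IEEE floats and preserves NaN, the storage format used
#' for disparity and depth maps.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @param type "uint16", "uint8" or "float".
#' @return invisibly, `path`.
#' @export
writeImageTiff <- function(image, path, type = c("uint16", "float",
                                                 "uint8")) {
  type <- match.arg(type)
  if (!is.matrix(image)) stop("image must be a single-channel matrix")
  if (type == "float") {
    .writeFloatTiff(image, path)
  } else {
    bits <- if (type == "uint16") 16L else 8L
    mx <- 2^bits - 1
    if (any(image < 0 | image > mx, na.rm = TRUE))
      stop("integer TIFF requires values in [0, ", mx, "]")
    tiff::writeTIFF(image / mx, path, bits.per.sample = bits)
  }
  invisible(path)
}

#' Write an RGB array as PNG
#' @param rgb array (rows, cols, 3) in [0, 1].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeImagePng <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

# Minimal single-strip uncompressed 32-bit float grayscale TIFF writer.
# The tiff package clamps data to [0, 1] on write, which cannot represent
# signed millimetre depths or NaN; readTIFF reads IEEE float TIFFs fine,
# so only the writer is needed.
.writeFloatTiff <- function(image, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nr <- nrow(image); nc <- ncol(image)
  dataBytes <- 4L * nr * nc
  # header: little-endian magic, IFD offset after the pixel data
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L + dataBytes, con, size = 4, endian = "little")
  # pixel data, row-major
  writeBin(as.numeric(t(image)), con, size = 4, endian = "little")
  tag <- function(id, type, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT, left-justified in the 4-byte slot
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(10L, con, size = 2, endian = "little")  # tag count
  tag(256, 4, nc)          # ImageWidth
  tag(257, 4, nr)          # ImageLength
  tag(258, 3, 32)          # BitsPerSample
  tag(259, 3, 1)           # no compression
  tag(262, 3, 1)           # BlackIsZero
  tag(273, 4, 8)           # StripOffsets: data follows the header
  tag(277, 3, 1)           # SamplesPerPixel
  tag(278, 4, nr)          # RowsPerStrip
  tag(279, 4, dataBytes)   # StripByteCounts
  tag(339, 3, 3)           # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

# known configuration schema: name -> required
.configSchema <- c(
  focal_length_mm = TRUE, pixel_pitch_um = TRUE, baseline_mm = TRUE,
  object_distance_mm = TRUE, reference_plane_offset_mm = FALSE,
  sensor_width_px = FALSE, sensor_height_px = FALSE,
  scales = FALSE, beta = FALSE, c = FALSE, threshold = FALSE,
  min_component_size = FALSE, normalize = FALSE,
  normalize_quantile = FALSE, normalize_gamma = FALSE,
  cost = FALSE, census_window = FALSE, p1 = FALSE, p2 = FALSE,
  n_paths = FALSE, lr_tolerance = FALSE, subpixel = FALSE,
  subpixel_method = FALSE, z_span_mm = FALSE,
  band = FALSE, mu_eff = FALSE, psf_fwhm_at_1mm = FALSE,
  psf_fwhm_slope = FALSE,
  display_range_mm = FALSE, seed = FALSE)

#' Read and validate a pipeline configuration
#'
#' YAML with the rig geometry ({focal_length_mm, pixel_pitch_um,
#' baseline_mm, object_distance_mm, reference_plane_offset_mm}) plus
#' optional enhancement, matching, medium and display settings. Unknown
#' keys and missing required fields are schema errors naming the field.
#' The shipped defaults live in inst/extdata/default_config.yaml.
#'
#' @param path YAML file, or NULL for the shipped defaults.
#' @return validated named list.
#' @export
readPipelineConfig <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.yaml",
                        package = "nirstereo", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.configSchema))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(names(.configSchema)[.configSchema], names(cfg))
  if (length(missing))
    stop("missing required config field(s): ",
         paste(missing, collapse = ", "))
  defaults <- yaml::read_yaml(system.file("extdata",
                                          "default_config.yaml",
                                          package = "nirstereo",
                                          mustWork = TRUE))
  utils::modifyList(defaults, cfg)
}

#' Build a StereoRig from a pipeline configuration
#' @param cfg list from \code{\link{readPipelineConfig}}.
#' @return a \linkS4class{StereoRig}.
#' @export
rigFromConfig <- function(cfg) {
  cam <- cameraModel(focalLength = cfg$focal_length_mm,
                     pixelPitch = cfg$pixel_pitch_um,
                     sensorWidth = cfg$sensor_width_px,
                     sensorHeight = cfg$sensor_height_px)
  stereoRig(cam, baseline = cfg$baseline_mm,
            referenceDistance = cfg$object_distance_mm,
            referencePlaneOffset = cfg$reference_plane_offset_mm)
}
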