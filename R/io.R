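# On-disk representation of synthetic eyes: 8-bit PNG (or TIFF) images,
# PNG masks with values {0, 255}, and a JSON sidecar with the generation
# parameters.  Layout: <dir>/<eye_id>/<plexus>.png etc.

png_bit_depth <- function(path) {
  # IHDR bit depth lives at byte offset 24 (0-based) of a PNG stream
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 25L)
  if (length(hdr) < 25L ||
      !identical(hdr[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    stop("not a PNG file: ", path)
  as.integer(hdr[25L])
}

write_gray_png <- function(img, path) {
  png::writePNG(img / 255, path)
}

read_gray_image <- function(path, on_16bit = c("rescale", "error")) {
  on_16bit <- match.arg(on_16bit)
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    depth <- png_bit_depth(path)
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    if (depth > 8L) {
      if (on_16bit == "error")
        stop("16-bit image not allowed by configuration: ", path)
      warning("rescaling ", depth, "-bit image to 8-bit: ", path)
    }
    img <- round(a * 255)
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(a, "bits.per.sample")
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    if (!is.null(bits) && bits > 8L) {
      if (on_16bit == "error")
        stop("16-bit image not allowed by configuration: ", path)
      warning("rescaling ", bits, "-bit image to 8-bit: ", path)
    }
    img <- round(a * 255)
  } else stop("unsupported image format '", ext, "': ", path)
  storage.mode(img) <- "integer"
  img
}

read_mask_png <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  v <- round(a * 255)
  if (!all(v %in% c(0, 255)))
    stop("mask contains values other than {0, 255}: ", path)
  v == 255
}

#' Write a synthetic eye to disk
#'
#' Writes `<dir>/<eye_id>/<plexus>.png` (8-bit grayscale), the ground
#' truth masks `<plexus>_vessel_mask.png` and `<plexus>_faz_mask.png`
#' (values 0/255), and a JSON sidecar `<plexus>.json` with the generation
#' parameters.
#'
#' @param eye a `synthetic_eye`.
#' @param dir cohort directory.
#' @param eye_id identifier; defaults to the eye's own id.
#' @return the eye directory, invisibly.
#' @export
write_eye <- function(eye, dir, eye_id = eye$eye_id) {
  if (is.null(eye_id)) stop("eye has no id; pass eye_id explicitly")
  plx <- eye$params$plexus
  d <- file.path(dir, eye_id)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_gray_png(eye$image, file.path(d, paste0(plx, ".png")))
  write_gray_png(eye$vessel_truth * 255,
                 file.path(d, paste0(plx, "_vessel_mask.png")))
  write_gray_png(eye$faz_truth * 255,
                 file.path(d, paste0(plx, "_faz_mask.png")))
  meta <- list(eye_id = eye_id, plexus = plx, seed = eye$params$seed,
               center = eye$center,
               params = unclass(eye$params))
  jsonlite::write_json(meta, file.path(d, paste0(plx, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(d)
}

#' Read a synthetic eye back from disk
#'
#' Inverse of [write_eye()]: `read_eye(write_eye(x))` reproduces the
#' image, masks and metadata exactly.
#'
#' @param dir cohort directory.
#' @param eye_id eye identifier (subdirectory name).
#' @param plexus plexus name.
#' @param on_16bit policy for images with more than 8 bits per sample:
#'   `"rescale"` (with a warning) or `"error"`.
#' @return a `synthetic_eye`.
#' @export
read_eye <- function(dir, eye_id, plexus = c("SCP", "DCP", "CC"),
                     on_16bit = c("rescale", "error")) {
  plexus <- match.arg(plexus)
  d <- file.path(dir, eye_id)
  img <- read_gray_image(file.path(d, paste0(plexus, ".png")), on_16bit)
  vm <- read_mask_png(file.path(d, paste0(plexus, "_vessel_mask.png")))
  fm <- read_mask_png(file.path(d, paste0(plexus, "_faz_mask.png")))
  mpath <- file.path(d, paste0(plexus, ".json"))
  if (!file.exists(mpath)) stop("metadata sidecar not found: ", mpath)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  pars <- meta$params
  keep <- setdiff(intersect(names(pars), names(formals(plexus_params))), "plexus")
  params <- do.call(plexus_params, c(list(plexus = plexus), pars[keep]))
  new_synthetic_eye(img, vm, fm, unlist(meta$center), params, eye_id = meta$eye_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
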