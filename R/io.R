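# File I/O for the formats the pipeline consumes and emits: TIFF/PNG
# images, float-TIFF maps, CSV tables, JSON reports, ASCII PLY clouds.

#' Read a grayscale or RGB image
#'
#' Reads TIFF or PNG (by extension).  RGB inputs are reduced to one
#' channel (default the red channel, which carries the coherent speckle
#' signal on an RGB sensor).
#'
#' @param path image path (.tif/.tiff/.png).
#' @param pixel_size object pixel size (mm) to attach.
#' @param channel `"red"`, `"green"`, `"blue"`, or `"mean"`.
#' @return an [image_grid()].
#' @export
read_image <- function(path, pixel_size, channel = "red") {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) {
    img <- switch(channel,
                  red = img[, , 1],
                  green = img[, , 2],
                  blue = img[, , 3],
                  mean = (img[, , 1] + img[, , 2] + img[, , 3]) / 3,
                  stop("unknown channel: ", channel))
  }
  image_grid(img, pixel_size)
}

#' Write a matrix as an image
#'
#' Float maps (possibly with NA) go to 32-bit float TIFF; masks and
#' display images to 8-bit PNG/TIFF after clamping to \[0, 1\].
#'
#' @param m numeric or logical matrix.
#' @param path output path; format by extension.
#' @param bits 8 or 32 (TIFF only; PNG is always 8/16-bit integer).
#' @return `path`, invisibly.
#' @export
write_image <- function(m, path, bits = 32L) {
  ext <- tolower(tools::file_ext(path))
  m <- unclass(m) * 1
  if (ext %in% c("tif", "tiff")) {
    if (bits == 32L) {
      m[!is.finite(m)] <- NaN
      tiff::writeTIFF(m, path, bits.per.sample = 32L)
    } else {
      tiff::writeTIFF(pmin(pmax(m, 0), 1), path, bits.per.sample = 8L)
    }
  } else if (ext == "png") {
    png::writePNG(pmin(pmax(m, 0), 1), path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Write a point cloud as ASCII PLY
#'
#' @param cloud list with matrices `X`, `Y`, `Z` (mm); invalid points
#'   (non-finite Z) are dropped.
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  ok <- is.finite(cloud$Z)
  n <- sum(ok)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(
    data.frame(x = cloud$X[ok], y = cloud$Y[ok], z = cloud$Z[ok]),
    con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a PSD curve as CSV
#' @param psd a `psd_curve`; `path` output path.
#' @return `path`, invisibly.
#' @export
psd_write_csv <- function(psd, path) {
  utils::write.csv(data.frame(kr = psd$kr, value = psd$values), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write an optical-property map bundle
#'
#' Two float TIFFs (mu_a, mu_s'), an 8-bit mask TIFF, and a JSON
#' provenance sidecar.
#'
#' @param opmap an `optical_property_map` from [property_maps()].
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_property_maps <- function(opmap, prefix) {
  paths <- c(mu_a = paste0(prefix, "_mu_a.tif"),
             mu_s = paste0(prefix, "_mu_s_prime.tif"),
             mask = paste0(prefix, "_mask.tif"),
             meta = paste0(prefix, "_provenance.json"))
  write_image(opmap$mu_a_map, paths["mu_a"], bits = 32L)
  write_image(opmap$mu_s_map, paths["mu_s"], bits = 32L)
  write_image(opmap$mask, paths["mask"], bits = 8L)
  jsonlite::write_json(c(opmap$provenance, list(n_masked = opmap$n_masked)),
                       paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
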