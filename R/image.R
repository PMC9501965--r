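#' Construct an intensity image
#'
#' The basic container of the package: a 2D grid of nonnegative integer
#' photon counts with an explicit bit depth and a physical pixel pitch.
#' Confocal frames in the regime this package targets are 16-bit,
#' 512 x 512, with a 250 nm pixel interval.
#'
#' @param pixels numeric matrix of nonnegative integers, row-major with
#'   origin at the top-left (row 1, column 1).
#' @param bit_depth integer, 8 or 16.
#' @param pitch_xy physical pixel interval in nanometres (> 0).
#' @return an object of class `intensity_image` with fields `pixels`,
#'   `bit_depth` and `pitch_xy`.
#' @export
intensity_image <- function(pixels, bit_depth = 16L, pitch_xy = 250) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (!is.numeric(pitch_xy) || length(pitch_xy) != 1L || pitch_xy <= 0)
    stop("`pitch_xy` must be a single positive number (nm)")
  if (anyNA(pixels)) stop("`pixels` contains NA")
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1))
    stop("pixel values must lie in [0, 2^bit_depth - 1]")
  if (any(pixels != round(pixels)))
    stop("pixel values must be integers")
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, bit_depth = bit_depth, pitch_xy = pitch_xy),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d, %d-bit, pitch %s nm\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              format_nm(x$pitch_xy)))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

# round-half-up display of a pitch held internally as an exact numeric
format_nm <- function(nm) as.character(floor(nm + 0.5))

#' Construct a z-stack of intensity images
#'
#' @param slices list of [intensity_image] objects sharing dimensions,
#'   bit depth and xy pitch, ordered by increasing z.
#' @param pitch_z z interval between consecutive slices in nm.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(slices, pitch_z = 1000) {
  if (!length(slices)) stop("a stack needs at least one slice")
  if (!all(vapply(slices, inherits, logical(1), "intensity_image")))
    stop("all slices must be intensity_image objects")
  d1 <- dim(slices[[1L]]$pixels)
  ok <- vapply(slices, function(s)
    identical(dim(s$pixels), d1) &&
      s$bit_depth == slices[[1L]]$bit_depth &&
      isTRUE(all.equal(s$pitch_xy, slices[[1L]]$pitch_xy)), logical(1))
  if (!all(ok)) stop("slices differ in shape, bit depth or pitch")
  if (pitch_z <= 0) stop("`pitch_z` must be positive (nm)")
  structure(list(slices = slices, pitch_z = pitch_z), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  s <- x$slices[[1L]]
  cat(sprintf("<image_stack> %d slices of %d x %d, %d-bit, pitch %s nm, z %s nm\n",
              length(x$slices), nrow(s$pixels), ncol(s$pixels), s$bit_depth,
              format_nm(s$pitch_xy), format_nm(x$pitch_z)))
  invisible(x)
}

#' Read a single-channel grayscale TIFF
#'
#' Values and bit depth are preserved exactly; multi-page files yield an
#' [image_stack]. RGB and floating-point TIFFs are rejected.
#'
#' @param path path to a TIFF file.
#' @param pitch_xy,pitch_z physical pitches in nm to attach (TIFF
#'   resolution tags are not interpreted).
#' @return an [intensity_image] or, for multi-page files, an [image_stack].
#' @export
read_tiff <- function(path, pitch_xy = 250, pitch_z = 1000) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  to_img <- function(p) {
    if (length(dim(p)) == 3L && dim(p)[3L] > 1L)
      stop("unsupported format: multi-channel (RGB) TIFF")
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    if (is.double(p) && any(p != round(p)))
      stop("unsupported format: floating-point TIFF")
    bits <- attr(p, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(p) > 255) 16L else 8L
    if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits)
    intensity_image(matrix(as.numeric(p), nrow(p), ncol(p)),
                    bit_depth = bits, pitch_xy = pitch_xy)
  }
  imgs <- lapply(pages, to_img)
  if (length(imgs) == 1L) imgs[[1L]] else image_stack(imgs, pitch_z = pitch_z)
}

#' Write an image or stack to TIFF
#'
#' @param img an [intensity_image] or [image_stack].
#' @param path output path; multi-slice stacks become multi-page files.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path) {
  if (inherits(img, "intensity_image")) {
    tiff::writeTIFF(img$pixels / (2^img$bit_depth - 1), path,
                    bits.per.sample = img$bit_depth, compression = "none")
  } else if (inherits(img, "image_stack")) {
    bd <- img$slices[[1L]]$bit_depth
    tiff::writeTIFF(lapply(img$slices, function(s) s$pixels / (2^bd - 1)),
                    path, bits.per.sample = bd, compression = "none")
  } else stop("`img` must be an intensity_image or image_stack")
  invisible(path)
}

#' Convert a 16-bit image to 8-bit
#'
#' Default is fixed full-range scaling `round(v * 255 / 65535)`
#' (round-half-up), which keeps intensities comparable across images;
#' `minmax = TRUE` stretches each image's own range instead.
#'
#' @param img a 16-bit [intensity_image].
#' @param minmax use per-image min-max stretching instead of the fixed
#'   full-range projection.
#' @return an 8-bit [intensity_image].
#' @export
convert_16_to_8 <- function(img, minmax = FALSE) {
  stopifnot(inherits(img, "intensity_image"))
  if (img$bit_depth != 16L) stop("input is already 8-bit")
  v <- img$pixels
  out <- if (minmax) {
    rng <- range(v)
    if (rng[2L] > rng[1L]) floor((v - rng[1L]) * 255 / (rng[2L] - rng[1L]) + 0.5)
    else v * 0
  } else {
    floor(v * 255 / 65535 + 0.5)
  }
  intensity_image(out, bit_depth = 8L, pitch_xy = img$pitch_xy)
}

#' Split an image into square tiles
#'
#' Non-overlapping, row-major tiling with no padding: both image sides
#' must be divisible by `tile_side`. A 2048 x 2048 frame at side 512
#' yields 16 sub-images, the geometry used for network training and
#' tiled inference.
#'
#' @param img an [intensity_image].
#' @param tile_side tile side length in px.
#' @return an object of class `tile_grid` with fields `tiles` (row-major
#'   list of [intensity_image]), `rows`, `cols`, `tile_side`.
#' @export
tile <- function(img, tile_side) {
  stopifnot(inherits(img, "intensity_image"))
  d <- dim(img$pixels)
  if (any(d %% tile_side != 0))
    stop("image sides (", d[1L], " x ", d[2L],
         ") are not divisible by tile_side ", tile_side)
  rows <- d[1L] %/% tile_side
  cols <- d[2L] %/% tile_side
  tiles <- vector("list", rows * cols)
  k <- 1L
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      ri <- ((i - 1L) * tile_side + 1L):(i * tile_side)
      cj <- ((j - 1L) * tile_side + 1L):(j * tile_side)
      tiles[[k]] <- intensity_image(img$pixels[ri, cj, drop = FALSE],
                                    bit_depth = img$bit_depth,
                                    pitch_xy = img$pitch_xy)
      k <- k + 1L
    }
  }
  structure(list(tiles = tiles, rows = rows, cols = cols,
                 tile_side = as.integer(tile_side)),
            class = "tile_grid")
}

#' Reassemble a tile grid into one image
#'
#' Exact inverse of [tile()]: tiles are disjoint, so no blending occurs
#' and `assemble(tile(img, s))` reproduces `img` pixel for pixel.
#'
#' @param grid a `tile_grid`.
#' @return an [intensity_image].
#' @export
assemble <- function(grid) {
  stopifnot(inherits(grid, "tile_grid"))
  if (length(grid$tiles) != grid$rows * grid$cols)
    stop("tile count does not match grid dimensions")
  s <- grid$tile_side
  shapes_ok <- all(vapply(grid$tiles, function(t)
    identical(dim(t$pixels), c(s, s)), logical(1)))
  if (!shapes_ok) stop("inconsistent tile shapes")
  out <- matrix(0, grid$rows * s, grid$cols * s)
  k <- 1L
  for (i in seq_len(grid$rows)) {
    for (j in seq_len(grid$cols)) {
      out[((i - 1L) * s + 1L):(i * s), ((j - 1L) * s + 1L):(j * s)] <-
        grid$tiles[[k]]$pixels
      k <- k + 1L
    }
  }
  intensity_image(out, bit_depth = grid$tiles[[1L]]$bit_depth,
                  pitch_xy = grid$tiles[[1L]]$pitch_xy)
}
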