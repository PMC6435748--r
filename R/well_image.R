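#' Multi-channel well image
#'
#' A `well_image` bundles the co-registered channels of one whole-well
#' acquisition: the Hoechst nuclear stain, the O4/MBP membrane (myelin)
#' stain, and optionally a brightfield plane showing the nanofiber scaffold.
#' All channels are numeric matrices indexed `[row, col]` with the origin at
#' the top-left corner (row = y downward, col = x rightward, 0-based in all
#' exported coordinate values), sharing one shape and one physical pixel
#' size (default 0.5 µm/px, the resolution of the automated acquisition).
#'
#' @param channels named list of numeric matrices; recognised roles are
#'   `"nuclei"`, `"membrane"` (both required by the segmentation engines) and
#'   `"brightfield"` (optional).
#' @param pixel_size_um physical size of one pixel in µm (> 0).
#' @param name identifier carried through to tabular outputs.
#' @return An object of class `well_image`.
#' @examples
#' img <- well_image(list(nuclei = matrix(0, 32, 32),
#'                        membrane = matrix(0, 32, 32)))
#' dim(img)
#' @export
well_image <- function(channels, pixel_size_um = 0.5, name = "well") {
  stopifnot(is.list(channels), length(channels) > 0, !is.null(names(channels)))
  shapes <- lapply(channels, dim)
  if (length(unique(lapply(shapes, as.integer))) != 1L)
    stop("all channel rasters must share an identical shape")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  channels <- lapply(channels, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (any(m < 0)) stop("channel intensities must be non-negative")
    m
  })
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 name = name),
            class = "well_image")
}

#' @export
dim.well_image <- function(x) dim(x$channels[[1]])

#' @export
print.well_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<well_image '%s'> %d x %d px @ %.3g um/px; channels: %s\n",
              x$name, d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Fetch one channel of a well image
#'
#' @param image a [well_image()].
#' @param role channel role name.
#' @return The channel matrix.
#' @export
get_channel <- function(image, role) {
  stopifnot(inherits(image, "well_image"))
  ch <- image$channels[[role]]
  if (is.null(ch)) stop(sprintf("channel role '%s' not present", role))
  ch
}

#' Read a multi-plane TIFF as a well image
#'
#' Planes of the file are assigned to channel roles through `channel_map`, a
#' named list/vector of 0-based plane indices, e.g.
#' `list(nuclei = 0, membrane = 1)`. The `nuclei` and `membrane` roles are
#' required; `brightfield` is optional.
#'
#' @param path TIFF file (single- or multi-plane, 8- or 16-bit; intensities
#'   are returned on the `[0, 1]` scale used throughout the package).
#' @param channel_map named list mapping role -> 0-based plane index.
#' @param pixel_size_um,name passed to [well_image()].
#' @return A [well_image()].
#' @export
read_well_image <- function(path, channel_map, pixel_size_um = 0.5,
                            name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  for (role in c("nuclei", "membrane"))
    if (is.null(channel_map[[role]]))
      stop(sprintf("missing required role '%s' in channel_map", role))
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- unlist(lapply(planes, split_plane_channels), recursive = FALSE)
  channels <- lapply(channel_map, function(i) {
    i <- as.integer(i)
    if (i < 0 || i >= length(planes))
      stop(sprintf("plane index %d out of range (file has %d planes)",
                   i, length(planes)))
    planes[[i + 1L]]
  })
  well_image(channels, pixel_size_um = pixel_size_um, name = name)
}

# A plane read by readTIFF may carry samples in a third array dim.
split_plane_channels <- function(p) {
  if (length(dim(p)) == 3L)
    lapply(seq_len(dim(p)[3]), function(k) p[, , k]) else list(p)
}

#' Write a well image to a multi-plane TIFF
#'
#' Channels are written as consecutive 16-bit planes in the order given by
#' `roles` (default: the image's own channel order); intensities are clipped
#' to `[0, 1]`. Round trips through [read_well_image()] are lossless at
#' 16-bit quantisation.
#'
#' @param image a [well_image()].
#' @param path output file.
#' @param roles channel roles to write, in plane order.
#' @return Invisibly, the named 0-based channel map of the written file.
#' @export
write_well_image <- function(image, path, roles = names(image$channels)) {
  stopifnot(inherits(image, "well_image"))
  planes <- lapply(roles, function(r) quantize16(get_channel(image, r)))
  tiff::writeTIFF(planes, path, bits.per.sample = 16)
  invisible(stats::setNames(as.list(seq_along(roles) - 1L), roles))
}

quantize16 <- function(m) round(pmin(pmax(m, 0), 1) * 65535) / 65535

#' Read / write 16-bit label masks
#'
#' Label masks are integer rasters with 0 = background and k > 0 = object k,
#' stored as 16-bit TIFF (wells with more than 65535 labelled objects are
#' rejected; real wells carry ~2000 candidates).
#'
#' @param path TIFF file.
#' @return `read_label_mask()`: an integer matrix.
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  m <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  lab <- round(m * 65535)
  storage.mode(lab) <- "integer"
  lab
}

#' @rdname read_label_mask
#' @param mask integer matrix of non-negative labels.
#' @export
write_label_mask <- function(mask, path) {
  mask <- as.matrix(mask)
  if (any(mask < 0)) stop("labels must be non-negative")
  if (max(mask) > 65535) stop("more than 65535 labels cannot be stored at 16 bit")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}
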