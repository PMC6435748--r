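#' Read an ImageJ polygon ROI set
#'
#' Ground-truth tracings are exchanged as ImageJ polygon ROIs, one ROI per
#' traced object. `path` may be a single `.roi` file, a directory of `.roi`
#' files, or a `.zip` archive of them (an ImageJ "RoiSet"). Only polygon
#' ROIs are accepted; any other ROI type is an error.
#'
#' Nucleus/sheath pairing is encoded in the ROI name: names start with
#' `cell<K>-`, where `K` is the integer cell id, followed by `nucleus` for
#' the nuclear outline or any other suffix (e.g. `ens1`) for an ensheathment
#' outline. Vertices are in image pixel coordinates, origin top-left,
#' x rightward, y downward, 0-based.
#'
#' @param path `.roi` file, directory, or `.zip` archive.
#' @return A tibble with columns `cell_id` (int), `kind`
#'   (`"nucleus"`/`"ensheathment"`), `name` (chr) and `polygon` (list of
#'   n x 2 matrices with columns `x`, `y`).
#' @export
read_roi_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("path not found: %s", path))
  files <-
    if (dir.exists(path)) {
      list.files(path, pattern = "\\.roi$", full.names = TRUE)
    } else if (grepl("\\.zip$", path, ignore.case = TRUE)) {
      ex <- tempfile("roiset")
      dir.create(ex)
      utils::unzip(path, exdir = ex)
      list.files(ex, pattern = "\\.roi$", full.names = TRUE, recursive = TRUE)
    } else path
  entries <- lapply(sort(files), read_imagej_roi)
  out <- dplyr::bind_rows(lapply(entries, function(e) {
    tibble::tibble(cell_id = e$cell_id, kind = e$kind, name = e$name,
                   polygon = list(e$polygon))
  }))
  if (nrow(out) == 0L)
    out <- tibble::tibble(cell_id = integer(), kind = character(),
                          name = character(), polygon = list())
  validate_roi_set(out)
  out
}

validate_roi_set <- function(rois) {
  if (nrow(rois) == 0L) return(invisible(rois))
  if (any(vapply(rois$polygon, nrow, 0L) < 3L))
    stop("polygons must have at least 3 vertices")
  nuc <- rois$cell_id[rois$kind == "nucleus"]
  if (anyDuplicated(nuc))
    stop("duplicate nucleus ROI for one cell_id")
  ens <- unique(rois$cell_id[rois$kind == "ensheathment"])
  orphan <- setdiff(ens, nuc)
  if (length(orphan))
    stop(sprintf("ensheathment ROI without matching nucleus for cell id(s): %s",
                 paste(orphan, collapse = ", ")))
  invisible(rois)
}

# Minimal ImageJ .roi record reader (big-endian; polygon type only).
read_imagej_roi <- function(file) {
  raw <- readBin(file, "raw", file.info(file)$size)
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop(sprintf("corrupt ROI record: %s", basename(file)))
  int16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                                 size = 2, endian = "big")
  int32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                                 size = 4, endian = "big")
  type <- as.integer(raw[7])
  if (type != 0L)
    stop(sprintf("non-polygon ROI type (%d) in %s", type, basename(file)))
  top <- int16(8); left <- int16(10)
  n <- int16(16)
  if (n < 3L || length(raw) < 64 + 4 * n)
    stop(sprintf("corrupt ROI record: %s", basename(file)))
  xs <- readBin(raw[65:(64 + 2 * n)], "integer", n = n, size = 2,
                endian = "big") + left
  ys <- readBin(raw[(65 + 2 * n):(64 + 4 * n)], "integer", n = n, size = 2,
                endian = "big") + top
  name <- roi_name(raw, int32)
  if (!nzchar(name)) name <- sub("\\.roi$", "", basename(file))
  info <- parse_roi_name(name)
  list(cell_id = info$cell_id, kind = info$kind, name = name,
       polygon = cbind(x = xs, y = ys))
}

roi_name <- function(raw, int32) {
  h2 <- int32(60)
  if (h2 <= 0 || h2 + 64 > length(raw)) return("")
  off <- int32(h2 + 16); len <- int32(h2 + 20)
  if (len <= 0 || off + 2 * len > length(raw)) return("")
  chars <- readBin(raw[(off + 1):(off + 2 * len)], "integer", n = len,
                   size = 2, endian = "big")
  intToUtf8(chars)
}

parse_roi_name <- function(name) {
  m <- regmatches(name, regexec("^cell([0-9]+)-(.*)$", name))[[1]]
  if (length(m) < 3)
    stop(sprintf("ROI name '%s' does not follow the 'cell<K>-...' convention",
                 name))
  list(cell_id = as.integer(m[2]),
       kind = if (grepl("^nuc", m[3])) "nucleus" else "ensheathment")
}

#' Write an ImageJ polygon ROI file
#'
#' Companion writer for [read_roi_set()]; emits one polygon `.roi` record
#' with the given name, so ROI round trips can be exercised without ImageJ.
#'
#' @param polygon n x 2 matrix of (x, y) vertices in pixel coordinates.
#' @param name ROI name (carries the `cell<K>-` pairing convention).
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_imagej_roi <- function(polygon, name, file) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3)
  xs <- as.integer(round(polygon[, 1])); ys <- as.integer(round(polygon[, 2]))
  left <- min(xs); top <- min(ys)
  n <- length(xs)
  con <- file(file, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "big")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "big")
  writeChar("Iout", con, 4, eos = NULL)
  w16(227)                              # version
  writeBin(as.raw(c(0, 0)), con)        # type = polygon, pad
  w16(c(top, left, max(ys), max(xs)))   # bounds
  w16(n)
  writeBin(raw(46), con)                # unused header fields
  hdr2 <- 64L + 4L * n
  seek(con, 60); w32(hdr2)
  seek(con, 64)
  w16(xs - left); w16(ys - top)
  writeBin(raw(64), con)                # header2 block
  name_off <- hdr2 + 64L
  seek(con, hdr2 + 16); w32(name_off); w32(nchar(name))
  seek(con, name_off)
  w16(utf8ToInt(name))
  invisible(file)
}

#' Rasterize a ROI set into paired label masks
#'
#' Each cell id becomes one label value, identical in both masks: the nuclei
#' mask holds the filled nucleus polygons, the sheath mask the union of that
#' cell's filled ensheathment polygons. Filling uses the even-odd rule
#' evaluated at pixel centers; pixels whose center lies exactly on a polygon
#' edge are included.
#'
#' @param rois tibble from [read_roi_set()].
#' @param shape `c(height, width)` of the target rasters.
#' @return list with integer matrices `nuclei` and `sheaths`.
#' @export
rasterize_rois <- function(rois, shape) {
  validate_roi_set(rois)
  shape <- as.integer(shape)
  nuclei <- matrix(0L, shape[1], shape[2])
  sheaths <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(nrow(rois))) {
    poly <- rois$polygon[[i]]
    if (any(poly[, 1] < 0 | poly[, 1] > shape[2] |
            poly[, 2] < 0 | poly[, 2] > shape[1]))
      stop(sprintf("ROI '%s' has out-of-bounds vertices", rois$name[i]))
    idx <- polygon_pixels(poly, shape)
    if (rois$kind[i] == "nucleus") nuclei[idx] <- rois$cell_id[i]
    else sheaths[idx] <- rois$cell_id[i]
  }
  list(nuclei = nuclei, sheaths = sheaths)
}

#' Pixels covered by a polygon
#'
#' Linear indices (into a `shape[1]` x `shape[2]` matrix) of pixels whose
#' center passes the even-odd point-in-polygon test; centers exactly on an
#' edge count as inside. Pixel `(row, col)` (1-based) has its center at
#' `(x, y) = (col - 0.5, row - 0.5)` in 0-based image coordinates.
#'
#' @param poly n x 2 matrix of (x, y) vertices.
#' @param shape `c(height, width)`.
#' @return Integer vector of linear indices.
#' @export
polygon_pixels <- function(poly, shape) {
  poly <- as.matrix(poly)
  rows <- max(1L, floor(min(poly[, 2]) + 0.5)):min(shape[1], ceiling(max(poly[, 2]) + 0.5))
  cols <- max(1L, floor(min(poly[, 1]) + 0.5)):min(shape[2], ceiling(max(poly[, 1]) + 0.5))
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  n <- nrow(poly)
  for (e in seq_len(n)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    x2 <- poly[e %% n + 1, 1]; y2 <- poly[e %% n + 1, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      flip <- px[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    # center exactly on the edge segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - x1) * dx + (py - y1) * dy) / len2
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      boundary <- boundary | (t >= 0 & t <= 1 & d2 < 1e-18)
    }
  }
  keep <- inside | boundary
  ri <- rep(rows, times = length(cols))[keep]
  ci <- rep(cols, each = length(rows))[keep]
  as.integer((ci - 1L) * shape[1] + ri)
}
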