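#' Candidate-detection parameters
#'
#' Controls nucleus detection and the membrane-blob filter that excludes
#' clearly non-ensheathing cells (no positively stained membrane near the
#' nucleus) before UNet inference.
#'
#' @param nucleus_min_area_um2 components smaller than this are discarded.
#' @param binarize_method `"otsu"` or `"fixed"`.
#' @param binarize_value threshold when `binarize_method = "fixed"`.
#' @param close_radius_um,open_radius_um radii of the morphological closing
#'   then opening that turn the binarized membrane image into blobs.
#' @param crop_size_px side of the (square) masked-nucleus crop; 256 px at
#'   0.5 µm/px gives a 128 µm field that comfortably contains one cell's
#'   arbor.
#' @param pixel_size_um µm per pixel.
#' @return A `candidate_params` list.
#' @export
candidate_params <- function(nucleus_min_area_um2 = 20,
                             binarize_method = c("otsu", "fixed"),
                             binarize_value = 0.5,
                             close_radius_um = 3, open_radius_um = 2,
                             crop_size_px = 256, pixel_size_um = 0.5) {
  binarize_method <- match.arg(binarize_method)
  stopifnot(nucleus_min_area_um2 > 0, close_radius_um > 0,
            open_radius_um > 0, crop_size_px %% 2 == 0, pixel_size_um > 0)
  structure(list(nucleus_min_area_um2 = nucleus_min_area_um2,
                 binarize_method = binarize_method,
                 binarize_value = binarize_value,
                 close_radius_um = close_radius_um,
                 open_radius_um = open_radius_um,
                 crop_size_px = as.integer(crop_size_px),
                 pixel_size_um = pixel_size_um),
            class = "candidate_params")
}

binarize <- function(raster, params) {
  thr <- if (params$binarize_method == "otsu")
    EBImage::otsu(EBImage::Image(pmin(raster, 1))) else params$binarize_value
  (raster > thr) + 0
}

#' Detect Hoechst-stained nuclei
#'
#' Binarize, distance-transform, watershed-split touching nuclei, and
#' discard components below `nucleus_min_area_um2`.
#'
#' @param nuclei_raster 2-D intensity matrix of the nuclear stain.
#' @param params a [candidate_params()].
#' @return Integer label mask (labels 1..n).
#' @export
detect_nuclei <- function(nuclei_raster, params = candidate_params()) {
  if (length(dim(nuclei_raster)) != 2L) stop("raster must be 2-D")
  bin <- binarize(nuclei_raster, params)
  if (!any(bin > 0)) return(matrix(0L, nrow(bin), ncol(bin)))
  bin <- EBImage::fillHull(bin)
  dt <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dt, tolerance = 1)
  min_px <- params$nucleus_min_area_um2 / params$pixel_size_um^2
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= min_px)
  out <- matrix(0L, nrow(bin), ncol(bin))
  relabel <- integer(length(counts))
  relabel[keep] <- seq_along(keep)
  sel <- lab > 0
  out[sel] <- relabel[lab[sel]]
  out
}

#' Filter candidate cells by membrane blobs
#'
#' The membrane raster is binarized, morphologically closed then opened
#' into blobs; nuclei whose centroid lies inside a blob are candidates for
#' quantification, the rest (no stained membrane near the nucleus) are
#' excluded to avoid analysing unstained cells.
#'
#' @param nuclei integer label mask from [detect_nuclei()].
#' @param membrane_raster 2-D intensity matrix.
#' @param params a [candidate_params()].
#' @return Tibble of candidates: `cell_id`, `centroid_y`, `centroid_x`
#'   (0-based px) and `nucleus_px` (list of linear indices).
#' @export
filter_candidates <- function(nuclei, membrane_raster,
                              params = candidate_params()) {
  stopifnot(all(dim(nuclei) == dim(membrane_raster)))
  cand <- nucleus_centroids(nuclei)
  cand$nucleus_px <- lapply(cand$cell_id, function(id) which(nuclei == id))
  if (nrow(cand) == 0) return(cand)
  bin <- binarize(membrane_raster, params)
  r_close <- max(1L, round(params$close_radius_um / params$pixel_size_um))
  r_open <- max(1L, round(params$open_radius_um / params$pixel_size_um))
  blobs <- EBImage::closing(bin, EBImage::makeBrush(2 * r_close + 1, "disc"))
  blobs <- EBImage::opening(blobs, EBImage::makeBrush(2 * r_open + 1, "disc"))
  blobs <- as.matrix(blobs)
  at <- cbind(round(cand$centroid_y) + 1, round(cand$centroid_x) + 1)
  cand[blobs[at] > 0, ]
}

#' Build one masked-nucleus input crop
#'
#' The UNet's unit input: a 3-channel square crop centered on a candidate
#' nucleus centroid, zero-padded at image borders. Channel 1 is the
#' membrane/myelin stain, channel 2 the binary mask of the nucleus of
#' interest (this cell only), channel 3 the full nuclear stain (other
#' nuclei remain visible there). The mask channel is what prompts the
#' network to segment only this cell's sheaths.
#'
#' @param image a [well_image()].
#' @param cand one-row tibble (or list) with `cell_id`, `centroid_y`,
#'   `centroid_x`, `nucleus_px`.
#' @param crop_size_px side of the square crop.
#' @return A `masked_input` list: `crop` (H x W x 3 array), `offset`
#'   (0-based `c(y, x)` of the crop's top-left in well coordinates),
#'   `cell_id`, `well`.
#' @export
build_masked_input <- function(image, cand, crop_size_px = 256) {
  stopifnot(inherits(image, "well_image"))
  npx <- if (is.list(cand$nucleus_px)) cand$nucleus_px[[1]] else cand$nucleus_px
  if (length(npx) == 0) stop("degenerate candidate: empty nucleus mask")
  d <- dim(image)
  nmask <- matrix(0, d[1], d[2]); nmask[npx] <- 1
  off <- c(round(cand$centroid_y) - crop_size_px / 2,
           round(cand$centroid_x) - crop_size_px / 2)   # 0-based top-left
  crop <- array(0, c(crop_size_px, crop_size_px, 3))
  crop[, , 1] <- crop_window(get_channel(image, "membrane"), off, crop_size_px)
  crop[, , 2] <- crop_window(nmask, off, crop_size_px)
  crop[, , 3] <- crop_window(get_channel(image, "nuclei"), off, crop_size_px)
  structure(list(crop = crop, offset = as.integer(off),
                 cell_id = cand$cell_id, well = image$name),
            class = "masked_input")
}

# Extract a crop with zero padding; off is the 0-based (y, x) of the top-left.
crop_window <- function(m, off, size) {
  out <- matrix(0, size, size)
  r0 <- off[1]; c0 <- off[2]
  rr <- max(0, r0):min(nrow(m) - 1, r0 + size - 1)
  cc <- max(0, c0):min(ncol(m) - 1, c0 + size - 1)
  if (length(rr) && length(cc) && max(rr) >= 0 && max(cc) >= 0)
    out[rr - r0 + 1, cc - c0 + 1] <- m[rr + 1, cc + 1]
  out
}

# Place a crop's values back into well coordinates (drops padded area).
uncrop_indices <- function(off, size, d) {
  rr <- (off[1]):(off[1] + size - 1); cc <- (off[2]):(off[2] + size - 1)
  ok_r <- rr >= 0 & rr < d[1]; ok_c <- cc >= 0 & cc < d[2]
  list(crop_r = which(ok_r), crop_c = which(ok_c),
       well_r = rr[ok_r] + 1, well_c = cc[ok_c] + 1)
}

#' Assemble a training set from traced ground truth
#'
#' One example per traced nucleus: the masked-nucleus input crop plus the
#' binary crop of that cell's sheath label over the same window. Cells
#' without sheaths yield all-zero truth crops (negative examples).
#'
#' @param image a [well_image()].
#' @param truth_nuclei,truth_sheaths paired integer label masks sharing
#'   cell labels (e.g. from [rasterize_rois()] or a phantom truth).
#' @param params a [candidate_params()] (uses `crop_size_px`).
#' @return List of examples: `x` (H x W x 3), `y` (H x W binary),
#'   `cell_id`, `offset`.
#' @export
build_training_set <- function(image, truth_nuclei, truth_sheaths,
                               params = candidate_params()) {
  stopifnot(all(dim(truth_nuclei) == dim(truth_sheaths)))
  sheath_ids <- unique(truth_sheaths[truth_sheaths > 0])
  orphan <- setdiff(sheath_ids, unique(truth_nuclei[truth_nuclei > 0]))
  if (length(orphan))
    stop("sheath labels without matching nucleus label: ",
         paste(orphan, collapse = ", "))
  cands <- nucleus_centroids(truth_nuclei)
  cands$nucleus_px <- lapply(cands$cell_id, function(id)
    which(truth_nuclei == id))
  lapply(seq_len(nrow(cands)), function(i) {
    mi <- build_masked_input(image, cands[i, ], params$crop_size_px)
    yfull <- (truth_sheaths == cands$cell_id[i]) + 0
    y <- crop_window(yfull, mi$offset, params$crop_size_px)
    list(x = mi$crop, y = y, cell_id = cands$cell_id[i], offset = mi$offset)
  })
}
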