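#' Heuristic segmentation parameters
#'
#' Tuning knobs of the two-stream heuristic engine. `ridge_sigma_px` sets
#' the scale of the Gaussian second-derivative filters and thereby the
#' diameter of fibers the ridge filter responds to; it defaults to the
#' 2 µm sheath thickness expressed in pixels (4 px at 0.5 µm/px).
#' `ridge_sensitivity` is the user-specified sensitivity of segmentation,
#' mapped to a score-quantile threshold (the top `ridge_sensitivity`
#' fraction of ridge scores is kept), which makes it robust to the absolute
#' intensity scale. `hmax_depth` suppresses shallow local maxima of the
#' distance transform before watershed splitting of touching cell bodies.
#' `association_gap_um` is the continuity tolerance: a segment is
#' associated with a cell body only if it approaches it at least this
#' closely (default: one sheath thickness).
#'
#' @param clahe_clip CLAHE clip fraction.
#' @param clahe_tile_px CLAHE tile size in px.
#' @param ridge_sigma_px Gaussian scale of the Hessian in px.
#' @param ridge_sensitivity in (0, 1]: fraction of top ridge scores kept.
#' @param hmax_depth depth (px) below which distance-transform maxima are
#'   suppressed when splitting touching cell bodies.
#' @param body_open_radius_um radius of the morphological opening that
#'   isolates soma-scale blobs from sheath-scale structures before the
#'   body watershed.
#' @param min_length_um,min_thickness_um manual-criterion floors (µm).
#' @param association_gap_um continuity tolerance (µm).
#' @param pixel_size_um µm per pixel.
#' @return A `heuristic_params` list.
#' @export
heuristic_params <- function(clahe_clip = 0.01, clahe_tile_px = 64,
                             ridge_sigma_px = NULL, ridge_sensitivity = 0.05,
                             hmax_depth = 2, body_open_radius_um = 2,
                             min_length_um = 12, min_thickness_um = 2,
                             association_gap_um = 2, pixel_size_um = 0.5) {
  if (is.null(ridge_sigma_px))
    ridge_sigma_px <- min_thickness_um / pixel_size_um
  p <- list(clahe_clip = clahe_clip, clahe_tile_px = as.integer(clahe_tile_px),
            ridge_sigma_px = ridge_sigma_px,
            ridge_sensitivity = ridge_sensitivity, hmax_depth = hmax_depth,
            body_open_radius_um = body_open_radius_um,
            min_length_um = min_length_um,
            min_thickness_um = min_thickness_um,
            association_gap_um = association_gap_um,
            pixel_size_um = pixel_size_um)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v > 0, TRUE)),
            ridge_sensitivity <= 1)
  structure(p, class = "heuristic_params")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Pre-processing contrast step applied to the membrane channel before both
#' analytic streams. Output is rescaled to `[0, 1]`.
#'
#' @param raster 2-D intensity matrix.
#' @param clip clip fraction (on the 0-1 histogram scale; internally scaled to the
#'   per-tile histogram limit).
#' @param tile_px tile size in pixels.
#' @return Equalized matrix in `[0, 1]`.
#' @export
clahe_enhance <- function(raster, clip = 0.01, tile_px = 64) {
  if (length(dim(raster)) != 2L) stop("raster must be 2-D")
  rng <- range(raster)
  x <- if (diff(rng) > 0) (raster - rng[1]) / diff(rng) else raster - rng[1]
  nx <- max(2L, round(nrow(x) / tile_px))
  ny <- max(2L, round(ncol(x) / tile_px))
  out <- EBImage::clahe(x, nx = nx, ny = ny, bins = 256,
                        limit = max(clip * 256, 0.01))
  out <- as.matrix(out)
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

# Gaussian-derivative Hessian components at scale sigma, gamma-normalized.
hessian_at_scale <- function(raster, sigma) {
  half <- ceiling(4 * sigma)
  if (2 * half + 1 > min(dim(raster)))
    stop("sigma too large: derivative kernel exceeds the image")
  u <- (-half):half
  g <- exp(-u^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -u / sigma^2 * g
  g2 <- (u^2 - sigma^2) / sigma^4 * g
  k_xx <- outer(g, g2)    # second derivative across columns (x)
  k_yy <- outer(g2, g)
  k_xy <- outer(g1, g1)
  s2 <- sigma^2           # scale normalization
  list(xx = s2 * as.matrix(EBImage::filter2(raster, k_xx, boundary = "replicate")),
       yy = s2 * as.matrix(EBImage::filter2(raster, k_yy, boundary = "replicate")),
       xy = s2 * as.matrix(EBImage::filter2(raster, k_xy, boundary = "replicate")))
}

#' Ridge-likeness score from Hessian eigenvalues
#'
#' Eigenvalues of the scale-normalized Hessian are sorted by magnitude,
#' `|lambda1| <= |lambda2|`. Bright ridges require strong negative
#' curvature across the ridge (`lambda2 < 0`) and weak curvature along it;
#' the score is `|lambda2| * (1 - |lambda1| / |lambda2|)`, zero elsewhere.
#'
#' @param raster 2-D intensity matrix (typically CLAHE-enhanced).
#' @param sigma Gaussian scale in px; bars of width ~`sigma` respond
#'   maximally.
#' @return Matrix of non-negative ridge scores.
#' @export
ridge_score <- function(raster, sigma) {
  h <- hessian_at_scale(raster, sigma)
  tr <- h$xx + h$yy
  disc <- sqrt(((h$xx - h$yy) / 2)^2 + h$xy^2)
  e1 <- tr / 2 + disc; e2 <- tr / 2 - disc
  swap <- abs(e1) > abs(e2)
  lam1 <- ifelse(swap, e2, e1)   # smaller magnitude
  lam2 <- ifelse(swap, e1, e2)   # larger magnitude
  score <- ifelse(lam2 < 0, abs(lam2) * (1 - abs(lam1) / pmax(abs(lam2), 1e-12)), 0)
  score[score < 0] <- 0
  score
}

#' Ridge filter: segment bright elongated fiber structures
#'
#' Thresholds the [ridge_score()] map at its `1 - sensitivity` quantile, so
#' the top `sensitivity` fraction of scores is kept (zero-score pixels are
#' never kept).
#'
#' @param raster 2-D matrix.
#' @param sigma Gaussian scale in px.
#' @param sensitivity fraction in (0, 1].
#' @return Binary integer matrix.
#' @export
ridge_filter <- function(raster, sigma = 4, sensitivity = 0.05) {
  score <- ridge_score(raster, sigma)
  thr <- stats::quantile(score, 1 - sensitivity, names = FALSE)
  (score > 0 & score >= thr) + 0L
}

#' Estimate cell bodies by distance-transform watershed
#'
#' The membrane raster is binarized (Otsu), opened at soma scale to strip
#' sheath-width structures, and split by a watershed of the distance
#' transform whose shallow maxima (depth < `hmax_depth`) are suppressed —
#' the imposed-local-maxima step that separates crowded, touching cell
#' bodies. Regions are kept only where they colocalize with a detected
#' nucleus; regions containing several nuclei are split between them by
#' geodesic propagation, so the result has exactly one body label per
#' colocalized nucleus, labelled by that nucleus.
#'
#' @param membrane_raster 2-D intensity matrix.
#' @param nuclei integer label mask of detected nuclei.
#' @param params a [heuristic_params()].
#' @return Integer label mask of cell bodies (labels = nucleus labels).
#' @export
segment_cell_bodies <- function(membrane_raster, nuclei,
                                params = heuristic_params()) {
  stopifnot(all(dim(membrane_raster) == dim(nuclei)))
  if (!any(nuclei > 0)) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  thr <- EBImage::otsu(EBImage::Image(membrane_raster))
  bin <- (membrane_raster > thr) + 0
  r_open <- max(1L, round(params$body_open_radius_um / params$pixel_size_um))
  blobs <- EBImage::opening(bin, EBImage::makeBrush(2 * r_open + 1, "disc"))
  if (!any(blobs > 0)) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  dt <- EBImage::distmap(blobs)
  regions <- EBImage::watershed(dt, tolerance = params$hmax_depth)
  seeds <- nuclei * (blobs > 0)
  kept_regions <- unique(regions[seeds > 0])
  kept_regions <- kept_regions[kept_regions > 0]
  mask <- matrix(0, nrow(nuclei), ncol(nuclei))
  mask[regions %in% kept_regions] <- 1
  if (!any(seeds > 0)) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  bodies <- EBImage::propagate(matrix(0, nrow(nuclei), ncol(nuclei)),
                               seeds = seeds, mask = mask)
  out <- as.matrix(EBImage::imageData(bodies))
  storage.mode(out) <- "integer"
  out
}

#' Subtract cell bodies from the ridge mask
#'
#' @param ridge_mask binary matrix from [ridge_filter()].
#' @param bodies label mask from [segment_cell_bodies()].
#' @return Binary matrix: `ridge_mask & !(bodies > 0)`.
#' @export
subtract_cell_bodies <- function(ridge_mask, bodies) {
  if (!all(dim(ridge_mask) == dim(bodies))) stop("shape mismatch")
  (ridge_mask > 0 & !(bodies > 0)) + 0L
}

#' Associate subtracted segments with cell bodies by continuity
#'
#' Each connected segment is assigned to a cell body iff it approaches that
#' body within `association_gap_um`; when several bodies qualify, the
#' nearest wins. A segment is never assigned to more than one cell;
#' segments approaching no body are dropped.
#'
#' @param segments integer label mask of segments (8-connected components).
#' @param bodies integer label mask of bodies.
#' @param params a [heuristic_params()].
#' @return Tibble with columns `segment` and `cell_id`.
#' @export
associate_segments <- function(segments, bodies,
                               params = heuristic_params()) {
  empty <- tibble::tibble(segment = integer(), cell_id = integer())
  seg_ids <- sort(unique(segments[segments > 0]))
  if (!length(seg_ids) || !any(bodies > 0)) return(empty)
  gap_px <- params$association_gap_um / params$pixel_size_um
  d_body <- as.matrix(EBImage::distmap(1 - (bodies > 0)))
  vor <- as.matrix(EBImage::propagate(matrix(0, nrow(bodies), ncol(bodies)),
                                      seeds = bodies))
  res <- lapply(seg_ids, function(s) {
    px <- which(segments == s)
    dmin <- min(d_body[px])
    if (dmin > gap_px) return(NULL)
    at <- px[which.min(d_body[px])]
    tibble::tibble(segment = as.integer(s), cell_id = as.integer(vor[at]))
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) empty else out
}

#' Run the two-stream heuristic segmentation engine
#'
#' Composes the full pipeline: CLAHE enhancement of the membrane channel;
#' (stream 1) ridge-filter extraction of ensheathed fiber segments;
#' (stream 2) nucleus detection and watershed cell-body estimation;
#' subtraction of the bodies from the ridge mask; continuity-based
#' association of the remaining segments with cells; and the two-pass
#' minimum-length filter. Deterministic given its inputs.
#'
#' @param image a [well_image()] with `nuclei` and `membrane` channels.
#' @param params a [heuristic_params()].
#' @param cand_params a [candidate_params()] for nucleus detection.
#' @param post a [post_params()]; defaults mirror `params`.
#' @return A [sheath_records()] table; the `cells` attribute lists all
#'   detected nuclei with centroids.
#' @export
run_heuristic <- function(image, params = heuristic_params(),
                          cand_params = candidate_params(
                            pixel_size_um = params$pixel_size_um),
                          post = post_params(
                            min_length_um = params$min_length_um,
                            pixel_size_um = params$pixel_size_um)) {
  stopifnot(inherits(image, "well_image"))
  mem <- clahe_enhance(get_channel(image, "membrane"),
                       clip = params$clahe_clip,
                       tile_px = params$clahe_tile_px)
  nuclei <- detect_nuclei(get_channel(image, "nuclei"), cand_params)
  ridge <- ridge_filter(mem, sigma = params$ridge_sigma_px,
                        sensitivity = params$ridge_sensitivity)
  bodies <- segment_cell_bodies(mem, nuclei, params)
  sub <- subtract_cell_bodies(ridge, bodies)
  segments <- label8(sub)
  assoc <- associate_segments(segments, bodies, params)
  d <- dim(sub)
  cells <- nucleus_centroids(nuclei)
  rows <- lapply(seq_len(nrow(assoc)), function(i)
    tibble::tibble(cell_id = assoc$cell_id[i],
                   px = list(which(segments == assoc$segment[i]))))
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0)
    tbl <- tibble::tibble(cell_id = integer(), px = list())
  tbl <- dplyr::arrange(tbl, .data$cell_id)
  tbl <- dplyr::group_by(tbl, .data$cell_id)
  tbl <- dplyr::mutate(tbl, sheath_id = dplyr::row_number())
  tbl <- dplyr::ungroup(tbl)
  rec <- sheath_records(tbl, d, image$pixel_size_um, cells = cells)
  filter_by_length(rec, post)
}

nucleus_centroids <- function(nuclei) {
  ids <- sort(unique(nuclei[nuclei > 0]))
  if (!length(ids))
    return(tibble::tibble(cell_id = integer(), centroid_y = numeric(),
                          centroid_x = numeric()))
  rs <- row(nuclei)[nuclei > 0] - 1; cs <- col(nuclei)[nuclei > 0] - 1
  lb <- nuclei[nuclei > 0]
  tibble::tibble(cell_id = as.integer(ids),
                 centroid_y = as.numeric(tapply(rs, lb, mean)),
                 centroid_x = as.numeric(tapply(cs, lb, mean)))
}
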