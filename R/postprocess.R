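#' Post-processing parameters
#'
#' Controls the three post-inference operators applied to per-cell sheath
#' masks: unfair distribution of ambiguously shared sheaths, skeleton-based
#' removal of sticky cross-fiber bridges, and the two-pass minimum-length
#' filter (with a stricter threshold for cells left with only one or two
#' sheaths, damping false positives from weakly ensheathing cells).
#'
#' @param min_length_um minimum sheath length (µm); the manual criterion
#'   uses ~12 µm.
#' @param strict_multiplier multiplier (in `[1, 4]`, conventionally 3-4)
#'   applied to `min_length_um` for cells with 1-2 surviving sheaths.
#' @param fiber_axis `"vertical"` or `"horizontal"`; branches running
#'   across this axis are "sticky" bridges.
#' @param pixel_size_um µm per pixel.
#' @return A `post_params` list.
#' @export
post_params <- function(min_length_um = 12, strict_multiplier = 3,
                        fiber_axis = c("vertical", "horizontal"),
                        pixel_size_um = 0.5) {
  fiber_axis <- match.arg(fiber_axis)
  stopifnot(min_length_um > 0, strict_multiplier >= 1, pixel_size_um > 0)
  structure(list(min_length_um = min_length_um,
                 strict_multiplier = strict_multiplier,
                 fiber_axis = fiber_axis, pixel_size_um = pixel_size_um),
            class = "post_params")
}

#' Sheath records table
#'
#' The common tabular currency of the segmentation engines: one row per
#' sheath, with the owning `cell_id`, a `px` list-column of 1-based linear
#' pixel indices into the well raster, and derived morphometrics. Carries
#' the raster shape, pixel size, and the per-cell candidate table
#' (`cell_id`, `centroid_y`, `centroid_x`, 0-based) as attributes.
#'
#' @param tbl tibble with at least `cell_id` and `px`.
#' @param dim `c(height, width)` of the parent raster.
#' @param pixel_size_um µm per pixel.
#' @param cells tibble of candidate cells (may include cells with no rows
#'   in `tbl`, i.e. detected but non-ensheathing candidates).
#' @return A `sheath_records` tibble.
#' @export
sheath_records <- function(tbl, dim, pixel_size_um, cells = NULL) {
  tbl <- tibble::as_tibble(tbl)
  if (is.null(tbl[["length_um"]]))
    tbl$length_um <- vapply(tbl$px, measure_length, 0,
                            dim = dim, pixel_size_um = pixel_size_um)
  if (is.null(tbl[["area_px"]])) tbl$area_px <- lengths(tbl$px)
  structure(tbl, raster_dim = as.integer(dim), pixel_size_um = pixel_size_um,
            cells = cells,
            class = c("sheath_records", class(tibble::tibble())))
}

#' @export
print.sheath_records <- function(x, ...) {
  d <- attr(x, "raster_dim")
  cat(sprintf("<sheath_records> %d sheaths / %d cells on %d x %d px raster\n",
              nrow(x), length(unique(x$cell_id)), d[1], d[2]))
  NextMethod()
}

sheath_dim <- function(records) {
  d <- attr(records, "raster_dim")
  if (is.null(d)) stop("sheath_records lost its raster dim attribute")
  d
}

#' Binary raster from pixel indices
#'
#' @param px integer vector of 1-based linear indices.
#' @param dim `c(height, width)`.
#' @return Integer 0/1 matrix.
#' @export
px_to_mask <- function(px, dim) {
  m <- matrix(0L, dim[1], dim[2])
  m[px] <- 1L
  m
}

#' Resolve sheaths claimed by several cells ("unfair distribution")
#'
#' Any connected sheath component claimed by two or more cells is assigned
#' wholly to the claimant with the larger total sheath pixel area — the
#' working assumption being that a shared segment more plausibly belongs to
#' a large cell with multiple ensheathments than to a small cell with a
#' single one. Exact area ties go to the lower `cell_id`. The result is
#' independent of row order, and output masks are pairwise disjoint across
#' cells.
#'
#' @param records a [sheath_records()] table (overlaps permitted).
#' @return A [sheath_records()] table with pairwise-disjoint per-cell masks.
#' @export
resolve_overlaps <- function(records) {
  d <- sheath_dim(records)
  if (nrow(records) == 0) return(records)
  records <- dplyr::arrange(records, .data$cell_id)
  union_mask <- matrix(0L, d[1], d[2])
  union_mask[unlist(records$px)] <- 1L
  comp <- label8(union_mask)
  comp_of <- lapply(records$px, function(p) unique(comp[p]))
  area_by_cell <- tapply(lengths(records$px), records$cell_id, sum)

  out_px <- records$px
  keep <- rep(TRUE, nrow(records))
  all_comps <- sort(unique(unlist(comp_of)))
  for (cid in all_comps) {
    rows <- which(vapply(comp_of, function(cc) cid %in% cc, TRUE))
    claimants <- unique(records$cell_id[rows])
    if (length(claimants) < 2) next
    areas <- area_by_cell[as.character(claimants)]
    winner <- claimants[areas == max(areas)]
    winner <- min(winner)                     # tie -> lower cell_id
    comp_px <- which(comp == cid)
    first_winner_row <- rows[records$cell_id[rows] == winner][1]
    for (r in rows) {
      if (records$cell_id[r] == winner && r == first_winner_row) {
        out_px[[r]] <- sort(unique(c(setdiff(out_px[[r]], comp_px), comp_px)))
      } else {
        out_px[[r]] <- setdiff(out_px[[r]], comp_px)
        if (length(out_px[[r]]) == 0) keep[r] <- FALSE
      }
    }
  }
  res <- records
  res$px <- out_px
  res <- res[keep, ]
  # canonical row order (cell, then first pixel) so the result is literally
  # independent of the input row order
  res <- res[order(res$cell_id, vapply(res$px, min, 0L)), ]
  res$length_um <- vapply(res$px, measure_length, 0, dim = d,
                          pixel_size_um = attr(records, "pixel_size_um"))
  res$area_px <- lengths(res$px)
  res <- dplyr::group_by(res, .data$cell_id)
  res <- dplyr::mutate(res, sheath_id = dplyr::row_number())
  res <- dplyr::ungroup(res)
  sheath_records(res, d, attr(records, "pixel_size_um"),
                 cells = attr(records, "cells"))
}

#' Remove sticky cross-fiber bridges from a sheath mask
#'
#' Adjacent sheaths on neighbouring fibers are sometimes fused by a short
#' bridge of signal ("sticky connection") into a single object. The mask is
#' skeletonized (Zhang-Suen thinning); branch points are removed; each
#' remaining skeletal branch is classified as cross-fiber when its extent
#' perpendicular to `fiber_axis` exceeds its extent along it (a 45-degree
#' dividing line); cross-fiber branches are deleted; branch points
#' re-connecting two or more retained along-fiber branches are re-inserted;
#' finally each original mask pixel is kept iff its nearest skeleton pixel
#' (Euclidean; ties kept) belongs to a retained branch.
#'
#' @param mask binary matrix (one cell's sheath mask, or any binary raster).
#' @param params a [post_params()].
#' @return Binary matrix, a subset of `mask`.
#' @export
remove_sticky <- function(mask, params = post_params()) {
  mask <- (as.matrix(mask) > 0) + 0L
  if (!any(mask > 0)) return(mask)
  work <- if (params$fiber_axis == "horizontal") t(mask) else mask
  skel <- thin_zhang_suen(work)
  # junctions via the crossing number (simple arcs score 2, junctions >= 3);
  # a plain neighbour count misfires on the staircase skeletons of oblique bars
  xn <- crossing_number8(skel)
  core <- (skel == 1L & xn >= 3L) + 0L
  # include the junction's skeletal 8-neighbourhood: removing only the
  # junction pixel leaves its arms diagonally connected around it
  branch_pts <- skel == 1L & (core == 1L | neighbour_count8(core) > 0L)
  branches <- label8((skel == 1L & !branch_pts) + 0L)
  n_br <- max(branches)
  if (n_br == 0) {
    out <- work
  } else {
    keep_branch <- logical(n_br)
    rs <- row(branches)[branches > 0]; cs <- col(branches)[branches > 0]
    lb <- branches[branches > 0]
    rspan <- tapply(rs, lb, function(v) diff(range(v)))
    cspan <- tapply(cs, lb, function(v) diff(range(v)))
    keep_branch[as.integer(names(rspan))] <- rspan >= cspan
    retained <- matrix(0L, nrow(work), ncol(work))
    retained[branches > 0 & keep_branch[pmax(branches, 1L)]] <- 1L
    # re-insert branch-point clusters that reconnect >= 2 retained branches
    clus <- label8(branch_pts + 0L)
    for (k in seq_len(max(clus))) {
      cpx <- which(clus == k)
      touched <- integer(0)
      for (i in cpx) {
        r <- (i - 1L) %% nrow(work) + 1L; c <- (i - 1L) %/% nrow(work) + 1L
        rr <- max(1, r - 1):min(nrow(work), r + 1)
        cc <- max(1, c - 1):min(ncol(work), c + 1)
        nbl <- branches[rr, cc]
        touched <- c(touched, nbl[nbl > 0])
      }
      touched <- unique(touched)
      touched <- touched[keep_branch[touched]]
      if (length(touched) >= 2) retained[cpx] <- 1L
    }
    deleted <- (skel == 1L) & (retained == 0L)
    if (!any(deleted)) {
      out <- work
    } else if (!any(retained == 1L)) {
      out <- matrix(0L, nrow(work), ncol(work))
    } else {
      d_ret <- EBImage::distmap(1 - retained)
      d_del <- EBImage::distmap(1 - (deleted + 0L))
      out <- work
      out[!(d_ret <= d_del)] <- 0L
    }
  }
  if (params$fiber_axis == "horizontal") t(out) else out
}

#' Sheath length from second moments
#'
#' Length of a pixel set as the major axis of its second-moment-matched
#' shape, scaled to µm. The default `"rect"` convention calibrates to an
#' equivalent rectangle (`sqrt(12) * sigma_major`), which returns the exact
#' end-to-end length for straight bars — the geometry of nanofiber
#' ensheathments; `"ellipse"` gives the classical regionprops ellipse major
#' axis (`4 * sigma_major`, = 2/sqrt(3) times larger). A 1/12 px^2 term is
#' added to each coordinate variance so a single pixel has unit extent.
#'
#' @param px 1-based linear pixel indices (non-empty).
#' @param dim `c(height, width)` of the parent raster.
#' @param pixel_size_um µm per pixel.
#' @param convention `"rect"` or `"ellipse"`.
#' @return Length in µm.
#' @export
measure_length <- function(px, dim, pixel_size_um = 0.5,
                           convention = c("rect", "ellipse")) {
  convention <- match.arg(convention)
  if (length(px) == 0) stop("cannot measure an empty pixel set")
  r <- (px - 1) %% dim[1]; c <- (px - 1) %/% dim[1]
  n <- length(px)
  vr <- sum((r - mean(r))^2) / n + 1 / 12
  vc <- sum((c - mean(c))^2) / n + 1 / 12
  vrc <- sum((r - mean(r)) * (c - mean(c))) / n
  lam <- (vr + vc) / 2 + sqrt(((vr - vc) / 2)^2 + vrc^2)
  f <- if (convention == "rect") sqrt(12) else 4
  f * sqrt(lam) * pixel_size_um
}

#' Two-pass minimum-length filter
#'
#' First pass: sheaths shorter than `min_length_um` are dropped. Second
#' pass: cells left with one or two sheaths must clear
#' `strict_multiplier * min_length_um` — the stricter criterion for
#' single/doubly-ensheathing cells that damps the false positives human
#' non-experts are prone to. Cells with no surviving sheath are
#' non-ensheathing. The operation is idempotent and its output is always a
#' subset of its input.
#'
#' @param records a [sheath_records()] table with computed lengths.
#' @param params a [post_params()].
#' @return Filtered [sheath_records()].
#' @export
filter_by_length <- function(records, params = post_params()) {
  d <- sheath_dim(records)
  res <- dplyr::filter(records, .data$length_um >= params$min_length_um)
  res <- dplyr::group_by(res, .data$cell_id)
  res <- dplyr::filter(res, dplyr::n() > 2 |
    .data$length_um >= params$strict_multiplier * params$min_length_um)
  res <- dplyr::ungroup(res)
  sheath_records(res, d, attr(records, "pixel_size_um"),
                 cells = attr(records, "cells"))
}

#' Apply the full post-processing chain
#'
#' Unfair distribution, per-cell sticky removal, then the two-pass length
#' filter, in that order (overlap resolution precedes sticky removal so the
#' skeleton operates on single-owner masks).
#'
#' @param records a [sheath_records()] table.
#' @param params a [post_params()].
#' @return Post-processed [sheath_records()].
#' @export
postprocess_records <- function(records, params = post_params()) {
  d <- sheath_dim(records)
  res <- resolve_overlaps(records)
  if (nrow(res)) {
    rows <- vector("list", 0)
    for (cid in unique(res$cell_id)) {
      sub <- res[res$cell_id == cid, ]
      mask <- px_to_mask(unlist(sub$px), d)
      cleaned <- remove_sticky(mask, params)
      comp <- label8(cleaned)
      for (k in seq_len(max(comp)))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cell_id = cid, sheath_id = k, px = list(which(comp == k)))
    }
    res <- dplyr::bind_rows(rows)
  }
  res <- sheath_records(res, d, attr(records, "pixel_size_um"),
                        cells = attr(records, "cells"))
  filter_by_length(res, params)
}
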