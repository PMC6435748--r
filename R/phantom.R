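#' Phantom specification
#'
#' Parameters of the synthetic nanofiber-culture phantom. The phantom
#' emulates the geometry the segmentation engines are built for: parallel
#' nanofibers at fixed spacing, oligodendrocyte somata with Hoechst-stained
#' nuclei, and bright myelin-like sheath bars of ~2 µm thickness running
#' along fibers, with log-normally distributed lengths truncated below at
#' the 12 µm manual-classification floor. Every rendered structure has exact
#' per-cell ground truth, so the phantom serves as the oracle for the whole
#' pipeline.
#'
#' Defaults encode the study geometry: 0.5 µm pixels, 2 µm sheath thickness,
#' log10-length standard deviation 0.29 (back-derived from the published
#' power statement via [derive_log_length_sd()]). `log10_length_mean = 1.7`
#' (~50 µm typical sheath) keeps the 12 µm floor in the far tail so the
#' length distribution is only mildly truncated. Ensheathing cells draw
#' `1 + Poisson(sheaths_per_cell_mean - 1)` sheaths, capped by the number of
#' fiber slots reachable from the soma. Non-ensheathing cells are rendered
#' unstained (nucleus only), matching the cells the candidate filter is
#' meant to exclude.
#'
#' @param height_px,width_px image size in pixels.
#' @param pixel_size_um µm per pixel.
#' @param fiber_spacing_um spacing of the parallel nanofibers.
#' @param fiber_axis `"vertical"` or `"horizontal"`.
#' @param n_cells total number of cells placed.
#' @param p_ensheathing probability a cell is ensheathing (stained).
#' @param sheaths_per_cell_mean mean sheath count of ensheathing cells.
#' @param log10_length_mean,log10_length_sd parameters of the log10 µm
#'   length distribution (before the 12 µm floor).
#' @param sheath_thickness_um rendered sheath bar thickness.
#' @param nucleus_radius_um,soma_radius_um nuclear and cell-body radii (the
#'   "soma" disc stands for the soma plus proximal arbor that contacts the
#'   fibers it ensheathes).
#' @param background_level,noise_sd flat background level and additive
#'   Gaussian noise SD (intensity units, images scaled to `[0, 1]`).
#' @param crowding in `[0, 1]`: fraction of ensheathing cells that
#'   participate in a deliberately overlapped sheath pair (the ground truth
#'   records each constructed overlap and its rightful owner, so
#'   unfair-distribution tests have known answers).
#' @param seed RNG seed; generation is bit-reproducible for a fixed spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(height_px = 1024, width_px = 1024,
                         pixel_size_um = 0.5, fiber_spacing_um = 8,
                         fiber_axis = c("vertical", "horizontal"),
                         n_cells = 20, p_ensheathing = 0.7,
                         sheaths_per_cell_mean = 5,
                         log10_length_mean = 1.7, log10_length_sd = 0.29,
                         sheath_thickness_um = 2,
                         nucleus_radius_um = 5, soma_radius_um = 20,
                         background_level = 0.08, noise_sd = 0.02,
                         crowding = 0, seed = 1) {
  fiber_axis <- match.arg(fiber_axis)
  spec <- list(height_px = as.integer(height_px),
               width_px = as.integer(width_px),
               pixel_size_um = pixel_size_um,
               fiber_spacing_um = fiber_spacing_um, fiber_axis = fiber_axis,
               n_cells = as.integer(n_cells), p_ensheathing = p_ensheathing,
               sheaths_per_cell_mean = sheaths_per_cell_mean,
               log10_length_mean = log10_length_mean,
               log10_length_sd = log10_length_sd,
               sheath_thickness_um = sheath_thickness_um,
               nucleus_radius_um = nucleus_radius_um,
               soma_radius_um = soma_radius_um,
               background_level = background_level, noise_sd = noise_sd,
               crowding = crowding, seed = as.integer(seed))
  sizes <- c("height_px", "width_px", "pixel_size_um", "fiber_spacing_um",
             "sheath_thickness_um", "nucleus_radius_um", "soma_radius_um",
             "log10_length_sd")
  for (f in sizes) if (spec[[f]] <= 0) stop(sprintf("%s must be positive", f))
  for (f in c("p_ensheathing", "crowding"))
    if (spec[[f]] < 0 || spec[[f]] > 1) stop(sprintf("%s must be in [0, 1]", f))
  if (spec$sheaths_per_cell_mean < 1)
    stop("sheaths_per_cell_mean must be >= 1")
  if (spec$n_cells < 0) stop("n_cells must be >= 0")
  structure(spec, class = "phantom_spec")
}

# µm floor below which an elongated segment does not count as a sheath.
MIN_SHEATH_LENGTH_UM <- 12

#' Moments of the phantom's truncated log10 length distribution
#'
#' Sheath lengths are drawn from Normal(`log10_length_mean`,
#' `log10_length_sd`) on the log10 µm scale, truncated below at
#' log10(12 µm). This returns the closed-form mean and SD of that truncated
#' normal — the correct comparison target for parameter-recovery checks
#' (comparing to the untruncated mean would be biased by the floor).
#'
#' @param spec a [phantom_spec()].
#' @return Named list with `mean` and `sd` of truncated log10 lengths.
#' @export
phantom_log_length_moments <- function(spec) {
  mu <- spec$log10_length_mean; sigma <- spec$log10_length_sd
  a <- (log10(MIN_SHEATH_LENGTH_UM) - mu) / sigma
  lambda <- stats::dnorm(a) / (1 - stats::pnorm(a))
  delta <- lambda * (lambda - a)
  list(mean = mu + sigma * lambda, sd = sigma * sqrt(1 - delta))
}

#' Generate a synthetic nanofiber-culture phantom
#'
#' Renders a [well_image()] (nuclei, membrane and brightfield channels) plus
#' exact ground truth. Fibers are parallel lines along `fiber_axis`; each
#' ensheathing cell's sheaths are bars centered on fibers reachable from its
#' soma, with one end inside the soma disc (so continuity with the cell body
#' holds by construction). Placement is rejection-sampled so that with
#' `crowding = 0` all cells' structures are pairwise disjoint; with
#' `crowding > 0`, sheath-tip overlaps between designated cell pairs are
#' constructed deliberately and recorded in the truth.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` (a [well_image()]) and `truth`, a
#'   `phantom_truth` object: integer label masks `nuclei` and `sheaths`
#'   (sheath label = owning cell label), a `cells` tibble (`cell_id`,
#'   `centroid_y`, `centroid_x` in 0-based pixels, `ensheathing`), a
#'   `sheaths_tbl` tibble (`cell_id`, `sheath_id`, `length_um`, plus bar
#'   geometry), and an `overlaps` tibble (`cell_a`, `cell_b`, `owner`,
#'   `px` list of overlap pixel indices).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  # generate in vertical-fiber frame; transpose at the end if horizontal
  H <- spec$height_px; W <- spec$width_px
  if (spec$fiber_axis == "horizontal") { tmp <- H; H <- W; W <- tmp }
  px <- spec$pixel_size_um
  r_soma <- round(spec$soma_radius_um / px)
  r_nuc <- round(spec$nucleus_radius_um / px)
  w_half <- max(1L, round(spec$sheath_thickness_um / px / 2))
  sp_px <- spec$fiber_spacing_um / px
  fibers <- seq(sp_px / 2, W - 1, by = sp_px)   # 0-based x of fiber centers
  if (2 * r_soma + 2 >= min(H, W))
    stop("geometry impossible: soma larger than the image")

  geo <- place_phantom_cells(spec, H, W, fibers, r_soma, r_nuc, w_half)

  img <- render_phantom(spec, geo, H, W, fibers, r_soma, r_nuc, w_half)
  truth <- phantom_truth_from_geometry(spec, geo, H, W)

  if (spec$fiber_axis == "horizontal") {
    img$channels <- lapply(img$channels, t)
    truth$nuclei <- t(truth$nuclei)
    truth$sheaths <- t(truth$sheaths)
    d <- c(spec$height_px, spec$width_px)
    truth$overlaps$px <- lapply(truth$overlaps$px, transpose_indices,
                                from = c(W, H))
    cells <- truth$cells
    truth$cells$centroid_y <- cells$centroid_x
    truth$cells$centroid_x <- cells$centroid_y
  }
  list(image = img, truth = truth)
}

transpose_indices <- function(idx, from) {
  r <- (idx - 1L) %% from[1]; c <- (idx - 1L) %/% from[1]
  as.integer(r * from[2] + c + 1L)
}

# ---- internal geometry -----------------------------------------------------

draw_length_px <- function(n, spec) {
  lo <- log10(MIN_SHEATH_LENGTH_UM)
  out <- numeric(0)
  while (length(out) < n) {
    l <- stats::rnorm(n, spec$log10_length_mean, spec$log10_length_sd)
    out <- c(out, l[l >= lo])
  }
  pmax(2L, as.integer(round(10^out[seq_len(n)] / spec$pixel_size_um)))
}

# Slots (fiber, direction) reachable from a soma centered at 0-based (cy, cx),
# ordered nearest fiber first.
soma_slots <- function(cx, fibers, r_soma, w_half) {
  dx <- fibers - cx
  ok <- abs(dx) <= r_soma - w_half - 2
  f <- fibers[ok][order(abs(dx[ok]))]
  if (!length(f)) return(NULL)
  data.frame(fiber_x = rep(f, each = 2), dir = rep(c(-1L, 1L), length(f)))
}

# Pixel indices (1-based linear, H x W) of a bar and a disc.
bar_px <- function(rows, fiber_x, w_half, H, W) {
  cols <- (round(fiber_x) - w_half + 1):(round(fiber_x) + w_half)  # 0-based
  cols <- cols[cols >= 0 & cols < W]
  rows <- rows[rows >= 0 & rows < H]
  as.integer(outer(rows + 1L, cols * H, `+`))
}

disc_px <- function(cy, cx, r, H, W) {
  rr <- max(0, floor(cy - r)):min(H - 1, ceiling(cy + r))
  cc <- max(0, floor(cx - r)):min(W - 1, ceiling(cx + r))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - cy)^2 + (g$c - cx)^2 <= r^2
  as.integer(g$c[keep] * H + g$r[keep] + 1L)
}

expand_px <- function(idx, H, W, margin = 2L) {
  r <- (idx - 1L) %% H; c <- (idx - 1L) %/% H
  sh <- expand.grid(dr = -margin:margin, dc = -margin:margin)
  out <- unlist(lapply(seq_len(nrow(sh)), function(k) {
    rr <- r + sh$dr[k]; cc <- c + sh$dc[k]
    ok <- rr >= 0 & rr < H & cc >= 0 & cc < W
    cc[ok] * H + rr[ok] + 1L
  }))
  unique(as.integer(out))
}

# Rows (0-based) of a sheath bar of length L on a fiber at horizontal offset
# dx from the soma center, direction -1 (up) or +1 (down); the near end sits
# `depth` px inside the soma boundary chord.
sheath_rows <- function(cy, dx, r_soma, L, dir, depth = 4) {
  h <- floor(sqrt(max(r_soma^2 - dx^2, 0)))
  near <- round(cy + dir * (h - depth))
  if (dir < 0) seq(near - L + 1, near) else seq(near, near + L - 1)
}

place_phantom_cells <- function(spec, H, W, fibers, r_soma, r_nuc, w_half) {
  n <- spec$n_cells
  cells <- vector("list", n)
  if (n == 0L) return(list(cells = cells, overlaps = list()))
  ens <- stats::runif(n) < spec$p_ensheathing
  counts <- ifelse(ens, 1L + stats::rpois(n, spec$sheaths_per_cell_mean - 1), 0L)
  occupied <- rep(FALSE, H * W)
  n_ens <- sum(ens)
  n_pairs <- floor(spec$crowding * n_ens / 2)
  pair_partner <- rep(NA_integer_, n)   # pair i-th ens cell with next ens cell
  if (n_pairs > 0) {
    ens_idx <- which(ens)
    for (p in seq_len(n_pairs))
      pair_partner[ens_idx[2 * p]] <- ens_idx[2 * p - 1]
  }
  overlaps <- list()

  for (i in seq_len(n)) {
    partner <- pair_partner[i]
    placed <- FALSE
    # lengths drawn once per round of attempts, not per attempt: re-drawing
    # on every collision selects against long sheaths and narrows the
    # distribution; a redraw after 100 failed placements only affects cells
    # that barely fit
    for (attempt in 1:800) {
      if (attempt %% 100 == 1) lengths_px <- draw_length_px(counts[i], spec)
      if (!is.na(partner) && !is.null(cells[[partner]]) &&
          nrow(cells[[partner]]$sheaths) > 0) {
        g <- propose_overlapped_cell(spec, cells[[partner]], counts[i],
                                     lengths_px, H, W, fibers, r_soma,
                                     r_nuc, w_half)
      } else {
        cy <- stats::runif(1, r_soma + 1, H - r_soma - 2)
        cx <- stats::runif(1, r_soma + 1, W - r_soma - 2)
        g <- propose_cell(spec, cy, cx, counts[i], lengths_px, H, W, fibers,
                          r_soma, r_nuc, w_half)
      }
      if (is.null(g)) next
      body <- c(g$nucleus_px, if (g$ensheathing) g$soma_px)
      all_px <- unique(c(body, unlist(g$sheaths$px)))
      test_px <- setdiff(all_px, g$allowed_overlap)
      if (any(occupied[test_px])) next
      occupied[expand_px(all_px, H, W)] <- TRUE
      g$cell_id <- i
      cells[[i]] <- g
      if (length(g$overlap_px))
        overlaps[[length(overlaps) + 1L]] <-
          list(cell_a = partner, cell_b = i, px = g$overlap_px)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("phantom too crowded: could not place all cells; ",
           "reduce n_cells or enlarge the image")
  }
  list(cells = cells, overlaps = overlaps)
}

propose_cell <- function(spec, cy, cx, n_sheaths, lengths_px, H, W, fibers,
                         r_soma, r_nuc, w_half) {
  ensheathing <- n_sheaths > 0
  sheaths <- tibble::tibble(fiber_x = numeric(), dir = integer(),
                            rows = list(), px = list())
  if (ensheathing) {
    slots <- soma_slots(cx, fibers, r_soma, w_half)
    if (is.null(slots)) return(NULL)
    k <- min(n_sheaths, nrow(slots))
    use <- slots[sample(nrow(slots), k), , drop = FALSE]
    L <- lengths_px[seq_len(k)]
    rows <- vector("list", k); pxs <- vector("list", k)
    for (s in seq_len(k)) {
      rr <- sheath_rows(cy, use$fiber_x[s] - cx, r_soma, L[s], use$dir[s])
      if (min(rr) < 0 || max(rr) >= H) return(NULL)
      rows[[s]] <- rr
      pxs[[s]] <- bar_px(rr, use$fiber_x[s], w_half, H, W)
    }
    sheaths <- tibble::tibble(fiber_x = use$fiber_x, dir = use$dir,
                              rows = rows, px = pxs)
  }
  list(cy = cy, cx = cx, ensheathing = ensheathing,
       nucleus_px = disc_px(cy, cx, r_nuc, H, W),
       soma_px = if (ensheathing) disc_px(cy, cx, r_soma, H, W) else integer(),
       sheaths = sheaths, allowed_overlap = integer(), overlap_px = integer())
}

# Place a cell so its first sheath tip overlaps the tip of the partner's
# first sheath on the same fiber (deliberate "sticky"/shared segment).
propose_overlapped_cell <- function(spec, partner, n_sheaths, lengths_px,
                                    H, W, fibers, r_soma, r_nuc, w_half,
                                    overlap_len = 5L) {
  ps <- partner$sheaths[sample.int(nrow(partner$sheaths), 1), ]
  fiber_x <- ps$fiber_x
  dirA <- ps$dir
  tipA <- if (dirA < 0) min(ps$rows[[1]]) else max(ps$rows[[1]])
  L <- lengths_px[1]
  dirB <- -dirA
  # B's sheath runs toward A: choose B's soma center beyond the tip
  tipB <- tipA - dirA * (overlap_len - 1L)
  # near end of B's sheath = cyB + dirB*(h - depth); tip = near + dirB*(L-1)
  # solve cyB given tip: cyB = tipB - dirB*(L - 1) - dirB*(h - depth)
  cxB <- fiber_x + stats::runif(1, -r_soma / 2, r_soma / 2)
  h <- floor(sqrt(max(r_soma^2 - (fiber_x - cxB)^2, 0)))
  if (h <= 6) return(NULL)
  cyB <- tipB - dirB * (L - 1) - dirB * (h - 4)
  if (cyB < r_soma + 1 || cyB > H - r_soma - 2) return(NULL)
  g <- propose_cell(spec, cyB, cxB, max(n_sheaths, 1L), lengths_px, H, W,
                    fibers, r_soma, r_nuc, w_half)
  if (is.null(g)) return(NULL)
  # overwrite sheath 1 with the constructed overlapping bar
  rr <- sheath_rows(cyB, fiber_x - cxB, r_soma, L, dirB)
  if (min(rr) < 0 || max(rr) >= H) return(NULL)
  ppx <- bar_px(rr, fiber_x, w_half, H, W)
  g$sheaths$fiber_x[1] <- fiber_x; g$sheaths$dir[1] <- dirB
  g$sheaths$rows[[1]] <- rr; g$sheaths$px[[1]] <- ppx
  ov <- intersect(ppx, ps$px[[1]])
  if (length(ov) < 2) return(NULL)
  g$allowed_overlap <- expand_px(ov, H, W)
  g$overlap_px <- ov
  g
}

# ---- rendering and truth ---------------------------------------------------

render_phantom <- function(spec, geo, H, W, fibers, r_soma, r_nuc, w_half) {
  bg <- spec$background_level
  nuclei_ch <- matrix(bg, H, W)
  membrane_ch <- matrix(bg, H, W)
  bright_ch <- matrix(0.5, H, W)
  for (fx in fibers) {
    cc <- round(fx) + 1L
    if (cc >= 1 && cc <= W) bright_ch[, cc] <- 0.35
  }
  for (g in geo$cells) {
    if (is.null(g)) next
    nuclei_ch[g$nucleus_px] <- 0.85
    if (g$ensheathing) {
      membrane_ch[g$soma_px] <- 0.55
      for (ppx in g$sheaths$px) membrane_ch[ppx] <- 0.85
    }
  }
  if (spec$noise_sd > 0) {
    nuclei_ch <- nuclei_ch + stats::rnorm(H * W, 0, spec$noise_sd)
    membrane_ch <- membrane_ch + stats::rnorm(H * W, 0, spec$noise_sd)
  }
  clip01 <- function(m) {m[m < 0] <- 0; m[m > 1] <- 1; m}
  well_image(list(nuclei = clip01(nuclei_ch), membrane = clip01(membrane_ch),
                  brightfield = bright_ch),
             pixel_size_um = spec$pixel_size_um,
             name = sprintf("phantom-seed%d", spec$seed))
}

phantom_truth_from_geometry <- function(spec, geo, H, W) {
  nuclei <- matrix(0L, H, W)
  sheaths <- matrix(0L, H, W)
  cells <- list(); stbl <- list()
  for (g in geo$cells) {
    if (is.null(g)) next
    nuclei[g$nucleus_px] <- g$cell_id
    for (s in seq_len(nrow(g$sheaths)))
      sheaths[g$sheaths$px[[s]]] <- g$cell_id
    cells[[length(cells) + 1L]] <-
      tibble::tibble(cell_id = g$cell_id, centroid_y = g$cy, centroid_x = g$cx,
                     ensheathing = g$ensheathing,
                     n_sheaths = nrow(g$sheaths))
    if (nrow(g$sheaths))
      stbl[[length(stbl) + 1L]] <- tibble::tibble(
        cell_id = g$cell_id, sheath_id = seq_len(nrow(g$sheaths)),
        fiber_x = g$sheaths$fiber_x, dir = g$sheaths$dir,
        y0 = vapply(g$sheaths$rows, min, 0), y1 = vapply(g$sheaths$rows, max, 0),
        length_um = vapply(g$sheaths$rows, length, 0L) * spec$pixel_size_um,
        px = g$sheaths$px)
  }
  cells <- if (length(cells)) dplyr::bind_rows(cells) else
    tibble::tibble(cell_id = integer(), centroid_y = numeric(),
                   centroid_x = numeric(), ensheathing = logical(),
                   n_sheaths = integer())
  stbl <- if (length(stbl)) dplyr::bind_rows(stbl) else
    tibble::tibble(cell_id = integer(), sheath_id = integer(),
                   fiber_x = numeric(), dir = integer(), y0 = numeric(),
                   y1 = numeric(), length_um = numeric(), px = list())
  # deliberate overlaps: pixels go to the owner with larger total sheath area
  overlaps <- if (length(geo$overlaps)) {
    area <- vapply(geo$cells, function(g)
      if (is.null(g)) 0L else length(unique(unlist(g$sheaths$px))), 0L)
    dplyr::bind_rows(lapply(geo$overlaps, function(o) {
      owner <- if (area[o$cell_a] > area[o$cell_b]) o$cell_a
               else if (area[o$cell_b] > area[o$cell_a]) o$cell_b
               else min(o$cell_a, o$cell_b)
      tibble::tibble(cell_a = o$cell_a, cell_b = o$cell_b, owner = owner,
                     px = list(o$px))
    }))
  } else tibble::tibble(cell_a = integer(), cell_b = integer(),
                        owner = integer(), px = list())
  for (k in seq_len(nrow(overlaps)))
    sheaths[overlaps$px[[k]]] <- overlaps$owner[k]
  structure(list(nuclei = nuclei, sheaths = sheaths, cells = cells,
                 sheaths_tbl = stbl, overlaps = overlaps,
                 pixel_size_um = spec$pixel_size_um),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d cells (%d ensheathing), %d sheaths, %d recorded overlaps\n",
              nrow(x$cells), sum(x$cells$ensheathing), nrow(x$sheaths_tbl),
              nrow(x$overlaps)))
  invisible(x)
}

#' Back-derive the log-length dispersion from a power statement
#'
#' Solves the two-sample, equal-n minimum-detectable-difference relation
#' `delta = (z[1 - alpha/2] + z[power]) * sigma * sqrt(2 / n)` for `sigma`.
#' With the published design (detect 0.01 log-lengths at 80% power,
#' alpha = 0.05, n = 13,000 sheaths per group) this gives sigma ~ 0.288,
#' which is where the phantom's default `log10_length_sd = 0.29` comes from.
#'
#' @param delta detectable difference in log10 length units.
#' @param n per-group sample size.
#' @param power statistical power in (0, 1).
#' @param alpha two-sided significance level in (0, 1).
#' @return The implied standard deviation `sigma`.
#' @seealso [min_detectable_difference()] for the forward direction.
#' @export
derive_log_length_sd <- function(delta, n, power = 0.8, alpha = 0.05) {
  stopifnot(is.finite(delta), is.finite(n), n > 1,
            power > 0, power < 1, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  delta / (z * sqrt(2 / n))
}
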