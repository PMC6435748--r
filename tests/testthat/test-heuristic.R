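test_that("CLAHE keeps range contracts and flat inputs flat", {
  out <- clahe_enhance(matrix(0.4, 128, 128))
  expect_lt(diff(range(out)), 1e-6)                    # constant stays constant
  set.seed(2)
  noisy <- matrix(runif(128 * 128, 0, 0.3), 128, 128)
  e <- clahe_enhance(noisy)
  expect_gte(min(e), 0); expect_lte(max(e), 1)
  expect_error(clahe_enhance(array(0, c(4, 4, 2))), "2-D")
})

test_that("CLAHE increases sheath-background separation on a dim phantom", {
  # low-contrast rendering under an illumination gradient: global rescaling
  # cannot restore contrast, adaptive equalization can
  ph <- generate_phantom(phantom_spec(height_px = 512, width_px = 512,
                                      n_cells = 5, p_ensheathing = 1,
                                      seed = 6))
  mem <- get_channel(ph$image, "membrane") * 0.25
  grad <- matrix(rep(seq(0, 0.6, length.out = 512), each = 512), 512, 512)
  low <- mem + grad
  sheath <- ph$truth$sheaths > 0
  raw <- (low - min(low)) / diff(range(low))
  enh <- clahe_enhance(low)
  sep_raw <- mean(raw[sheath]) - mean(raw[!sheath])
  sep_enh <- mean(enh[sheath]) - mean(enh[!sheath])
  expect_gt(sep_enh, sep_raw)
})

test_that("ridge filter detects bars, rejects blobs, and scales with sensitivity", {
  expect_equal(sum(ridge_filter(matrix(0, 64, 64), sigma = 3)), 0)
  # single bright vertical bar 4 px wide, 100 px long
  img <- matrix(0, 160, 64); img[31:130, 31:34] <- 1
  mask <- ridge_filter(img, sigma = 4, sensitivity = 0.05)
  bar <- matrix(FALSE, 160, 64); bar[31:130, 31:34] <- TRUE
  expect_gte(sum(mask[bar]) / sum(bar), 0.9)
  expect_lte(sum(mask[!bar]) / sum(!bar), 0.05)
  # isotropic blob scores lower than an equal-peak bar
  xy <- expand.grid(r = 1:64, c = 1:64)
  blob <- matrix(exp(-((xy$r - 32)^2 + (xy$c - 32)^2) / (2 * 16)), 64, 64)
  barimg <- matrix(0, 64, 64); barimg[10:54, 31:34] <- 1
  expect_lt(max(ridge_score(blob, 4)), max(ridge_score(barimg, 4)))
  # monotonicity in sensitivity
  ph <- generate_phantom(phantom_spec(height_px = 512, width_px = 512,
                                      n_cells = 5, p_ensheathing = 1, seed = 3))
  enh <- clahe_enhance(get_channel(ph$image, "membrane"))
  counts <- sapply(c(0.01, 0.05, 0.1, 0.3), function(s)
    sum(ridge_filter(enh, 4, s)))
  expect_true(all(diff(counts) >= 0))
  expect_error(ridge_filter(matrix(0, 16, 16), sigma = 10), "kernel exceeds")
})

test_that("cell-body segmentation requires nucleus colocalization", {
  d <- c(128, 128)
  mem <- matrix(0, d[1], d[2])
  xy <- expand.grid(r = 1:d[1], c = 1:d[2])
  disc1 <- (xy$r - 40)^2 + (xy$c - 40)^2 <= 20^2
  disc2 <- (xy$r - 40)^2 + (xy$c - 95)^2 <= 20^2
  mem[disc1 | disc2] <- 0.8
  nuc <- matrix(0L, d[1], d[2])
  nuc[(xy$r - 40)^2 + (xy$c - 40)^2 <= 6^2] <- 1L     # only disc 1 has a nucleus
  bodies <- segment_cell_bodies(mem, nuc, heuristic_params())
  expect_setequal(unique(bodies[bodies > 0]), 1L)
  expect_gt(sum(bodies[disc1] == 1L) / sum(disc1), 0.8)
  expect_equal(sum(bodies[disc2] > 0), 0)             # no nucleus, no body
  # empty nuclei mask: empty result, not an error
  expect_true(all(segment_cell_bodies(mem, matrix(0L, d[1], d[2]),
                                      heuristic_params()) == 0L))
})

test_that("overlapping discs split into one body per nucleus", {
  d <- c(128, 128)
  xy <- expand.grid(r = 1:d[1], c = 1:d[2])
  r1 <- (xy$r - 64)^2 + (xy$c - 45)^2 <= 22^2
  r2 <- (xy$r - 64)^2 + (xy$c - 76)^2 <= 22^2          # overlap ~30% of radius
  mem <- matrix(0, d[1], d[2]); mem[r1 | r2] <- 0.8
  nuc <- matrix(0L, d[1], d[2])
  nuc[(xy$r - 64)^2 + (xy$c - 45)^2 <= 6^2] <- 1L
  nuc[(xy$r - 64)^2 + (xy$c - 76)^2 <= 6^2] <- 2L
  bodies <- segment_cell_bodies(mem, nuc, heuristic_params())
  expect_setequal(sort(unique(bodies[bodies > 0])), c(1L, 2L))
  # oracle: each disc's exclusive pixels majority-assigned to its own label
  only1 <- r1 & !r2; only2 <- r2 & !r1
  expect_gt(mean(bodies[only1] == 1L), 0.5)
  expect_gt(mean(bodies[only2] == 2L), 0.5)
})

test_that("subtraction obeys set arithmetic", {
  ridge <- matrix(0L, 32, 32); ridge[5:28, 10:12] <- 1L
  bodies <- matrix(0L, 32, 32); bodies[20:32, 5:20] <- 3L
  out <- subtract_cell_bodies(ridge, bodies)
  expect_equal(sum(out), sum(ridge) - sum(ridge & bodies > 0))
  expect_true(all(out[bodies > 0] == 0L))
  # disjoint masks: unchanged; enclosed ridge: empty
  expect_identical(subtract_cell_bodies(ridge, matrix(0L, 32, 32)), ridge)
  expect_equal(sum(subtract_cell_bodies(ridge, (ridge > 0) * 2L)), 0)
  expect_error(subtract_cell_bodies(ridge, matrix(0L, 16, 16)), "mismatch")
})

test_that("segment association follows the continuity rule", {
  d <- c(100, 100)
  bodies <- matrix(0L, d[1], d[2])
  bodies[40:60, 5:20] <- 1L; bodies[40:60, 70:90] <- 2L
  segs <- matrix(0L, d[1], d[2])
  segs[45:55, 22:23] <- 1L     # 1 px gap to body A (ends col 20... gap 1)
  segs[45:55, 45:46] <- 2L     # ~12 px from both bodies: beyond the 2 um gap
  pars <- heuristic_params(association_gap_um = 2, pixel_size_um = 0.5)
  out <- associate_segments(segs, bodies, pars)
  expect_equal(nrow(out), 1L)
  expect_equal(out$cell_id[out$segment == 1L], 1L)
  # nearest body wins when both are in reach
  segs2 <- matrix(0L, d[1], d[2])
  segs2[45:55, 22:23] <- 1L                            # 1 px from A, ~47 from B
  out2 <- associate_segments(segs2, bodies, heuristic_params(
    association_gap_um = 30, pixel_size_um = 0.5))
  expect_equal(out2$cell_id, 1L)
  # empty inputs: empty map
  expect_equal(nrow(associate_segments(matrix(0L, 4, 4), matrix(0L, 4, 4),
                                       pars)), 0L)
})

test_that("heuristic engine recovers well-separated phantom cells", {
  ph <- generate_phantom(phantom_spec(n_cells = 10, p_ensheathing = 1,
                                      noise_sd = 0.01, seed = 17))
  rec <- run_heuristic(ph$image)
  tr <- ph$truth
  det_cells <- attr(rec, "cells")
  jis <- c(); detected <- 0
  for (cid in tr$cells$cell_id) {
    tc <- tr$cells[tr$cells$cell_id == cid, ]
    dd <- sqrt((det_cells$centroid_y - tc$centroid_y)^2 +
               (det_cells$centroid_x - tc$centroid_x)^2)
    did <- det_cells$cell_id[which.min(dd)]
    ppx <- unlist(rec$px[rec$cell_id == did])
    if (length(ppx) > 0) detected <- detected + 1
    tpx <- which(tr$sheaths == cid)
    jis <- c(jis, length(intersect(tpx, ppx)) / length(union(tpx, ppx)))
  }
  expect_gte(detected, 8)
  expect_gte(median(jis), 0.5)
  # criteria: no sheath pixel claimed by two cells
  expect_equal(anyDuplicated(unlist(rec$px)), 0L)
  # zero ensheathing cells in, zero out
  ph0 <- generate_phantom(phantom_spec(height_px = 512, width_px = 512,
                                       n_cells = 6, p_ensheathing = 0,
                                       seed = 2))
  expect_equal(nrow(run_heuristic(ph0$image)), 0L)
})
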