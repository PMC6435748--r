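test_that("unfair distribution assigns shared components to the larger cell", {
  d <- c(60, 60)
  m <- matrix(0L, d[1], d[2])
  # cell 1: five bars totalling 2000 px; cell 2: one 150 px bar overlapping
  rows1 <- lapply(1:5, function(k) {
    mm <- matrix(0L, d[1], d[2]); mm[1:50, (k * 8):(k * 8 + 3)] <- 1L
    tibble::tibble(cell_id = 1L, sheath_id = k, px = list(which(mm == 1L)))
  })
  mm <- matrix(0L, d[1], d[2]); mm[40:59, 8:11] <- 1L  # overlaps bar 1 rows 40:50
  rows2 <- list(tibble::tibble(cell_id = 2L, sheath_id = 1L,
                               px = list(which(mm == 1L))))
  rec <- as_records(c(rows1, rows2), d)
  res <- resolve_overlaps(rec)
  expect_false(2L %in% res$cell_id)           # small claimant loses everything
  # set-arithmetic oracle: winner owns the merged component plus its other bars
  merged <- length(unique(unlist(c(rows1[[1]]$px, rows2[[1]]$px))))
  others <- sum(vapply(rows1[-1], function(r) length(r$px[[1]]), 0L))
  expect_equal(sum(lengths(res$px[res$cell_id == 1L])), merged + others)
  # disjointness: sum of per-cell pixels equals the union
  expect_equal(sum(lengths(res$px)), length(unique(unlist(res$px))))
})

test_that("unfair distribution is order-invariant and ties go to lower id", {
  d <- c(40, 30)
  bar <- function(cid, col, top, len, sid = 1L) {
    mm <- matrix(0L, d[1], d[2]); mm[top:(top + len - 1), col:(col + 3)] <- 1L
    tibble::tibble(cell_id = cid, sheath_id = sid, px = list(which(mm == 1L)))
  }
  # exact area tie: both cells own a single 20-px-long bar on the same fiber
  rows <- list(bar(5L, 10, 1, 20), bar(3L, 10, 15, 20))
  base <- resolve_overlaps(as_records(rows, d))
  expect_true(all(base$cell_id == 3L))        # tie -> lower cell_id
  set.seed(1)
  for (k in 1:5) {
    prm <- resolve_overlaps(as_records(sample(rows), d))
    expect_identical(lapply(prm$px, sort), lapply(base$px, sort))
    expect_identical(prm$cell_id, base$cell_id)
  }
  # no overlaps: input returned unchanged (same pixel sets)
  rows2 <- list(bar(1L, 5, 1, 10), bar(2L, 20, 1, 10))
  out <- resolve_overlaps(as_records(rows2, d))
  expect_setequal(unlist(out$px), unlist(lapply(rows2, function(r) r$px[[1]])))
  expect_equal(nrow(out), 2L)
})

test_that("sticky removal prunes cross-fiber bridges and keeps oblique arms", {
  Hm <- matrix(0L, 60, 40)
  Hm[10:50, 10:13] <- 1L; Hm[10:50, 28:31] <- 1L; Hm[28:31, 14:27] <- 1L
  out <- remove_sticky(Hm, post_params())
  expect_equal(max(label8(out)), 2L)
  expect_equal(sum(out[28:31, 16:25]), 0L)                 # bridge gone
  expect_gte(sum(out[, c(10:13, 28:31)]) / sum(Hm[, c(10:13, 28:31)]), 0.95)

  X <- matrix(0L, 80, 80)
  for (i in 0:60) {
    r <- 10 + i; c1 <- 25 + round(i * 0.5); c2 <- 55 - round(i * 0.5)
    X[r, c1:(c1 + 3)] <- 1L; X[r, c2:(c2 + 3)] <- 1L
  }
  outX <- remove_sticky(X, post_params())
  expect_equal(max(label8(outX)), 1L)                      # arms reconnected
  expect_gte(sum(outX) / sum(X), 0.9)

  B <- matrix(0L, 60, 20); B[5:55, 8:11] <- 1L
  expect_identical(remove_sticky(B, post_params()), B)     # single bar intact
  expect_identical(remove_sticky(matrix(0L, 8, 8), post_params()),
                   matrix(0L, 8, 8))
})

test_that("sticky removal never merges separate components", {
  set.seed(3)
  for (k in 1:5) {
    m <- matrix(0L, 50, 50)
    for (b in 1:4) {
      r0 <- sample(1:30, 1); c0 <- sample(seq(2, 44, by = 12), 1)
      m[r0:(r0 + sample(10:18, 1)), c0:(c0 + 2)] <- 1L
    }
    out <- remove_sticky(m, post_params())
    expect_true(all(out <= m))
    # components of out map into distinct components of m
    lm <- label8(m); lo <- label8(out)
    if (max(lo) > 0) {
      parent <- sapply(seq_len(max(lo)), function(b)
        unique(lm[lo == b]))
      expect_true(all(lengths(parent) == 1))
    }
  }
})

test_that("length measurement matches bar geometry and is rotation-stable", {
  d <- c(120, 120)
  m <- matrix(0L, d[1], d[2]); m[11:110, 60] <- 1L       # 100 px vertical run
  len <- measure_length(which(m == 1L), d, pixel_size_um = 0.5)
  expect_equal(len, 50, tolerance = 0.05 * 50)
  # single pixel: degenerate 1-px object, below any sheath threshold
  expect_lt(measure_length(5000L, d, 0.5), 12)
  expect_error(measure_length(integer(), d, 0.5), "empty")
  # rotation: same 80-px bar at 0, 45, 90 degrees within 2%
  l0 <- measure_length(which(m == 1L)[1:80], d, 0.5)
  m45 <- matrix(0L, d[1], d[2]); for (i in 0:79) m45[20 + i, 20 + i] <- 1L
  l45 <- measure_length(which(m45 == 1L), d, 0.5) / sqrt(2)
  m90 <- matrix(0L, d[1], d[2]); m90[60, 21:100] <- 1L
  l90 <- measure_length(which(m90 == 1L), d, 0.5)
  expect_lt(abs(l45 - l0) / l0, 0.02)
  expect_lt(abs(l90 - l0) / l0, 0.02)
  # ellipse convention is 2/sqrt(3) times the rectangle calibration
  expect_equal(measure_length(which(m == 1L), d, 0.5, convention = "ellipse"),
               len * 2 / sqrt(3), tolerance = 1e-9)
})

test_that("two-pass length filter follows the strict 1-2 sheath rule", {
  d <- c(400, 60)
  mk <- function(cid, lens_um) {
    lapply(seq_along(lens_um), function(k) {
      n <- round(lens_um[k] / 0.5)
      mm <- matrix(0L, d[1], d[2])
      mm[5:(4 + n), (k * 10):(k * 10 + 3)] <- 1L
      tibble::tibble(cell_id = cid, sheath_id = k, px = list(which(mm == 1L)))
    })
  }
  # the worked example: 10/15/40 um at min 12, multiplier 3 -> only 40 survives
  rec <- as_records(mk(1L, c(10, 15, 40)), d)
  out <- filter_by_length(rec, post_params(min_length_um = 12,
                                           strict_multiplier = 3))
  expect_equal(nrow(out), 1L)
  expect_equal(out$length_um, 40, tolerance = 1)
  # single 50 um sheath survives (50 >= 36); single 20 um sheath does not
  expect_equal(nrow(filter_by_length(as_records(mk(2L, 50), d),
                                     post_params())), 1L)
  expect_equal(nrow(filter_by_length(as_records(mk(3L, 20), d),
                                     post_params())), 0L)
  # three surviving sheaths are exempt from the strict rule
  rec3 <- as_records(mk(4L, c(15, 16, 17)), d)
  expect_equal(nrow(filter_by_length(rec3, post_params())), 3L)
  # subset property and idempotence
  once <- filter_by_length(rec, post_params())
  twice <- filter_by_length(once, post_params())
  expect_identical(lapply(twice$px, sort), lapply(once$px, sort))
  expect_true(all(unlist(once$px) %in% unlist(rec$px)))
})

test_that("monotonicity: raising the length floor never adds sheaths", {
  ph <- generate_phantom(phantom_spec(height_px = 512, width_px = 512,
                                      n_cells = 5, p_ensheathing = 1, seed = 3))
  rec <- sheath_records(ph$truth$sheaths_tbl[, c("cell_id", "sheath_id", "px")],
                        dim(ph$truth$sheaths), 0.5)
  ns <- sapply(c(5, 12, 20, 30), function(ml)
    nrow(filter_by_length(rec, post_params(min_length_um = ml))))
  expect_true(all(diff(ns) <= 0))
})

test_that("deliberately overlapped phantom sheaths resolve to the truth owner", {
  hits <- 0; total <- 0
  for (s in c(7, 8)) {
    ph <- generate_phantom(phantom_spec(n_cells = 12, p_ensheathing = 1,
                                        crowding = 0.6, seed = s))
    tr <- ph$truth
    # feed the generator's per-cell masks (with their true overlaps) in
    rec <- sheath_records(tr$sheaths_tbl[, c("cell_id", "sheath_id", "px")],
                          dim(tr$sheaths), 0.5)
    res <- resolve_overlaps(rec)
    for (k in seq_len(nrow(tr$overlaps))) {
      opx <- tr$overlaps$px[[k]]
      owner_rows <- res$cell_id[vapply(res$px, function(p)
        any(opx %in% p), TRUE)]
      total <- total + 1
      if (all(owner_rows == tr$overlaps$owner[k])) hits <- hits + 1
    }
  }
  expect_gte(total, 4)
  expect_gte(hits / total, 0.9)
})
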