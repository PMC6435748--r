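# Small deterministic fixtures shared across tests (built in code; no files).

tiny_well <- function(h = 64, w = 64, seed = 1) {
  set.seed(seed)
  well_image(list(nuclei = matrix(runif(h * w), h, w),
                  membrane = matrix(runif(h * w), h, w)),
             pixel_size_um = 0.5, name = "tiny")
}

# a vertical bar mask as sheath_records input
bar_records <- function(dim = c(100, 40), col0 = 18, len = 60, top = 20,
                        cell_id = 1L, width = 4, pixel_size_um = 0.5) {
  m <- matrix(0L, dim[1], dim[2])
  m[top:(top + len - 1), col0:(col0 + width - 1)] <- 1L
  tibble::tibble(cell_id = cell_id, sheath_id = 1L, px = list(which(m == 1L)))
}

as_records <- function(rows, dim, cells = NULL, pixel_size_um = 0.5) {
  sheath_records(dplyr::bind_rows(rows), dim, pixel_size_um, cells = cells)
}

# brute-force even-odd point-in-polygon over every pixel center
brute_polygon_pixels <- function(poly, shape) {
  inside <- function(px, py) {
    n <- nrow(poly); flag <- FALSE
    for (e in seq_len(n)) {
      x1 <- poly[e, 1]; y1 <- poly[e, 2]
      x2 <- poly[e %% n + 1, 1]; y2 <- poly[e %% n + 1, 2]
      if ((y1 > py) != (y2 > py) &&
          px < x1 + (py - y1) * (x2 - x1) / (y2 - y1)) flag <- !flag
    }
    flag
  }
  idx <- c()
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2]))
    if (inside(c - 0.5, r - 0.5)) idx <- c(idx, (c - 1) * shape[1] + r)
  as.integer(idx)
}
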