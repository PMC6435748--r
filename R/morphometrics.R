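#' Jaccard index of two binary masks
#'
#' Intersection over union. Two empty masks agree perfectly on absence and
#' score 1.
#'
#' @param a,b binary matrices of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Per-cell Jaccard comparison of two segmentations
#'
#' Cells of the reference and test segmentations are paired by nucleus
#' centroid (greedy, closest first, one-to-one, within
#' `pairing_radius_um`); the JI of the paired cells' sheath masks is
#' reported per pair. Unpaired cells are excluded from the per-cell list
#' but counted.
#'
#' @param ref,test [sheath_records()] tables in common well coordinates
#'   (their `cells` attribute supplies the centroids).
#' @param pairing_radius_um maximum centroid distance for a pair.
#' @return A `ji_report`: list with `per_cell` tibble (`cell_id_ref`,
#'   `cell_id_test`, `ji`), `global_ji`, `n_unpaired_ref`,
#'   `n_unpaired_test`, `pairing_radius_um`.
#' @export
per_cell_ji <- function(ref, test, pairing_radius_um = 10) {
  d <- sheath_dim(ref)
  px_um <- attr(ref, "pixel_size_um")
  rc <- attr(ref, "cells"); tc <- attr(test, "cells")
  rc <- rc[rc$cell_id %in% ref$cell_id, ]
  tc <- tc[tc$cell_id %in% test$cell_id, ]
  pairs <- list()
  if (nrow(rc) && nrow(tc)) {
    dm <- outer(seq_len(nrow(rc)), seq_len(nrow(tc)), function(i, j)
      sqrt((rc$centroid_y[i] - tc$centroid_y[j])^2 +
           (rc$centroid_x[i] - tc$centroid_x[j])^2)) * px_um
    dm[dm > pairing_radius_um] <- Inf
    while (any(is.finite(dm))) {
      k <- arrayInd(which.min(dm), dim(dm))
      pairs[[length(pairs) + 1L]] <- c(k[1], k[2])
      dm[k[1], ] <- Inf; dm[, k[2]] <- Inf
    }
  }
  per_cell <- dplyr::bind_rows(lapply(pairs, function(p) {
    a <- px_to_mask(unlist(ref$px[ref$cell_id == rc$cell_id[p[1]]]), d)
    b <- px_to_mask(unlist(test$px[test$cell_id == tc$cell_id[p[2]]]), d)
    tibble::tibble(cell_id_ref = rc$cell_id[p[1]],
                   cell_id_test = tc$cell_id[p[2]], ji = jaccard(a, b))
  }))
  if (length(pairs) == 0)
    per_cell <- tibble::tibble(cell_id_ref = integer(),
                               cell_id_test = integer(), ji = numeric())
  structure(list(per_cell = per_cell, global_ji = global_ji(ref, test),
                 n_unpaired_ref = nrow(rc) - nrow(per_cell),
                 n_unpaired_test = nrow(tc) - nrow(per_cell),
                 pairing_radius_um = pairing_radius_um),
            class = "ji_report")
}

#' @export
print.ji_report <- function(x, ...) {
  cat(sprintf(
    "<ji_report> %d pairs (median JI %.3f), global JI %.3f; unpaired ref/test: %d/%d\n",
    nrow(x$per_cell), stats::median(x$per_cell$ji), x$global_ji,
    x$n_unpaired_ref, x$n_unpaired_test))
  invisible(x)
}

#' Global Jaccard index of two segmentations
#'
#' JI of the unions of all per-cell sheath masks.
#'
#' @param ref,test [sheath_records()] tables.
#' @return Scalar in `[0, 1]`.
#' @export
global_ji <- function(ref, test) {
  d <- sheath_dim(ref)
  jaccard(px_to_mask(unlist(ref$px), d), px_to_mask(unlist(test$px), d))
}

#' Per-cell morphology from sheath records
#'
#' @param records a [sheath_records()] table.
#' @return Tibble with one row per ensheathing cell: `cell_id`,
#'   `n_sheaths`, `mean_length_um` (the cell's mSLC contribution),
#'   `mean_log10_length`.
#' @export
cell_morphology <- function(records) {
  tbl <- dplyr::group_by(tibble::as_tibble(records), .data$cell_id)
  tbl <- dplyr::summarise(tbl, n_sheaths = dplyr::n(),
                          mean_length_um = mean(.data$length_um),
                          mean_log10_length = mean(log10(.data$length_um)),
                          .groups = "drop")
  tbl
}

sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_

#' Summarize a well
#'
#' Aggregates per-cell morphology into the well-level morphometrics: number
#' of candidates and of ensheathing cells, sheaths per cell (mean ± SEM
#' over cells), mean sheath length per cell (mSLC, mean ± SEM over cells)
#' and pooled log10 sheath length (mean ± SEM over sheaths; lengths are
#' log-transformed because sheath length distributions are log-normal).
#'
#' @param records a [sheath_records()] table.
#' @param n_candidates number of candidate cells examined (defaults to the
#'   `cells` attribute count).
#' @return A one-row `well_summary` tibble.
#' @export
summarize_well <- function(records, n_candidates = NULL) {
  cm <- cell_morphology(records)
  if (is.null(n_candidates)) {
    cells <- attr(records, "cells")
    n_candidates <- if (!is.null(cells)) nrow(cells) else nrow(cm)
  }
  lens <- unlist(records[["length_um"]])
  out <- tibble::tibble(
    n_candidates = as.integer(n_candidates),
    n_ensheathing_cells = nrow(cm),
    sheaths_per_cell_mean = if (nrow(cm)) mean(cm$n_sheaths) else NA_real_,
    sheaths_per_cell_sem = sem(cm$n_sheaths),
    mslc_mean = if (nrow(cm)) mean(cm$mean_length_um) else NA_real_,
    mslc_sem = sem(cm$mean_length_um),
    log10_length_mean = if (length(lens)) mean(log10(lens)) else NA_real_,
    log10_length_sem = sem(log10(lens)),
    n_sheaths = length(lens))
  class(out) <- c("well_summary", class(out))
  out
}

#' Minimum detectable difference at a different sample size
#'
#' At fixed power and significance, the minimum detectable difference of a
#' two-sample comparison scales as `1/sqrt(n)`:
#' `delta = delta_ref * sqrt(n_ref / n)`. With the published reference
#' design (13,000 sheaths detect 0.01 log-length units at 80% power), a
#' 300-sheath study can only discern ~0.07 log units.
#'
#' @param n sample size of interest (> 1).
#' @param n_ref reference sample size (> 1).
#' @param delta_ref difference detectable at `n_ref` (> 0).
#' @return The minimum detectable difference at `n`.
#' @seealso [derive_log_length_sd()] for the inverse problem.
#' @export
min_detectable_difference <- function(n, n_ref = 13000, delta_ref = 0.01) {
  stopifnot(n > 1, n_ref > 1, delta_ref > 0)
  delta_ref * sqrt(n_ref / n)
}

#' Compare two groups of well summaries
#'
#' Pooled difference of group means ± combined SEM for sheaths per cell
#' and log10 sheath length, with pass-through p-values from the standard
#' tests (Mann-Whitney U on per-well sheath counts, Welch t on log
#' lengths). Group means are computed over wells; the SEM of the
#' difference is `sqrt(sem_a^2 + sem_b^2)`.
#'
#' @param a,b lists (or row-bound tibbles) of [summarize_well()] results,
#'   one element/row per well.
#' @return Tibble with one row per metric: `metric`, `mean_a`, `mean_b`,
#'   `difference`, `sem`, `p_value`.
#' @export
compare_groups <- function(a, b) {
  norm <- function(x) if (inherits(x, "data.frame")) x else dplyr::bind_rows(x)
  a <- norm(a); b <- norm(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("each group needs at least one well")
  metric_row <- function(metric, va, vb, test) {
    p <- if (length(va) > 1 && length(vb) > 1)
      suppressWarnings(test(va, vb)$p.value) else NA_real_
    tibble::tibble(metric = metric, mean_a = mean(va), mean_b = mean(vb),
                   difference = mean(va) - mean(vb),
                   sem = sqrt(sem(va)^2 + sem(vb)^2), p_value = p)
  }
  dplyr::bind_rows(
    metric_row("sheaths_per_cell", a$sheaths_per_cell_mean,
               b$sheaths_per_cell_mean, stats::wilcox.test),
    metric_row("log10_length", a$log10_length_mean, b$log10_length_mean,
               stats::t.test))
}
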