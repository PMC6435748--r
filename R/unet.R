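#' UNet architecture configuration
#'
#' The reduced UNet: a five-layer down-sampling arm of 5 x 5, stride-2
#' convolutions whose filter counts rise 10, 20, 30, 40, 50; a symmetric
#' up-sampling arm of fractional-stride (transposed) convolutions dropping
#' 50, 40, 30, 20, 10, each concatenating the down-arm feature map of
#' matching resolution before the next up-convolution; and a final 1 x 1
#' softmax layer producing two mutually exclusive per-pixel classes
#' (background, sheath). Scaling to only 50 filters at the bottleneck keeps
#' the network practical on a CPU.
#'
#' @param depth number of down-sampling stages.
#' @param kernel_px convolution kernel size (px).
#' @param stride down/up-sampling stride.
#' @param filters_down filter counts of the down arm; the up arm is its
#'   reverse.
#' @param n_classes output classes.
#' @param in_channels input channels (membrane, nucleus mask, nuclei).
#' @param prob_threshold probability threshold for binarizing inference.
#' @return A `unet_config` list.
#' @export
unet_config <- function(depth = 5, kernel_px = 5, stride = 2,
                        filters_down = c(10, 20, 30, 40, 50),
                        n_classes = 2, in_channels = 3,
                        prob_threshold = 0.5) {
  stopifnot(length(filters_down) == depth, kernel_px == 5, stride == 2,
            n_classes == 2, prob_threshold >= 0)
  structure(list(depth = depth, kernel_px = kernel_px, stride = stride,
                 filters_down = filters_down,
                 filters_up = rev(filters_down), n_classes = n_classes,
                 in_channels = in_channels, prob_threshold = prob_threshold),
            class = "unet_config")
}

#' Loss-weighting parameters
#'
#' Class weighting multiplies the per-pixel loss on sheath pixels by
#' `class_weight` (default 10), counteracting the background/sheath class
#' imbalance. Spatial weighting follows the exponential edge-decay formula
#' `w = exp(1 - D/f + b)` where `D` is the Chebyshev distance of a pixel to
#' the nearest sheath pixel of the ground truth, `f` sets the falloff rate
#' and `b` offsets the weights. The printed formula places `b` in the
#' exponent (`spatial_mode = "exponent"`, the default); its stated role of
#' keeping weights away from zero also fits an additive floor
#' `exp(1 - D/f) + b` (`spatial_mode = "additive_floor"`), so both are
#' available.
#'
#' @param class_weight multiplier on sheath-pixel loss (>= 1).
#' @param f edge falloff scale in px (> 0).
#' @param b offset.
#' @param spatial_mode `"exponent"` or `"additive_floor"`.
#' @param spatial whether the spatial term is applied at all (`FALSE`
#'   yields pure class weighting with unit spatial weights).
#' @return A `weight_params` list.
#' @export
weight_params <- function(class_weight = 10, f = 6, b = 0,
                          spatial_mode = c("exponent", "additive_floor"),
                          spatial = TRUE) {
  spatial_mode <- match.arg(spatial_mode)
  stopifnot(class_weight >= 1, f > 0)
  structure(list(class_weight = class_weight, f = f, b = b,
                 spatial_mode = spatial_mode, spatial = spatial),
            class = "weight_params")
}

#' Spatial weight map from a ground-truth mask
#'
#' `D` is the Chebyshev (chessboard) distance of each pixel to the nearest
#' truth (sheath) pixel, computed on the inverted ground-truth mask; truth
#' pixels have `D = 0` and hence maximal weight `exp(1 + b)`. For an empty
#' truth the distances are image-wide and weights are uniformly tiny.
#'
#' @param truth binary matrix.
#' @param params a [weight_params()].
#' @return Numeric matrix of weights.
#' @export
spatial_weight_map <- function(truth, params = weight_params()) {
  truth <- (as.matrix(truth) > 0) + 0L
  D <- chebyshev_dt(truth)
  if (params$spatial_mode == "exponent")
    exp(1 - D / params$f + params$b)
  else
    exp(1 - D / params$f) + params$b
}

#' Class- and spatially-weighted per-pixel cross-entropy
#'
#' Mean over pixels of `w(p) * c(p) * CE(p)`, where `w` is the spatial
#' weight, `c` is `class_weight` on truth pixels and 1 elsewhere, and CE is
#' the categorical cross-entropy of the two-class prediction.
#'
#' @param pred `H x W x 2` array of class probabilities (slices sum to 1;
#'   slice 2 = sheath).
#' @param truth binary matrix.
#' @param weights spatial weight matrix (e.g. [spatial_weight_map()]).
#' @param class_weight sheath-class multiplier.
#' @return Non-negative scalar loss.
#' @export
weighted_loss <- function(pred, truth, weights = NULL, class_weight = 1) {
  stopifnot(length(dim(pred)) == 3, dim(pred)[3] == 2)
  truth <- (as.matrix(truth) > 0) + 0
  if (is.null(weights)) weights <- matrix(1, nrow(truth), ncol(truth))
  if (any(pred < -1e-9) || any(pred > 1 + 1e-9))
    stop("probabilities outside [0, 1]")
  p_true <- pred[, , 1] * (1 - truth) + pred[, , 2] * truth
  cw <- weights * (1 + (class_weight - 1) * truth)
  mean(cw * (-log(pmax(p_true, 1e-12))))
}

#' Build (initialize) a UNet model
#'
#' He-normal weight initialization, seeded for reproducibility. The model
#' is a plain list of weight matrices consumed by the compiled
#' forward/backward routines; [unet_n_params()] gives its trainable
#' parameter count.
#'
#' @param config a [unet_config()].
#' @param seed RNG seed for the initialization.
#' @return A `unet_model` list with elements `config` and `params`.
#' @export
build_unet <- function(config = unet_config(), seed = 1) {
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  k2 <- config$kernel_px^2
  down_in <- c(config$in_channels, utils::head(config$filters_down, -1))
  up_in <- integer(config$depth)
  up_in[1] <- config$filters_down[config$depth]
  for (j in seq_len(config$depth - 1))
    up_in[j + 1] <- config$filters_up[j] + config$filters_down[config$depth - j]
  he <- function(nr, nc, fan_in)
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  params <- list(
    down_W = lapply(seq_len(config$depth), function(i)
      he(config$filters_down[i], k2 * down_in[i], k2 * down_in[i])),
    down_b = lapply(config$filters_down, function(o) numeric(o)),
    up_W = lapply(seq_len(config$depth), function(j)
      he(up_in[j], k2 * config$filters_up[j], k2 * up_in[j])),
    up_b = lapply(config$filters_up, function(o) numeric(o)),
    final_W = he(config$n_classes, utils::tail(config$filters_up, 1),
                 utils::tail(config$filters_up, 1)),
    final_b = numeric(config$n_classes))
  structure(list(config = config, params = params), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, filters %s, %d trainable parameters\n",
              x$config$depth, paste(x$config$filters_down, collapse = "/"),
              unet_n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a UNet model
#' @param model a `unet_model`.
#' @return Integer parameter count.
#' @export
unet_n_params <- function(model) {
  length(unlist(model$params))
}

#' Per-pixel class probabilities for one input
#'
#' @param model a trained or initialized `unet_model`.
#' @param x `H x W x 3` input array (or a `masked_input`); H and W must be
#'   multiples of `2^depth`.
#' @return `H x W x 2` array of softmax probabilities (slice 2 = sheath).
#' @export
unet_predict <- function(model, x) {
  if (inherits(x, "masked_input")) x <- x$crop
  d <- dim(x)
  if (length(d) != 3 || d[3] != model$config$in_channels)
    stop("input must be H x W x ", model$config$in_channels)
  if (any(d[1:2] %% model$config$stride^model$config$depth != 0))
    stop("input sides must be multiples of ",
         model$config$stride^model$config$depth)
  unet_forward_cpp(model$params, x)
}

#' Binary sheath mask for one masked-nucleus input
#'
#' @param model a `unet_model`.
#' @param x input array or `masked_input`.
#' @param threshold sheath-probability threshold (default 0.5).
#' @return Integer binary matrix.
#' @export
infer_cell <- function(model, x, threshold = 0.5) {
  p <- unet_predict(model, x)
  (p[, , 2] >= threshold) + 0L
}

#' Training configuration
#'
#' One step is one minibatch gradient update. `rotate_augment =
#' "random_angle"` rotates each drawn example (input and truth) by a
#' uniform random angle, used to train orientation-robust networks.
#'
#' @param steps optimization steps (> 0).
#' @param batch_size examples per step.
#' @param learning_rate Adam step size.
#' @param optimizer_name only `"adam"` is provided.
#' @param seed RNG seed controlling initialization order, batch sampling
#'   and augmentation.
#' @param val_every validation cadence in steps (<= steps).
#' @param rotate_augment `"none"` or `"random_angle"`.
#' @return A `train_config` list.
#' @export
train_config <- function(steps, batch_size = 4, learning_rate = 1e-4,
                         optimizer_name = "adam", seed = 1,
                         val_every = max(1, steps %/% 10),
                         rotate_augment = c("none", "random_angle")) {
  rotate_augment <- match.arg(rotate_augment)
  stopifnot(steps > 0, val_every <= steps, batch_size > 0,
            learning_rate > 0, optimizer_name == "adam")
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer_name = optimizer_name, seed = as.integer(seed),
                 val_every = as.integer(val_every),
                 rotate_augment = rotate_augment),
            class = "train_config")
}

rotate_example <- function(ex, angle) {
  rot <- function(m) {
    r <- EBImage::rotate(m, angle, output.dim = dim(m), bg.col = 0)
    as.matrix(r)
  }
  x <- ex$x
  for (k in seq_len(dim(x)[3])) x[, , k] <- rot(ex$x[, , k])
  x[, , 2] <- (x[, , 2] >= 0.5) + 0   # keep the nucleus mask binary
  list(x = x, y = (rot(ex$y) >= 0.5) + 0)
}

#' Train the UNet
#'
#' Minibatch Adam on the class- and spatially-weighted per-pixel
#' cross-entropy. Every `val_every` steps the validation loss and mean
#' per-example Jaccard index (at threshold 0.5) are recorded; the returned
#' model is the checkpoint with the best validation JI. Training aborts
#' with an informative error if the loss diverges to NaN. With a fixed
#' seed (and single-threaded numerics) the run is reproducible.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param trainset,valset lists of examples (`x` array, `y` binary matrix),
#'   e.g. from [build_training_set()].
#' @param tconfig a [train_config()].
#' @param wparams a [weight_params()].
#' @return List with `model` (best checkpoint) and `log` (a `train_log`
#'   tibble: step, train_loss, val_loss, val_mean_ji).
#' @export
unet_train <- function(model, trainset, valset, tconfig,
                       wparams = weight_params()) {
  stopifnot(length(trainset) > 0, length(valset) > 0)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(tconfig$seed)
  prep <- function(ex) {
    w <- if (wparams$spatial) spatial_weight_map(ex$y, wparams)
         else matrix(1, nrow(ex$y), ncol(ex$y))
    list(x = ex$x, y = (as.matrix(ex$y) > 0) + 0, w = w)
  }
  train_prepped <- lapply(trainset, prep)
  val_prepped <- lapply(valset, prep)

  theta <- unlist(model$params)
  skel <- model$params
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(ji = -Inf, theta = theta)
  log_rows <- list()

  for (step in seq_len(tconfig$steps)) {
    idx <- sample.int(length(train_prepped), tconfig$batch_size,
                      replace = length(train_prepped) < tconfig$batch_size)
    gsum <- NULL; loss_sum <- 0
    for (i in idx) {
      ex <- train_prepped[[i]]
      if (tconfig$rotate_augment == "random_angle") {
        rex <- rotate_example(list(x = ex$x, y = ex$y),
                              stats::runif(1, 0, 360))
        ex <- list(x = rex$x, y = rex$y,
                   w = if (wparams$spatial) spatial_weight_map(rex$y, wparams)
                       else matrix(1, nrow(rex$y), ncol(rex$y)))
      }
      res <- unet_grad_cpp(utils::relist(theta, skel), ex$x, ex$y, ex$w,
                           wparams$class_weight)
      loss_sum <- loss_sum + res$loss
      g <- unlist(res$grads)
      gsum <- if (is.null(gsum)) g else gsum + g
    }
    loss <- loss_sum / length(idx)
    if (!is.finite(loss))
      stop(sprintf("training diverged: non-finite loss at step %d", step))
    g <- gsum / length(idx)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^step); vhat <- v / (1 - b2^step)
    theta <- theta - tconfig$learning_rate * mhat / (sqrt(vhat) + eps)

    if (step %% tconfig$val_every == 0 || step == tconfig$steps) {
      cur <- utils::relist(theta, skel)
      vstats <- validate_unet(cur, val_prepped, wparams)
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        step = step, train_loss = loss, val_loss = vstats$loss,
        val_mean_ji = vstats$ji)
      if (vstats$ji > best$ji) best <- list(ji = vstats$ji, theta = theta)
    }
  }
  out <- model
  out$params <- utils::relist(best$theta, skel)
  log <- dplyr::bind_rows(log_rows)
  class(log) <- c("train_log", class(log))
  list(model = out, log = log)
}

validate_unet <- function(params, val_prepped, wparams) {
  losses <- numeric(length(val_prepped)); jis <- numeric(length(val_prepped))
  for (i in seq_along(val_prepped)) {
    ex <- val_prepped[[i]]
    p <- unet_forward_cpp(params, ex$x)
    losses[i] <- weighted_loss(p, ex$y, ex$w, wparams$class_weight)
    pred <- (p[, , 2] >= 0.5) + 0L
    jis[i] <- jaccard(pred, ex$y)
  }
  list(loss = mean(losses), ji = mean(jis))
}

#' Run per-candidate inference over a whole well
#'
#' Cycles the network over each candidate cell's masked-nucleus crop and
#' places the thresholded masks back at their crop offsets in well
#' coordinates (padded areas are excluded). Overlapping claims between
#' cells are retained, to be settled by [resolve_overlaps()].
#'
#' @param model a `unet_model`.
#' @param image a [well_image()].
#' @param candidates tibble from [filter_candidates()].
#' @param threshold sheath-probability threshold.
#' @param crop_size_px crop side (multiple of `2^depth`).
#' @return A [sheath_records()] table (one row per connected sheath
#'   component per cell).
#' @export
infer_well <- function(model, image, candidates, threshold = 0.5,
                       crop_size_px = 256) {
  d <- dim(image)
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    mi <- build_masked_input(image, candidates[i, ], crop_size_px)
    mask <- infer_cell(model, mi, threshold)
    u <- uncrop_indices(mi$offset, crop_size_px, d)
    well_mask <- matrix(0L, d[1], d[2])
    well_mask[u$well_r, u$well_c] <- mask[u$crop_r, u$crop_c]
    comp <- label8(well_mask)
    for (k in seq_len(max(comp)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell_id = candidates$cell_id[i], sheath_id = k,
        px = list(which(comp == k)))
  }
  tbl <- dplyr::bind_rows(rows)
  if (length(rows) == 0)
    tbl <- tibble::tibble(cell_id = integer(), sheath_id = integer(),
                          px = list())
  sheath_records(tbl, d, image$pixel_size_um,
                 cells = candidates[, c("cell_id", "centroid_y", "centroid_x")])
}

#' Phantom masked-nucleus example set
#'
#' Convenience generator for training-scale experiments: renders one
#' phantom per seed (all cells ensheathing, so every example is positive)
#' and assembles the masked-nucleus training examples from its exact truth.
#'
#' @param seeds integer vector; one phantom per seed.
#' @param crop_size_px crop side in px.
#' @param n_cells cells per phantom.
#' @return List of examples (`x`, `y`, `cell_id`, `offset`).
#' @export
phantom_example_set <- function(seeds, crop_size_px = 128, n_cells = 15) {
  out <- list()
  for (s in seeds) {
    ph <- generate_phantom(phantom_spec(n_cells = n_cells,
                                        p_ensheathing = 1, seed = s))
    out <- c(out, build_training_set(ph$image, ph$truth$nuclei,
                                     ph$truth$sheaths,
                                     candidate_params(crop_size_px = crop_size_px)))
  }
  out
}

#' Scaled-down weighted-vs-unweighted learning comparison
#'
#' Trains the UNet twice per seed on the same phantom example set — once
#' with class + spatial loss weighting, once unweighted — and reports, per
#' seed and configuration, the best validation JI, the JI of the untrained
#' model, and the first step at which validation JI reached `ji_target`
#' (`Inf` if never). Weighting is expected to reach the target in fewer
#' steps: the weighted loss pushes the sheath class out of the
#' all-background regime earlier.
#'
#' @param seeds seeds for the paired runs (default 3).
#' @param trainset,valset example lists; defaults build a 240/60 split of
#'   128 px phantom crops.
#' @param steps,learning_rate,batch_size,val_every training-loop settings
#'   for the scaled runs.
#' @param ji_target JI threshold for the speed comparison.
#' @return Tibble: `seed`, `weighted`, `best_ji`, `untrained_ji`,
#'   `steps_to_target`.
#' @export
unet_learning_comparison <- function(seeds = 1:3, trainset = NULL,
                                     valset = NULL, steps = 120,
                                     learning_rate = 1e-3, batch_size = 4,
                                     val_every = 20, ji_target = 0.3) {
  if (is.null(trainset)) trainset <- phantom_example_set(1:16 * 7 + 1000)
  if (is.null(valset)) valset <- phantom_example_set(1:4 * 7 + 9000)
  val_prepped <- lapply(valset, function(ex)
    list(x = ex$x, y = (as.matrix(ex$y) > 0) + 0,
         w = matrix(1, nrow(ex$y), ncol(ex$y))))
  rows <- list()
  for (seed in seeds) {
    model0 <- build_unet(seed = seed)
    base <- validate_unet(model0$params, val_prepped, weight_params())$ji
    for (weighted in c(TRUE, FALSE)) {
      wp <- if (weighted) weight_params(class_weight = 10, spatial = TRUE)
            else weight_params(class_weight = 1, spatial = FALSE)
      tc <- train_config(steps = steps, batch_size = batch_size,
                         learning_rate = learning_rate, seed = seed,
                         val_every = val_every)
      res <- unet_train(model0, trainset, valset, tc, wp)
      hit <- res$log$step[res$log$val_mean_ji >= ji_target]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = seed, weighted = weighted,
        best_ji = max(res$log$val_mean_ji), untrained_ji = base,
        steps_to_target = if (length(hit)) min(hit) else Inf)
    }
  }
  dplyr::bind_rows(rows)
}
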