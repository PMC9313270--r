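#' Shared axes specification for curve rendering
#'
#' Rendering must use one fixed axes specification across a whole dataset so
#' that image scale does not leak per-plate calibration into the classifier.
#'
#' @param cycle_range Length-2 numeric, cycle axis limits.
#' @param fluor_range Length-2 numeric, fluorescence axis limits.
#' @param width,height Image size in pixels (default 32 x 32 grayscale).
#' @return A list of class `axes_spec`.
#' @export
axes_spec <- function(cycle_range, fluor_range, width = 32L, height = 32L) {
  stopifnot(length(cycle_range) == 2L, length(fluor_range) == 2L,
            diff(cycle_range) > 0, diff(fluor_range) > 0)
  structure(list(cycle_range = as.numeric(cycle_range),
                 fluor_range = as.numeric(fluor_range),
                 width = as.integer(width), height = as.integer(height)),
            class = "axes_spec")
}

#' Axes covering a set of traces
#'
#' @param traces List of [fluorescence_trace()].
#' @param ... Passed to [axes_spec()].
#' @return An [axes_spec()] spanning all cycles and fluorescence values.
#' @export
axes_for_traces <- function(traces, ...) {
  fl <- range(unlist(lapply(traces, `[[`, "fluorescence")))
  cy <- range(unlist(lapply(traces, `[[`, "cycles")))
  axes_spec(cy, fl + c(-1, 1) * 1e-9, ...)
}

#' Rasterize an amplification curve
#'
#' Deterministic line rendering of the trace onto a fixed-size grayscale
#' pixel grid: the polyline through the cycle/fluorescence points is sampled
#' densely and every touched pixel is set to 1 (curve) on a 0 background.
#' Row 1 is the top of the image (highest fluorescence). Values outside the
#' axes are clipped with a warning.
#'
#' @param trace A [fluorescence_trace()].
#' @param axes An [axes_spec()].
#' @return A `height x width` matrix in \[0, 1\] of class `curve_image`.
#' @export
render_curve_image <- function(trace, axes) {
  stopifnot(inherits(axes, "axes_spec"))
  x <- trace$cycles
  y <- trace$fluorescence
  if (any(y < axes$fluor_range[1]) || any(y > axes$fluor_range[2]) ||
      any(x < axes$cycle_range[1]) || any(x > axes$cycle_range[2])) {
    warning("trace exceeds axes range; clipping")
    y <- pmin(pmax(y, axes$fluor_range[1]), axes$fluor_range[2])
    x <- pmin(pmax(x, axes$cycle_range[1]), axes$cycle_range[2])
  }
  # dense sampling along each polyline segment guarantees a connected stroke
  n_sub <- 4L * max(axes$width, axes$height)
  tt <- seq(0, 1, length.out = n_sub)
  xs <- as.vector(vapply(seq_len(length(x) - 1L),
                         function(i) x[i] + tt * (x[i + 1L] - x[i]),
                         numeric(n_sub)))
  ys <- as.vector(vapply(seq_len(length(y) - 1L),
                         function(i) y[i] + tt * (y[i + 1L] - y[i]),
                         numeric(n_sub)))
  col <- 1L + floor((xs - axes$cycle_range[1]) /
                      diff(axes$cycle_range) * (axes$width - 1e-9))
  frac <- (ys - axes$fluor_range[1]) / diff(axes$fluor_range)
  row <- axes$height - floor(frac * (axes$height - 1e-9))
  img <- matrix(0, axes$height, axes$width)
  img[cbind(pmin(pmax(row, 1L), axes$height),
            pmin(pmax(col, 1L), axes$width))] <- 1
  structure(img, class = c("curve_image", "matrix", "array"),
            well_id = trace$well_id)
}

#' Build a labeled image dataset from traces
#'
#' Renders every trace with the shared axes and labels it `high` if its true
#' concentration exceeds `threshold` ng/mL, `low` otherwise. A concentration
#' exactly at the threshold is assigned `low` and reported via a message.
#'
#' @param traces List of [fluorescence_trace()].
#' @param concentrations True concentration per trace, ng/mL.
#' @param threshold Decision threshold in ng/mL (default 5, the clinical
#'   high/low leptin cut).
#' @param axes Optional [axes_spec()]; defaults to axes covering all traces.
#' @return A list of class `curve_dataset`: `images` (matrix `[h*w, N]`),
#'   `labels` (factor `low`/`high`), `concentrations`, `well_ids`, `axes`.
#' @export
build_dataset <- function(traces, concentrations, threshold = 5,
                          axes = NULL) {
  if (length(traces) != length(concentrations))
    stop_peakfluo("one concentration per trace is required")
  if (length(traces) == 0L)
    stop_peakfluo("empty trace list")
  if (is.null(axes)) axes <- axes_for_traces(traces)
  if (any(concentrations == threshold))
    message(sum(concentrations == threshold),
            " trace(s) exactly at the threshold assigned to class 'low'")
  imgs <- vapply(traces, function(tr)
    as.vector(render_curve_image(tr, axes)),
    numeric(axes$height * axes$width))
  labels <- factor(ifelse(concentrations > threshold, "high", "low"),
                   levels = c("low", "high"))
  structure(list(images = imgs, labels = labels,
                 concentrations = as.numeric(concentrations),
                 well_ids = vapply(traces, `[[`, "", "well_id"),
                 axes = axes),
            class = "curve_dataset")
}

#' Simulate the curve-classification corpus
#'
#' Generates amplification curves with the composition of the assay's
#' validation corpus: by default 278 curves, 201 from concentrations above
#' the 5 ng/mL threshold and 77 below, drawn log-uniformly inside
#' well-separated high/low concentration bands, each curve simulated with
#' its own process-noise realization.
#'
#' @param n_high,n_low Curves per class (defaults 201 and 77).
#' @param cfg A [sim_config()]; its noise settings apply.
#' @param low_range,high_range Concentration bands in ng/mL.
#' @param seed Integer seed.
#' @param threshold Labeling threshold passed to [build_dataset()].
#' @return A `curve_dataset`.
#' @export
make_cnn_dataset <- function(n_high = 201L, n_low = 77L, cfg = sim_config(),
                             low_range = c(0.1, 1), high_range = c(8, 12),
                             seed = 1L, threshold = 5) {
  concs <- with_seed(derive_seed(seed, "cnn_concs"), {
    c(exp(stats::runif(n_low, log(low_range[1]), log(low_range[2]))),
      exp(stats::runif(n_high, log(high_range[1]), log(high_range[2]))))
  })
  traces <- with_seed(derive_seed(seed, "cnn_traces"), {
    lapply(seq_along(concs), function(i) {
      pn <- if (cfg$noise_sd_process > 0)
        cumsum(stats::rnorm(cfg$n_cycles, 0, cfg$noise_sd_process))
      else numeric(cfg$n_cycles)
      simulate_trace(concs[i], cfg, pn, well_id = sprintf("curve%03d", i))
    })
  })
  build_dataset(traces, concs, threshold = threshold)
}

#' Construct the 6-layer CNN
#'
#' Exactly the stated stack: convolution, max-pooling, convolution,
#' max-pooling, flatten, dense. The dense layer outputs a single sigmoid
#' probability of class `high`. Hyperparameters: 16 and 32 filters of 3x3
#' with ReLU, 2x2 pooling, He initialization.
#'
#' @param input_shape Height and width of the input images.
#' @param filters Filter counts of the two convolution layers.
#' @param kernel Convolution kernel size.
#' @param seed Seed for weight initialization.
#' @return A list of class `cnn_model`; `$layers` gives the layer-type
#'   sequence.
#' @export
build_cnn <- function(input_shape = c(32L, 32L), filters = c(16L, 32L),
                      kernel = 3L, seed = 1L) {
  dims <- cnn_dims(input_shape, as.integer(filters), as.integer(kernel))
  structure(list(
    layers = c("conv", "maxpool", "conv", "maxpool", "flatten", "dense"),
    dims = dims,
    idx1 = im2col_idx(dims$H, dims$W, 1L, dims$kernel),
    pidx1 = pool_idx(dims$H1, dims$W1, dims$filters[1]),
    idx2 = im2col_idx(dims$Hp1, dims$Wp1, dims$filters[1], dims$kernel),
    pidx2 = pool_idx(dims$H2, dims$W2, dims$filters[2]),
    params = cnn_init_params(dims, seed),
    seed = as.integer(seed)
  ), class = "cnn_model")
}

#' Number of trainable parameters
#' @param model A [build_cnn()] model.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' Predict class probabilities
#'
#' @param model A (trained) [build_cnn()] model.
#' @param dataset A `curve_dataset`, or an image matrix `[h*w, N]`.
#' @return Probability of class `high` per image.
#' @export
classify_predict <- function(model, dataset) {
  X <- if (inherits(dataset, "curve_dataset")) dataset$images else dataset
  cnn_forward_full(model, X)$prob
}

#' Train the CNN on a dataset
#'
#' @param model A [build_cnn()] model.
#' @param dataset A `curve_dataset`.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Seed for shuffling (weight initialization is seeded in
#'   [build_cnn()]).
#' @return The model with trained parameters and a `history` of epoch
#'   losses.
#' @export
classify_train <- function(model, dataset, epochs = 12L, batch_size = 32L,
                           lr = 1e-3, seed = 1L) {
  stopifnot(inherits(dataset, "curve_dataset"))
  y <- as.integer(dataset$labels == "high")
  cnn_train_params(model, dataset$images, y, epochs = epochs,
                   batch_size = batch_size, lr = lr, seed = seed)
}

#' Stratified fold assignment
#'
#' Shuffles within each class and deals class members round-robin over the k
#' folds, so every fold's class counts match the global ratio within one
#' sample. The dealing start rotates between classes so that the leftover
#' samples of different classes land in different folds, keeping total fold
#' sizes within one of each other as well.
#'
#' @param labels Factor of class labels.
#' @param k Number of folds.
#' @param seed Seed for the within-class shuffles.
#' @return Integer fold id (1..k) per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  if (k < 2L) stop_peakfluo("k must be >= 2")
  if (min(table(labels)) < k)
    stop_peakfluo("k exceeds the minority class size")
  fold <- integer(length(labels))
  start <- 0L
  with_seed(seed, {
    for (cl in levels(factor(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- (seq_along(idx) - 1L + start) %% k + 1L
      start <- (start + length(idx)) %% k
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the CNN
#'
#' Trains k models, each on k-1 folds, and evaluates accuracy and binary
#' cross-entropy on the held-out fold. Stratification compensates for class
#' imbalance; everything (fold assignment, weight initialization, shuffling)
#' is driven by `seed`.
#'
#' @param dataset A `curve_dataset` containing both classes.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param epochs,batch_size,lr Training settings per fold.
#' @param input_shape Image shape; defaults to the dataset's axes.
#' @return A list of class `cv_report`: `folds` (per-fold accuracy/loss),
#'   `mean_accuracy`, `sd_accuracy`, `mean_loss`, `sd_loss`,
#'   `fold_assignment`, `seed`.
#' @export
cross_validate <- function(dataset, k = 10L, seed = 1L, epochs = 12L,
                           batch_size = 32L, lr = 1e-3,
                           input_shape = NULL) {
  stopifnot(inherits(dataset, "curve_dataset"))
  if (nlevels(droplevels(dataset$labels)) < 2L)
    stop_peakfluo("cross-validation requires both classes in the dataset")
  if (is.null(input_shape))
    input_shape <- c(dataset$axes$height, dataset$axes$width)
  y <- as.integer(dataset$labels == "high")
  fold <- stratified_folds(dataset$labels, k, seed = derive_seed(seed, "folds"))
  res <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- build_cnn(input_shape, seed = derive_seed(seed, paste0("init", f)))
    model <- cnn_train_params(model, dataset$images[, tr, drop = FALSE],
                              y[tr], epochs = epochs,
                              batch_size = batch_size, lr = lr,
                              seed = derive_seed(seed, paste0("train", f)))
    prob <- cnn_forward_full(model, dataset$images[, !tr, drop = FALSE])$prob
    yte <- y[!tr]
    eps <- 1e-12
    data.frame(fold = f,
               n_test = sum(!tr),
               accuracy = mean((prob > 0.5) == (yte == 1L)),
               loss = -mean(yte * log(prob + eps) +
                              (1 - yte) * log(1 - prob + eps)))
  })
  folds <- do.call(rbind, res)
  structure(list(folds = folds,
                 mean_accuracy = mean(folds$accuracy),
                 sd_accuracy = stats::sd(folds$accuracy),
                 mean_loss = mean(folds$loss),
                 sd_loss = stats::sd(folds$loss),
                 fold_assignment = fold, seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold stratified CV: accuracy %.3f +/- %.3f, loss %.3f +/- %.3f\n",
              nrow(x$folds), x$mean_accuracy, x$sd_accuracy,
              x$mean_loss, x$sd_loss))
  invisible(x)
}
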