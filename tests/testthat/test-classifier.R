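test_that("render_curve_image is deterministic and geometric", {
  ax <- axes_spec(c(1, 40), c(0, 1200))
  tr <- simulate_trace(1, cfg_noisefree(), numeric(40), "w")
  i1 <- render_curve_image(tr, ax)
  i2 <- render_curve_image(tr, ax)
  expect_identical(unclass(i1), unclass(i2))
  expect_true(all(i1 %in% c(0, 1)))
  expect_identical(dim(i1), c(32L, 32L))
  # flat trace at mid-range: exactly one nonzero row spanning all columns
  flat <- fluorescence_trace("f", rep(600, 40))
  fi <- render_curve_image(flat, ax)
  expect_equal(sum(rowSums(fi) > 0), 1)
  expect_true(all(fi[rowSums(fi) > 0, ] == 1))
  # a sigmoid covers strictly more columns than a half-span flat segment
  half <- fluorescence_trace("h", rep(600, 20))
  hi <- render_curve_image(half, ax)
  expect_true(sum(colSums(i1) > 0) > sum(colSums(hi) > 0))
  # out-of-range traces clip with a warning
  expect_warning(render_curve_image(fluorescence_trace("c", rep(2000, 40)),
                                    ax), "clip")
})

test_that("rendering is invariant to a common multiplicative rescale when axes follow the data", {
  cfg <- sim_config(seed = 9L)
  design <- panel(replicates = 1L)
  plate <- simulate_plate(design, cfg)
  scaled <- lapply(plate, function(tr)
    fluorescence_trace(tr$well_id, tr$fluorescence * 3.7))
  ax1 <- axes_for_traces(plate)
  ax2 <- axes_for_traces(scaled)
  for (w in names(plate)) {
    expect_identical(unclass(render_curve_image(plate[[w]], ax1)),
                     unclass(render_curve_image(scaled[[w]], ax2)))
  }
  # with a FIXED axes spec the same rescale does change the pixels
  expect_false(identical(
    unclass(render_curve_image(plate$std1_r1, ax1)),
    unclass(suppressWarnings(render_curve_image(scaled$std1_r1, ax1)))))
})

test_that("build_dataset labels at the 5 ng/mL threshold", {
  cfg <- cfg_noisefree()
  concs <- c(0.1, 1, 5, 10)
  trs <- lapply(seq_along(concs), function(i)
    simulate_trace(concs[i], cfg, numeric(cfg$n_cycles), paste0("w", i)))
  expect_message(ds <- build_dataset(trs, concs), "threshold")
  expect_equal(as.character(ds$labels), c("low", "low", "low", "high"))
  expect_error(build_dataset(list(), numeric(0)), "empty")
  expect_error(build_dataset(trs, c(1, 2)), "one concentration per trace")
})

test_that("stratified folds preserve the class ratio within one sample", {
  labels <- factor(rep(c("high", "low"), c(201, 77)),
                   levels = c("low", "high"))
  fold <- stratified_folds(labels, 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  per_fold_n <- table(fold)
  expect_true(all(per_fold_n %in% 27:28))
  per_fold_high <- tapply(labels == "high", fold, sum)
  expect_true(all(per_fold_high %in% 20:21))   # 201/10 within one sample
  expect_identical(stratified_folds(labels, 10, seed = 3), fold)
  expect_error(stratified_folds(labels, 100), "minority")
})

test_that("build_cnn exposes the six-layer architecture", {
  m1 <- build_cnn(seed = 4)
  expect_identical(m1$layers,
                   c("conv", "maxpool", "conv", "maxpool", "flatten", "dense"))
  m2 <- build_cnn(seed = 4)
  expect_identical(m1$params, m2$params)        # seeded construction
  expect_true(is.finite(n_params(m1)) && n_params(m1) > 0)
  # probability contract for arbitrary inputs
  X <- matrix(runif(32 * 32 * 3), 32 * 32, 3)
  p <- classify_predict(m1, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(build_cnn(c(6, 6)), "too small")
})

test_that("backpropagation matches numerical gradients", {
  model <- build_cnn(c(10, 10), filters = c(2, 3), seed = 7)
  set.seed(88)
  X <- matrix(runif(100 * 4), 100, 4)
  y <- c(1, 0, 1, 0)
  lg <- peakfluo:::cnn_loss_grads(model, X, y)
  num_grad <- function(nm, i) {
    eps <- 1e-6
    up <- model; up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- model; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    (peakfluo:::cnn_loss_grads(up, X, y)$loss -
        peakfluo:::cnn_loss_grads(dn, X, y)$loss) / (2 * eps)
  }
  for (nm in names(model$params)) {
    idx <- sample(length(model$params[[nm]]), min(4, length(model$params[[nm]])))
    ana <- lg$grads[[nm]][idx]
    num <- vapply(idx, function(i) num_grad(nm, i), numeric(1))
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("cross-validation separates a well-separated small corpus deterministically", {
  ds <- make_cnn_dataset(n_high = 30, n_low = 12, seed = 5)
  r1 <- cross_validate(ds, k = 3, seed = 5, epochs = 6)
  expect_true(r1$mean_accuracy >= 0.9)
  r2 <- cross_validate(ds, k = 3, seed = 5, epochs = 6)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
  expect_identical(r1$folds, r2$folds)
  # single-class dataset refuses
  one <- ds
  one$labels <- factor(rep("high", length(ds$labels)),
                       levels = c("low", "high"))
  expect_error(cross_validate(one, k = 3), "both classes")
})
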