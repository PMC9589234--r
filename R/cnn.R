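#' CNN configuration
#'
#' Defines the classifier: three convolutional layers, two 2x2 max-pooling
#' stages (after conv1 and conv2), and three fully connected layers ending
#' in a single sigmoid unit whose output is the AI score in \[0, 1\].
#' Defaults follow the reference design: a 400 x 400 single-channel
#' input, an 11x11/128 first convolution and a 5x5/256 second convolution.
#' The third convolution's shape and the pooling/stride geometry are free
#' choices; the defaults complete the census with a 3x3/256 layer and an
#' AlexNet-style stride of 4 on the first convolution (the 11x11/128 +
#' 5x5/256 pairing is the AlexNet convention, and stride 1 at 400 x 400
#' would make the first fully connected layer infeasibly large).
#'
#' @param input input image side in pixels (default 400).
#' @param kernel integer vector of 3 kernel sides (default c(11, 5, 3)).
#' @param filters integer vector of 3 filter counts (default c(128, 256, 256)).
#' @param stride integer vector of 3 conv strides (default c(4, 1, 1)).
#' @param fc widths of the first two fully connected layers (default
#'   c(128, 32)); the third has one sigmoid unit.
#' @param dropout dropout rate on the fully connected layers (default 0.5).
#' @param l2 L2 weight-decay coefficient on the fully connected layers
#'   (default 1e-4).
#' @param lr learning rate (default 1e-4; 1e-3 is the alternative the
#'   original description also reports).
#' @param batch minibatch size (default 32).
#' @param epochs training iterations (default 20).
#' @param augment logical; when `TRUE` each training presentation applies a
#'   seeded random circular time shift and (with probability 1/2) a time
#'   reversal to the image. Resting EEG is stationary within a window, so
#'   both transforms preserve the label while multiplying the effective
#'   training set; validation and prediction always see unaltered images.
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @param select how [select_best_epoch()] reads "the highest accuracy of
#'   the two": `"min"` maximizes min(train, val) (default, conservative);
#'   `"val"` maximizes validation accuracy alone.
#' @return a `cnn_config` list (includes derived layer sizes).
#' @export
cnn_config <- function(input = 400, kernel = c(11, 5, 3),
                       filters = c(128, 256, 256), stride = c(4, 1, 1),
                       fc = c(128, 32), dropout = 0.5, l2 = 1e-4,
                       lr = 1e-4, batch = 32, epochs = 20, augment = FALSE,
                       seed = 1L, select = c("min", "val")) {
  stopifnot(length(kernel) == 3, length(filters) == 3, length(stride) == 3,
            length(fc) == 2, epochs >= 1, batch >= 1,
            dropout >= 0, dropout < 1, is.logical(augment), length(augment) == 1)
  o1 <- (input - kernel[1]) %/% stride[1] + 1
  p1 <- o1 %/% 2
  o2 <- (p1 - kernel[2]) %/% stride[2] + 1
  p2 <- o2 %/% 2
  o3 <- (p2 - kernel[3]) %/% stride[3] + 1
  if (o1 < 2 || o2 < 2 || o3 < 1)
    stop("input too small for the configured kernels/strides")
  cfg <- list(input = as.integer(input), kernel = as.integer(kernel),
              filters = as.integer(filters), stride = as.integer(stride),
              fc = as.integer(fc), dropout = dropout, l2 = l2, lr = lr,
              batch = as.integer(batch), epochs = as.integer(epochs),
              augment = isTRUE(augment),
              seed = as.integer(seed), select = match.arg(select),
              dims = list(o1 = o1, p1 = p1, o2 = o2, p2 = p2, o3 = o3,
                          flat = o3 * o3 * filters[3]))
  class(cfg) <- "cnn_config"
  cfg
}

#' A reduced CNN configuration for small pilot runs
#'
#' Same topology as [cnn_config()] but sized for 100 x 100 inputs with few
#' filters, so a full 10-fold experiment trains in minutes on one CPU.
#' @param ... overrides passed to [cnn_config()].
#' @export
cnn_config_reduced <- function(...) {
  args <- utils::modifyList(
    list(input = 100, kernel = c(9, 5, 3), filters = c(8, 16, 16),
         stride = c(3, 1, 1), fc = c(32, 16), dropout = 0, l2 = 1e-4,
         lr = 0.2, batch = 8, epochs = 90, augment = TRUE),
    list(...))
  do.call(cnn_config, args)
}

#' Number of trainable parameters for a configuration
#' @param config a `cnn_config`.
#' @return integer parameter count.
#' @export
count_params <- function(config) {
  k <- config$kernel; f <- config$filters; d <- config$dims
  fc <- config$fc
  sum(c(k[1]^2 * 1 * f[1] + f[1],
        k[2]^2 * f[1] * f[2] + f[2],
        k[3]^2 * f[2] * f[3] + f[3],
        d$flat * fc[1] + fc[1],
        fc[1] * fc[2] + fc[2],
        fc[2] * 1 + 1))
}

#' Build an (untrained) model: seeded He-initialized weights
#'
#' @param config a `cnn_config`.
#' @return a `cnn_model` list with `config`, `params`, empty `history`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  he <- function(fan_in, nr, nc) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  k <- config$kernel; f <- config$filters; d <- config$dims; fc <- config$fc
  params <- list(
    cW1 = he(k[1]^2, k[1]^2 * 1, f[1]),       cb1 = numeric(f[1]),
    cW2 = he(k[2]^2 * f[1], k[2]^2 * f[1], f[2]), cb2 = numeric(f[2]),
    cW3 = he(k[3]^2 * f[2], k[3]^2 * f[2], f[3]), cb3 = numeric(f[3]),
    fW1 = he(d$flat, d$flat, fc[1]),          fb1 = numeric(fc[1]),
    fW2 = he(fc[1], fc[1], fc[2]),            fb2 = numeric(fc[2]),
    fW3 = he(fc[2], fc[2], 1),                fb3 = numeric(1))
  structure(list(config = config, params = params, history = NULL,
                 snapshots = NULL),
            class = "cnn_model")
}

# stack a list of images (or pixel matrices) into an input array scaled to
# [-1, 1]; accepts integer 0..255 matrices or already-scaled numerics.
images_to_array <- function(images, input) {
  n <- length(images)
  arr <- array(0, dim = c(input, input, max(n, 1)))
  for (i in seq_len(n)) {
    im <- images[[i]]
    if (!is.matrix(im) || nrow(im) != input || ncol(im) != input)
      stop(sprintf("image %d is not %d x %d", i, input, input))
    if (is.integer(im) || max(im) > 1.5) im <- (im - 127.5) / 127.5
    arr[, , i] <- im
  }
  arr
}

#' Train the CNN by stochastic gradient descent
#'
#' Runs `config$epochs` iterations of seeded minibatch SGD with binary
#' cross-entropy loss, recording training and validation accuracy after
#' every iteration and (by default) a weight snapshot per iteration so the
#' optimal iteration can be selected afterwards.
#'
#' @param model a `cnn_model` from [build_model()].
#' @param train_images,val_images lists of pixel matrices.
#' @param train_labels,val_labels 0/1 vectors (1 = positive class).
#' @param keep_snapshots keep per-epoch weights (default TRUE).
#' @return the trained `cnn_model` with `history` (data.frame epoch, loss,
#'   train_acc, val_acc) and `snapshots`.
#' @export
train_model <- function(model, train_images, train_labels,
                        val_images = list(), val_labels = numeric(0),
                        keep_snapshots = TRUE) {
  stopifnot(inherits(model, "cnn_model"))
  if (length(unique(train_labels)) < 2)
    stop("training set must contain both classes")
  cfg <- model$config
  tx <- images_to_array(train_images, cfg$input)
  vx <- if (length(val_images))
    images_to_array(val_images, cfg$input) else
    array(0, dim = c(cfg$input, cfg$input, 0))
  res <- cpp_cnn_train(cfg, model$params, tx, as.numeric(train_labels),
                       vx, as.numeric(val_labels),
                       cfg$epochs, cfg$seed, keep_snapshots)
  model$params <- res$final
  model$history <- data.frame(epoch = seq_len(cfg$epochs),
                              loss = res$history[, 1],
                              train_acc = res$history[, 2],
                              val_acc = res$history[, 3])
  if (keep_snapshots) model$snapshots <- res$snapshots
  model
}

#' Compute AI scores for images
#'
#' @param model a `cnn_model`.
#' @param images a single pixel matrix or a list of them.
#' @return numeric vector of scores in \[0, 1\]; the classification label
#'   is `score >= 0.5`.
#' @export
predict_ai_score <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.matrix(images)) images <- list(images)
  arr <- images_to_array(images, model$config$input)
  as.numeric(cpp_cnn_predict(model$config, model$params, arr))
}

#' Select the optimal training iteration from the accuracy history
#'
#' The optimal model is the iteration with the highest accuracy; with the
#' default `"min"` statistic that is read conservatively as the iteration
#' maximizing min(train accuracy, validation accuracy), with `"val"` as the
#' iteration maximizing validation accuracy. Ties break to the earliest
#' iteration.
#'
#' @param history data.frame with `train_acc` and `val_acc` columns.
#' @param statistic `"min"` or `"val"`.
#' @return 1-based epoch index.
#' @export
select_best_epoch <- function(history, statistic = c("min", "val")) {
  statistic <- match.arg(statistic)
  if (is.null(history) || nrow(history) == 0) stop("empty training history")
  crit <- if (statistic == "min") {
    v <- history$val_acc
    v[is.na(v)] <- history$train_acc[is.na(v)]
    pmin(history$train_acc, v)
  } else {
    history$val_acc
  }
  which.max(crit)                     # which.max ties -> earliest
}

#' Restore the weights of a given training iteration
#' @param model trained `cnn_model` with snapshots.
#' @param epoch 1-based iteration index.
#' @return the model with that iteration's weights as current parameters.
#' @export
restore_epoch <- function(model, epoch) {
  if (is.null(model$snapshots)) stop("model was trained without snapshots")
  model$params <- model$snapshots[[epoch]]
  model$selected_epoch <- epoch
  model
}
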