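## Compact 2-D CNN: architecture definition, parameter accounting, Adam
## training with early stopping, and inference.  The default architecture
## is four (conv -> ReLU -> max-pool -> dropout) blocks with 32/64/128/128
## filters (kernels 3x3 then 3x1, same padding, pools 2x2/2x2/2x2/3x2),
## flatten (3072 features), dropout, dense(96, ReLU), dense(1, sigmoid).
## Sigmoid scores near 1 indicate normal rhythm, near 0 disease.

#' Model configuration
#'
#' @param input_shape image input shape, default `c(96, 96, 1)`.
#' @param conv_filters filters per conv block, default `c(32, 64, 128, 128)`.
#' @param conv_kernels list of `(kh, kw)` kernels, default
#'   `list(c(3,3), c(3,1), c(3,1), c(3,1))` ('same' padding throughout).
#' @param pool_sizes list of `(ph, pw)` max-pool sizes, default
#'   `list(c(2,2), c(2,2), c(2,2), c(3,2))`; spatial dims shrink by floor
#'   division, so the default schedule maps 96x96 to 4x6 before flatten.
#' @param dense_units width of the fully connected layer (default 96).
#' @param dropout five dropout rates (after each block and after flatten),
#'   each within \[0.25, 0.50\]; default `c(0.25, 0.25, 0.4, 0.5, 0.5)`.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 32).
#' @param epochs training epochs (default 40; with early stopping the
#'   effective run is usually shorter once validation loss plateaus).
#' @param val_split fraction held out for validation (default 0.2).
#' @param patience early-stopping patience on validation loss (default 8).
#' @param seed integer seed fixing weight initialization, shuffling and
#'   dropout (default 7).
#' @return a validated list of class `"model_config"`.
#' @export
modelConfig <- function(input_shape = c(96L, 96L, 1L),
                        conv_filters = c(32L, 64L, 128L, 128L),
                        conv_kernels = list(c(3L, 3L), c(3L, 1L),
                                            c(3L, 1L), c(3L, 1L)),
                        pool_sizes = list(c(2L, 2L), c(2L, 2L),
                                          c(2L, 2L), c(3L, 2L)),
                        dense_units = 96L,
                        dropout = c(0.25, 0.25, 0.40, 0.50, 0.50),
                        learning_rate = 1e-3, batch_size = 32L,
                        epochs = 40L, val_split = 0.2, patience = 8L,
                        seed = 7L) {
  nb <- length(conv_filters)
  if (length(conv_kernels) != nb || length(pool_sizes) != nb)
    stop_config("conv_kernels and pool_sizes must match conv_filters in length")
  if (length(dropout) != nb + 1L)
    stop_config("dropout needs one rate per conv block plus one after flatten")
  if (any(dropout < 0.25 | dropout > 0.50))
    stop_config("dropout rates must lie within [0.25, 0.50]")
  if (length(input_shape) != 3L || input_shape[3] != 1L)
    stop_config("input_shape must be c(height, width, 1)")
  structure(list(
    input_shape = as.integer(input_shape),
    conv_filters = as.integer(conv_filters),
    conv_kernels = lapply(conv_kernels, as.integer),
    pool_sizes = lapply(pool_sizes, as.integer),
    dense_units = as.integer(dense_units),
    dropout = as.numeric(dropout),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), val_split = val_split,
    patience = as.integer(patience), seed = as.integer(seed)
  ), class = "model_config")
}

## spatial dims after each block (same-padding convs, floor-division pools)
.layer_shapes <- function(config) {
  H <- config$input_shape[1]; W <- config$input_shape[2]; C <- 1L
  shapes <- vector("list", length(config$conv_filters))
  for (l in seq_along(config$conv_filters)) {
    p <- config$pool_sizes[[l]]
    Hp <- H %/% p[1]; Wp <- W %/% p[2]
    if (Hp < 1L || Wp < 1L)
      stop_config("pooling schedule incompatible with input shape at block %d", l)
    shapes[[l]] <- list(in_h = H, in_w = W, in_c = C,
                        out_h = Hp, out_w = Wp, out_c = config$conv_filters[l])
    H <- Hp; W <- Wp; C <- config$conv_filters[l]
  }
  attr(shapes, "flat") <- H * W * C
  shapes
}

.arch_list <- function(config) {
  list(
    H = config$input_shape[1], W = config$input_shape[2],
    kh = vapply(config$conv_kernels, `[`, integer(1), 1L),
    kw = vapply(config$conv_kernels, `[`, integer(1), 2L),
    pool_h = vapply(config$pool_sizes, `[`, integer(1), 1L),
    pool_w = vapply(config$pool_sizes, `[`, integer(1), 2L),
    filters = config$conv_filters,
    dense_units = config$dense_units,
    dropout = config$dropout
  )
}

.glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow = nrow, ncol = ncol)
}

#' Build the CNN
#'
#' Initializes Glorot-uniform weights (reproducibly, from `config$seed`)
#' for the architecture described by `config` and returns an untrained
#' model handle.  With the default configuration the flattened feature
#' count is 3072 (a 4x6 map with 128 channels).
#'
#' @param config a [modelConfig()] list.
#' @return an untrained [CNNModel-class].
#' @examples
#' m <- buildModel(modelConfig())
#' countParameters(m)$per_layer
#' @export
buildModel <- function(config = modelConfig()) {
  if (!inherits(config, "model_config"))
    stop_config("config must come from modelConfig()")
  shapes <- .layer_shapes(config)              # errors if pools don't fit
  flat <- attr(shapes, "flat")
  set.seed(config$seed)
  weights <- list()
  for (l in seq_along(config$conv_filters)) {
    k <- config$conv_kernels[[l]]
    Cin <- shapes[[l]]$in_c
    Fl <- config$conv_filters[l]
    fan_in <- k[1] * k[2] * Cin
    weights[[paste0("W", l)]] <- .glorot(Fl, fan_in, fan_in, Fl)
    weights[[paste0("b", l)]] <- numeric(Fl)
  }
  weights$Wd <- .glorot(config$dense_units, flat, flat, config$dense_units)
  weights$bd <- numeric(config$dense_units)
  weights$Wo <- .glorot(1L, config$dense_units, config$dense_units, 1L)
  weights$bo <- 0
  new("CNNModel", config = unclass(config), weights = weights,
      history = data.frame(), trained = FALSE)
}

#' Per-layer trainable-parameter report
#'
#' Counts trainable parameters per layer both from the closed-form
#' identities (conv: `(kh*kw*in_channels + 1) * filters`; dense:
#' `(fan_in + 1) * units`) and from the dimensions of the stored weight
#' arrays; the two must agree.
#'
#' @param model a [CNNModel-class].
#' @return list with `per_layer` (named counts for conv1..convN, dense and
#'   output), `core_total` (sum over the conv layers and the hidden dense
#'   layer) and `grand_total` (including the 1-unit output layer).
#' @examples
#' countParameters(buildModel(modelConfig()))$core_total  # 375520
#' @export
countParameters <- function(model) {
  if (!is(model, "CNNModel")) stop_argument("model must be a CNNModel")
  cfg <- model@config
  shapes <- .layer_shapes(cfg)
  flat <- attr(shapes, "flat")
  per <- integer()
  for (l in seq_along(cfg$conv_filters)) {
    k <- cfg$conv_kernels[[l]]
    closed <- (k[1] * k[2] * shapes[[l]]$in_c + 1L) * cfg$conv_filters[l]
    stored <- length(model@weights[[paste0("W", l)]]) +
      length(model@weights[[paste0("b", l)]])
    if (closed != stored)
      stop_argument("parameter bookkeeping mismatch in conv%d", l)
    per[paste0("conv", l)] <- closed
  }
  dense <- (flat + 1L) * cfg$dense_units
  stopifnot(dense == length(model@weights$Wd) + length(model@weights$bd))
  per["dense"] <- dense
  out <- cfg$dense_units + 1L
  stopifnot(out == length(model@weights$Wo) + length(model@weights$bo))
  per["output"] <- out
  list(per_layer = per,
       core_total = sum(per[names(per) != "output"]),
       grand_total = sum(per))
}

## coerce patches (list of ImagePatch / 3-d array / matrix) to H x W x N
.image_array <- function(images, config) {
  H <- config$input_shape[1]; W <- config$input_shape[2]
  if (is(images, "ImagePatch")) images <- list(images)
  if (is.list(images)) {
    mats <- lapply(images, function(im) {
      if (is(im, "ImagePatch")) im@pixels else as.matrix(im)
    })
    images <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  }
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1L))
  d <- dim(images)
  if (length(d) != 3L || d[1] != H || d[2] != W)
    stop_argument("images must be %dx%d (got %s)", H, W,
                  paste(d[1:2], collapse = "x"))
  images
}

.encode_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop_argument("numeric labels must be 0/1")
    return(as.numeric(labels))
  }
  if (!all(labels %in% c("norm", "afib")))
    stop_argument("labels must be 'norm' or 'afib'")
  as.numeric(labels == "norm")     # sigmoid ~1 = normal, ~0 = disease
}

#' Train the CNN
#'
#' Minimizes binary cross-entropy with Adam over shuffled minibatches,
#' holding out a stratified validation split, with early stopping on
#' validation loss (best weights restored).  All randomness (shuffling,
#' dropout, validation split) derives from `config$seed`, so a fixed seed
#' reproduces the history exactly.
#'
#' @param model an untrained or trained [CNNModel-class].
#' @param images training images: list of [ImagePatch-class] or an
#'   `H x W x N` array.
#' @param labels per-image labels (`"norm"`/`"afib"` or 1/0, 1 = norm).
#' @param epochs,batch_size,learning_rate,val_split,patience optional
#'   overrides of the model config.
#' @param verbose print per-epoch progress.
#' @return the fitted [CNNModel-class] with a populated training history.
#' @export
trainModel <- function(model, images, labels, epochs = NULL,
                       batch_size = NULL, learning_rate = NULL,
                       val_split = NULL, patience = NULL, verbose = FALSE) {
  if (!is(model, "CNNModel")) stop_argument("model must be a CNNModel")
  cfg <- model@config
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
  if (!is.null(batch_size)) cfg$batch_size <- as.integer(batch_size)
  if (!is.null(learning_rate)) cfg$learning_rate <- learning_rate
  if (!is.null(val_split)) cfg$val_split <- val_split
  if (!is.null(patience)) cfg$patience <- as.integer(patience)

  X <- .image_array(images, cfg)
  y <- .encode_labels(labels)
  N <- dim(X)[3]
  if (length(y) != N) stop_argument("one label per image required")
  if (length(unique(y)) < 2L)
    stop_slecg("slecg_validation_error",
               "training data must contain both classes")

  if (cfg$epochs == 0L) {
    model@history <- data.frame()
    return(model)
  }

  set.seed(cfg$seed)
  arch <- .arch_list(cfg)

  # stratified validation split
  idx0 <- which(y == 0); idx1 <- which(y == 1)
  v0 <- sample(idx0, max(1L, round(cfg$val_split * length(idx0))))
  v1 <- sample(idx1, max(1L, round(cfg$val_split * length(idx1))))
  val <- sort(c(v0, v1))
  tr <- setdiff(seq_len(N), val)
  Xval <- X[, , val, drop = FALSE]; yval <- y[val]

  w <- model@weights
  mom <- lapply(w, function(p) array(0, dim = dim(p) %||% length(p)))
  vel <- mom
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0

  hist <- data.frame()
  best_loss <- Inf; best_w <- w; wait <- 0L

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      bidx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      res <- .cnn_run(unname(w), arch, X[, , bidx, drop = FALSE], y[bidx],
                      TRUE, sample.int(.Machine$integer.max, 1L), TRUE)
      g <- res$grads
      t <- t + 1
      for (nm in names(w)) {
        gn <- g[[nm]]
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gn
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gn^2
        mhat <- mom[[nm]] / (1 - b1^t)
        vhat <- vel[[nm]] / (1 - b2^t)
        w[[nm]] <- w[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + res$loss * length(bidx)
      ep_correct <- ep_correct + sum((res$scores >= 0.5) == (y[bidx] == 1))
    }
    vres <- .cnn_run(unname(w), arch, Xval, yval, FALSE, 0L, FALSE)
    row <- data.frame(
      epoch = ep,
      loss = ep_loss / length(ord),
      accuracy = ep_correct / length(ord),
      val_loss = vres$loss,
      val_accuracy = mean((vres$scores >= 0.5) == (yval == 1)))
    hist <- rbind(hist, row)
    if (verbose)
      message(sprintf(
        "epoch %2d  loss %.4f acc %.3f  val_loss %.4f val_acc %.3f",
        ep, row$loss, row$accuracy, row$val_loss, row$val_accuracy))
    if (row$val_loss < best_loss - 1e-6) {
      best_loss <- row$val_loss; best_w <- w; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model@weights <- best_w
  model@history <- hist
  model@trained <- TRUE
  model@config <- cfg
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score images with the CNN
#'
#' Runs the forward pass with dropout disabled and returns one sigmoid
#' score per image, in input order; scores near 1 indicate normal rhythm,
#' near 0 disease.  Repeated calls on the same input give identical
#' scores.
#'
#' @param model a [CNNModel-class].
#' @param images an [ImagePatch-class], list of patches, or `H x W x N`
#'   array.
#' @return numeric vector of scores in \[0, 1\].
#' @export
predictSegment <- function(model, images) {
  if (!is(model, "CNNModel")) stop_argument("model must be a CNNModel")
  X <- .image_array(images, model@config)
  res <- .cnn_run(unname(model@weights), .arch_list(model@config), X,
                  NULL, FALSE, 0L, FALSE)
  res$scores
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file RDS snapshots of the model handle (config,
#' weights, history).
#'
#' @param model a [CNNModel-class].
#' @param path checkpoint file path.
#' @return `saveModel`: `path` invisibly; `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  if (!is(model, "CNNModel")) stop_argument("model must be a CNNModel")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop_config("no such model checkpoint: %s", path)
  m <- readRDS(path)
  if (!is(m, "CNNModel")) stop_format("'%s' is not a model checkpoint", path)
  m
}
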