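#' Residual network configuration
#'
#' Mirrors the layer table of the image classifier: an opening 7x7, 64-channel
#' convolution with stride 2, then eight residual blocks of paired 3x3
#' convolutions with channel widths 64, 64, 128, 128, 256, 256, 512, 128
#' (max-pooling after the first two blocks), and a head of global average
#' pooling plus a 3-way softmax. The drop from 512 back to 128 channels in
#' the final block follows the printed layer table; `monotone = TRUE`
#' switches that block to 512 channels for the conventional widening-only
#' profile.
#'
#' @param side input image side; a multiple of 8, at least 32 (default 64).
#' @param monotone use the monotone channel profile (default `FALSE`).
#' @param seed integer seed for weight initialisation.
#' @return an `rpnet_config` list.
#' @export
rpnet_config <- function(side = 64, monotone = FALSE, seed = 1) {
  widths <- c(64L, 64L, 64L, 128L, 128L, 256L, 256L, 512L,
              if (monotone) 512L else 128L)
  structure(list(side = as.integer(side), widths = widths,
                 seed = as.integer(seed)),
            class = "rpnet_config")
}

#' Build the residual recurrence-image classifier
#'
#' Weight initialisation is deterministic given `config$seed`: two builds
#' from the same config have identical parameters.
#'
#' @param config an [rpnet_config()].
#' @return an `rpnet` model object.
#' @export
build_rpnet <- function(config = rpnet_config()) {
  stopifnot(inherits(config, "rpnet_config"))
  ptr <- rpnet_new(config$side, config$widths, config$seed)
  structure(list(ptr = ptr, config = config, trained = FALSE), class = "rpnet")
}

#' @export
print.rpnet <- function(x, ...) {
  cat(sprintf("<rpnet> side %d, widths %s, %s parameters%s\n",
              x$config$side, paste(x$config$widths, collapse = "/"),
              format(n_parameters(x), big.mark = ","),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Number of trainable parameters (including batch-norm scales/offsets)
#' @param model an `rpnet`.
#' @return integer-valued scalar.
#' @export
n_parameters <- function(model) rpnet_param_count(model$ptr)

# Coerce a list of side x side matrices (or an array) to a (side, side, n)
# array, checking sides against the model.
as_image_array <- function(images, side) {
  if (is.list(images)) {
    n <- length(images)
    arr <- array(0, c(side, side, n))
    for (i in seq_len(n)) {
      m <- as.matrix(images[[i]])
      if (!all(dim(m) == side))
        stop("image ", i, " is ", nrow(m), "x", ncol(m),
             " but the model expects ", side, "x", side)
      arr[, , i] <- m
    }
    arr
  } else if (is.matrix(images)) {
    if (!all(dim(images) == side))
      stop("image is ", nrow(images), "x", ncol(images),
           " but the model expects ", side, "x", side)
    array(images, c(side, side, 1))
  } else {
    arr <- images
    d <- dim(arr)
    if (length(d) != 3 || d[1] != side || d[2] != side)
      stop("images must be a ", side, "x", side, "xN array")
    arr
  }
}

state_to_int <- function(labels) {
  idx <- match(as.character(labels), eeg_states)
  if (anyNA(idx))
    stop("labels must be among: ", paste(eeg_states, collapse = ", "))
  idx - 1L
}

#' Train the recurrence-image classifier
#'
#' Adam with cross-entropy loss on a stratified train/validation split drawn
#' with the given seed; mini-batch order is reshuffled each epoch from the
#' same seed, so a rerun reproduces the trajectory.
#'
#' @param model an `rpnet` from [build_rpnet()].
#' @param images list of matrices or a `(side, side, n)` array, values
#'   nominally in \[0, 1\].
#' @param labels state labels (`calm`/`transitional`/`morbidity`), length n.
#' @param epochs training epochs (default 30).
#' @param batch mini-batch size (default 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed controlling the split and batch order.
#' @param val_fraction held-out fraction per class (default 0.25; 0 disables
#'   validation).
#' @return the model, with a `report` entry: per-epoch train loss, train and
#'   validation accuracy, the validation indices, and the seed.
#' @export
train_rpnet <- function(model, images, labels, epochs = 30, batch = 16,
                        lr = 1e-3, seed = 1, val_fraction = 0.25) {
  stopifnot(inherits(model, "rpnet"))
  if (epochs < 1) stop("epochs must be >= 1")
  arr <- as_image_array(images, model$config$side)
  y <- state_to_int(labels)
  if (length(y) != dim(arr)[3]) stop("one label per image required")
  if (length(unique(y)) < 2)
    stop("training needs at least 2 classes; got only '",
         eeg_states[unique(y) + 1], "'")
  val_idx <- integer(0)
  with_seed(seed, {
    if (val_fraction > 0) {
      for (k in unique(y)) {
        ik <- which(y == k)
        n_val <- max(1L, round(val_fraction * length(ik)))
        val_idx <- c(val_idx, sample(ik, n_val))
      }
    }
    val_idx <- sort(val_idx)
  })
  train_idx <- setdiff(seq_along(y), val_idx)
  rep <- rpnet_train_cpp(model$ptr, arr, y, train_idx - 1L, val_idx - 1L,
                         as.integer(epochs), as.integer(batch), lr,
                         as.integer(seed))
  model$trained <- TRUE
  model$report <- list(train_loss = rep$train_loss, train_acc = rep$train_acc,
                       val_acc = rep$val_acc, epochs = epochs, seed = seed,
                       val_idx = val_idx)
  model
}

#' Classify recurrence images
#'
#' @param model a trained `rpnet`.
#' @param images one matrix, a list of matrices, or a `(side, side, n)`
#'   array.
#' @return an n-by-3 matrix of class probabilities, columns
#'   `calm`/`transitional`/`morbidity`, each row on the simplex.
#' @export
predict_re <- function(model, images) {
  stopifnot(inherits(model, "rpnet"))
  arr <- as_image_array(images, model$config$side)
  p <- rpnet_predict_cpp(model$ptr, arr)
  colnames(p) <- eeg_states
  p
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file holding the configuration, the training
#' report and all weights and batch-norm statistics; loading rebuilds the
#' network and restores them.
#'
#' @param model an `rpnet`.
#' @param path file path.
#' @export
save_rpnet <- function(model, path) {
  saveRDS(list(config = model$config, trained = model$trained,
               report = model$report, state = rpnet_get_weights(model$ptr)),
          path)
  invisible(path)
}

#' @rdname save_rpnet
#' @export
load_rpnet <- function(path) {
  st <- readRDS(path)
  model <- build_rpnet(st$config)
  rpnet_set_weights(model$ptr, st$state)
  model$trained <- st$trained
  model$report <- st$report
  model
}

#' Extract or restore the raw network state
#'
#' `rpnet_state` returns every weight matrix and batch-norm running
#' statistic in a fixed traversal order; `rpnet_restore` writes such a
#' state back into a model of the same architecture. Used by the
#' checkpoint I/O and by diagnostics that manipulate weights directly.
#'
#' @param model an `rpnet`.
#' @return `rpnet_state`: list with `weights` and `running` entries.
#' @export
rpnet_state <- function(model) rpnet_get_weights(model$ptr)

#' @rdname rpnet_state
#' @param state a list produced by `rpnet_state`.
#' @export
rpnet_restore <- function(model, state) {
  rpnet_set_weights(model$ptr, state)
  invisible(model)
}

#' Zero out all residual branches (diagnostic)
#'
#' Multiplies every residual-branch output scale by `factor`; with
#' `factor = 0` the forward pass equals the shortcut-only computation,
#' which is how the identity-mapping property of the blocks is verified.
#'
#' @param model an `rpnet`.
#' @param factor scale factor.
#' @return the model, invisibly.
#' @export
scale_residual_branches <- function(model, factor) {
  rpnet_scale_residual(model$ptr, factor)
  invisible(model)
}
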