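#' Architecture settings for the two-pathway seed classifier
#'
#' The classifier fuses two branches run on the same 4-channel chip: a
#' VGG16-style branch (13 stacked 3x3 convolutions with 5 max-pools, then —
#' replacing the huge original fully connected head — a 7x7 valid convolution
#' with 512 channels followed by two 512-unit fully connected layers) and a
#' ResNet50-style branch (bottleneck residual blocks in the 3-4-6-3
#' configuration, global average pooling, one 512-unit fully connected
#' layer). The two 512-vectors are concatenated into a 1,024-dimensional
#' fused feature, mapped by a final fully connected layer to the two classes
#' and a softmax. `width_multiplier` scales every channel count (including
#' the branch embeddings) so reduced models train on a CPU in minutes;
#' 1.0 reproduces the printed architecture.
#'
#' @param input_channels image channels (4 = RGB + NIR).
#' @param input_size chip side length; the VGG branch requires the value to
#'   reach a 7x7 map after five pools (224).
#' @param width_multiplier channel scaling in `(0, 1]`.
#' @param n_classes number of classes (>= 2).
#' @param branch_embed_dim per-branch embedding width before scaling.
#' @param fused_dim concatenated feature width; must equal
#'   `2 * branch_embed_dim`.
#' @param pretrained_init `"none"` (random He initialization) or
#'   `"imagenet-adapted"`, in which case first-layer RGB kernels must be
#'   supplied to [set_first_conv()] after adaptation with
#'   [adapt_pretrained_first_layer()]; the package never downloads weights.
#' @return A validated `arch_spec` object.
#' @export
arch_spec <- function(input_channels = 4, input_size = 224,
                      width_multiplier = 1.0, n_classes = 2,
                      branch_embed_dim = 512, fused_dim = 2 * branch_embed_dim,
                      pretrained_init = c("none", "imagenet-adapted")) {
  pretrained_init <- match.arg(pretrained_init)
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop_invalid("`width_multiplier` must lie in (0, 1]")
  if (n_classes < 2) stop_invalid("`n_classes` must be >= 2")
  if (fused_dim != 2 * branch_embed_dim)
    stop_invalid("`fused_dim` must equal 2 * branch_embed_dim")
  structure(list(input_channels = input_channels, input_size = input_size,
                 width_multiplier = width_multiplier, n_classes = n_classes,
                 branch_embed_dim = branch_embed_dim, fused_dim = fused_dim,
                 pretrained_init = pretrained_init),
            class = "arch_spec")
}

#' Build the two-pathway network
#'
#' @param spec an [arch_spec()].
#' @param rng_seed seed for He-normal weight initialization.
#' @param classes class labels in index order (first = output unit 1).
#' @return A `corn_seed_net` object holding the network, its spec and (after
#'   [csn_train()]) the training history.
#' @export
corn_seed_net <- function(spec = arch_spec(), rng_seed = 1,
                          classes = c("good", "bad")) {
  stopifnot(inherits(spec, "arch_spec"))
  if (length(classes) != spec$n_classes)
    stop_invalid("`classes` must name each output unit")
  ptr <- csn_build_(spec$input_channels, spec$input_size, spec$n_classes,
                    spec$width_multiplier, spec$branch_embed_dim,
                    as.integer(rng_seed))
  structure(list(ptr = ptr, spec = spec, classes = classes,
                 history = NULL, rng_seed = rng_seed),
            class = "corn_seed_net")
}

layer_table <- function(raw, branch) {
  bind_rows(lapply(raw, function(r)
    tibble(branch = branch, type = r$type, stage = r$stage, note = r$note,
           out_channels = r$out_channels, out_h = r$out_h, out_w = r$out_w,
           kernel = r$kernel, stride = r$stride, params = r$params)))
}

#' Layer-by-layer description of a built network
#'
#' One row per layer (residual blocks are expanded), with branch, stage
#' (`trunk` / `head` / `fusion`), kernel geometry and parameter counts —
#' the basis for the architecture audits.
#'
#' @param model a [corn_seed_net()].
#' @return A tibble of layers plus attributes `embed_dim` and `fused_dim`.
#' @export
describe_net <- function(model) {
  stopifnot(inherits(model, "corn_seed_net"))
  d <- csn_describe_(model$ptr)
  out <- bind_rows(layer_table(d$vgg, "vgg"),
                   layer_table(d$resnet, "resnet"),
                   layer_table(d$head, "fusion"))
  attr(out, "embed_dim") <- d$embed_dim
  attr(out, "fused_dim") <- d$fused_dim
  out
}

#' @export
print.corn_seed_net <- function(x, ...) {
  lt <- describe_net(x)
  cat(sprintf(
    "<corn_seed_net> %dx%dx%d input, width %.2f, fused dim %d, %d classes\n",
    x$spec$input_size, x$spec$input_size, x$spec$input_channels,
    x$spec$width_multiplier, attr(lt, "fused_dim"), x$spec$n_classes))
  cat(sprintf("  parameters: %s  (vgg %s, resnet %s)\n",
              format(sum(lt$params), big.mark = ","),
              format(sum(lt$params[lt$branch == "vgg"]), big.mark = ","),
              format(sum(lt$params[lt$branch == "resnet"]), big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final test accuracy %.3f\n",
                nrow(x$history), tail(x$history$test_accuracy, 1)))
  invisible(x)
}

#' Softmax probabilities
#'
#' `y_m = exp(z_m) / sum_k exp(z_k)`, computed with max-subtraction for
#' numerical stability; the output sums to exactly 1.
#'
#' @param z numeric vector of finite scores.
#' @return Probability vector of the same length.
#' @export
softmax <- function(z) {
  if (any(!is.finite(z))) stop_invalid("softmax requires finite scores")
  e <- exp(z - max(z))
  e / sum(e)
}

#' Categorical cross-entropy
#'
#' `L = -sum_i log(y_i, true)` over the batch (natural log; probabilities are
#' clipped at 1e-12 before the log). `reduce = "mean"` divides by the batch
#' size, the convention used during training.
#'
#' @param probs `n x k` matrix of per-class probabilities (rows sum to 1).
#' @param one_hot `n x k` 0/1 matrix with a single 1 per row.
#' @param reduce `"sum"` (the printed formula) or `"mean"`.
#' @return The scalar loss.
#' @export
cross_entropy <- function(probs, one_hot, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  probs <- rbind(probs); one_hot <- rbind(one_hot)
  if (!all(dim(probs) == dim(one_hot)))
    stop_invalid("`probs` and `one_hot` must have identical shapes")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop_invalid("each probability row must sum to 1")
  L <- -sum(one_hot * log(pmax(probs, 1e-12)))
  if (reduce == "mean") L / nrow(probs) else L
}

#' Training configuration
#'
#' Defaults follow the settings that trained the final model: SGD with
#' momentum 0.9, initial learning rate 0.001, and halving of the learning
#' rate once the test loss stops decreasing (patience of 3 epochs here; the
#' halving factor is fixed at 0.5).
#'
#' @param optimizer `"sgd"` or `"adam"`.
#' @param momentum SGD momentum.
#' @param learning_rate initial learning rate (> 0).
#' @param epochs training epochs (>= 1).
#' @param plateau_patience epochs without test-loss improvement before the
#'   learning rate is halved.
#' @param lr_halving_factor fixed at 0.5.
#' @param batch_size minibatch size.
#' @param loss_reduction `"mean"` (default) divides the batch cross-entropy
#'   by the batch size, the convention deep-learning frameworks pair with
#'   their published learning rates; `"sum"` applies the batch-summed loss of
#'   the printed formula (identical up to a constant factor on the learning
#'   rate).
#' @param rng_seed seed controlling shuffling (and hence the whole run).
#' @return A validated `training_config` object.
#' @export
training_config <- function(optimizer = c("sgd", "adam"), momentum = 0.9,
                            learning_rate = 0.001, epochs = 100,
                            plateau_patience = 3, lr_halving_factor = 0.5,
                            batch_size = 32, loss_reduction = c("mean", "sum"),
                            rng_seed = 1) {
  optimizer <- match.arg(optimizer)
  loss_reduction <- match.arg(loss_reduction)
  if (learning_rate <= 0) stop_invalid("`learning_rate` must be > 0")
  if (epochs < 1) stop_invalid("`epochs` must be >= 1")
  if (lr_halving_factor != 0.5)
    stop_invalid("the plateau schedule halves the learning rate; `lr_halving_factor` is fixed at 0.5")
  structure(list(optimizer = optimizer, momentum = momentum,
                 learning_rate = learning_rate, epochs = epochs,
                 plateau_patience = plateau_patience,
                 lr_halving_factor = lr_halving_factor,
                 batch_size = batch_size, loss_reduction = loss_reduction,
                 rng_seed = rng_seed),
            class = "training_config")
}

#' Plateau learning-rate schedule
#'
#' Given the sequence of per-epoch test losses, returns the learning rate in
#' force during each epoch: after `patience` consecutive epochs without
#' improvement over the best test loss so far, the rate is halved (and the
#' stall counter reset).
#'
#' @param test_losses numeric vector of per-epoch test losses.
#' @param lr0 initial learning rate.
#' @param patience epochs without improvement before halving.
#' @param factor halving factor (0.5).
#' @return Numeric vector: the learning rate used in each epoch.
#' @export
plateau_schedule <- function(test_losses, lr0, patience = 3, factor = 0.5) {
  lr <- lr0; best <- Inf; stall <- 0L
  out <- numeric(length(test_losses))
  for (i in seq_along(test_losses)) {
    out[i] <- lr
    if (test_losses[i] < best - 1e-12) {
      best <- test_losses[i]; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) { lr <- lr * factor; stall <- 0L }
    }
  }
  out
}

chips_to_array <- function(chips, idx, size, channels) {
  array(unlist(chips$pixels[idx], use.names = FALSE),
        c(size, size, channels, length(idx)))
}

labels_to_index <- function(labels, classes) {
  i <- match(labels, classes)
  if (anyNA(i))
    stop_invalid(sprintf("labels outside %s", paste(classes, collapse = "/")))
  as.integer(i - 1L)
}

eval_in_batches <- function(model, chips, batch_size) {
  n <- nrow(chips)
  sz <- model$spec$input_size; ch <- model$spec$input_channels
  y <- labels_to_index(chips$label, model$classes)
  loss <- 0; acc <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    r <- csn_eval_batch_(model$ptr, chips_to_array(chips, idx, sz, ch), y[idx])
    loss <- loss + r$loss * length(idx)
    acc <- acc + r$accuracy * length(idx)
  }
  list(loss = loss / n, accuracy = acc / n)
}

#' Train the two-pathway network
#'
#' Minibatch training with the configured optimizer; after each epoch the
#' test set is evaluated and the plateau schedule may halve the learning
#' rate. Runs are deterministic under `config$rng_seed` (shuffling uses R's
#' RNG; the numerical backend is deterministic for a fixed thread count).
#' A non-finite loss aborts with a diagnostic.
#'
#' @param model a [corn_seed_net()].
#' @param train_chips,test_chips chip tibbles with `label` and `pixels`; both
#'   must be non-empty and the training set must contain every class.
#' @param config a [training_config()].
#' @return The model, with `$history` a tibble of per-epoch `epoch`, `lr`,
#'   `train_loss`, `train_accuracy`, `test_loss`, `test_accuracy`.
#' @export
csn_train <- function(model, train_chips, test_chips,
                      config = training_config()) {
  stopifnot(inherits(model, "corn_seed_net"), inherits(config, "training_config"))
  if (nrow(train_chips) == 0 || nrow(test_chips) == 0)
    stop_invalid("train and test sets must be non-empty")
  if (!all(model$classes %in% train_chips$label))
    stop_invalid("training set must contain every class")
  sz <- model$spec$input_size; ch <- model$spec$input_channels
  y_train <- labels_to_index(train_chips$label, model$classes)
  n <- nrow(train_chips)
  lr <- config$learning_rate; best <- Inf; stall <- 0L
  hist <- vector("list", config$epochs)
  with_seed(config$rng_seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tl <- 0; ta <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        r <- csn_train_batch_(
          model$ptr, chips_to_array(train_chips, idx, sz, ch), y_train[idx],
          list(optimizer = config$optimizer, learning_rate = lr,
               momentum = config$momentum,
               loss_reduction = config$loss_reduction))
        tl <- tl + r$loss * length(idx); ta <- ta + r$accuracy * length(idx)
      }
      ev <- eval_in_batches(model, test_chips, config$batch_size)
      hist[[epoch]] <- tibble(epoch = epoch, lr = lr,
                              train_loss = tl / n, train_accuracy = ta / n,
                              test_loss = ev$loss, test_accuracy = ev$accuracy)
      if (ev$loss < best - 1e-12) { best <- ev$loss; stall <- 0L }
      else {
        stall <- stall + 1L
        if (stall >= config$plateau_patience) { lr <- lr * 0.5; stall <- 0L }
      }
    }
  })
  model$history <- bind_rows(hist)
  model
}

#' Classify chips
#'
#' Batched inference; batch prediction equals chip-by-chip prediction.
#'
#' @param object a trained [corn_seed_net()].
#' @param chips a chip tibble (or a single `H x W x 4` array).
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return A tibble with one row per chip: the chip's id, `pred_label`,
#'   `prob` (probability of the predicted class) and one `prob_<class>`
#'   column per class (rows sum to 1).
#' @export
predict.corn_seed_net <- function(object, chips, batch_size = 32, ...) {
  if (is.array(chips))
    chips <- tibble(chip_id = 1L, label = NA_character_, pixels = list(chips))
  sz <- object$spec$input_size; ch <- object$spec$input_channels
  n <- nrow(chips)
  probs <- matrix(0, n, object$spec$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    probs[idx, ] <- csn_predict_(object$ptr,
                                 chips_to_array(chips, idx, sz, ch))
  }
  colnames(probs) <- paste0("prob_", object$classes)
  pred <- object$classes[max.col(probs, ties.method = "first")]
  id <- if ("chip_id" %in% names(chips)) chips$chip_id
        else if ("instance_id" %in% names(chips)) chips$instance_id
        else seq_len(n)
  out <- tibble(chip_id = id, pred_label = pred,
                prob = probs[cbind(seq_len(n), max.col(probs, ties.method = "first"))])
  bind_cols(out, as_tibble(probs))
}

#' @importFrom dplyr bind_cols
NULL

#' Adapt pretrained 3-channel first-layer kernels to 4 channels
#'
#' Copies the R, G, B kernels unchanged and initializes the NIR kernel as
#' their mean — one reading of how an ImageNet-pretrained first layer can
#' drive a 4-channel input without changing any other layer.
#'
#' @param rgb_kernels `kh x kw x 3 x n_out` array of first-layer kernels.
#' @return A `kh x kw x 4 x n_out` array.
#' @export
adapt_pretrained_first_layer <- function(rgb_kernels) {
  d <- dim(rgb_kernels)
  if (length(d) != 4 || d[3] != 3)
    stop_invalid("`rgb_kernels` must be a kh x kw x 3 x n_out array")
  out <- array(0, c(d[1], d[2], 4, d[4]))
  out[, , 1:3, ] <- rgb_kernels
  out[, , 4, ] <- (rgb_kernels[, , 1, ] + rgb_kernels[, , 2, ] +
                     rgb_kernels[, , 3, ]) / 3
  out
}

#' Set a branch's first convolution kernels
#'
#' @param model a [corn_seed_net()].
#' @param branch `"vgg"` or `"resnet"`.
#' @param kernels `kh x kw x input_channels x n_out` array, e.g. from
#'   [adapt_pretrained_first_layer()].
#' @return The model, invisibly.
#' @export
set_first_conv <- function(model, branch = c("vgg", "resnet"), kernels) {
  branch <- match.arg(branch)
  d <- dim(kernels)
  cur <- csn_first_conv_weights_(model$ptr, if (branch == "resnet") "res" else "vgg")
  if (length(d) != 4 || prod(d[1:3]) != nrow(cur) || d[4] != ncol(cur))
    stop_invalid(sprintf("kernel array must be %s per output, %d outputs",
                         nrow(cur), ncol(cur)))
  w <- matrix(kernels, nrow = prod(d[1:3]), ncol = d[4])
  csn_set_first_conv_weights_(model$ptr, if (branch == "resnet") "res" else "vgg", w)
  invisible(model)
}

#' Save / load a trained model
#'
#' Checkpoints hold the architecture settings, class labels, all weights
#' (including batch-norm running statistics) and the training history; a
#' restored model predicts identically.
#'
#' @param model a [corn_seed_net()].
#' @param path checkpoint path (`.rds`).
#' @return `save_model()`: `path`, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "corn_seed_net"))
  saveRDS(list(spec = model$spec, classes = model$classes,
               rng_seed = model$rng_seed, history = model$history,
               weights = csn_weights_(model$ptr)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  st <- readRDS(path)
  model <- corn_seed_net(st$spec, rng_seed = st$rng_seed %||% 1,
                         classes = st$classes)
  csn_set_weights_(model$ptr, st$weights)
  model$history <- st$history
  model
}

#' @export
tidy.corn_seed_net <- function(x, ...) {
  x$history %||% tibble(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), train_accuracy = numeric(),
                        test_loss = numeric(), test_accuracy = numeric())
}

#' @export
glance.corn_seed_net <- function(x, ...) {
  lt <- describe_net(x)
  h <- x$history
  tibble(n_parameters = sum(lt$params),
         fused_dim = attr(lt, "fused_dim"),
         epochs_trained = if (is.null(h)) 0L else nrow(h),
         train_accuracy = if (is.null(h)) NA_real_ else tail(h$train_accuracy, 1),
         test_accuracy = if (is.null(h)) NA_real_ else tail(h$test_accuracy, 1))
}

#' @export
autoplot.corn_seed_net <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(
    h[, c("epoch", "train_loss", "test_loss", "train_accuracy", "test_accuracy")],
    -"epoch", names_to = c("set", "metric"), names_sep = "_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL)
}
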