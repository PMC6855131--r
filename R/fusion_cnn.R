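# Strategy 3: voxel-level integration with a one-dimensional convolutional
# network. The input of a subject is laid out as modality-channels x
# voxels; the convolution has kernel width 1 along the voxel axis and spans
# the modality channels, so each of the filters produces a new "map" that
# is a per-voxel linear combination of the input maps (followed by ReLU).
# The filter maps are flattened into a fully connected ReLU layer and a
# two-node softmax output. Training is plain SGD with momentum and weight
# decay on the cross-entropy loss; everything is implemented with dense
# matrix algebra, so fits are exactly reproducible from the seed.

#' Hyperparameters of the 1D-CNN fusion model
#'
#' Defaults are the reference configuration: 10 filters of kernel width 1,
#' 50 hidden units, 50 epochs, batch size 4, learning rate 0.001, momentum
#' 0.9, weight decay 0.0005, ReLU activations.
#'
#' @param n_filters Convolution filters.
#' @param kernel_width Kernel width along the voxel axis; only width 1
#'   (within-voxel channel mixing) is supported.
#' @param hidden_units Fully connected hidden layer size.
#' @param epochs Training epochs (full passes over the training set).
#' @param batch_size Mini-batch size.
#' @param learning_rate,momentum,weight_decay SGD hyperparameters.
#' @param seed Integer seed for initialization and batch shuffling.
#' @return A `cnn_spec`.
#' @export
cnn_spec <- function(n_filters = 10, kernel_width = 1, hidden_units = 50,
                     epochs = 50, batch_size = 4, learning_rate = 0.001,
                     momentum = 0.9, weight_decay = 0.0005, seed = 1L) {
  vals <- c(n_filters, kernel_width, hidden_units, epochs, batch_size,
            learning_rate, momentum, weight_decay)
  if (any(vals[1:6] <= 0) || momentum < 0 || weight_decay < 0)
    stop_mmfuse("CNN hyperparameters must be positive", "mmfuse_config_error")
  if (kernel_width != 1)
    stop_mmfuse("only kernel width 1 (within-voxel channel mixing) is supported",
                "mmfuse_config_error")
  structure(list(n_filters = as.integer(n_filters), kernel_width = 1L,
                 hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, activation = "relu",
                 seed = as.integer(seed)),
            class = "cnn_spec")
}

#' Total trainable parameter count of the CNN
#' @param n_voxels,n_modalities Input dimensions.
#' @param spec A [cnn_spec()].
#' @return Integer parameter count
#'   `F(MK+1) + H(FV+1) + 2(H+1)` for F filters, kernel width K, H hidden
#'   units, V voxels, M modalities.
#' @export
cnn_parameter_count <- function(n_voxels, n_modalities, spec = cnn_spec()) {
  f <- spec$n_filters; h <- spec$hidden_units; k <- spec$kernel_width
  f * (n_modalities * k + 1) + h * (f * n_voxels + 1) + 2 * (h + 1)
}

#' Build (initialize) a CNN fusion model
#'
#' Weights are He-uniform initialized deterministically from `spec$seed`;
#' biases start at zero. The modality channel order is recorded in the
#' model.
#'
#' @param n_voxels,n_modalities Input dimensions (>= 1).
#' @param spec A [cnn_spec()].
#' @param modality_names Optional channel-order record.
#' @return A `cnn_model` with weights `Wc` (modalities x filters), `bc`,
#'   `W1` ((filters*voxels) x hidden), `b1`, `W2` (hidden x 2), `b2`.
#' @export
build_cnn <- function(n_voxels, n_modalities, spec = cnn_spec(),
                      modality_names = NULL) {
  if (n_voxels < 1 || n_modalities < 1)
    stop_mmfuse("n_voxels and n_modalities must be >= 1", "mmfuse_argument_error")
  f <- spec$n_filters; h <- spec$hidden_units
  set.seed(spec$seed)
  he <- function(nr, nc, fan_in)
    matrix(stats::runif(nr * nc, -sqrt(6 / fan_in), sqrt(6 / fan_in)), nr, nc)
  structure(list(
    Wc = he(n_modalities, f, n_modalities),
    bc = rep(0, f),
    W1 = he(f * n_voxels, h, f * n_voxels),
    b1 = rep(0, h),
    W2 = he(h, 2, h),
    b2 = rep(0, 2),
    n_voxels = as.integer(n_voxels), n_modalities = as.integer(n_modalities),
    modality_names = modality_names, spec = spec, loss_log = numeric(0)),
    class = "cnn_model")
}

check_cnn_input <- function(model, x_list) {
  if (!is.list(x_list) || length(x_list) != model$n_modalities)
    stop_mmfuse("input must be a list with one matrix per modality channel",
                "mmfuse_shape_error")
  n <- nrow(x_list[[1]])
  for (x in x_list)
    if (!is.matrix(x) || nrow(x) != n || ncol(x) != model$n_voxels)
      stop_mmfuse("input shape does not match the model", "mmfuse_shape_error")
  n
}

# Forward pass; returns intermediates for backprop when `keep = TRUE`.
# Filter maps are held as one n x (F*V) matrix whose column blocks
# ((j-1)*V + v) match the row layout of W1, so the hidden layer and its
# gradients are single BLAS calls.
cnn_forward <- function(model, x_list, keep = FALSE) {
  f <- ncol(model$Wc); v <- model$n_voxels
  n <- nrow(x_list[[1]])
  pre <- matrix(0, n, f * v)
  for (j in seq_len(f)) {
    s <- matrix(model$bc[j], n, v)
    for (m in seq_along(x_list)) s <- s + model$Wc[m, j] * x_list[[m]]
    pre[, ((j - 1) * v + 1):(j * v)] <- s
  }
  act <- pmax(pre, 0)
  z1 <- act %*% model$W1 + matrix(model$b1, n, length(model$b1), byrow = TRUE)
  h1 <- pmax(z1, 0)
  out <- sweep(h1 %*% model$W2, 2, model$b2, "+")
  # numerically stable softmax
  mx <- apply(out, 1, max)
  e <- exp(out - mx)
  p <- e / rowSums(e)
  if (keep) list(p = p, h1 = h1, z1 = z1, pre = pre, act = act) else list(p = p)
}

#' Predict patient probabilities with a CNN model
#'
#' @param model A `cnn_model`.
#' @param x_list List of modality matrices (subjects x voxels) in the
#'   model's channel order, preprocessed as in training.
#' @return Patient-node softmax probability per subject.
#' @export
predict_cnn <- function(model, x_list) {
  check_cnn_input(model, x_list)
  as.numeric(cnn_forward(model, x_list)$p[, 2])
}

#' Train a CNN fusion model by SGD
#'
#' Cross-entropy on the two-node softmax output, SGD with momentum and
#' weight decay, fixed epoch/batch schedule, shuffling seeded from
#' `spec$seed`. The per-epoch mean training loss is logged in
#' `$loss_log`; a non-finite loss aborts with a diagnostic.
#'
#' @param x_list List of modality matrices (subjects x voxels),
#'   standardized per voxel-channel from training statistics.
#' @param labels Binary labels (1 = patient).
#' @param spec A [cnn_spec()].
#' @param model Optional pre-built model (e.g. for warm starts); default is
#'   [build_cnn()] from the input dimensions.
#' @return The trained `cnn_model`.
#' @export
train_cnn <- function(x_list, labels, spec = cnn_spec(), model = NULL) {
  if (is.null(model))
    model <- build_cnn(ncol(x_list[[1]]), length(x_list), spec,
                       names(x_list))
  n <- check_cnn_input(model, x_list)
  if (length(unique(labels)) < 2)
    stop_mmfuse("training data contains a single class", "mmfuse_single_class_error")
  f <- ncol(model$Wc); v <- model$n_voxels
  lr <- spec$learning_rate; mom <- spec$momentum; wd <- spec$weight_decay
  vel <- lapply(model[c("Wc", "bc", "W1", "b1", "W2", "b2")],
                function(w) w * 0)
  set.seed(derive_seed(spec$seed, "cnn-shuffle"))
  for (epoch in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
    ep_loss <- 0
    for (b in batches) {
      xb <- lapply(x_list, function(x) x[b, , drop = FALSE])
      yb <- labels[b]
      nb <- length(b)
      fw <- cnn_forward(model, xb, keep = TRUE)
      pi <- pmin(pmax(fw$p[cbind(seq_len(nb), yb + 1L)], 1e-12), 1)
      ep_loss <- ep_loss - sum(log(pi))
      yhot <- matrix(0, nb, 2)
      yhot[cbind(seq_len(nb), yb + 1L)] <- 1
      d_out <- (fw$p - yhot) / nb
      g <- list(
        W2 = crossprod(fw$h1, d_out),
        b2 = colSums(d_out))
      d_z1 <- tcrossprod(d_out, model$W2) * (fw$z1 > 0)
      g$b1 <- colSums(d_z1)
      g$W1 <- crossprod(fw$act, d_z1)
      d_pre <- tcrossprod(d_z1, model$W1) * (fw$pre > 0)
      g$Wc <- matrix(0, nrow(model$Wc), f)
      g$bc <- numeric(f)
      for (j in seq_len(f)) {
        cols <- ((j - 1) * v + 1):(j * v)
        dp <- d_pre[, cols, drop = FALSE]
        for (m in seq_along(xb)) g$Wc[m, j] <- sum(xb[[m]] * dp)
        g$bc[j] <- sum(dp)
      }
      for (w in names(vel)) {
        vel[[w]] <- mom * vel[[w]] - lr * (g[[w]] + wd * model[[w]])
        model[[w]] <- model[[w]] + vel[[w]]
      }
    }
    ep_loss <- ep_loss / n
    if (!is.finite(ep_loss))
      stop_mmfuse(sprintf("CNN training diverged at epoch %d (non-finite loss)",
                          epoch), "mmfuse_divergence_error")
    model$loss_log <- c(model$loss_log, ep_loss)
  }
  model
}

#' Cross-validated CNN fusion
#'
#' Per fold: residualize every modality with train-only confound models,
#' standardize each voxel-channel by training mean/SD, train the CNN on the
#' training rows, score the test rows. Outputs feed [accuracy_summary()]
#' and [redundancy_matrix()] unchanged.
#'
#' @param cohort A `multimodal_cohort`.
#' @param spec A [cnn_spec()].
#' @param foldplan The shared [make_folds()] plan.
#' @param modalities Channel order (default: all cohort modalities).
#' @return A `prediction_table` with source and algorithm `"cnn_1d"`.
#' @export
cross_validate_cnn <- function(cohort, spec = cnn_spec(), foldplan,
                               modalities = names(cohort$data)) {
  check_foldplan(cohort, foldplan)
  tables <- lapply(seq_len(foldplan$n_folds), function(k) {
    train <- foldplan$assignment != k
    test <- which(!train)
    preps <- lapply(modalities, function(mod)
      preprocess_fit(cohort$data[[mod]][train, , drop = FALSE],
                     cohort$age[train], cohort$sex[train]))
    names(preps) <- modalities
    xs_train <- lapply(modalities, function(mod)
      preprocess_apply(preps[[mod]], cohort$data[[mod]][train, , drop = FALSE],
                       cohort$age[train], cohort$sex[train]))
    xs_test <- lapply(modalities, function(mod)
      preprocess_apply(preps[[mod]], cohort$data[[mod]][test, , drop = FALSE],
                       cohort$age[test], cohort$sex[test]))
    names(xs_train) <- names(xs_test) <- modalities
    sp <- spec
    sp$seed <- derive_seed(spec$seed, "cnn", k)
    model <- train_cnn(xs_train, cohort$labels[train], sp)
    probs <- predict_cnn(model, xs_test)
    new_prediction_table(cohort$subject_id[test], k, "cnn_1d", "cnn_1d",
                         probs, cohort$labels[test])
  })
  do.call(bind_predictions, tables)
}

#' Serialize CNN weights and training log
#'
#' Writes a JSON file with all weight matrices (full double precision),
#' dimensions, channel order and the per-epoch loss log.
#'
#' @param model A `cnn_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cnn_model <- function(model, path) {
  payload <- list(Wc = model$Wc, bc = model$bc, W1 = model$W1, b1 = model$b1,
                  W2 = model$W2, b2 = model$b2,
                  n_voxels = model$n_voxels, n_modalities = model$n_modalities,
                  modality_names = model$modality_names,
                  spec = unclass(model$spec), loss_log = model$loss_log)
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}
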