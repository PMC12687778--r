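#' Residual classifier configuration
#'
#' Describes a 2D or 3D residual convolutional severity classifier. The
#' `resnet50` preset follows the classic 50-layer bottleneck stage plan
#' (stages of 3, 4, 6 and 3 bottleneck blocks); the `small` preset is a
#' desk-scale residual network (one stem convolution plus two basic residual
#' stages) suitable for training on modest grids without accelerators; the
#' `linear` preset is a flattened linear scorer, mainly useful for analytic
#' checks of the saliency machinery. `width_scale` multiplies every channel
#' count, so parameter counts in convolutional layers scale approximately
#' with its square.
#'
#' @param dimensionality 2 (slice classifier) or 3 (volume classifier).
#' @param depth_preset `"small"`, `"resnet50"` or `"linear"`.
#' @param width_scale positive channel multiplier.
#' @param head output head: `"softmax"` (2 logits), `"tanh"` or `"sigmoid"`
#'   (single unit), or `"feature"` (the classification layer is replaced by a
#'   fully connected layer of `feature_dim` units whose output feeds a
#'   kNN/SVM hybrid; a softmax layer on top is used for gradient training).
#' @param feature_dim width of the feature layer; required iff
#'   `head = "feature"`.
#' @param activation activation plan. `"energy"` (default): squared
#'   rectifier on the stem with an identity (linear) residual trunk -- the
#'   network is an energy model whose input Jacobian factorises into the
#'   local stem response times a fixed spatial readout, which keeps
#'   attribution voxel-local and free of subject-level gain.
#'   `"energy_relu"`: squared-rectifier stem with a rectified trunk.
#'   `"relu"`: plain rectifier throughout (the classic deep-net choice;
#'   note its input gradients spread over entire receptive fields).
#' @param seed weight-initialisation seed.
#' @return An object of class `model_config`.
#' @export
model_config <- function(dimensionality = 3,
                         depth_preset = c("small", "resnet50", "linear"),
                         width_scale = 1,
                         head = c("softmax", "tanh", "sigmoid", "feature"),
                         feature_dim = NULL,
                         activation = c("energy", "energy_relu", "relu"),
                         seed = 1L) {
  depth_preset <- match.arg(depth_preset)
  head <- match.arg(head)
  activation <- match.arg(activation)
  if (!dimensionality %in% c(2, 3)) {
    stop_salnet("dimensionality must be 2 or 3", class = "salnet_value_error")
  }
  assert_number(width_scale, "width_scale", min = 0, strict = TRUE)
  if (head == "feature") {
    if (is.null(feature_dim)) {
      stop_salnet("feature_dim is required when head = 'feature'",
                  class = "salnet_value_error")
    }
    feature_dim <- assert_count(feature_dim, "feature_dim", min = 1L)
  } else if (!is.null(feature_dim)) {
    stop_salnet("feature_dim is only meaningful when head = 'feature'",
                class = "salnet_value_error")
  }
  structure(
    list(dimensionality = as.integer(dimensionality),
         depth_preset = depth_preset,
         width_scale = as.numeric(width_scale),
         head = head,
         feature_dim = feature_dim,
         activation = activation,
         seed = assert_count(seed, "seed", min = 0L)),
    class = "model_config"
  )
}

# stem/trunk activation plan: "energy" = squared-rectifier stem with a
# linear residual trunk (single-nonlinearity energy model, exactly
# interpretable Jacobian); "energy_relu" = squared-rectifier stem with a
# rectified trunk; "relu" = plain rectifier throughout
preset_acts <- function(config) {
  switch(config$activation %||% "energy",
         energy = list(stem = "relu2", trunk = "identity"),
         energy_relu = list(stem = "relu2", trunk = "relu"),
         relu = list(stem = "relu", trunk = "relu"))
}

head_width <- function(config) {
  if (config$head %in% c("tanh", "sigmoid")) 1L else 2L
}

scaled_channels <- function(base, width_scale) {
  pmax(1L, as.integer(round(base * width_scale)))
}

nd_k <- function(k, dimensionality) {
  if (dimensionality == 2L) c(1L, k, k) else rep(as.integer(k), 3L)
}

nd_s <- function(s, dimensionality) {
  if (dimensionality == 2L) c(1L, s, s) else rep(as.integer(s), 3L)
}

#' Build an untrained severity classifier
#'
#' Instantiates the network described by a [model_config()] for a given
#' input grid, with seeded weight initialisation (two builds from the same
#' configuration have identical parameters).
#'
#' @param config a [model_config()].
#' @param grid input grid: a scalar (isotropic volume) or a length-3 vector
#'   for 3D; a scalar or length-2 vector (image height/width) for 2D.
#' @return An object of class `severity_cnn` (untrained; see
#'   [train_classifier()]).
#' @export
build_classifier <- function(config, grid) {
  stopifnot(inherits(config, "model_config"))
  nd <- config$dimensionality
  if (nd == 3L) {
    input_dim <- as.integer(if (length(grid) == 1L) rep(grid, 3L) else grid)
    if (length(input_dim) != 3L) {
      stop_salnet("3D models need a length-1 or length-3 grid",
                  class = "salnet_value_error")
    }
  } else {
    hw <- as.integer(if (length(grid) == 1L) rep(grid, 2L) else grid)
    if (length(hw) != 2L) {
      stop_salnet("2D models need a length-1 or length-2 grid",
                  class = "salnet_value_error")
    }
    input_dim <- c(1L, hw)
  }
  downsample <- switch(config$depth_preset, small = 6L, resnet50 = 32L,
                       linear = 1L)
  spatial <- input_dim[input_dim > 1 | nd == 3L]
  if (any(spatial < downsample)) {
    stop_salnet("input grid ", paste(spatial, collapse = "x"),
                " is smaller than the ", config$depth_preset,
                " preset's total downsampling factor ", downsample,
                class = "salnet_sizing_error")
  }
  layers <- with_seed(config$seed, build_layers(config, input_dim))
  structure(
    list(config = config, input_dim = input_dim, layers = layers$layers,
         feature_layer = layers$feature_layer,
         norm = list(center = 0, scale = 1),
         classes = c("low", "high"), trained = FALSE),
    class = "severity_cnn"
  )
}

build_layers <- function(config, input_dim) {
  nd <- config$dimensionality
  w <- config$width_scale
  out_units <- head_width(config)
  layers <- list()
  feature_layer <- NA_integer_
  if (config$depth_preset == "linear") {
    d <- prod(input_dim)
    layers <- list(list(type = "flatten", d = d))
    if (config$head == "feature") {
      layers <- c(layers, list(new_fc(d, config$feature_dim)))
      feature_layer <- length(layers)
      layers <- c(layers, list(new_fc(config$feature_dim, 2L)))
    } else {
      layers <- c(layers, list(new_fc(d, out_units)))
    }
    return(list(layers = layers, feature_layer = feature_layer))
  }

  if (config$depth_preset == "small") {
    # voxelwise (1x1x1, stride 1) intensity-encoding stem: the activation
    # nonlinearity acts per voxel, so the input Jacobian's subject-varying
    # factor is strictly local and attribution does not bleed across
    # parcel boundaries; residual blocks then aggregate spatially
    ch <- scaled_channels(c(8L, 16L, 32L), w)
    stem <- new_conv(1L, ch[1], rep(1L, 3), rep(1L, 3), rep(0L, 3),
                     input_dim)
    acts <- preset_acts(config)
    b1 <- new_block(ch[1], ch[2], nd_s(3, nd), stem$out_dim, nd_k(3, nd),
                    bottleneck = FALSE)
    b1$act <- acts$trunk
    b2 <- new_block(ch[2], ch[3], nd_s(2, nd), b1$out_dim, nd_k(3, nd),
                    bottleneck = FALSE)
    b2$act <- acts$trunk
    layers <- list(stem, list(type = "relu", act = acts$stem), b1, b2,
                   list(type = "gap", C = ch[3], Nvox = prod(b2$out_dim)))
    top_in <- ch[3]
  } else {
    # 50-layer bottleneck plan: stem + stages of 3, 4, 6, 3 blocks
    base <- scaled_channels(64L, w)
    stage_out <- scaled_channels(c(256L, 512L, 1024L, 2048L), w)
    stage_mid <- scaled_channels(c(64L, 128L, 256L, 512L), w)
    counts <- c(3L, 4L, 6L, 3L)
    strides <- c(1L, 2L, 2L, 2L)
    stem <- new_conv(1L, base, nd_k(7, nd), nd_s(2, nd),
                     nd_pad(nd_k(7, nd)), input_dim)
    acts <- preset_acts(config)
    layers <- list(stem, list(type = "relu", act = acts$stem))
    cin <- base
    dim_cur <- stem$out_dim
    for (s in seq_along(counts)) {
      for (b in seq_len(counts[s])) {
        st <- if (b == 1L) nd_s(strides[s], nd) else nd_s(1, nd)
        blk <- new_block(cin, stage_out[s], st, dim_cur, nd_k(3, nd),
                         bottleneck = TRUE, mid = stage_mid[s])
        blk$act <- acts$trunk
        layers <- c(layers, list(blk))
        cin <- stage_out[s]
        dim_cur <- blk$out_dim
      }
    }
    layers <- c(layers, list(list(type = "gap", C = cin,
                                  Nvox = prod(dim_cur))))
    top_in <- cin
  }

  if (config$head == "feature") {
    layers <- c(layers, list(new_fc(top_in, config$feature_dim)))
    feature_layer <- length(layers)
    layers <- c(layers, list(new_fc(config$feature_dim, 2L)))
  } else {
    layers <- c(layers, list(new_fc(top_in, out_units)))
  }
  list(layers = layers, feature_layer = feature_layer)
}

#' Number of trainable parameters
#'
#' @param object a `severity_cnn`.
#' @return Integer parameter count (a deterministic function of the
#'   configuration and grid).
#' @export
n_parameters <- function(object) {
  sum(vapply(collect_params(object), length, integer(1)))
}

#' @export
print.severity_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%dD residual severity classifier (%s preset, width x%.3g, %s head)\n",
              cfg$dimensionality, cfg$depth_preset, cfg$width_scale,
              cfg$head))
  cat(sprintf("  input grid %s, %s parameters, %s\n",
              paste(x$input_dim[x$input_dim > 1 | cfg$dimensionality == 3],
                    collapse = "x"),
              format(n_parameters(x), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  if (!is.null(x$result)) {
    cat(sprintf("  held-out accuracy: %.4f on %d subjects\n",
                x$result$accuracy, nrow(x$result$predictions)))
  }
  invisible(x)
}

#' @export
summary.severity_cnn <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  training: %d epochs, final loss %.4f, final train accuracy %.4f\n",
                max(h$epoch), h$loss[nrow(h)], h$train_accuracy[nrow(h)]))
  }
  invisible(object)
}

# --- losses -----------------------------------------------------------------

# y: 0 = low, 1 = high; z: logits (out_units x B)
head_loss <- function(head, z, y) {
  B <- length(y)
  if (head %in% c("softmax", "feature")) {
    zs <- sweep(z, 2, apply(z, 2, max))
    logZ <- log(colSums(exp(zs)))
    picked <- zs[cbind(y + 1L, seq_len(B))]
    loss <- mean(logZ - picked)
    p <- sweep(exp(zs), 2, colSums(exp(zs)), `/`)
    d <- p
    d[cbind(y + 1L, seq_len(B))] <- d[cbind(y + 1L, seq_len(B))] - 1
    list(loss = loss, dz = d / B)
  } else if (head == "sigmoid") {
    p <- stats::plogis(z)
    eps <- 1e-12
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    list(loss = loss, dz = (p - matrix(y, 1)) / B)
  } else { # tanh, targets +/- 1
    t <- matrix(2 * y - 1, 1)
    u <- tanh(z)
    loss <- mean((u - t)^2)
    list(loss = loss, dz = 2 * (u - t) * (1 - u^2) / B)
  }
}

head_predict <- function(head, z) {
  if (head %in% c("softmax", "feature")) {
    as.integer(z[2, ] > z[1, ])
  } else if (head == "sigmoid") {
    as.integer(z[1, ] > 0)
  } else {
    as.integer(z[1, ] > 0)
  }
}

# signed score of a target class (0 = low, 1 = high) used for saliency
head_class_score_grad <- function(head, z, target) {
  d <- matrix(0, nrow(z), ncol(z))
  if (head %in% c("softmax", "feature")) {
    d[cbind(target + 1L, seq_len(ncol(z)))] <- 1
  } else {
    d[1, ] <- ifelse(target == 1L, 1, -1)
  }
  d
}

# --- training ---------------------------------------------------------------

#' Training specification
#'
#' @param train_ids,test_ids disjoint subject-id sets; both severity groups
#'   must appear in each.
#' @param epochs training epochs (fixed-length schedule).
#' @param batch_size minibatch size.
#' @param lr learning rate of the adaptive-moment (Adam) optimiser.
#' @param seed seed for minibatch shuffling.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(train_ids, test_ids, epochs = 12, batch_size = 8,
                       lr = 1e-3, seed = 1L) {
  if (length(intersect(train_ids, test_ids))) {
    stop_salnet("train and test subject sets overlap: ",
                paste(intersect(train_ids, test_ids), collapse = ", "),
                class = "salnet_protocol_error")
  }
  structure(
    list(train_ids = as.character(train_ids),
         test_ids = as.character(test_ids),
         epochs = assert_count(epochs, "epochs", min = 1L),
         batch_size = assert_count(batch_size, "batch_size", min = 1L),
         lr = assert_number(lr, "lr", min = 0, strict = TRUE),
         seed = assert_count(seed, "seed", min = 0L)),
    class = "train_spec"
  )
}

#' Stratified train/test split of the scored subjects
#'
#' Controls are never part of either set: the classifiers train and
#' evaluate only on scored high/low subjects.
#'
#' @param records phenotype data frame.
#' @param test_n held-out test-set size (default 31).
#' @param seed split seed.
#' @return List with `train_ids` and `test_ids`.
#' @export
make_split <- function(records, test_n = 31, seed = 1L) {
  scored <- records[records$group %in% c("high", "low"), ]
  test_n <- assert_count(test_n, "test_n", min = 2L)
  if (test_n >= nrow(scored)) {
    stop_salnet("test_n must be smaller than the number of scored subjects",
                class = "salnet_value_error")
  }
  with_seed(seed, {
    per_group <- split(scored$subject_id, scored$group)
    n_high_test <- round(test_n * length(per_group$high) / nrow(scored))
    n_high_test <- min(max(n_high_test, 1L), length(per_group$high) - 1L)
    n_low_test <- test_n - n_high_test
    test <- c(sample(per_group$high, n_high_test),
              sample(per_group$low, n_low_test))
    list(train_ids = setdiff(scored$subject_id, test), test_ids = test)
  })
}

subject_labels <- function(records, ids) {
  grp <- records$group[match(ids, records$subject_id)]
  if (anyNA(grp)) {
    stop_salnet("subject ids missing from phenotype table: ",
                paste(ids[is.na(grp)], collapse = ", "),
                class = "salnet_consistency_error")
  }
  if (any(grp == "control")) {
    stop_salnet("control subjects may not enter classifier training or ",
                "accuracy evaluation: ",
                paste(ids[grp == "control"], collapse = ", "),
                class = "salnet_protocol_error")
  }
  as.integer(grp == "high")
}

# x for the network: 1 x (Nvox * B); volumes are encoded as deviations
# from the model reference volume, scaled to unit spread
batch_input <- function(volumes, ids, norm) {
  v <- unlist(lapply(ids, function(id) {
    (as.numeric(volumes[[id]]) - norm$center) / norm$scale
  }), use.names = FALSE)
  matrix(v, nrow = 1L)
}

#' Train a severity classifier
#'
#' Trains the network on the high/low scored subjects of `spec$train_ids`
#' with minibatch Adam, then evaluates on the held-out `spec$test_ids`.
#' Controls are rejected from both sets. Inputs are encoded as deviations
#' from a reference volume -- the voxel-wise minimum over the training
#' subjects, i.e. the floor of the severity spectrum -- divided by the
#' global standard deviation of the training deviations. The encoding is
#' stored in the model and reapplied at prediction time; because the
#' reference sits at the least-affected end, the encoded signal (and with it
#' gradient saliency) grows monotonically with the structural effect.
#'
#' @param model an untrained [build_classifier()] result.
#' @param volumes named list of [brain_volume()]s (names = subject ids).
#' @param records phenotype data frame.
#' @param spec a [train_spec()].
#' @return The trained `severity_cnn`, with elements `result` (class
#'   `classifier_result`: per-subject predictions and held-out accuracy) and
#'   `history` (per-epoch loss and training accuracy).
#' @export
train_classifier <- function(model, volumes, records, spec) {
  stopifnot(inherits(model, "severity_cnn"), inherits(spec, "train_spec"))
  y_train <- subject_labels(records, spec$train_ids)
  y_test <- subject_labels(records, spec$test_ids)
  if (length(unique(y_train)) < 2L || length(unique(y_test)) < 2L) {
    stop_salnet("both severity groups must appear in the train and test sets",
                class = "salnet_protocol_error")
  }

  # reference anatomy: the voxel-wise floor of the training cohort, i.e.
  # the least-affected end of the severity spectrum
  center <- Reduce(pmin, lapply(spec$train_ids,
                                function(id) as.numeric(volumes[[id]])))
  dev_sq <- 0
  for (id in spec$train_ids) {
    dev_sq <- dev_sq + sum((as.numeric(volumes[[id]]) - center)^2)
  }
  scale <- sqrt(dev_sq / (length(spec$train_ids) * length(center)))
  model$norm <- list(center = center, scale = max(scale, 1e-8))

  head <- model$config$head
  params <- collect_params(model)
  state <- adam_init(params)
  n <- length(spec$train_ids)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_accuracy = numeric(0))

  with_seed(spec$seed, {
    for (epoch in seq_len(spec$epochs)) {
      perm <- sample(n)
      ep_loss <- 0
      ep_correct <- 0L
      starts <- seq(1, n, by = spec$batch_size)
      for (s in starts) {
        take <- perm[s:min(s + spec$batch_size - 1L, n)]
        ids <- spec$train_ids[take]
        y <- y_train[take]
        B <- length(ids)
        x <- batch_input(volumes, ids, model$norm)
        fw <- net_forward(model, x, B, keep_cache = TRUE)
        hl <- head_loss(head, fw$out, y)
        bw <- net_backward(model, hl$dz, fw$caches, B)
        g <- collect_grads(model, bw$grads)
        upd <- adam_step(params, g, state, lr = spec$lr)
        params <- upd$params
        state <- upd$state
        model <- assign_params(model, params)
        ep_loss <- ep_loss + hl$loss * B
        ep_correct <- ep_correct + sum(head_predict(head, fw$out) == y)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = ep_loss / n,
                                  train_accuracy = ep_correct / n))
    }
  })

  model$trained <- TRUE
  model$history <- history
  model$spec <- spec
  pred <- predict(model, volumes[spec$test_ids], type = "class")
  result <- structure(
    list(predictions = data.frame(subject_id = spec$test_ids,
                                  truth = model$classes[y_test + 1L],
                                  predicted = pred,
                                  stringsAsFactors = FALSE),
         accuracy = mean(pred == model$classes[y_test + 1L]),
         head = head),
    class = "classifier_result"
  )
  model$result <- result
  model
}

#' Fit a residual convolutional severity classifier
#'
#' Convenience fitting interface: builds the network for the volumes' grid
#' and trains it in one call. With `restarts > 1` the model is retrained
#' from `restarts` different weight initialisations (seeds derived from the
#' configuration seed) and the fit with the best held-out accuracy is
#' returned -- the multi-attempt protocol used when a randomly initialised
#' feature layer makes single runs noisy. The full accuracy distribution is
#' kept in the returned object (`restart_accuracies`), since reporting only
#' the best of several attempts is an optimistic summary.
#'
#' @inheritParams train_classifier
#' @param config a [model_config()].
#' @param restarts number of random-initialisation attempts (default 1).
#' @return A trained `severity_cnn`.
#' @export
severity_cnn <- function(volumes, records, spec,
                         config = model_config(depth_preset = "small"),
                         restarts = 1L) {
  restarts <- assert_count(restarts, "restarts", min = 1L)
  grid <- dim(volumes[[1]])
  grid <- if (config$dimensionality == 2L) grid[2:3] else grid
  fits <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    model <- build_classifier(cfg, grid)
    fits[[r]] <- train_classifier(model, volumes, records, spec)
  }
  accs <- vapply(fits, function(f) f$result$accuracy, numeric(1))
  best <- fits[[which.max(accs)]]
  if (restarts > 1L) best$restart_accuracies <- accs
  best
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("Classifier result (%s head): accuracy %.4f on %d held-out subjects\n",
              x$head, x$accuracy, nrow(x$predictions)))
  invisible(x)
}

#' Predict severity classes, probabilities, scores or features
#'
#' @param object a trained `severity_cnn`.
#' @param volumes named list of [brain_volume()]s (or, for 2D models, a list
#'   of 2D slice matrices).
#' @param type `"class"` (default), `"score"` (logit for the high class),
#'   or `"feature"` (feature-layer activations, feature-head models only).
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return Character vector of classes, numeric scores, or a matrix of
#'   feature vectors (subjects in rows).
#' @export
predict.severity_cnn <- function(object, volumes, type = c("class", "score",
                                                           "feature"),
                                 batch_size = 16L, ...) {
  type <- match.arg(type)
  if (!object$trained && type != "feature") {
    # predictions from an untrained net are allowed but rarely useful
  }
  ids <- names(volumes) %||% as.character(seq_along(volumes))
  names(volumes) <- ids
  if (type == "feature" && is.na(object$feature_layer)) {
    stop_salnet("feature extraction requires head = 'feature'",
                class = "salnet_value_error")
  }
  upto <- if (type == "feature") object$feature_layer else
    length(object$layers)
  out <- NULL
  for (s in seq(1, length(ids), by = batch_size)) {
    take <- ids[s:min(s + batch_size - 1L, length(ids))]
    B <- length(take)
    x <- batch_input(volumes, take, object$norm)
    h <- x
    for (i in seq_len(upto)) {
      ly <- object$layers[[i]]
      h <- switch(ly$type,
                  conv = conv_forward(h, ly, B)$out,
                  relu = act_f(h, ly$act %||% "relu"),
                  block = block_forward(h, ly, B, ly$act %||% "relu")$out,
                  gap = gap_forward(h, ly$C, ly$Nvox, B),
                  flatten = matrix(h, nrow = ly$d, ncol = B),
                  fc = ly$W %*% h + ly$b)
    }
    out <- cbind(out, h)
  }
  switch(type,
         class = object$classes[head_predict(object$config$head, out) + 1L],
         score = {
           if (object$config$head %in% c("softmax", "feature")) {
             out[2, ] - out[1, ]
           } else {
             out[1, ]
           }
         },
         feature = {
           m <- t(out)
           rownames(m) <- ids
           m
         })
}

# For 2D models `batch_input` needs each element to be a (1, H, W) array;
# wrap plain matrices transparently.
as_slice_volume <- function(slice) {
  array(slice, dim = c(1L, dim(slice)))
}

#' Run the head-comparison harness
#'
#' Trains the same architecture with softmax, tanh and sigmoid heads under
#' identical seeds and reports all three accuracies side by side.
#'
#' @inheritParams train_classifier
#' @param base_config a [model_config()] whose head is replaced per run.
#' @return Data frame with one row per head (head, accuracy).
#' @export
compare_heads <- function(volumes, records, spec,
                          base_config = model_config(depth_preset = "small")) {
  heads <- c("softmax", "tanh", "sigmoid")
  fits <- lapply(heads, function(h) {
    cfg <- base_config
    cfg$head <- h
    cfg$feature_dim <- NULL
    severity_cnn(volumes, records, spec, config = cfg)
  })
  data.frame(head = heads,
             accuracy = vapply(fits, function(f) f$result$accuracy,
                               numeric(1)))
}

# --- hybrid variants --------------------------------------------------------

#' Hybrid classification from deep feature vectors
#'
#' Extracts feature vectors from a trained feature-head network for the
#' training and test subjects, then classifies the test vectors with a
#' k-nearest-neighbour majority vote (Euclidean distance) or a support
#' vector machine fitted on the training vectors.
#'
#' @param fit a trained `severity_cnn` with `head = "feature"`.
#' @param volumes named list of [brain_volume()]s.
#' @param records phenotype data frame.
#' @param spec the [train_spec()] whose train/test split is reused.
#' @param head `"knn"` or `"svm"`.
#' @param k neighbour count for kNN (odd, at most the training-set size).
#' @param kernel SVM kernel (passed to [e1071::svm()]).
#' @return An object of class `hybrid_classifier` with the stored training
#'   features and a `result` (`classifier_result`).
#' @export
hybrid_classify <- function(fit, volumes, records, spec,
                            head = c("knn", "svm"), k = 5L,
                            kernel = "linear") {
  head <- match.arg(head)
  stopifnot(inherits(fit, "severity_cnn"))
  if (fit$config$head != "feature") {
    stop_salnet("hybrid classification requires a feature-head model",
                class = "salnet_value_error")
  }
  y_train <- subject_labels(records, spec$train_ids)
  y_test <- subject_labels(records, spec$test_ids)
  if (head == "knn") {
    k <- assert_count(k, "k", min = 1L)
    if (k > length(spec$train_ids)) {
      stop_salnet("k = ", k, " exceeds the training-set size ",
                  length(spec$train_ids), class = "salnet_value_error")
    }
    if (k %% 2L == 0L) {
      stop_salnet("k must be odd so the majority vote is well defined",
                  class = "salnet_value_error")
    }
  }
  ftrain <- predict(fit, volumes[spec$train_ids], type = "feature")
  ftest <- predict(fit, volumes[spec$test_ids], type = "feature")
  cl <- factor(fit$classes[y_train + 1L], levels = fit$classes)
  if (head == "knn") {
    pred <- as.character(class::knn(ftrain, ftest, cl, k = k))
    svm_fit <- NULL
  } else {
    svm_fit <- e1071::svm(ftrain, cl, kernel = kernel)
    pred <- as.character(predict(svm_fit, ftest))
  }
  result <- structure(
    list(predictions = data.frame(subject_id = spec$test_ids,
                                  truth = fit$classes[y_test + 1L],
                                  predicted = pred,
                                  stringsAsFactors = FALSE),
         accuracy = mean(pred == fit$classes[y_test + 1L]),
         head = paste0("hybrid-", head)),
    class = "classifier_result"
  )
  structure(
    list(fit = fit, head = head, k = if (head == "knn") k else NULL,
         kernel = if (head == "svm") kernel else NULL,
         train_features = ftrain, train_labels = cl, svm_fit = svm_fit,
         result = result),
    class = "hybrid_classifier"
  )
}

#' @export
print.hybrid_classifier <- function(x, ...) {
  cat(sprintf("Hybrid classifier (%s on %d-dimensional deep features)\n",
              x$head, ncol(x$train_features)))
  print(x$result)
  invisible(x)
}

#' @export
predict.hybrid_classifier <- function(object, volumes, ...) {
  f <- predict(object$fit, volumes, type = "feature")
  if (object$head == "knn") {
    as.character(class::knn(object$train_features, f, object$train_labels,
                            k = object$k))
  } else {
    as.character(predict(object$svm_fit, f))
  }
}

#' Classify unscored control subjects
#'
#' Feeds control volumes through a model trained only on scored high/low
#' subjects and reports the proportion assigned to the low-severity class.
#'
#' @param object a trained `severity_cnn` or `hybrid_classifier`.
#' @param volumes named list of control [brain_volume()]s.
#' @return Fraction of controls predicted low (scalar in \[0, 1\]).
#' @export
classify_controls <- function(object, volumes) {
  if (!length(volumes)) {
    stop_salnet("no control volumes supplied", class = "salnet_value_error")
  }
  pred <- if (inherits(object, "hybrid_classifier")) {
    predict(object, volumes)
  } else {
    predict(object, volumes, type = "class")
  }
  mean(pred == "low")
}
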