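#' Day-based train/validation/test split specification
#'
#' Training and validation come from the training days only and are
#' contiguous in time within each fly-day recording: the first
#' \code{train_frac} of frames train, the final \code{val_frac} validate
#' (frames between the two, if any, are dropped). The test set is every frame
#' of the held-out test day. Because consecutive video frames are strongly
#' correlated, frames are never shuffled across the train/validation
#' boundary, and no day ever contributes to more than one side of the
#' train/test divide.
#'
#' @param train_days integer vector (default \code{c(1, 2)}).
#' @param test_day held-out day (default 3).
#' @param train_frac leading fraction of each training day used for training
#'   (default 0.85).
#' @param val_frac trailing fraction used for validation (default 0.15).
#' @return object of class \code{split_spec}.
#' @export
split_spec <- function(train_days = c(1L, 2L), test_day = 3L,
                       train_frac = 0.85, val_frac = 0.15) {
  if (train_frac + val_frac > 1 + 1e-12)
    stop("train_frac + val_frac must not exceed 1")
  if (test_day %in% train_days)
    stop("test day must not be a training day")
  structure(list(train_days = as.integer(train_days),
                 test_day = as.integer(test_day),
                 train_frac = train_frac, val_frac = val_frac),
            class = "split_spec")
}

#' Compute split indices from chip metadata
#'
#' @param meta data.frame with columns \code{identity}, \code{day},
#'   \code{frame}.
#' @param spec a [split_spec()].
#' @return list of integer index vectors \code{train}, \code{val},
#'   \code{test}; the three are disjoint by construction (asserted).
#' @export
split_indices <- function(meta, spec) {
  stopifnot(inherits(spec, "split_spec"))
  have <- unique(meta$day)
  missing <- setdiff(c(spec$train_days, spec$test_day), have)
  if (length(missing))
    stop("dataset is missing day(s): ", paste(missing, collapse = ", "))
  train <- integer(0); val <- integer(0)
  for (id in unique(meta$identity)) {
    for (d in spec$train_days) {
      idx <- which(meta$identity == id & meta$day == d)
      idx <- idx[order(meta$frame[idx])]
      n <- length(idx)
      n_tr <- floor(spec$train_frac * n)
      n_va <- floor(spec$val_frac * n)
      train <- c(train, idx[seq_len(n_tr)])
      if (n_va > 0) val <- c(val, idx[(n - n_va + 1):n])
    }
  }
  test <- which(meta$day == spec$test_day)
  if (length(intersect(train, val)) || length(intersect(train, test)) ||
      length(intersect(val, test)))
    stop("internal error: split leakage detected")
  list(train = train, val = val, test = test)
}

#' Split a chip stack by day into train/validation/test
#'
#' @param stack a [chip_stack()] containing all days the spec needs.
#' @param spec a [split_spec()].
#' @return list of three \code{chip_stack}s: \code{train}, \code{val},
#'   \code{test}, each tagged with its role and the spec.
#' @export
split_dataset <- function(stack, spec = split_spec()) {
  idx <- split_indices(stack$meta, spec)
  out <- lapply(names(idx), function(role) {
    s <- subset_stack(stack, idx[[role]])
    attr(s, "role") <- role
    attr(s, "split_spec") <- spec
    attr(s, "fly_sizes") <- attr(stack, "fly_sizes")
    attr(s, "fly_sexes") <- attr(stack, "fly_sexes")
    s
  })
  names(out) <- names(idx)
  out
}

#' Train a fly-eye network on labelled chip stacks
#'
#' Standardizes both stacks with the training stack's statistics, then
#' optimizes the softmax cross-entropy with Adam under early stopping on
#' validation macro F1. Guards against leakage: the validation days must be a
#' subset of the training days (a validation set drawn from the test day is
#' refused), and every class must appear in the training set.
#'
#' @param model a [build_network()] model whose input size matches the chips.
#' @param train,val \code{chip_stack}s (e.g. from [split_dataset()] after
#'   [map_chips()] with [bottleneck_29()]).
#' @param epochs maximal epochs (default 30).
#' @param batch_size mini-batch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param patience early-stopping patience in epochs on validation macro F1
#'   (default 5).
#' @param seed RNG seed for shuffling; fixed seed and single-threaded BLAS
#'   give identical final weights.
#' @param verbose print per-epoch progress.
#' @return object of class \code{flyeye_fit}: the trained \code{model} (best
#'   validation weights), \code{norm} statistics, the class labels, and a
#'   per-epoch \code{history} data.frame.
#' @export
train_reid <- function(model, train, val, epochs = 30L, batch_size = 64L,
                       lr = 1e-3, patience = 5L, seed = 1L,
                       verbose = FALSE) {
  stopifnot(inherits(model, "flyeye_network"),
            inherits(train, "chip_stack"), inherits(val, "chip_stack"))
  vdays <- unique(val$meta$day)
  if (length(vdays) && !all(vdays %in% unique(train$meta$day)))
    stop("leakage guard: validation set contains day(s) ",
         paste(setdiff(vdays, unique(train$meta$day)), collapse = ", "),
         " absent from the training days")
  classes <- sort(unique(c(train$meta$identity, val$meta$identity)))
  absent <- setdiff(unique(val$meta$identity), unique(train$meta$identity))
  if (length(absent))
    stop("class(es) absent from the training set: ",
         paste(absent, collapse = ", "))
  if (length(classes) != model$n_classes)
    stop("model has ", model$n_classes, " classes but data has ",
         length(classes))

  norm <- fit_norm(train)
  x_tr <- as_matrix_stack(apply_norm(train, norm))
  x_va <- as_matrix_stack(apply_norm(val, norm))
  y_tr <- match(train$meta$identity, classes)
  y_va <- match(val$meta$identity, classes)

  fit <- fit_network(model, x_tr, y_tr, x_va, y_va, epochs = epochs,
                     batch_size = batch_size, lr = lr, patience = patience,
                     seed = seed, verbose = verbose)
  structure(list(model = fit$model, norm = norm, classes = classes,
                 history = fit$history, best_epoch = fit$best_epoch),
            class = "flyeye_fit")
}

#' Evaluate a trained model on a test stack
#'
#' Applies the training standardization, predicts each chip's identity and
#' scores the result with [eval_report()] (macro F1, per-class metrics,
#' ordered confusion matrix, sex-collapsed F1 when the stack carries per-fly
#' sex labels).
#'
#' @param fit a \code{flyeye_fit} from [train_reid()] (or a
#'   \code{ridge_fit} from [train_ridge()]).
#' @param test a labelled \code{chip_stack}; must be non-empty.
#' @return an [eval_report()].
#' @export
evaluate_model <- function(fit, test) {
  stopifnot(inherits(test, "chip_stack"))
  if (n_chips(test) == 0L) stop("empty test set")
  pred <- predict_ids(fit, test)
  eval_report(test$meta$identity, pred,
              levels = fit$classes,
              sex = attr(test, "fly_sexes"),
              size = attr(test, "fly_sizes"))
}

#' Predict identities for a chip stack
#' @param fit a \code{flyeye_fit} or \code{ridge_fit}.
#' @param stack a \code{chip_stack}.
#' @return vector of predicted identity labels.
#' @export
predict_ids <- function(fit, stack) {
  x <- as_matrix_stack(apply_norm(stack, fit$norm))
  if (inherits(fit, "flyeye_fit")) {
    probs <- predict_network(fit$model, x)
    fit$classes[max.col(probs, ties.method = "first")]
  } else {
    as.integer(as.character(stats::predict(fit$model, newx = x,
                                           s = fit$lambda, type = "class")))
  }
}

#' Nearest-centroid baseline in pixel space
#'
#' Classifies each test chip to the identity with the closest mean training
#' chip (Euclidean distance). Used as a model-free probe that the generator
#' embeds a learnable identity signal.
#'
#' @param train,test \code{chip_stack}s.
#' @return predicted identity vector for \code{test}.
#' @export
nearest_centroid_predict <- function(train, test) {
  x_tr <- as_matrix_stack(train); x_te <- as_matrix_stack(test)
  ids <- sort(unique(train$meta$identity))
  cent <- t(vapply(ids, function(id)
    colMeans(x_tr[train$meta$identity == id, , drop = FALSE]),
    numeric(ncol(x_tr))))
  # squared distances via ||x||^2 - 2 x.c + ||c||^2
  d <- outer(rowSums(x_te^2), rep(1, length(ids))) -
    2 * x_te %*% t(cent) + outer(rep(1, nrow(x_te)), rowSums(cent^2))
  ids[max.col(-d, ties.method = "first")]
}

#' Ridge multinomial comparator
#'
#' A standard off-the-shelf baseline: multinomial logistic regression with a
#' ridge penalty (glmnet) on flattened chips, with the penalty chosen on the
#' validation set. It plays the role of a generic high-capacity comparator
#' run through the same preprocessing paths as the fly-eye model.
#'
#' @param train,val \code{chip_stack}s.
#' @param nlambda length of the penalty path searched (default 8).
#' @return object of class \code{ridge_fit} usable with [evaluate_model()].
#' @export
train_ridge <- function(train, val, nlambda = 8L) {
  classes <- sort(unique(train$meta$identity))
  norm <- fit_norm(train)
  x_tr <- as_matrix_stack(apply_norm(train, norm))
  x_va <- as_matrix_stack(apply_norm(val, norm))
  y_tr <- factor(train$meta$identity, levels = classes)
  fit <- glmnet::glmnet(x_tr, y_tr, family = "multinomial", alpha = 0,
                        nlambda = nlambda, standardize = FALSE)
  pred <- stats::predict(fit, newx = x_va, type = "class")
  scores <- apply(pred, 2L, function(p)
    macro_f1(as.character(val$meta$identity), p))
  best <- fit$lambda[which.max(scores)]
  structure(list(model = fit, lambda = best, norm = norm, classes = classes),
            class = "ridge_fit")
}

#' Run the across-day re-identification experiment end to end
#'
#' For each replicate: generate a synthetic dataset, apply the chosen
#' preprocessing path (optionally preceded by the random zoom ablation on
#' every frame, training and test alike), split by day, train the chosen
#' model, and evaluate on the held-out day. Replicates differ in their
#' dataset seed, mirroring independent biological replicates.
#'
#' @param config a named list or a YAML file path. Recognized fields (all
#'   optional): \code{generator} (arguments to [session_spec()]),
#'   \code{split} (arguments to [split_spec()]), \code{model} ("flyeye" or
#'   "ridge"), \code{mode} ("bottleneck29", "highres" or
#'   "bottleneck_upsize"), \code{zoom} (TRUE applies [random_zoom()] to all
#'   frames), \code{zoom_max_frac} (default 0.25), \code{feature_size}
#'   (side length the 224x224 comparator inputs are reduced to before the
#'   ridge fit; default 56), \code{connectome} (CSV path), \code{train}
#'   (arguments to [train_reid()]), \code{seeds} (one per replicate,
#'   default 1), \code{n_replicates}.
#' @return list with \code{reports} (one [eval_report()] per replicate),
#'   \code{fits}, and \code{summary}: mean and sd of macro F1 (sd is NA for
#'   a single replicate).
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  gen <- do.call(session_spec, config[["generator"]] %||% list())
  spl <- do.call(split_spec, config[["split"]] %||% list())
  model_kind <- config[["model"]] %||% "flyeye"
  mode <- config[["mode"]] %||% "bottleneck29"
  if (!mode %in% c("bottleneck29", "highres", "bottleneck_upsize"))
    stop("unknown preprocessing mode: ", mode)
  if (model_kind == "flyeye" && mode != "bottleneck29")
    stop("the fly-eye model takes the 29x29 bottleneck path only")
  zoom <- isTRUE(config[["zoom"]])
  zoom_frac <- config[["zoom_max_frac"]] %||% 0.25
  feat <- config[["feature_size"]] %||% 56L
  seeds <- config[["seeds"]] %||% seq_len(config[["n_replicates"]] %||% 1L)

  path_fun <- switch(mode,
    bottleneck29 = bottleneck_29,
    highres = function(ch) resize_chip(highres_path(ch), feat),
    bottleneck_upsize = function(ch) resize_chip(bottleneck_then_upsize(ch),
                                                 feat))
  transform <- if (zoom)
    function(ch) path_fun(random_zoom(ch, max_frac = zoom_frac))
  else path_fun

  reports <- list(); fits <- list()
  for (i in seq_along(seeds)) {
    ds <- make_dataset(gen, seed = seeds[i], transform = transform)
    parts <- split_dataset(ds, spl)
    fit <- if (model_kind == "flyeye") {
      tab <- load_connectome(config[["connectome"]] %||% default_connectome_path())
      net <- build_network(tab, dim(parts$train$images)[1:2],
                           n_classes = gen$n_flies,
                           seed = (config[["train"]][["seed"]] %||% 1L) + i - 1L)
      do.call(train_reid, c(list(model = net, train = parts$train,
                                 val = parts$val),
                            config[["train"]] %||% list()))
    } else if (model_kind == "ridge") {
      train_ridge(parts$train, parts$val)
    } else stop("unknown model kind: ", model_kind)
    reports[[i]] <- evaluate_model(fit, parts$test)
    fits[[i]] <- fit
  }
  f1s <- vapply(reports, function(r) r$macro_f1, 0)
  list(reports = reports, fits = fits,
       summary = data.frame(model = model_kind, mode = mode, zoom = zoom,
                            n_replicates = length(seeds),
                            macro_f1_mean = mean(f1s),
                            macro_f1_sd = if (length(f1s) > 1) sd(f1s)
                                          else NA_real_))
}
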