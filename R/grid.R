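#' Stratified random train/test split
#'
#' Partitions a manifest into disjoint train and test sets, stratified
#' within group: the per-group test count is `round((1 - train_fraction) *
#' group size)`. Deterministic given the seed. With `unit = "subject"` whole
#' subjects are assigned to one side (avoiding subject-identity leakage);
#' the default `unit = "image"` matches the image-level bookkeeping of the
#' reference design, where the six sessions of one subject may straddle the
#' partition.
#'
#' @param manifest a `jnp_manifest` (or data frame with `path`,
#'   `subject_id`, `group`).
#' @param train_fraction fraction of each group used for training, in (0, 1).
#' @param seed integer split seed.
#' @param unit `"image"` or `"subject"`.
#' @return list of class `split_result`: `train` and `test` (character ids
#'   from `manifest$path`), and `counts`, a per-group table of train/test
#'   sizes.
#' @export
split_dataset <- function(manifest, train_fraction, seed,
                          unit = c("image", "subject")) {
  unit <- match.arg(unit)
  if (!is.finite(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  groups <- c("control", "experimental")
  test_ids <- character()
  with_seed(derive_seed(seed, 9001), {
    for (g in groups) {
      if (unit == "image") {
        ids <- manifest$path[manifest$group == g]
      } else {
        ids <- unique(manifest$subject_id[manifest$group == g])
      }
      if (length(ids) < 2)
        stop("group '", g, "' has fewer than 2 ", unit, "s; cannot split")
      n_test <- round((1 - train_fraction) * length(ids))
      n_test <- max(1L, min(length(ids) - 1L, n_test))
      test_ids <- c(test_ids, sample(ids, n_test))
    }
  })
  if (unit == "subject")
    test_ids <- manifest$path[manifest$subject_id %in% test_ids]
  train_ids <- setdiff(manifest$path, test_ids)
  counts <- table(
    partition = ifelse(manifest$path %in% test_ids, "test", "train"),
    group = manifest$group)
  structure(list(train = train_ids, test = test_ids, counts = counts,
                 train_fraction = train_fraction, seed = seed, unit = unit),
            class = "split_result")
}

# Standardization fitted on the training split only; columns with zero
# spread are centred but left unscaled.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(scaler, x) {
  scale(x, center = scaler$mean, scale = scaler$sd)
}

#' Train a binary classifier on standardized features
#'
#' Wraps the three classical learners behind one interface, the target
#' class being the experimental (elderly) group:
#'
#' * `"svm"` — support vector machine, radial-basis kernel, cost 1
#'   (via \pkg{e1071}).
#' * `"lr"` — ridge-penalized logistic regression (\pkg{glmnet}, `alpha = 0`,
#'   `lambda = 1/n`, i.e. unit regularization strength on the unaveraged
#'   log-likelihood).
#' * `"nb"` — Gaussian naive Bayes (\pkg{e1071}) with a variance floor of
#'   1e-9 so zero-spread features cannot produce degenerate densities.
#'
#' @param x numeric feature matrix (training rows, already standardized).
#' @param y labels, `"control"` / `"experimental"`.
#' @param kind `"svm"`, `"lr"` or `"nb"`.
#' @return object of class `jnp_classifier`.
#' @export
train_classifier <- function(x, y, kind = c("svm", "lr", "nb")) {
  kind <- match.arg(kind)
  y <- factor(as.character(y), levels = c("control", "experimental"))
  if (anyNA(y)) stop("labels must be 'control' or 'experimental'")
  if (nlevels(droplevels(y)) < 2)
    stop("training labels contain a single class")
  if (anyNA(x) || !all(is.finite(x))) stop("non-finite feature values")
  x <- as.matrix(x)
  fit <- switch(kind,
    svm = e1071::svm(x, y, kernel = "radial", cost = 1, scale = FALSE),
    lr = withCallingHandlers(
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = 1 / nrow(x), standardize = FALSE),
      # small-class advisory is expected at toy sample sizes
      warning = function(w) {
        if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    nb = {
      m <- e1071::naiveBayes(as.data.frame(x), y)
      m$tables <- lapply(m$tables, function(tab) {
        tab[, 2] <- pmax(tab[, 2], sqrt(1e-9))
        tab
      })
      m
    })
  structure(list(kind = kind, fit = fit, features = colnames(x)),
            class = "jnp_classifier")
}

#' Predict group labels (and probabilities) for new features
#'
#' @param object a `jnp_classifier`.
#' @param newdata standardized feature matrix.
#' @param type `"class"` for labels, `"prob"` for the probability of the
#'   experimental class (SVM returns `NA` probabilities; it is used as a
#'   hard classifier).
#' @param ... unused.
#' @return character labels or numeric probabilities.
#' @export
predict.jnp_classifier <- function(object, newdata, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (object$kind == "svm") {
    cls <- as.character(predict(object$fit, newdata))
    if (type == "prob") return(rep(NA_real_, nrow(newdata)))
    return(cls)
  }
  if (object$kind == "lr") {
    p <- as.numeric(predict(object$fit, newx = newdata, type = "response"))
    if (type == "prob") return(p)
    return(ifelse(p >= 0.5, "experimental", "control"))
  }
  df <- as.data.frame(newdata)
  if (type == "prob") {
    pr <- predict(object$fit, df, type = "raw")
    return(as.numeric(pr[, "experimental"]))
  }
  as.character(predict(object$fit, df, type = "class"))
}

#' Enumerate the model grid
#'
#' `mode = "paper"` reproduces the reference design: 5 pretrained backbones
#' x 3 classifiers x 3 epoch settings (10/15/20) x 2 training fractions
#' (60%/70%) = 90 model specifications, numbered split-major (M1-M45 for the
#' 60% block, M46-M90 for 70%), then by epoch, classifier (lr, nb, svm) and
#' backbone in alphabetical order — the numbering consistent with every
#' published model id. `mode = "desk"` swaps the backbones for the two
#' offline backends (moments, which has no epochs, and scratch_cnn at each
#' epoch setting), giving 24 cells.
#'
#' @param mode `"desk"` or `"paper"`.
#' @param train_fractions training fractions (default `c(0.6, 0.7)`).
#' @param epochs epoch settings for training backends (default
#'   `c(10, 15, 20)`).
#' @param classifiers classifier kinds (default `c("lr", "nb", "svm")`).
#' @param train_seed seed recorded into each backend spec.
#' @return list of `model_spec` objects, each with `model` (id string),
#'   `backend` (a `backend_spec`), `classifier` and `train_fraction`.
#' @export
enumerate_grid <- function(mode = c("desk", "paper"),
                           train_fractions = c(0.6, 0.7),
                           epochs = c(10L, 15L, 20L),
                           classifiers = c("lr", "nb", "svm"),
                           train_seed = 1L) {
  mode <- match.arg(mode)
  specs <- list()
  i <- 0L
  prefix <- if (mode == "paper") "M" else "D"
  for (fr in sort(train_fractions)) {
    if (mode == "paper") {
      for (ep in sort(epochs))
        for (cl in classifiers)
          for (bb in c("alexnet", "densenet201", "resnet50", "vgg16",
                       "vgg19")) {
            i <- i + 1L
            specs[[i]] <- structure(list(
              model = sprintf("%s%d", prefix, i),
              backend = backend_spec("pretrained", backbone_id = bb,
                                     epochs = ep, train_seed = train_seed),
              classifier = cl, train_fraction = fr), class = "model_spec")
          }
    } else {
      for (cl in classifiers) {
        i <- i + 1L
        specs[[i]] <- structure(list(
          model = sprintf("%s%d", prefix, i),
          backend = backend_spec("moments", train_seed = train_seed),
          classifier = cl, train_fraction = fr), class = "model_spec")
      }
      for (ep in sort(epochs))
        for (cl in classifiers) {
          i <- i + 1L
          specs[[i]] <- structure(list(
            model = sprintf("%s%d", prefix, i),
            backend = backend_spec("scratch_cnn", epochs = ep,
                                   train_seed = train_seed),
            classifier = cl, train_fraction = fr), class = "model_spec")
        }
    }
  }
  specs
}

#' Evaluate a model grid on a rendered dataset
#'
#' The central fitting routine: for every model specification the dataset is
#' split (one shared stratified split per training fraction), the feature
#' backend is fitted on the training images only, features are extracted for
#' both partitions, standardized with training-split statistics, the
#' classifier is trained and the held-out images are scored into a confusion
#' matrix and its six metrics. Backend fits and feature matrices are cached
#' per (backend, split), so all classifiers at one grid point reuse the same
#' features. The whole run is reproducible from the master seed.
#'
#' Cell failures are caught and recorded in the result (the run continues)
#' unless `strict = TRUE`.
#'
#' @param manifest a `jnp_manifest` whose `path` column holds image ids.
#' @param images named list of `jnp_image` keyed by manifest `path`.
#' @param grid list of model specs from [enumerate_grid()]; default the desk
#'   grid.
#' @param seed master seed governing splits.
#' @param unit splitting unit, see [split_dataset()].
#' @param strict abort on the first cell failure?
#' @return an object of class `jnp_grid` with methods `print`, `summary`,
#'   `as.data.frame`, `plot` and `predict`.
#' @export
run_grid <- function(manifest, images, grid = enumerate_grid("desk"),
                     seed = 1, unit = "image", strict = FALSE) {
  if (!length(grid)) stop("empty model grid")
  fx <- validate_manifest(manifest)
  if (length(fx)) stop("invalid manifest: ", fx[1])
  if (!all(manifest$path %in% names(images)))
    stop("images missing for manifest entries: ",
         paste(utils::head(setdiff(manifest$path, names(images)), 3),
               collapse = ", "))
  fractions <- sort(unique(vapply(grid, `[[`, 0, "train_fraction")))
  splits <- list()
  for (fr in fractions)
    splits[[sprintf("%.6g", fr)]] <-
      split_dataset(manifest, fr, seed = derive_seed(seed, round(fr * 100)),
                    unit = unit)
  labels <- structure(manifest$group, names = manifest$path)
  # shared downsampled stack for scratch backends, aligned to manifest order
  needs_cnn <- any(vapply(grid, function(s) s$backend$kind == "scratch_cnn",
                          TRUE))
  stack <- NULL
  if (needs_cnn) stack <- downsample_stack(images[manifest$path])
  stack_index <- structure(seq_along(manifest$path), names = manifest$path)
  feature_cache <- list()
  get_features <- function(bspec, split_key) {
    bkey <- backend_key(bspec)
    cache_key <- paste(bkey, split_key, sep = "@")
    if (!is.null(feature_cache[[cache_key]]))
      return(feature_cache[[cache_key]])
    split <- splits[[split_key]]
    backend <- fit_backend(images[split$train], labels[split$train], bspec)
    all_ids <- manifest$path
    if (bspec$kind == "scratch_cnn") {
      fm <- extract_features(backend, images[all_ids],
                             downsampled = stack[, , , stack_index[all_ids],
                                                 drop = FALSE])
    } else {
      fm <- extract_features(backend, images[all_ids])
    }
    out <- list(backend = backend, features = fm,
                train_ids = split$train)
    feature_cache[[cache_key]] <<- out
    out
  }
  results <- list()
  cells <- list()
  errors <- list()
  for (ms in grid) {
    split_key <- sprintf("%.6g", ms$train_fraction)
    cell <- tryCatch({
      fx <- get_features(ms$backend, split_key)
      split <- splits[[split_key]]
      xtr <- fx$features[split$train, , drop = FALSE]
      xte <- fx$features[split$test, , drop = FALSE]
      scaler <- fit_scaler(xtr)
      clf <- train_classifier(apply_scaler(scaler, xtr),
                              labels[split$train], ms$classifier)
      pred <- predict(clf, apply_scaler(scaler, xte))
      cm <- confusion(pred, labels[split$test])
      list(spec = ms, confusion = cm, metrics = metric_set(cm),
           split_seed = split$seed, classifier = clf, scaler = scaler,
           backend = fx$backend,
           backend_fingerprint = fx$backend$fingerprint,
           train_ids = split$train, test_ids = split$test)
    }, error = function(e) {
      if (strict) stop("grid cell ", ms$model, " failed: ",
                       conditionMessage(e), call. = FALSE)
      errors[[ms$model]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(cell)) {
      results[[ms$model]] <- cell
    }
    cells[[ms$model]] <- ms
  }
  structure(list(results = results, errors = errors, grid = cells,
                 splits = splits, seed = seed, unit = unit,
                 manifest = manifest,
                 n_images = length(images)),
            class = "jnp_grid")
}

#' @export
as.data.frame.jnp_grid <- function(x, ...) {
  if (!length(x$results))
    return(data.frame(model = character(), epoch = integer(),
                      backend = character(), learner = character(),
                      accuracy = numeric(), sensitivity = numeric(),
                      specificity = numeric(), ppv = numeric(),
                      npv = numeric(), kappa = numeric(),
                      train_fraction = numeric(),
                      tp = integer(), fn = integer(), fp = integer(),
                      tn = integer()))
  rows <- lapply(x$results, function(cell) {
    m <- cell$metrics
    data.frame(model = cell$spec$model,
               epoch = cell$spec$backend$epochs,
               backend = backend_key(cell$spec$backend),
               learner = cell$spec$classifier,
               accuracy = m[["accuracy"]], sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]], ppv = m[["ppv"]],
               npv = m[["npv"]], kappa = m[["kappa"]],
               train_fraction = cell$spec$train_fraction,
               tp = cell$confusion$tp, fn = cell$confusion$fn,
               fp = cell$confusion$fp, tn = cell$confusion$tn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.jnp_grid <- function(x, ...) {
  cat(sprintf("<jnp_grid> %d/%d cells evaluated on %d images (seed %d, %s-level splits)\n",
              length(x$results), length(x$grid), x$n_images, x$seed, x$unit))
  if (length(x$errors))
    cat("  failed cells:", paste(names(x$errors), collapse = ", "), "\n")
  df <- as.data.frame(x)
  if (nrow(df)) {
    best <- df[which.max(df$kappa), ]
    cat(sprintf("  best by kappa: %s (%s + %s, %d%% train) accuracy %.3f, kappa %.3f\n",
                best$model, best$backend, best$learner,
                round(100 * best$train_fraction), best$accuracy, best$kappa))
  }
  invisible(x)
}

#' @export
summary.jnp_grid <- function(object, min_accuracy = 0.95, min_kappa = 0.88,
                             ...) {
  df <- as.data.frame(object)
  ranked <- rank_models(df, min_accuracy = min_accuracy,
                        min_kappa = min_kappa)
  out <- list(n_cells = length(object$grid),
              n_evaluated = length(object$results),
              errors = object$errors,
              all = df[order(df$kappa, df$accuracy, df$model), ],
              ranked = ranked,
              thresholds = c(accuracy = min_accuracy, kappa = min_kappa))
  class(out) <- "summary.jnp_grid"
  out
}

#' @export
print.summary.jnp_grid <- function(x, ...) {
  cat(sprintf("Model grid: %d cells, %d evaluated\n", x$n_cells,
              x$n_evaluated))
  cat(sprintf("Ranked models (accuracy >= %.2f, kappa >= %.2f), ascending kappa:\n",
              x$thresholds["accuracy"], x$thresholds["kappa"]))
  if (nrow(x$ranked)) {
    disp <- x$ranked
    for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                "kappa"))
      disp[[m]] <- sprintf("%.2f", disp[[m]])
    print(disp, row.names = FALSE)
  } else cat("  (none pass the filter)\n")
  invisible(x)
}

#' Dot plot of grid results by kappa
#'
#' @param x a `jnp_grid`.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.jnp_grid <- function(x, ...) {
  df <- as.data.frame(x)
  if (!nrow(df)) stop("no evaluated cells to plot")
  df <- df[order(df$kappa), ]
  graphics::dotchart(df$kappa,
                     labels = sprintf("%s %s+%s", df$model, df$backend,
                                      df$learner),
                     xlab = "Cohen's kappa", ...)
  invisible(x)
}

#' Predict group labels for new images with a fitted grid cell
#'
#' @param object a `jnp_grid`.
#' @param images list of `jnp_image`.
#' @param model model id; default the cell with the highest kappa.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.jnp_grid <- function(object, images, model = NULL, ...) {
  df <- as.data.frame(object)
  if (!nrow(df)) stop("no evaluated cells")
  if (is.null(model)) model <- df$model[which.max(df$kappa)]
  cell <- object$results[[model]]
  if (is.null(cell)) stop("no evaluated cell with model id '", model, "'")
  fm <- extract_features(cell$backend, images)
  predict(cell$classifier, apply_scaler(cell$scaler, fm))
}
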