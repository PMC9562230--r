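# Small fully-connected feed-forward regressors for quality prediction,
# written directly in R matrix code: dense layers, ReLU/ELU/LReLU/tanh
# activations, mean-absolute-error loss, RMSprop or Adam updates, and
# early stopping with best-weight restoration. Single-threaded and seeded,
# so runs reproduce exactly.

act_forward <- function(name, z) {
  switch(name,
    RELU   = pmax(z, 0),
    ELU    = ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
    LRELU  = ifelse(z > 0, z, 0.01 * z),
    tanh   = tanh(z),
    linear = z,
    abort(sprintf("Unknown activation '%s'.", name), class = "winepi_error_config"))
}

act_grad <- function(name, z, a) {
  switch(name,
    RELU   = (z > 0) * 1,
    ELU    = ifelse(z > 0, 1, a + 1),
    LRELU  = ifelse(z > 0, 1, 0.01),
    tanh   = 1 - a^2,
    linear = matrix(1, nrow(z), ncol(z)))
}

#' Network specification
#'
#' @param input_dim Number of input features.
#' @param layers List of hidden layers, each `list(units, activation)` with
#'   activation in RELU, ELU, LRELU, tanh, linear. A final 1-unit linear
#'   output layer is appended automatically.
#' @param optimizer `"RMSprop"` or `"Adam"`.
#' @param max_epochs Training epoch cap (default 2000).
#' @param patience Early-stopping patience in epochs (default 50).
#' @param name Optional label.
#' @return An object of class `network_spec`. Loss is always MAE.
#' @export
network_spec <- function(input_dim, layers, optimizer = c("Adam", "RMSprop"),
                         max_epochs = 2000L, patience = 50L, name = "custom") {
  optimizer <- match.arg(optimizer)
  layers <- map(layers, function(l) list(units = check_count(l[[1]], "units", 1L),
                                         activation = l[[2]]))
  layers <- c(layers, list(list(units = 1L, activation = "linear")))
  structure(list(name = name, input_dim = check_count(input_dim, "input_dim", 1L),
                 layers = layers, optimizer = optimizer, loss = "MAE",
                 max_epochs = check_count(max_epochs, "max_epochs", 1L),
                 early_stopping = list(monitor = "val_mae",
                                       patience = check_count(patience, "patience", 1L))),
            class = "network_spec")
}

#' Preset network specifications
#'
#' The three feed-forward presets used for quality regression, one per
#' dataset type: `data1` (14 chemical features; 64/RELU, 64/ELU, 32/ELU,
#' 16/ELU hidden layers; RMSprop), `data2` (6 physiochemical features;
#' 64/RELU x3, 8/RELU; Adam) and `data3` (6 physiochemical features;
#' 128/RELU, 128/ELU, 64/ELU, 64/ELU; Adam). All use MAE loss, a 2000-epoch
#' cap, early stopping, and a 1-unit linear output layer.
#'
#' @param name One of `"data1"`, `"data2"`, `"data3"`.
#' @return A `network_spec`.
#' @export
preset_spec <- function(name = c("data1", "data2", "data3")) {
  name <- match.arg(name)
  switch(name,
    data1 = network_spec(14L, list(list(64L, "RELU"), list(64L, "ELU"),
                                   list(32L, "ELU"), list(16L, "ELU")),
                         optimizer = "RMSprop", name = "data1"),
    data2 = network_spec(6L, list(list(64L, "RELU"), list(64L, "RELU"),
                                  list(64L, "RELU"), list(8L, "RELU")),
                         optimizer = "Adam", name = "data2"),
    data3 = network_spec(6L, list(list(128L, "RELU"), list(128L, "ELU"),
                                  list(64L, "ELU"), list(64L, "ELU")),
                         optimizer = "Adam", name = "data3"))
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> ", x$name, ": input ", x$input_dim, " -> ",
      paste(map_chr(x$layers, function(l) paste0(l$units, "/", l$activation)),
            collapse = " -> "),
      " (", x$optimizer, ", ", x$loss, ")\n", sep = "")
  invisible(x)
}

#' Z-score normalisation fitted on training data
#'
#' Centres and scales every column by the training mean and standard
#' deviation, and applies the same parameters to any further tables (never
#' their own statistics, to avoid leakage). Constant columns are mapped to 0
#' with a warning.
#'
#' @param train Training feature table (data frame or matrix), non-empty.
#' @param apply_to Optional named list of further tables scaled with the
#'   training parameters.
#' @return A list: `train` (scaled tibble), `applied` (list of scaled
#'   tibbles), `center`, `scale`.
#' @export
normalize_features <- function(train, apply_to = list()) {
  X <- as_value_matrix(train)
  if (nrow(X) == 0L) {
    abort("`train` must be non-empty.", class = "winepi_error_config")
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  if (nrow(X) == 1L) sdv[] <- NA_real_
  constant <- !is.finite(sdv) | sdv == 0
  if (any(constant)) {
    warn(paste0("Constant feature(s) mapped to 0: ",
                paste(colnames(X)[constant] %||% which(constant), collapse = ", ")))
    sdv[constant] <- 1
  }
  scale_tab <- function(tab) {
    M <- as_value_matrix(tab)
    as_tibble(as.data.frame(sweep(sweep(M, 2L, mu), 2L, sdv, `/`)))
  }
  list(train = scale_tab(X),
       applied = map(apply_to, scale_tab),
       center = mu, scale = sdv)
}

init_weights <- function(spec) {
  dims <- c(spec$input_dim, map_dbl(spec$layers, "units"))
  map(seq_along(spec$layers), function(l) {
    fan_in <- dims[l]; fan_out <- dims[l + 1L]
    act <- spec$layers[[l]]$activation
    # He-style limits for rectifier families, Glorot for tanh/linear
    limit <- if (act %in% c("RELU", "ELU", "LRELU")) sqrt(6 / fan_in)
             else sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_in * fan_out, -limit, limit), fan_in, fan_out),
         b = rep(0, fan_out))
  })
}

forward_pass <- function(weights, spec, X) {
  as_list <- vector("list", length(weights))
  zs <- vector("list", length(weights))
  a <- X
  for (l in seq_along(weights)) {
    z <- sweep(a %*% weights[[l]]$W, 2L, weights[[l]]$b, `+`)
    a <- act_forward(spec$layers[[l]]$activation, z)
    zs[[l]] <- z; as_list[[l]] <- a
  }
  list(activations = as_list, zs = zs)
}

predict_raw <- function(weights, spec, X) {
  fp <- forward_pass(weights, spec, X)
  as.vector(fp$activations[[length(weights)]])
}

mae <- function(pred, obs) mean(abs(pred - obs))

#' Train a feed-forward quality regressor
#'
#' Minimises mean absolute error with the spec's optimizer on mini-batches,
#' monitoring MAE on a validation split of the training rows and stopping
#' early when it fails to improve for `patience` epochs (best weights are
#' restored). The seed controls initialisation, the validation split and
#' shuffling, and runs are single-threaded, so the same seed and data
#' reproduce the identical history.
#'
#' @param spec A [network_spec()] or [preset_spec()].
#' @param features Feature table, already normalised (see
#'   [normalize_features()]); column count must match `spec$input_dim`.
#' @param targets Numeric quality targets, one per row.
#' @param seed Integer seed.
#' @param batch_size Mini-batch size (default 32; `Inf` trains full-batch).
#' @param learning_rate Step size; default 0.001 for both optimizers.
#' @param validation_split Fraction of rows held out for the early-stopping
#'   monitor (default 0.1; 0 monitors training loss instead).
#' @param shuffle Reshuffle mini-batches every epoch (default `TRUE`).
#' @param norm Optional normalisation parameters (`center`, `scale`) stored
#'   with the model so [predict()] can accept raw features.
#' @return An object of class `wine_dnn`: weights, spec, training history
#'   (one row per epoch), `stopping_epoch`, `best_epoch`, `norm`, `seed`.
#' @export
train_dnn <- function(spec, features, targets, seed = 1L, batch_size = 32L,
                      learning_rate = 0.001, validation_split = 0.1,
                      shuffle = TRUE, norm = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  X <- as_value_matrix(features)
  y <- as.numeric(targets)
  if (nrow(X) != length(y)) {
    abort("`features` and `targets` must be aligned.", class = "winepi_error_config")
  }
  if (ncol(X) != spec$input_dim) {
    abort(sprintf("Spec expects %d features, got %d.", spec$input_dim, ncol(X)),
          class = "winepi_error_config")
  }
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    abort("Features and targets must be finite.", class = "winepi_error_domain")
  }

  local_seed(seed, {
    weights <- init_weights(spec)
    n <- nrow(X)
    n_val <- floor(validation_split * n)
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

    bs <- min(batch_size, length(tr_idx))
    n_layer <- length(weights)
    opt_state <- map(weights, function(w) {
      list(vW = w$W * 0, vb = w$b * 0, mW = w$W * 0, mb = w$b * 0)
    })
    rho <- 0.9; beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-7
    step <- 0L

    apply_update <- function(l, gW, gb) {
      s <- opt_state[[l]]
      if (spec$optimizer == "RMSprop") {
        s$vW <- rho * s$vW + (1 - rho) * gW^2
        s$vb <- rho * s$vb + (1 - rho) * gb^2
        weights[[l]]$W <<- weights[[l]]$W - learning_rate * gW / (sqrt(s$vW) + eps)
        weights[[l]]$b <<- weights[[l]]$b - learning_rate * gb / (sqrt(s$vb) + eps)
      } else {
        s$mW <- beta1 * s$mW + (1 - beta1) * gW
        s$mb <- beta1 * s$mb + (1 - beta1) * gb
        s$vW <- beta2 * s$vW + (1 - beta2) * gW^2
        s$vb <- beta2 * s$vb + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        weights[[l]]$W <<- weights[[l]]$W -
          learning_rate * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
        weights[[l]]$b <<- weights[[l]]$b -
          learning_rate * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
      }
      opt_state[[l]] <<- s
    }

    history <- vector("list", spec$max_epochs)
    best <- list(metric = Inf, weights = weights, epoch = 0L)
    patience <- spec$early_stopping$patience
    wait <- 0L
    epoch <- 0L

    while (epoch < spec$max_epochs) {
      epoch <- epoch + 1L
      ord <- if (shuffle) sample.int(length(tr_idx)) else seq_along(tr_idx)
      for (start in seq(1L, length(ord), by = bs)) {
        idx <- ord[start:min(start + bs - 1L, length(ord))]
        Xb <- Xtr[idx, , drop = FALSE]; yb <- ytr[idx]
        fp <- forward_pass(weights, spec, Xb)
        pred <- fp$activations[[n_layer]]
        step <- step + 1L
        # MAE gradient at the linear output
        delta <- matrix(sign(as.vector(pred) - yb) / length(yb), ncol = 1L)
        for (l in rev(seq_len(n_layer))) {
          a_prev <- if (l == 1L) Xb else fp$activations[[l - 1L]]
          dz <- delta * act_grad(spec$layers[[l]]$activation,
                                 fp$zs[[l]], fp$activations[[l]])
          gW <- crossprod(a_prev, dz)
          gb <- colSums(dz)
          if (l > 1L) delta <- dz %*% t(weights[[l]]$W)
          apply_update(l, gW, gb)
        }
      }
      train_mae <- mae(predict_raw(weights, spec, Xtr), ytr)
      val_mae <- if (length(val_idx)) mae(predict_raw(weights, spec, Xval), yval)
                 else NA_real_
      history[[epoch]] <- tibble(epoch = epoch, loss = train_mae, val_loss = val_mae)
      monitored <- if (length(val_idx)) val_mae else train_mae
      if (monitored < best$metric - 1e-12) {
        best <- list(metric = monitored, weights = weights, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }

    structure(list(
      spec = spec, weights = best$weights, norm = norm,
      history = dplyr::bind_rows(history[seq_len(epoch)]),
      stopping_epoch = epoch, best_epoch = best$epoch,
      best_metric = best$metric,
      seed = as.integer(seed), batch_size = bs, learning_rate = learning_rate,
      validation_split = validation_split
    ), class = "wine_dnn")
  })
}

#' @export
print.wine_dnn <- function(x, ...) {
  cat("<wine_dnn> ", x$spec$name, ": stopped at epoch ", x$stopping_epoch,
      " (best ", x$best_epoch, ", monitored MAE ", signif(x$best_metric, 4), ")\n",
      sep = "")
  invisible(x)
}

#' Predict quality with a trained network
#'
#' @param object A `wine_dnn`.
#' @param newdata Feature table; raw features are accepted when the model
#'   stores normalisation parameters, otherwise they must be pre-scaled.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.wine_dnn <- function(object, newdata, ...) {
  X <- as_value_matrix(newdata)
  if (!is.null(object$norm)) {
    X <- sweep(sweep(X, 2L, object$norm$center), 2L, object$norm$scale, `/`)
  }
  predict_raw(object$weights, object$spec, X)
}

#' Mean absolute error of a trained network
#'
#' @param model A `wine_dnn`.
#' @param features Feature table (see [predict.wine_dnn()]).
#' @param targets Observed quality values.
#' @return MAE in rating units.
#' @export
evaluate_mae <- function(model, features, targets) {
  X <- as_value_matrix(features)
  if (nrow(X) != length(targets)) {
    abort("`features` and `targets` must be aligned.", class = "winepi_error_config")
  }
  mae(predict(model, X), as.numeric(targets))
}
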