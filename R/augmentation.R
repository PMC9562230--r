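# SMOTE-style tabular augmentation: inflate a 12-wine source table to ~1000
# synthetic training rows by nearest-neighbour interpolation, including the
# dummy-class construction (zero-row majority class, class-targeted
# oversampling, cleanup) used to coerce a no-class regression table through a
# class-based oversampler.

#' Augmentation plan
#'
#' @param n_source Rows used to generate synthetic samples (default 12).
#' @param n_holdout Rows held out for evaluation (default 6).
#' @param n_synth Number of synthetic rows to generate (default 1000).
#' @param k_neighbors Neighbourhood size for the KNN step (default 5; must be
#'   smaller than `n_source`).
#' @param formula Interpolation formula: `"paper-abs"` (default) uses
#'   `x' = x + rand(0,1) * |x - xk|`, one-sided and able to extrapolate
#'   upward past the neighbour; `"standard-signed"` uses the canonical SMOTE
#'   `x' = x + rand(0,1) * (xk - x)`, which stays on the segment between the
#'   seed row and its neighbour.
#' @param seed Integer seed driving the split, neighbour and gap draws.
#' @return An object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(n_source = 12L, n_holdout = 6L, n_synth = 1000L,
                              k_neighbors = 5L,
                              formula = c("paper-abs", "standard-signed"),
                              seed = 1L) {
  formula <- match.arg(formula)
  plan <- list(
    n_source = check_count(n_source, "n_source", min = 2L),
    n_holdout = check_count(n_holdout, "n_holdout", min = 0L),
    n_synth = check_count(n_synth, "n_synth", min = 0L),
    k_neighbors = check_count(k_neighbors, "k_neighbors", min = 1L),
    formula = formula,
    seed = as.integer(seed)
  )
  if (plan$k_neighbors >= plan$n_source) {
    abort("`k_neighbors` must be smaller than `n_source`.",
          class = "winepi_error_config")
  }
  structure(plan, class = "augmentation_plan")
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat("<augmentation_plan> ", x$n_source, "+", x$n_holdout, " split, ",
      x$n_synth, " synthetic rows, k=", x$k_neighbors,
      ", formula=", x$formula, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

augment_columns <- function(rows, feature_cols, quality_col, id_col) {
  nms <- names(rows)
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(nms[vapply(rows, is.numeric, logical(1))], quality_col)
  }
  if (!quality_col %in% nms) {
    abort(sprintf("Quality column '%s' not found.", quality_col),
          class = "winepi_error_config")
  }
  bad <- feature_cols[!map_lgl(rows[feature_cols], is.numeric)]
  if (length(bad)) {
    abort(paste0("Non-numeric feature column(s): ", paste(bad, collapse = ", ")),
          class = "winepi_error_config")
  }
  list(features = feature_cols, quality = quality_col,
       id = intersect(id_col, nms))
}

#' Split a wine table into augmentation source and holdout sets
#'
#' Random, disjoint, exhaustive split, deterministic given the plan seed.
#'
#' @param rows A table whose row count equals `plan$n_source + plan$n_holdout`.
#' @param plan An [augmentation_plan()].
#' @return A list with tibbles `source` and `holdout`.
#' @export
split_dataset <- function(rows, plan = augmentation_plan()) {
  rows <- as_tibble(rows)
  if (nrow(rows) != plan$n_source + plan$n_holdout) {
    abort(sprintf("Expected %d rows (n_source + n_holdout), got %d.",
                  plan$n_source + plan$n_holdout, nrow(rows)),
          class = "winepi_error_config")
  }
  src_idx <- local_seed(plan$seed, sort(sample(nrow(rows), plan$n_source)))
  list(source = rows[src_idx, , drop = FALSE],
       holdout = rows[setdiff(seq_len(nrow(rows)), src_idx), , drop = FALSE])
}

# Nearest neighbours by Euclidean distance over z-scored features, excluding
# each row itself. Constant features contribute nothing (scale fixed at 1).
knn_index <- function(X, k) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  t(apply(D, 1L, function(d) order(d)[seq_len(k)]))
}

# Shared interpolation core: one seed-row draw, one neighbour draw and one
# gap draw per synthetic row; the formula is applied coordinate-wise to the
# features and the quality column alike.
smote_core <- function(M, plan) {
  n <- nrow(M)
  if (n < plan$k_neighbors + 1L) {
    abort(sprintf("Need at least k_neighbors + 1 = %d source rows, got %d.",
                  plan$k_neighbors + 1L, n),
          class = "winepi_error_config")
  }
  nn <- knn_index(M[, -ncol(M), drop = FALSE], plan$k_neighbors)
  draws <- local_seed(plan$seed, list(
    base = sample.int(n, plan$n_synth, replace = TRUE),
    nb = sample.int(plan$k_neighbors, plan$n_synth, replace = TRUE),
    gap = runif(plan$n_synth)
  ))
  if (plan$n_synth == 0L) {
    return(list(rows = M[0, , drop = FALSE],
                provenance = tibble(row = integer(0), base_row = integer(0),
                                    neighbour_row = integer(0), gap = numeric(0))))
  }
  nb_row <- nn[cbind(draws$base, draws$nb)]
  X <- M[draws$base, , drop = FALSE]
  XK <- M[nb_row, , drop = FALSE]
  delta <- if (plan$formula == "paper-abs") abs(XK - X) else XK - X
  synth <- X + draws$gap * delta
  list(rows = synth,
       provenance = tibble(row = seq_len(plan$n_synth), base_row = draws$base,
                           neighbour_row = nb_row, gap = draws$gap))
}

finish_augmented <- function(core, cols, plan, method) {
  data <- as_tibble(as.data.frame(core$rows))
  names(data) <- c(cols$features, cols$quality)
  structure(list(data = data, provenance = core$provenance,
                 plan = plan, method = method),
            class = "augmented_dataset")
}

#' SMOTE-style augmentation of a source table
#'
#' Each synthetic row is built from a randomly drawn source row `x` and one
#' of its `k` nearest neighbours `xk` (Euclidean distance over z-scored
#' features, so concentration-scale compounds do not dominate pH-scale
#' variables), applying the plan's interpolation formula coordinate-wise with
#' a single gap draw per row. The quality column is interpolated with the
#' same draw. Deterministic given the plan seed.
#'
#' @param source Source table: numeric feature columns plus a quality column
#'   (a `wine_id` column, if present, is ignored for generation).
#' @param plan An [augmentation_plan()].
#' @param feature_cols Feature column names; default all numeric columns
#'   except the quality column.
#' @param quality_col Name of the quality column (default `"quality"`).
#' @param id_col Name of the identifier column (default `"wine_id"`).
#' @return An object of class `augmented_dataset`: `data` (tibble of
#'   `plan$n_synth` rows), `provenance` (one record per synthetic row: seed
#'   row, neighbour row, gap draw), `plan`, `method`.
#' @export
smote_augment <- function(source, plan = augmentation_plan(),
                          feature_cols = NULL, quality_col = "quality",
                          id_col = "wine_id") {
  source <- as_tibble(source)
  cols <- augment_columns(source, feature_cols, quality_col, id_col)
  M <- as.matrix(source[, c(cols$features, cols$quality)])
  finish_augmented(smote_core(M, plan), cols, plan, "smote")
}

#' Dummy-class SMOTE augmentation
#'
#' Reproduces the dummy-class construction used to push a class-less
#' regression table through a class-based oversampler: append `n_synth`
#' all-zero rows as the majority class (class 1), label the source rows as
#' the minority class (class 0), run class-targeted SMOTE oversampling of
#' the minority class (neighbours are searched among minority rows only, so
#' the zero rows never enter the KNN step), then drop the class column, all
#' all-zero rows, and the provenance-less original rows. The remaining
#' `n_synth` synthetic rows are element-wise identical to [smote_augment()]
#' run under the same plan, since both consume the same draw stream.
#'
#' @inheritParams smote_augment
#' @return An `augmented_dataset`; `method = "dummy-class"`.
#' @export
dummy_class_augment <- function(source, plan = augmentation_plan(),
                                feature_cols = NULL, quality_col = "quality",
                                id_col = "wine_id") {
  source <- as_tibble(source)
  cols <- augment_columns(source, feature_cols, quality_col, id_col)
  value_cols <- c(cols$features, cols$quality)

  # literal dummy construction: source rows (class 0) + n_synth zero rows
  # (class 1, the majority)
  zeros <- as_tibble(matrix(0, nrow = plan$n_synth, ncol = length(value_cols),
                            dimnames = list(NULL, value_cols)))
  dummy <- dplyr::bind_rows(
    source[, value_cols] |> mutate(class = 0L, .origin = "source"),
    zeros |> mutate(class = 1L, .origin = "zero")
  )

  minority <- dummy |> filter(.data$class == 0L)
  core <- smote_core(as.matrix(minority[, value_cols]), plan)
  synth <- as_tibble(as.data.frame(core$rows))
  names(synth) <- value_cols
  balanced <- dplyr::bind_rows(dummy,
                               synth |> mutate(class = 0L, .origin = "synthetic"))

  # cleanup: drop the class column, every all-zero row, and the
  # provenance-less originals
  all_zero <- rowSums(abs(balanced[, value_cols])) == 0
  kept <- balanced |>
    filter(!all_zero, .data$.origin == "synthetic") |>
    select(-"class", -".origin")
  stopifnot(nrow(kept) == plan$n_synth)
  finish_augmented(list(rows = as.matrix(kept), provenance = core$provenance),
                   cols, plan, "dummy-class")
}

#' @export
print.augmented_dataset <- function(x, ...) {
  cat("<augmented_dataset> ", nrow(x$data), " synthetic rows (",
      x$method, ", formula=", x$plan$formula, ", seed=", x$plan$seed, ")\n", sep = "")
  invisible(x)
}

#' Write an augmented dataset
#'
#' The synthetic table goes to CSV; provenance goes to JSON lines, one record
#' per synthetic row.
#'
#' @param x An `augmented_dataset`.
#' @param data_path CSV output path.
#' @param provenance_path JSON-lines output path (default alongside the CSV).
#' @return Invisibly, the paths written.
#' @export
write_augmented <- function(x, data_path,
                            provenance_path = sub("\\.csv$", "_provenance.jsonl", data_path)) {
  readr::write_csv(x$data, data_path)
  con <- file(provenance_path, open = "wt")
  on.exit(close(con))
  apply(x$provenance, 1L, function(r) {
    writeLines(jsonlite::toJSON(as.list(r), auto_unbox = TRUE, digits = NA), con)
  })
  invisible(c(data_path, provenance_path))
}
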