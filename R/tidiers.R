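# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a grid-search result
#'
#' @param x A `qp_grid_search`.
#' @param full Return the whole evaluated surface instead of the retained
#'   top combinations (default `FALSE`).
#' @param ... Unused.
#' @return A tibble with one row per (alpha, n) combination: `rank`, `alpha`,
#'   `n`, `k`, `distance`.
#' @export
tidy.qp_grid_search <- function(x, full = FALSE, ...) {
  if (full) x$grid else x$top
}

#' Glance at a grid-search result
#'
#' @param x A `qp_grid_search`.
#' @param ... Unused.
#' @return A one-row tibble: best `alpha`, `n`, `k`, `distance`, the grid
#'   size and the number of wines.
#' @export
glance.qp_grid_search <- function(x, ...) {
  best <- x$grid[1L, ]
  tibble(alpha = best$alpha, n = best$n, k = best$k, distance = best$distance,
         n_combinations = nrow(x$grid), n_wines = x$n_wines, k_mode = x$k_mode)
}

#' Tidy a trained network's history
#'
#' @param x A `wine_dnn`.
#' @param ... Unused.
#' @return The per-epoch history tibble: `epoch`, `loss` (training MAE),
#'   `val_loss` (validation MAE, `NA` without a validation split).
#' @export
tidy.wine_dnn <- function(x, ...) x$history

#' Glance at a trained network
#'
#' @param x A `wine_dnn`.
#' @param ... Unused.
#' @return A one-row tibble: preset name, optimizer, stopping and best
#'   epochs, best monitored MAE, final training MAE, seed.
#' @export
glance.wine_dnn <- function(x, ...) {
  tibble(name = x$spec$name, optimizer = x$spec$optimizer,
         stopping_epoch = x$stopping_epoch, best_epoch = x$best_epoch,
         best_monitored_mae = x$best_metric,
         final_train_mae = x$history$loss[nrow(x$history)],
         seed = x$seed)
}

#' Tidy a synthetic study into one long table
#'
#' @param x A `synthetic_study`.
#' @param ... Unused.
#' @return A long tibble `wine_id`, `variable`, `value` covering the
#'   generated tables and the quality vector.
#' @export
tidy.synthetic_study <- function(x, ...) {
  tabs <- purrr::compact(list(x$chemistry, x$physiochem,
                              x$quality |> dplyr::rename(value = "quality") |>
                                mutate(variable = "quality") |>
                                select("wine_id", "variable", "value")))
  long <- map(tabs, function(tab) {
    if (all(c("variable", "value") %in% names(tab))) return(tab)
    tidyr::pivot_longer(tab, -"wine_id", names_to = "variable", values_to = "value")
  })
  dplyr::bind_rows(long)
}
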