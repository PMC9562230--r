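# Exponent-weighted quality proxy and its calibration by grid search.
#
# The quality proxy is QP = k * prod_i pi_i^{n_i}. Choosing every exponent
# freely is intractable, so exponents follow a geometric schedule with common
# ratio alpha: n_i = alpha^(i-1) * n. Calibration searches (alpha, n) on a
# grid, ranking candidates by the Euclidean distance between predicted proxies
# and the perceived-quality vector.

#' Geometric exponent schedule
#'
#' Weights `n, alpha*n, alpha^2*n, ...` for `m` Pi-groups: successive
#' exponents keep the common ratio `alpha`, reducing `m` free exponents to
#' the two parameters `(alpha, n)`.
#'
#' @param alpha Common ratio (> 0, dimensionless).
#' @param n Base exponent of the first Pi-group (> 0).
#' @param m Number of Pi-groups (>= 1).
#' @return An object of class `exponent_schedule` with fields `alpha`, `n`,
#'   `m`, `weights` (`weights[i] == alpha^(i-1) * n` exactly).
#' @examples
#' exponent_schedule(0.8, 1, 5)$weights # 1, 0.8, 0.64, 0.512, 0.4096
#' @export
exponent_schedule <- function(alpha, n, m = 5L) {
  alpha <- check_positive(alpha, "alpha")
  n <- check_positive(n, "n")
  m <- check_count(m, "m", min = 1L)
  structure(list(alpha = alpha, n = n, m = m,
                 weights = alpha^(seq_len(m) - 1L) * n),
            class = "exponent_schedule")
}

#' @export
print.exponent_schedule <- function(x, ...) {
  cat("<exponent_schedule> alpha=", x$alpha, ", n=", x$n, ": ",
      paste(signif(x$weights, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Quality-proxy model
#'
#' Bundles the Pi-form choice per modulator, the exponent schedule and the
#' proportionality constant `k` that together define the proxy
#' `QP = k * prod_i pi_i^{w_i}`.
#'
#' @param pi_forms One Pi-form id (recycled) or one per modulator.
#' @param schedule An [exponent_schedule()].
#' @param k Proportionality constant (> 0); defaults to unity, the
#'   uncalibrated convention.
#' @return An object of class `quality_model`.
#' @export
quality_model <- function(pi_forms, schedule, k = 1) {
  stopifnot(inherits(schedule, "exponent_schedule"))
  k <- check_positive(k, "k")
  ids <- map_chr(as.list(pi_forms), function(f) parse_pi_form(f)$id)
  if (length(ids) == 1L) ids <- rep(ids, schedule$m)
  if (length(ids) != schedule$m) {
    abort("Number of Pi-forms must match the schedule's number of groups.",
          class = "winepi_error_config")
  }
  structure(list(pi_forms = ids, schedule = schedule, k = k),
            class = "quality_model")
}

#' @export
print.quality_model <- function(x, ...) {
  cat("<quality_model> k=", signif(x$k, 6),
      ", alpha=", x$schedule$alpha, ", n=", x$schedule$n, "\n", sep = "")
  cat("  forms: ", paste(x$pi_forms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Exponent-weighted quality proxy
#'
#' Computes `QP = k * prod_i pis[i]^weights[i]` in the log domain (summing
#' `w_i * log(pi_i)` and exponentiating), which keeps the product well
#' conditioned for strongly unbalanced Pi-term magnitudes.
#'
#' @param pis Positive Pi-term values: a vector of length `m` (one wine) or a
#'   matrix/data frame with `m` columns (rows are wines).
#' @param model A [quality_model()].
#' @return Numeric vector of proxy values, one per wine.
#' @export
quality_proxy <- function(pis, model) {
  stopifnot(inherits(model, "quality_model"))
  m <- as_value_matrix(pis)
  if (ncol(m) != model$schedule$m) {
    abort(sprintf("Expected %d Pi-terms per wine, got %d.", model$schedule$m, ncol(m)),
          class = "winepi_error_config")
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("All Pi-terms must be finite and strictly positive.",
          class = "winepi_error_domain")
  }
  as.vector(exp(log(model$k) + log(m) %*% model$schedule$weights))
}

#' Two-Pi-group quality proxy (physiochemical case studies)
#'
#' With two Pi-groups and the schedule collapsed to `n2/n1 = alpha = n`, the
#' proxy is `QP = k * pi1^n * pi2^(n^2)`.
#'
#' @param pi1,pi2 Positive Pi-term values (vectorised).
#' @param k Proportionality constant (> 0).
#' @param n Base exponent (> 0).
#' @return Numeric vector of proxy values.
#' @examples
#' quality_proxy_two_group(1, 1, k = 0.94, n = 1) # 0.94
#' @export
quality_proxy_two_group <- function(pi1, pi2, k = 1, n = 1) {
  k <- check_positive(k, "k")
  n <- check_positive(n, "n")
  if (any(!is.finite(c(pi1, pi2))) || any(pi1 <= 0) || any(pi2 <= 0)) {
    abort("All Pi-terms must be finite and strictly positive.",
          class = "winepi_error_domain")
  }
  exp(log(k) + n * log(pi1) + n^2 * log(pi2))
}

#' Euclidean distance between predicted and observed quality
#'
#' @param predicted,observed Numeric vectors of equal length (>= 1), in
#'   rating units.
#' @return `sqrt(sum((predicted - observed)^2))`.
#' @export
euclidean_distance <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1L) {
    abort("`predicted` and `observed` must have equal length >= 1.",
          class = "winepi_error_config")
  }
  sqrt(sum((predicted - observed)^2))
}

#' Default calibration grids
#'
#' `alpha` from 0.50 to 1.20 in steps of 0.01; `n` from 0.50 to 1.50 in steps
#' of 0.02 (values rounded to 10 decimals so grid points equal their decimal
#' literals exactly).
#'
#' @return A numeric vector.
#' @export
default_alpha_grid <- function() round(seq(0.50, 1.20, by = 0.01), 10)

#' @rdname default_alpha_grid
#' @export
default_n_grid <- function() round(seq(0.50, 1.50, by = 0.02), 10)

#' Grid search for the exponent-schedule parameters
#'
#' Evaluates the quality proxy for every `(alpha, n)` pair on the grids and
#' ranks pairs by Euclidean distance to the observed perceived-quality
#' vector. Deterministic; ties are broken by `(alpha, n)` lexicographic
#' order so rankings are reproducible.
#'
#' @param pis_per_wine Wine-by-modulator matrix (or tibble with an optional
#'   `wine_id` column) of strictly positive Pi-terms.
#' @param observed Per-wine perceived quality, rating units.
#' @param alpha_grid,n_grid Non-empty grids of positive values.
#' @param k Proportionality constant used for every pair (default unity).
#' @param top_m Number of best combinations retained (default 5).
#' @param k_mode `"fixed"` uses `k` as given; `"calibrate"` rescales `k` per
#'   pair to the least-squares optimum before computing the distance.
#' @return An object of class `qp_grid_search`: list with `top` (tibble
#'   `rank`, `alpha`, `n`, `k`, `distance`, non-decreasing distances),
#'   `grid` (the full evaluated surface), the grids, `k_mode` and `pi_forms`
#'   attribution if supplied.
#' @export
grid_search <- function(pis_per_wine, observed,
                        alpha_grid = default_alpha_grid(),
                        n_grid = default_n_grid(),
                        k = 1, top_m = 5L,
                        k_mode = c("fixed", "calibrate")) {
  k_mode <- match.arg(k_mode)
  if (is.data.frame(pis_per_wine) && "wine_id" %in% names(pis_per_wine)) {
    pis_per_wine <- pis_per_wine[, setdiff(names(pis_per_wine), "wine_id")]
  }
  P <- as_value_matrix(pis_per_wine)
  if (length(alpha_grid) == 0L || length(n_grid) == 0L) {
    abort("Grids must be non-empty.", class = "winepi_error_config")
  }
  if (any(alpha_grid <= 0) || any(n_grid <= 0)) {
    abort("Grid values must be positive.", class = "winepi_error_config")
  }
  if (any(!is.finite(P)) || any(P <= 0)) {
    abort("All Pi-terms must be finite and strictly positive.",
          class = "winepi_error_domain")
  }
  if (nrow(P) != length(observed)) {
    abort("`observed` must have one value per wine.", class = "winepi_error_config")
  }
  k <- check_positive(k, "k")
  top_m <- check_count(top_m, "top_m", min = 1L)

  combos <- tidyr::expand_grid(alpha = alpha_grid, n = n_grid)
  m <- ncol(P)
  logP <- log(P)
  # weight matrix: one column of exponents per (alpha, n) combination
  W <- vapply(seq_len(nrow(combos)),
              function(i) combos$alpha[i]^(seq_len(m) - 1L) * combos$n[i],
              numeric(m))
  Q <- exp(log(k) + logP %*% W)          # wines x combos
  if (k_mode == "calibrate") {
    k_hat <- colSums(Q * observed) / colSums(Q * Q)
    k_hat <- pmax(k_hat, .Machine$double.xmin)
    Q <- sweep(Q, 2L, k_hat, `*`)
    combos$k <- k * k_hat
  } else {
    combos$k <- k
  }
  combos$distance <- sqrt(colSums((Q - observed)^2))

  ranked <- combos |>
    arrange(.data$distance, .data$alpha, .data$n) |>
    mutate(rank = dplyr::row_number()) |>
    select("rank", "alpha", "n", "k", "distance")
  structure(list(
    top = head(ranked, top_m),
    grid = ranked,
    alpha_grid = alpha_grid, n_grid = n_grid,
    k_mode = k_mode, n_wines = nrow(P)
  ), class = "qp_grid_search")
}

#' @export
print.qp_grid_search <- function(x, ...) {
  cat("<qp_grid_search> ", nrow(x$grid), " (alpha, n) combinations over ",
      x$n_wines, " wines (k ", x$k_mode, ")\n", sep = "")
  print(x$top)
  invisible(x)
}

#' Grid search over per-modulator Pi-form assignments
#'
#' Extends [grid_search()] to also search the Pi-form chosen for each
#' modulator: every combination from `candidates` is evaluated on its own
#' `(alpha, n)` grid and the rankings are pooled.
#'
#' @param data Wine table with the modulator member columns.
#' @param modulators A `modulator_sets` object.
#' @param candidates A list of candidate Pi-forms (ids or `pi_form`s) offered
#'   to every modulator, or a named list of per-modulator candidate vectors.
#' @param observed,alpha_grid,n_grid,k,top_m,k_mode As in [grid_search()].
#' @return A tibble of the pooled `top_m` best rows: `rank`, form id per
#'   modulator, `alpha`, `n`, `k`, `distance`.
#' @export
grid_search_forms <- function(data, modulators, candidates, observed,
                              alpha_grid = default_alpha_grid(),
                              n_grid = default_n_grid(),
                              k = 1, top_m = 5L, k_mode = "fixed") {
  ids <- modulators$modulator
  if (!is.list(candidates) || is.null(names(candidates))) {
    candidates <- setNames(rep(list(unlist(candidates)), length(ids)), ids)
  }
  combo_grid <- tidyr::expand_grid(!!!map(candidates[ids], as.character))
  results <- map(seq_len(nrow(combo_grid)), function(i) {
    forms <- as.list(combo_grid[i, ])
    pis <- compute_pi_terms(data, modulators, setNames(forms, ids))
    gs <- grid_search(pis, observed, alpha_grid, n_grid, k, top_m, k_mode)
    dplyr::bind_cols(combo_grid[rep(i, nrow(gs$top)), ],
                     gs$top |> select("alpha", "n", "k", "distance"))
  })
  dplyr::bind_rows(results) |>
    arrange(.data$distance, .data$alpha, .data$n) |>
    mutate(rank = dplyr::row_number(), .before = 1) |>
    head(top_m)
}

#' Per-wine quality-proxy report
#'
#' Builds the wine-by-model report: one row per wine with the observed
#' perceived quality and one proxy column per fitted model, named
#' `alpha=<a>;n=<n>`.
#'
#' @param models A list of [quality_model()]s (possibly empty).
#' @param pis_per_wine Wine-by-modulator Pi-term matrix or tibble (optional
#'   `wine_id` column).
#' @param observed Per-wine perceived quality.
#' @param wine_ids Optional wine identifiers.
#' @return A tibble: `wine_id`, `observed`, one column per model.
#' @export
quality_report <- function(models, pis_per_wine, observed, wine_ids = NULL) {
  if (is.data.frame(pis_per_wine) && "wine_id" %in% names(pis_per_wine)) {
    wine_ids <- wine_ids %||% pis_per_wine$wine_id
    pis_per_wine <- pis_per_wine[, setdiff(names(pis_per_wine), "wine_id")]
  }
  P <- as_value_matrix(pis_per_wine)
  if (nrow(P) != length(observed)) {
    abort("`observed` must have one value per wine.", class = "winepi_error_config")
  }
  ids <- if (is.null(wine_ids)) sprintf("W%02d", seq_len(nrow(P))) else wine_ids
  out <- tibble(wine_id = ids, observed = observed)
  for (mod in models) {
    nm <- sprintf("alpha=%g;n=%g", mod$schedule$alpha, mod$schedule$n)
    out[[nm]] <- quality_proxy(P, mod)
  }
  out
}
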