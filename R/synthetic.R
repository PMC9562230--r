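# Synthetic study generator: chemistry, physiochemical and sensory tables
# with the statistical structure the analysis assumes, plus model-consistent
# datasets for parameter recovery.

#' Default compound specifications
#'
#' One row per modulator variable: flavour group membership, a plausible
#' concentration range for New Zealand Pinot noir, and a point odour
#' detection threshold (where only a threshold band is reported, its lower
#' bound — the most conservative detection assumption).
#'
#' Ranges and thresholds for the ethyl esters, beta-damascenone,
#' 2-phenylethan-1-ol, linalool, eugenol and guaiacol follow reported Pinot
#' noir values (`source = "reported"`; eugenol/guaiacol concentration ranges
#' are derived from their reported OAV and ODT bands, `source = "derived"`).
#' Compounds without reported ranges carry documented oenological defaults
#' (`source = "default"`); see the package vignette.
#'
#' @param m5_third Third member of the "other" group, as in
#'   [default_modulator_assignment()].
#' @return A tibble: `name`, `modulator`, `conc_low`, `conc_high`, `odt`
#'   (all concentrations in micrograms per litre), `source`.
#' @export
default_compound_specs <- function(m5_third = "4-ethylphenol") {
  specs <- dplyr::tribble(
    ~name,                 ~modulator, ~conc_low, ~conc_high,   ~odt,  ~source,
    "ethyl octanoate",     "fruity",        18.5,        874,      2,  "reported",
    "ethyl butanoate",     "fruity",        18.5,        874,     20,  "reported",
    "ethyl hexanoate",     "fruity",        18.5,        874,      5,  "reported",
    "hexan-1-ol",          "herbal",        1000,      12000,   2500,  "default",
    "(E)-hex-3-en-1-ol",   "herbal",         100,       2000,    400,  "default",
    "heptan-1-ol",         "herbal",          20,        200,   1000,  "default",
    "beta-damascenone",    "floral",         0.2,        102,   0.05,  "reported",
    "2-phenylethan-1-ol",  "floral",         236,     158473,  10000,  "reported",
    "linalool",            "floral",        0.83,        170,     25,  "reported",
    "eugenol",             "woody",          1.6,        144,      5,  "derived",
    "benzaldehyde",        "woody",            2,         50,   2000,  "default",
    "guaiacol",            "woody",          1.6,        144,      5,  "derived",
    "phenol",              "other",            5,        100,  25000,  "default",
    "4-ethylphenol",       "other",            5,       1000,    440,  "default"
  )
  if (!identical(m5_third, "4-ethylphenol")) {
    if (!is.null(m5_third) && !m5_third %in% specs$name) {
      abort(sprintf("No default spec for m5_third = '%s'; supply a custom spec table.",
                    m5_third), class = "winepi_error_config")
    }
    specs <- specs |> filter(.data$name != "4-ethylphenol")
  }
  validate_compound_specs(specs)
  specs
}

validate_compound_specs <- function(specs) {
  specs <- as_tibble(specs)
  need <- c("name", "modulator", "conc_low", "conc_high", "odt")
  miss <- setdiff(need, names(specs))
  if (length(miss)) {
    abort(paste0("Compound specs lack column(s): ", paste(miss, collapse = ", ")),
          class = "winepi_error_config")
  }
  if (any(specs$conc_low <= 0) || any(specs$conc_high < specs$conc_low)) {
    abort("Compound specs need 0 < conc_low <= conc_high.",
          class = "winepi_error_config")
  }
  if (any(specs$odt <= 0)) {
    abort("Compound specs need odt > 0.", class = "winepi_error_invalid_threshold")
  }
  if (anyDuplicated(specs$name)) {
    abort("Compound names must be unique.", class = "winepi_error_config")
  }
  invisible(specs)
}

#' Generate a wine-by-compound chemistry table
#'
#' Concentrations are drawn log-uniformly within each compound's
#' `[conc_low, conc_high]` range: ranges span up to three orders of magnitude,
#' so uniform sampling would make low concentrations vanishingly rare.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param n_wines Number of wines (>= 0).
#' @param specs Compound specifications, default [default_compound_specs()].
#' @param seed Integer seed.
#' @return A tibble: `wine_id` plus one concentration column per compound
#'   (micrograms per litre).
#' @export
generate_chemistry <- function(n_wines, specs = default_compound_specs(), seed = 1L) {
  n_wines <- check_count(n_wines, "n_wines")
  specs <- as_tibble(specs)
  if (nrow(specs) == 0L) {
    abort("`specs` must be non-empty.", class = "winepi_error_config")
  }
  validate_compound_specs(specs)
  vals <- local_seed(seed, {
    map(seq_len(nrow(specs)), function(i) {
      exp(runif(n_wines, log(specs$conc_low[i]), log(specs$conc_high[i])))
    })
  })
  out <- tibble(wine_id = wine_ids(n_wines))
  for (i in seq_len(nrow(specs))) out[[specs$name[i]]] <- vals[[i]]
  out
}

#' Default physiochemical variable ranges
#'
#' Documented oenological defaults for dry Pinot noir table wine (the source
#' study's measured values are not public): total sulphur dioxide (mg/L),
#' total phenolics (mg/L gallic acid equivalents), titratable acidity (g/L
#' tartaric), residual sugar (g/L), ethanol (% v/v) and pH.
#'
#' @return A tibble: `variable`, `low`, `high`, `unit`.
#' @export
default_physiochem_ranges <- function() {
  dplyr::tribble(
    ~variable,            ~low,  ~high, ~unit,
    "total_sulphur",        50,    150, "mg/L",
    "total_phenolics",    1200,   2200, "mg/L GAE",
    "titratable_acidity",  4.5,      7, "g/L",
    "sugar",               0.5,      5, "g/L",
    "ethanol",            12.5,   14.5, "% v/v",
    "pH",                  3.4,    3.9, ""
  )
}

#' Generate a wine-by-variable physiochemical table
#'
#' Values are drawn uniformly within each variable's range; the six case-study
#' variables are required. Deterministic given `seed`.
#'
#' @param n_wines Number of wines (>= 0).
#' @param ranges Per-variable ranges, default [default_physiochem_ranges()].
#' @param seed Integer seed.
#' @return A tibble: `wine_id` plus one column per variable.
#' @export
generate_physiochem <- function(n_wines, ranges = default_physiochem_ranges(), seed = 1L) {
  n_wines <- check_count(n_wines, "n_wines")
  ranges <- as_tibble(ranges)
  need <- default_physiochem_ranges()$variable
  miss <- setdiff(need, ranges$variable)
  if (length(miss) || nrow(ranges) != 6L) {
    abort(paste0("`ranges` must cover exactly the six physiochemical variables",
                 if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", "))),
          class = "winepi_error_config")
  }
  if (any(ranges$low >= ranges$high)) {
    abort("Each physiochemical range needs low < high.", class = "winepi_error_config")
  }
  vals <- local_seed(seed, {
    map(seq_len(nrow(ranges)), function(i) runif(n_wines, ranges$low[i], ranges$high[i]))
  })
  out <- tibble(wine_id = wine_ids(n_wines))
  for (i in seq_len(nrow(ranges))) out[[ranges$variable[i]]] <- vals[[i]]
  out
}

#' Generate panel ratings and per-wine perceived quality
#'
#' Emulates a descriptive-rating panel: rating = grand mean + wine effect +
#' panelist effect + residual noise (all Gaussian), clamped to the 1-10
#' category scale. Perceived quality is the per-wine mean rating.
#'
#' @param n_wines,n_panelists Counts (>= 1).
#' @param grand_mean Scale midpoint-ish baseline, default 5.5.
#' @param wine_effect_sd,panelist_effect_sd,noise_sd Standard deviations in
#'   rating units (>= 0); defaults 0.6, 0.7, 1.0.
#' @param seed Integer seed.
#' @return A list with `ratings` (tibble `panelist`, `wine_id`, `rating`) and
#'   `quality` (tibble `wine_id`, `quality`).
#' @export
generate_sensory <- function(n_wines, n_panelists = 22L, grand_mean = 5.5,
                             wine_effect_sd = 0.6, panelist_effect_sd = 0.7,
                             noise_sd = 1.0, seed = 1L) {
  n_wines <- check_count(n_wines, "n_wines", min = 1L)
  n_panelists <- check_count(n_panelists, "n_panelists", min = 1L)
  for (s in c(wine_effect_sd, panelist_effect_sd, noise_sd)) {
    if (!is.numeric(s) || s < 0) {
      abort("Effect standard deviations must be >= 0.", class = "winepi_error_config")
    }
  }
  res <- local_seed(seed, {
    wine_eff <- rnorm(n_wines, 0, wine_effect_sd)
    pan_eff <- rnorm(n_panelists, 0, panelist_effect_sd)
    noise <- matrix(rnorm(n_panelists * n_wines, 0, noise_sd), n_panelists, n_wines)
    grand_mean + outer(pan_eff, wine_eff, `+`) + noise
  })
  res <- pmin(pmax(res, 1), 10)
  ids <- wine_ids(n_wines)
  ratings <- tibble(
    panelist = rep(sprintf("P%02d", seq_len(n_panelists)), times = n_wines),
    wine_id = rep(ids, each = n_panelists),
    rating = as.vector(res)
  )
  list(ratings = ratings,
       quality = tibble(wine_id = ids, quality = colMeans(res)))
}

narrow_specs <- function(specs, conc_window) {
  if (!is.finite(conc_window)) return(specs)
  centre <- sqrt(specs$conc_low * specs$conc_high)
  specs |>
    mutate(conc_low = pmax(.data$conc_low, centre * exp(-conc_window)),
           conc_high = pmin(.data$conc_high, centre * exp(conc_window)))
}

resolve_truth_k <- function(k, centre_qp) {
  if (identical(k, "auto")) 5.5 / centre_qp else check_positive(k, "truth$k")
}

#' Generate a model-consistent chemistry study
#'
#' Produces a synthetic 18-wine-style study in which perceived quality is, by
#' construction, the power-law quality proxy of known truth parameters
#' evaluated on the generated chemistry, plus optional Gaussian noise — the
#' fixture used for parameter-recovery experiments.
#'
#' Concentrations are drawn log-uniformly within a window of half-width
#' `conc_window` (natural-log units) around each compound's geometric range
#' centre. The default window (0.15) emulates the modest wine-to-wine
#' variation of a single-variety sample set and yields a proxy dispersion of
#' about one rating unit; `conc_window = Inf` samples the full literature
#' ranges instead. When `truth$k = "auto"` the proportionality constant is
#' set so the proxy at the window centres equals 5.5, putting quality on the
#' 1-10 rating scale; an explicit numeric `k` (e.g. 1) is used as-is, in
#' which case quality lives on the proxy's natural scale.
#'
#' @param n_wines Number of wines, default 18.
#' @param truth List with `alpha`, `n`, `k` (positive number or `"auto"`) and
#'   optionally `forms` (one Pi-form per modulator, as in
#'   [compute_pi_terms()]).
#' @param specs,assignment Compound specs and modulator map.
#' @param conc_window Half-width of the log concentration window (ln units).
#' @param noise_sd Gaussian quality noise, rating units.
#' @param seed Integer seed.
#' @return An object of class `synthetic_study`: list with `wine_ids`,
#'   `chemistry`, `pi`, `quality`, `truth` (with the resolved `k`), `seed`.
#' @export
generate_model_consistent <- function(n_wines = 18L,
                                      truth = list(alpha = 0.8, n = 1.0, k = "auto"),
                                      specs = default_compound_specs(),
                                      assignment = default_modulator_assignment(),
                                      conc_window = 0.15,
                                      noise_sd = 0, seed = 1L) {
  n_wines <- check_count(n_wines, "n_wines", min = 1L)
  alpha <- check_positive(truth$alpha %||% 0.8, "truth$alpha")
  n_exp <- check_positive(truth$n %||% 1.0, "truth$n")
  forms <- truth$forms %||% "(x1+x2)/x3"
  specs <- narrow_specs(validate_compound_specs(as_tibble(specs)), conc_window)
  modulators <- assemble_modulators(unique(assignment$member), assignment)

  chem <- generate_chemistry(n_wines, specs, seed = seed)
  pis <- compute_pi_terms(chem, modulators, forms)

  centre <- specs |> mutate(centre = sqrt(.data$conc_low * .data$conc_high))
  centre_tab <- tibble(wine_id = "centre")
  for (i in seq_len(nrow(centre))) centre_tab[[centre$name[i]]] <- centre$centre[i]
  centre_pis <- compute_pi_terms(centre_tab, modulators, forms)

  sched <- exponent_schedule(alpha, n_exp, m = nrow(modulators))
  centre_qp <- quality_proxy(as.matrix(centre_pis[, -1]),
                             quality_model(forms, sched, k = 1))
  k <- resolve_truth_k(truth$k %||% "auto", centre_qp)
  model <- quality_model(forms, sched, k = k)
  qp <- quality_proxy(as.matrix(pis[, -1]), model)
  noise <- if (noise_sd > 0) {
    local_seed(seed + 1000003L, rnorm(n_wines, 0, noise_sd))
  } else rep(0, n_wines)

  structure(list(
    wine_ids = chem$wine_id,
    chemistry = chem,
    pi = pis,
    quality = tibble(wine_id = chem$wine_id, quality = qp + noise),
    truth = list(alpha = alpha, n = n_exp, k = k, forms = forms,
                 noise_sd = noise_sd, conc_window = conc_window),
    seed = as.integer(seed)
  ), class = "synthetic_study")
}

#' Generate a model-consistent physiochemical study
#'
#' Two-Pi-group analogue of [generate_model_consistent()]: quality is the
#' two-group proxy `k * pi1^n * pi2^(n^2)` over P1 = (total sulphur, total
#' phenolics, titratable acidity) and P2 = (sugar, ethanol, pH), plus optional
#' Gaussian noise. Default ranges already give a proxy dispersion of about one
#' rating unit, so no narrowing window is applied.
#'
#' @param n_wines Number of wines, default 18.
#' @param truth List with `n`, `k` (`"auto"` centres quality at 5.5).
#' @param ranges Physiochemical ranges, default [default_physiochem_ranges()].
#' @param noise_sd Gaussian quality noise, rating units.
#' @param seed Integer seed.
#' @return A `synthetic_study` with `physiochem` in place of `chemistry`.
#' @export
generate_model_consistent_physiochem <- function(n_wines = 18L,
                                                 truth = list(n = 1.0, k = "auto"),
                                                 ranges = default_physiochem_ranges(),
                                                 noise_sd = 0, seed = 1L) {
  n_wines <- check_count(n_wines, "n_wines", min = 1L)
  n_exp <- check_positive(truth$n %||% 1.0, "truth$n")
  assignment <- physiochem_modulator_assignment()
  modulators <- assemble_modulators(unique(assignment$member), assignment)

  phys <- generate_physiochem(n_wines, ranges, seed = seed)
  pis <- compute_pi_terms(phys, modulators, "(x1+x2)/x3")

  centres <- (ranges$low + ranges$high) / 2
  centre_tab <- tibble(wine_id = "centre")
  for (i in seq_len(nrow(ranges))) centre_tab[[ranges$variable[i]]] <- centres[i]
  cpis <- compute_pi_terms(centre_tab, modulators, "(x1+x2)/x3")
  centre_qp <- quality_proxy_two_group(cpis$P1, cpis$P2, k = 1, n = n_exp)
  k <- resolve_truth_k(truth$k %||% "auto", centre_qp)

  qp <- quality_proxy_two_group(pis$P1, pis$P2, k = k, n = n_exp)
  noise <- if (noise_sd > 0) {
    local_seed(seed + 1000003L, rnorm(n_wines, 0, noise_sd))
  } else rep(0, n_wines)

  structure(list(
    wine_ids = phys$wine_id,
    physiochem = phys,
    pi = pis,
    quality = tibble(wine_id = phys$wine_id, quality = qp + noise),
    truth = list(n = n_exp, k = k, noise_sd = noise_sd),
    seed = as.integer(seed)
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", length(x$wine_ids), " wines, seed ", x$seed, "\n", sep = "")
  if (!is.null(x$truth)) {
    cat("  truth:", paste(names(x$truth)[1:3],
                          signif(unlist(x$truth[1:3]), 4), sep = "=", collapse = ", "), "\n")
  }
  cat("  quality: ", paste(signif(range(x$quality$quality), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes chemistry/physiochemical/sensory tables as headered CSV with
#' `wine_id` in the first column, plus a JSON sidecar recording the seed and
#' any truth parameters.
#'
#' @param study A `synthetic_study` (or compatible list).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tab in c("chemistry", "physiochem", "quality")) {
    if (!is.null(study[[tab]])) {
      p <- file.path(dir, paste0(tab, ".csv"))
      readr::write_csv(study[[tab]], p)
      paths <- c(paths, p)
    }
  }
  sidecar <- file.path(dir, "study.json")
  jsonlite::write_json(list(seed = study$seed, truth = study$truth,
                            generator = "winepi synthetic_study"),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, sidecar))
}
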