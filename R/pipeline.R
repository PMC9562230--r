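# Pipeline driver: simulate/load -> modulators -> Pi-terms -> grid search ->
# report -> augment -> train -> evaluate, with per-stage artefacts and a
# reproducibility manifest.

#' Parse an inclusive ranged grid
#'
#' @param text Either `"low:high:step"` (inclusive, e.g. `"0.5:1.2:0.01"`) or
#'   a comma-separated list of values.
#' @return A numeric vector (ranged grids are rounded to 10 decimals so grid
#'   points equal their decimal literals).
#' @export
parse_grid <- function(text) {
  if (is.numeric(text)) return(text)
  text <- gsub("\\s+", "", text)
  if (grepl(":", text, fixed = TRUE)) {
    parts <- as.numeric(strsplit(text, ":", fixed = TRUE)[[1]])
    if (length(parts) != 3L || any(is.na(parts)) || parts[3] <= 0) {
      abort(sprintf("Cannot parse grid '%s'; expected 'low:high:step'.", text),
            class = "winepi_error_config")
    }
    return(round(seq(parts[1], parts[2], by = parts[3]), 10))
  }
  vals <- as.numeric(strsplit(text, ",", fixed = TRUE)[[1]])
  if (any(is.na(vals))) {
    abort(sprintf("Cannot parse grid '%s'.", text), class = "winepi_error_config")
  }
  vals
}

#' Pipeline configuration
#'
#' Builds (and validates) the configuration consumed by [run_pipeline()].
#' Either pass overrides as arguments or point `file` at a YAML file with the
#' same field names; explicit arguments override file values.
#'
#' @param ... Field overrides, see Details.
#' @param file Optional YAML config path.
#' @details Fields: `n_wines`, `seed`, `truth` (alpha, n, k), `conc_window`,
#'   `noise_sd`, `chemistry_csv`/`quality_csv` (load instead of simulate),
#'   `include_physiochem`, `forms`, `alpha_grid`, `n_grid`, `k`, `k_mode`,
#'   `top_m`, `plan` (n_source, n_holdout, n_synth, k_neighbors, formula),
#'   `preset`, `batch_size`, `max_epochs`, `m5_third`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  defaults <- list(
    n_wines = 18L, seed = 1L,
    truth = list(alpha = 0.8, n = 1.0, k = "auto"),
    conc_window = 0.15, noise_sd = 0.1,
    chemistry_csv = NULL, quality_csv = NULL,
    include_physiochem = TRUE,
    forms = "(x1+x2)/x3",
    alpha_grid = default_alpha_grid(), n_grid = default_n_grid(),
    k = 1, k_mode = "fixed", top_m = 5L,
    plan = list(n_source = 12L, n_holdout = 6L, n_synth = 1000L,
                k_neighbors = 5L, formula = "paper-abs"),
    preset = "data1", batch_size = 32L, max_epochs = NULL,
    m5_third = "4-ethylphenol"
  )
  cfg <- defaults
  if (!is.null(file)) {
    if (!file.exists(file)) {
      abort(sprintf("Config file '%s' not found.", file), class = "winepi_error_config")
    }
    cfg <- modifyList(cfg, yaml::read_yaml(file))
  }
  overrides <- list(...)
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  if (is.character(cfg$alpha_grid)) cfg$alpha_grid <- parse_grid(cfg$alpha_grid)
  if (is.character(cfg$n_grid)) cfg$n_grid <- parse_grid(cfg$n_grid)
  if (xor(is.null(cfg$chemistry_csv), is.null(cfg$quality_csv))) {
    abort("Provide both `chemistry_csv` and `quality_csv`, or neither (simulate).",
          class = "winepi_error_config")
  }
  cfg$seed <- check_count(cfg$seed, "seed")
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(stage, ..., t0 = NULL) {
  msg <- paste0("[winepi] ", stage, ": ", paste0(..., collapse = ""))
  if (!is.null(t0)) {
    msg <- paste0(msg, sprintf(" (%.2fs)", as.numeric(Sys.time()) - t0))
  }
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (or load) the study, screen and
#' assemble modulators, evaluate Pi-terms, calibrate the quality proxy by
#' grid search, write the per-wine report, augment the source split, train
#' the network preset, and evaluate MAE on the original wines — writing each
#' stage's artefacts plus a manifest (input hashes, seed, package version)
#' into `out_dir`. Failures abort with the failing stage named. Reruns with
#' the same configuration are byte-identical.
#'
#' @param config A [pipeline_config()] (or a list of overrides).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the stage results and artefact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, as.list(config))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "winepi",
                   version = as.character(utils::packageVersion("winepi")),
                   seed = config$seed, stages = list())
  artefacts <- character(0)
  run_stage <- function(stage, fn) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "winepi_error_stage", parent = e)
    })
    stage_log(stage, "done", t0 = t0)
    res
  }

  # --- simulate or load -----------------------------------------------------
  study <- run_stage("simulate", function() {
    if (!is.null(config$chemistry_csv)) {
      chem <- readr::read_csv(config$chemistry_csv, show_col_types = FALSE)
      qual <- readr::read_csv(config$quality_csv, show_col_types = FALSE)
      for (nm in c("wine_id")) {
        if (!nm %in% names(chem) || !nm %in% names(qual)) {
          abort(sprintf("Input tables need a '%s' column (file: %s).", nm,
                        config$chemistry_csv), class = "winepi_error_config")
        }
      }
      list(chemistry = chem, quality = qual, truth = NULL, seed = config$seed)
    } else {
      generate_model_consistent(
        n_wines = config$n_wines, truth = config$truth,
        specs = default_compound_specs(config$m5_third),
        assignment = default_modulator_assignment(config$m5_third),
        conc_window = config$conc_window,
        noise_sd = config$noise_sd, seed = config$seed)
    }
  })
  readr::write_csv(study$chemistry, fp <- file.path(out_dir, "chemistry.csv"))
  readr::write_csv(study$quality, fq <- file.path(out_dir, "quality.csv"))
  artefacts <- c(artefacts, fp, fq)

  # --- modulator screening --------------------------------------------------
  specs <- default_compound_specs(config$m5_third)
  assignment <- default_modulator_assignment(config$m5_third)
  mod_stage <- run_stage("modulators", function() {
    # dataset-level screening: can the compound exceed its ODT in this wine
    # type (upper range concentration), plus the literature overrides
    screen <- select_compounds(
      tibble(name = specs$name, concentration = specs$conc_high, odt = specs$odt))
    per_wine_oav <- study$chemistry |>
      tidyr::pivot_longer(-"wine_id", names_to = "name", values_to = "concentration") |>
      dplyr::inner_join(specs |> select("name", "odt"), by = "name") |>
      mutate(oav = compute_oav(.data$concentration, .data$odt))
    sets <- assemble_modulators(screen$name[screen$selected], assignment)
    list(screen = screen, per_wine_oav = per_wine_oav, sets = sets)
  })
  jsonlite::write_json(
    list(screen = mod_stage$screen,
         modulators = mod_stage$sets |> mutate(members = map(.data$members, identity))),
    fm <- file.path(out_dir, "modulators.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artefacts <- c(artefacts, fm)

  # --- Pi-terms and grid search --------------------------------------------
  pis <- run_stage("pi_terms", function() {
    compute_pi_terms(study$chemistry, mod_stage$sets, config$forms)
  })
  readr::write_csv(pis, fpi <- file.path(out_dir, "pi_terms.csv"))
  artefacts <- c(artefacts, fpi)

  gs <- run_stage("quality", function() {
    grid_search(pis, study$quality$quality,
                alpha_grid = config$alpha_grid, n_grid = config$n_grid,
                k = config$k, top_m = config$top_m, k_mode = config$k_mode)
  })
  report <- run_stage("report", function() {
    models <- map(seq_len(nrow(gs$top)), function(i) {
      quality_model(config$forms,
                    exponent_schedule(gs$top$alpha[i], gs$top$n[i], nrow(mod_stage$sets)),
                    k = gs$top$k[i])
    })
    quality_report(models, pis, study$quality$quality, wine_ids = study$chemistry$wine_id)
  })
  readr::write_csv(report, fr <- file.path(out_dir, "quality_report.csv"))
  jsonlite::write_json(list(k_mode = gs$k_mode, top = gs$top,
                            alpha_grid = range(gs$alpha_grid),
                            n_grid = range(gs$n_grid)),
                       fgs <- file.path(out_dir, "grid_search.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artefacts <- c(artefacts, fr, fgs)

  # --- physiochemical case study (optional) --------------------------------
  if (isTRUE(config$include_physiochem)) {
    phys <- run_stage("physiochem", function() {
      generate_model_consistent_physiochem(
        n_wines = config$n_wines, noise_sd = config$noise_sd, seed = config$seed + 1L)
    })
    readr::write_csv(phys$physiochem, fph <- file.path(out_dir, "physiochem.csv"))
    artefacts <- c(artefacts, fph)
    manifest$stages$physiochem <- "run"
  } else {
    manifest$stages$physiochem <- "skipped (chemistry-only configuration)"
  }

  # --- augmentation ---------------------------------------------------------
  plan <- augmentation_plan(n_source = config$plan$n_source,
                            n_holdout = config$plan$n_holdout,
                            n_synth = config$plan$n_synth,
                            k_neighbors = config$plan$k_neighbors,
                            formula = config$plan$formula,
                            seed = config$seed)
  full <- dplyr::inner_join(study$chemistry, study$quality, by = "wine_id")
  split <- run_stage("split", function() split_dataset(full, plan))
  aug <- run_stage("augment", function() smote_augment(split$source, plan))
  write_augmented(aug, fa <- file.path(out_dir, "augmented.csv"))
  artefacts <- c(artefacts, fa, sub("\\.csv$", "_provenance.jsonl", fa))

  # --- network training and evaluation -------------------------------------
  spec <- preset_spec(config$preset)
  if (!is.null(config$max_epochs)) spec$max_epochs <- config$max_epochs
  feat_cols <- setdiff(names(aug$data), "quality")
  model <- run_stage("train", function() {
    norm <- normalize_features(aug$data[, feat_cols])
    train_dnn(spec, norm$train, aug$data$quality, seed = config$seed,
              batch_size = config$batch_size,
              norm = list(center = norm$center, scale = norm$scale))
  })
  preds <- run_stage("evaluate", function() {
    p <- predict(model, full[, feat_cols])
    tibble(wine_id = full$wine_id, observed = full$quality,
           predicted = p, abs_error = abs(p - full$quality),
           holdout = full$wine_id %in% split$holdout$wine_id)
  })
  readr::write_csv(preds, fpred <- file.path(out_dir, "predictions.csv"))
  artefacts <- c(artefacts, fpred)

  manifest$stages$train <- list(preset = spec$name,
                                stopping_epoch = model$stopping_epoch,
                                best_epoch = model$best_epoch)
  manifest$mae <- list(all_originals = mean(preds$abs_error),
                       holdout_only = mean(preds$abs_error[preds$holdout]))
  manifest$grid_best <- as.list(gs$top[1, ])
  manifest$inputs <- as.list(tools::md5sum(sort(artefacts)))
  jsonlite::write_json(manifest, fman <- file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(study = study, modulators = mod_stage$sets, pi = pis,
                 grid_search = gs, report = report, augmented = aug,
                 model = model, predictions = preds,
                 manifest = manifest, paths = c(artefacts, fman)))
}
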