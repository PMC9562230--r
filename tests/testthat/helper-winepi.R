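# Shared fixtures, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracle over index tuples: counts every distinct
# balanced Pi-form directly from first principles, without touching the
# package's enumerator.
brute_force_counts <- function(k, max_degree) {
  additive <- 0L
  if (k >= 3L) {
    for (s in 2:(k - 1L)) {
      additive <- additive + choose(k, s) * (k - s)
    }
  }
  mono <- 0L
  exps <- as.matrix(expand.grid(rep(list(0:max_degree), k)))
  for (d in seq_len(max_degree)) {
    num <- exps[rowSums(exps) == d, , drop = FALSE]
    for (i in seq_len(nrow(num))) for (j in seq_len(nrow(num))) {
      if (!any(num[i, ] > 0 & num[j, ] > 0)) mono <- mono + 1L
    }
  }
  c(additive = 2L * additive, monomial = mono)
}

# A minimal 8-wine source table with two features and a quality column.
tiny_source <- function(n = 8L, seed = 42L) {
  set.seed(seed)
  tibble::tibble(
    wine_id = sprintf("S%02d", seq_len(n)),
    f1 = runif(n, 1, 5),
    f2 = runif(n, 10, 50),
    quality = runif(n, 4, 7)
  )
}

# A full model-consistent study joined into one wine table (features + quality).
study_table <- function(seed, type = c("chemistry", "physiochem"), noise_sd = 0.1) {
  type <- match.arg(type)
  if (type == "chemistry") {
    s <- generate_model_consistent(seed = seed, noise_sd = noise_sd)
    dplyr::inner_join(s$chemistry, s$quality, by = "wine_id")
  } else {
    s <- generate_model_consistent_physiochem(seed = seed, noise_sd = noise_sd)
    dplyr::inner_join(s$physiochem, s$quality, by = "wine_id")
  }
}

# Train a preset on the SMOTE-augmented source split and report MAE on all
# original wines.
augmented_fit_mae <- function(preset, seed, noise_sd = 0.1) {
  full <- study_table(seed, if (preset == "data1") "chemistry" else "physiochem",
                      noise_sd = noise_sd)
  plan <- augmentation_plan(seed = seed)
  sp <- split_dataset(full, plan)
  aug <- smote_augment(sp$source, plan)
  feat <- setdiff(names(aug$data), "quality")
  norm <- normalize_features(aug$data[, feat])
  model <- train_dnn(preset_spec(preset), norm$train, aug$data$quality, seed = seed,
                     norm = list(center = norm$center, scale = norm$scale))
  evaluate_mae(model, full[, feat], full$quality)
}
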