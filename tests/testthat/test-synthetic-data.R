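# Synthetic study generators: ranges, determinism, sensory structure and
# model-consistent construction.

test_that("default compound specs carry the reported ranges", {
  specs <- default_compound_specs()
  expect_identical(nrow(specs), 14L)
  lin <- specs[specs$name == "linalool", ]
  expect_equal(c(lin$conc_low, lin$conc_high, lin$odt), c(0.83, 170, 25))
  expect_equal(specs$odt[specs$name == "beta-damascenone"], 0.05)
  expect_equal(specs$odt[specs$name == "2-phenylethan-1-ol"], 10000)
  expect_true(all(specs$conc_low <= specs$conc_high))
  expect_true(all(specs$conc_low > 0 & specs$odt > 0))
  # compounds without printed values are flagged
  expect_true(all(specs$source[specs$name %in%
    c("hexan-1-ol", "benzaldehyde", "phenol")] == "default"))
})

test_that("chemistry is log-sampled within range and seed-deterministic", {
  specs <- default_compound_specs()
  chem <- generate_chemistry(18, specs, seed = 1)
  expect_identical(nrow(chem), 18L)
  expect_true(all(chem$linalool >= 0.83 & chem$linalool <= 170))
  expect_identical(chem, generate_chemistry(18, specs, seed = 1))
  expect_false(identical(chem, generate_chemistry(18, specs, seed = 2)))
  # empty case keeps the column contract
  empty <- generate_chemistry(0, specs, seed = 1)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), c("wine_id", specs$name))
  # range containment on a large draw: >10,000 values, all inside
  big <- generate_chemistry(1000, specs, seed = 3)
  for (i in seq_len(nrow(specs))) {
    v <- big[[specs$name[i]]]
    expect_true(all(v >= specs$conc_low[i] & v <= specs$conc_high[i]),
                label = specs$name[i])
  }
  expect_error(generate_chemistry(3, specs |> dplyr::mutate(conc_low = -1)),
               class = "winepi_error_config")
})

test_that("physiochemical table respects its documented ranges", {
  phys <- generate_physiochem(18, seed = 1)
  expect_true(all(phys$pH >= 3.0 & phys$pH <= 4.2))
  expect_identical(phys, generate_physiochem(18, seed = 1))
  expect_identical(nrow(generate_physiochem(0, seed = 1)), 0L)
  expect_error(generate_physiochem(3, default_physiochem_ranges()[-1, ]),
               class = "winepi_error_config")
})

test_that("sensory generator has the additive panel structure", {
  # degenerate noise: every rating equals the grand mean
  degenerate <- generate_sensory(5, 4, wine_effect_sd = 0, panelist_effect_sd = 0,
                                 noise_sd = 0, seed = 1)
  expect_true(all(degenerate$ratings$rating == 5.5))
  expect_true(all(degenerate$quality$quality == 5.5))
  expect_identical(nrow(degenerate$quality), 5L)
  # clamp: no rating can leave the 1-10 scale, however wild the effects
  wild <- generate_sensory(10, 10, wine_effect_sd = 5, panelist_effect_sd = 5,
                           noise_sd = 5, seed = 2)
  expect_true(all(wild$ratings$rating >= 1 & wild$ratings$rating <= 10))
  # per-wine mean dispersion matches the generating model:
  # sd = sqrt(wine_sd^2 + noise_sd^2 / n_panelists) ~= 0.637 at the defaults
  sds <- vapply(1:30, function(s) {
    sd(generate_sensory(18, 22, seed = s)$quality$quality)
  }, numeric(1))
  expect_equal(mean(sds), sqrt(0.6^2 + 1 / 22), tolerance = 0.08)
})

test_that("model-consistent quality is exactly the proxy when noiseless", {
  s <- generate_model_consistent(seed = 5)
  sets <- assemble_modulators(unique(default_modulator_assignment()$member))
  pis <- compute_pi_terms(s$chemistry, sets, s$truth$forms)
  model <- quality_model(s$truth$forms,
                         exponent_schedule(s$truth$alpha, s$truth$n, 5),
                         k = s$truth$k)
  expect_equal(quality_proxy(pis[, -1], model), s$quality$quality,
               tolerance = 1e-12)
  # auto-k puts quality on the rating scale, centred near 5.5
  expect_true(all(s$quality$quality > 1 & s$quality$quality < 10))
  expect_equal(median(s$quality$quality), 5.5, tolerance = 1.2)
  # determinism, including the noisy path
  n1 <- generate_model_consistent(seed = 5, noise_sd = 0.1)
  n2 <- generate_model_consistent(seed = 5, noise_sd = 0.1)
  expect_identical(n1$quality, n2$quality)
  expect_identical(n1$chemistry, n2$chemistry)
})

test_that("model-consistent physiochemical study mirrors the two-group proxy", {
  p <- generate_model_consistent_physiochem(seed = 9)
  qp <- quality_proxy_two_group(p$pi$P1, p$pi$P2, k = p$truth$k, n = p$truth$n)
  expect_equal(qp, p$quality$quality, tolerance = 1e-12)
  expect_identical(p$quality,
                   generate_model_consistent_physiochem(seed = 9)$quality)
})

test_that("a study writes headered CSVs with a JSON sidecar", {
  dir <- withr::local_tempdir()
  s <- generate_model_consistent(seed = 2)
  paths <- write_study(s, dir)
  expect_true(all(file.exists(file.path(dir, c("chemistry.csv", "quality.csv",
                                               "study.json")))))
  back <- readr::read_csv(file.path(dir, "chemistry.csv"), show_col_types = FALSE)
  expect_identical(names(back)[1], "wine_id")
  expect_equal(as.data.frame(back), as.data.frame(s$chemistry), tolerance = 1e-12)
  sidecar <- jsonlite::read_json(file.path(dir, "study.json"))
  expect_identical(sidecar$seed, 2L)
  expect_equal(sidecar$truth$alpha, 0.8)
})
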