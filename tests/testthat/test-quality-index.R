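# Exponent schedule, quality proxy, Euclidean ranking and grid search.

test_that("exponent schedule is the geometric weight sequence", {
  expect_equal(exponent_schedule(1, 1, 5)$weights, rep(1, 5))
  expect_equal(exponent_schedule(0.8, 1, 5)$weights,
               c(1, 0.8, 0.64, 0.512, 0.4096))
  expect_equal(exponent_schedule(0.5, 2, 3)$weights, c(2, 1, 0.5))
  expect_error(exponent_schedule(0, 1, 5), class = "winepi_error_config")
  expect_error(exponent_schedule(0.8, -1, 5), class = "winepi_error_config")
})

test_that("quality proxy equals the direct weighted product", {
  sched <- exponent_schedule(0.8, 1, 5)
  m1 <- quality_model("(x1+x2)/x3", sched, k = 1)
  expect_equal(quality_proxy(rep(1, 5), m1), 1)
  expect_equal(quality_proxy(c(2, 1, 1, 1, 1), m1), 2)
  # independent log-domain oracle: explicit product of powers
  pis <- c(2, 2, 2, 2, 2)
  direct <- prod(pis^sched$weights)
  expect_equal(quality_proxy(pis, m1), direct, tolerance = 1e-12)
  expect_equal(direct, 2^(1 + 0.8 + 0.64 + 0.512 + 0.4096))
  # random pis: relative error vs direct product below 1e-12
  set.seed(3)
  for (i in 1:20) {
    p <- exp(runif(5, log(0.05), log(50)))
    expect_equal(quality_proxy(p, m1), prod(p^sched$weights), tolerance = 1e-12)
  }
  expect_error(quality_proxy(c(2, 0, 1, 1, 1), m1), class = "winepi_error_domain")
})

test_that("two-group proxy follows k * pi1^n * pi2^(n^2)", {
  expect_equal(quality_proxy_two_group(1, 1, k = 0.94, n = 1), 0.94)
  expect_equal(quality_proxy_two_group(2, 1, k = 1, n = 1), 2)
  expect_equal(quality_proxy_two_group(2, 2, k = 1, n = 0.5), 2^0.5 * 2^0.25)
  expect_error(quality_proxy_two_group(0, 1, 1, 1), class = "winepi_error_domain")
})

test_that("the proxy is monotone and log-linear in each Pi-term", {
  sched <- exponent_schedule(0.8, 1.2, 5)
  model <- quality_model("(x1+x2)/x3", sched)
  base <- c(1.5, 2, 0.7, 3, 1.1)
  q0 <- quality_proxy(base, model)
  for (i in 1:5) {
    up <- base; up[i] <- up[i] * 1.3
    expect_gt(quality_proxy(up, model), q0)
    # finite-difference slope of log QP in log pi_i equals the weight
    h <- 1e-6
    bumped <- base; bumped[i] <- bumped[i] * exp(h)
    slope <- (log(quality_proxy(bumped, model)) - log(q0)) / h
    expect_equal(slope, sched$weights[i], tolerance = 1e-5)
  }
})

test_that("Euclidean distance matches direct arithmetic", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_error(euclidean_distance(1:3, 1:4), class = "winepi_error_config")
})

test_that("published per-wine columns reproduce the frozen reference distance", {
  ref <- reference_quality_table()
  expect_identical(nrow(ref), 18L)
  # frozen from direct sum-of-squares arithmetic over the printed pairs
  expect_equal(euclidean_distance(ref$alpha0.8_n1.0, ref$perceived_quality),
               4.8459594509, tolerance = 1e-9)
})

test_that("grid search matches an exhaustive re-evaluation on small grids", {
  set.seed(21)
  P <- matrix(exp(runif(8 * 5, log(0.5), log(5))), 8, 5)
  obs <- runif(8, 4, 7)
  ag <- c(0.6, 0.8, 1.0); ng <- c(0.8, 1.0, 1.2)
  gs <- grid_search(P, obs, ag, ng, top_m = 9)
  oracle <- expand.grid(n = ng, alpha = ag)
  oracle$distance <- mapply(function(a, n) {
    model <- quality_model("(x1+x2)/x3", exponent_schedule(a, n, 5))
    euclidean_distance(quality_proxy(P, model), obs)
  }, oracle$alpha, oracle$n)
  oracle <- oracle[order(oracle$distance, oracle$alpha, oracle$n), ]
  expect_equal(gs$top$distance, oracle$distance)
  expect_equal(gs$top$alpha, oracle$alpha)
  expect_equal(gs$top$n, oracle$n)
})

test_that("grid search honours its ranking contract", {
  set.seed(22)
  P <- matrix(exp(rnorm(6 * 5, 0, 0.3)), 6, 5)
  obs <- runif(6, 4, 7)
  # single cell
  one <- grid_search(P, obs, alpha_grid = 0.8, n_grid = 1.0, top_m = 3)
  expect_identical(nrow(one$top), 1L)
  model <- quality_model("(x1+x2)/x3", exponent_schedule(0.8, 1, 5))
  expect_equal(one$top$distance, euclidean_distance(quality_proxy(P, model), obs))
  # top_m = 5 on a 10 x 10 grid: exactly 5 rows, non-decreasing distances
  gs <- grid_search(P, obs, seq(0.5, 1.4, 0.1), seq(0.5, 1.4, 0.1), top_m = 5)
  expect_identical(nrow(gs$top), 5L)
  expect_true(all(diff(gs$top$distance) >= 0))
  expect_true(all(diff(gs$grid$distance) >= 0))
  # ties broken lexicographically: constant pis make every cell equal
  tie <- grid_search(matrix(1, 4, 5), rep(2, 4),
                     alpha_grid = c(0.9, 0.7), n_grid = c(1.2, 1.0), top_m = 4)
  expect_equal(tie$top$alpha, c(0.7, 0.7, 0.9, 0.9))
  expect_equal(tie$top$n, c(1.0, 1.2, 1.0, 1.2))
  expect_error(grid_search(P, obs, numeric(0), 1), class = "winepi_error_config")
})

test_that("calibration mode rescales k to the least-squares optimum", {
  set.seed(23)
  P <- matrix(exp(rnorm(10 * 5, 0, 0.2)), 10, 5)
  model <- quality_model("(x1+x2)/x3", exponent_schedule(0.8, 1, 5), k = 1)
  obs <- 3.7 * quality_proxy(P, model)
  gs <- grid_search(P, obs, alpha_grid = c(0.7, 0.8), n_grid = c(1.0, 1.1),
                    k_mode = "calibrate")
  best <- gs$top[1, ]
  expect_equal(c(best$alpha, best$n), c(0.8, 1.0))
  expect_equal(best$k, 3.7, tolerance = 1e-9)
  expect_equal(best$distance, 0, tolerance = 1e-9)
})

test_that("noiseless truth is recovered through the full search pipeline", {
  s <- generate_model_consistent(truth = list(alpha = 0.8, n = 1.0, k = 1), seed = 31)
  gs <- grid_search(s$pi, s$quality$quality)
  expect_equal(c(gs$top$alpha[1], gs$top$n[1]), c(0.8, 1.0))
  expect_lt(gs$top$distance[1], 1e-9)
})

test_that("form search identifies the generating Pi-form per modulator", {
  s <- generate_model_consistent(truth = list(alpha = 0.8, n = 1.0, k = 1), seed = 33)
  sets <- assemble_modulators(unique(default_modulator_assignment()$member))
  top <- grid_search_forms(s$chemistry, sets,
                           candidates = c("(x1+x2)/x3", "x3/(x1+x2)"),
                           observed = s$quality$quality,
                           alpha_grid = c(0.7, 0.8, 0.9),
                           n_grid = c(0.9, 1.0, 1.1), top_m = 3)
  expect_lt(top$distance[1], 1e-9)
  expect_true(all(top[1, c("M1", "M2", "M3", "M4", "M5")] == "(x1+x2)/x3"))
})

test_that("the per-wine report has one proxy column per model and round-trips", {
  s <- generate_model_consistent(seed = 4)
  models <- lapply(c(0.8, 0.7), function(a) {
    quality_model("(x1+x2)/x3", exponent_schedule(a, 1, 5), k = s$truth$k)
  })
  rep18 <- quality_report(models, s$pi, s$quality$quality, s$wine_ids)
  expect_identical(dim(rep18), c(18L, 4L))
  expect_identical(names(rep18)[1:2], c("wine_id", "observed"))
  none <- quality_report(list(), s$pi, s$quality$quality, s$wine_ids)
  expect_identical(names(none), c("wine_id", "observed"))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rep18, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(rep18), tolerance = 1e-12)
})

test_that("tidiers expose the search surface", {
  s <- generate_model_consistent(truth = list(alpha = 0.8, n = 1, k = 1), seed = 6)
  gs <- grid_search(s$pi, s$quality$quality, c(0.7, 0.8), c(0.9, 1.0))
  expect_identical(nrow(tidy(gs)), nrow(gs$top))
  expect_identical(nrow(tidy(gs, full = TRUE)), 4L)
  g <- glance(gs)
  expect_identical(g$n_combinations, 4L)
  expect_equal(c(g$alpha, g$n), c(0.8, 1.0))
  expect_s3_class(autoplot(gs), "ggplot")
})
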