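test_that("fit_ols recovers planted linear models", {
  # constant response: zero weights, intercept c
  fm_c <- toy_feature_matrix(30, coefs = c(0, 0), intercept = 0, seed = 1)
  fm_c$target_ha_rmsd <- rep(2.7, 30)
  m_c <- fit_ols(fm_c)
  expect_equal(unname(m_c$weights), c(0, 0), tolerance = 1e-10)
  expect_equal(m_c$intercept, 2.7, tolerance = 1e-10)

  # exact plant y = 2 x1 - 3 x2 + 1
  fm <- toy_feature_matrix(50, coefs = c(2, -3), intercept = 1, seed = 2)
  est <- tidy(fit_ols(fm))
  expect_equal(est$estimate, c(1, 2, -3), tolerance = 1e-8)

  # noisy plant at n = 1000: small coefficient error
  fm_n <- toy_feature_matrix(1000, coefs = c(2, -3, 0.5), intercept = 1,
                             noise_sd = 0.1, seed = 1)
  est_n <- tidy(fit_ols(fm_n))
  expect_lt(sqrt(mean((est_n$estimate - c(1, 2, -3, 0.5))^2)), 0.05)

  # rank-deficient design: pseudo-inverse with warning
  raw <- tibble::as_tibble(as.data.frame(toy_feature_matrix(20, coefs = c(1, 1), seed = 3)))
  raw$p3_dup <- raw$p1_t01 * 2  # feature-space collinearity survives scaling
  fm_rd <- decoyrank:::new_feature_matrix(raw)
  expect_warning(m_rd <- fit_ols(fm_rd), "rank-deficient")
  expect_lt(max(abs(predict(m_rd, fm_rd) - fm_rd$target_ha_rmsd)), 1e-8)
})

test_that("fit_pls matches OLS at full rank, finds single-feature plants, and
           plateaus at the planted latent dimension", {
  fm <- toy_feature_matrix(60, coefs = c(1.5, -2, 0.3, 1), noise_sd = 0.05, seed = 4)
  m_ols <- fit_ols(fm)
  m_pls <- fit_pls(fm, ncomp = 4)
  expect_equal(predict(m_pls, fm), predict(m_ols, fm), tolerance = 1e-8)
  expect_error(fit_pls(fm, ncomp = 5), "rank")

  # y exactly proportional to the sole feature: one component suffices
  fm1 <- toy_feature_matrix(40, coefs = c(3), seed = 5)
  m1 <- fit_pls(fm1, ncomp = 1)
  r2 <- 1 - sum((predict(m1, fm1) - fm1$target_ha_rmsd)^2) /
    sum((fm1$target_ha_rmsd - mean(fm1$target_ha_rmsd))^2)
  expect_equal(r2, 1, tolerance = 1e-10)

  # 3-latent-factor data: CV RMSE improves up to ncomp = 3 then plateaus
  withr::local_seed(1)
  n <- 200; p <- 12
  latent <- matrix(rnorm(n * 3), n, 3)
  load <- matrix(rnorm(3 * p), 3, p)
  X <- latent %*% load + matrix(rnorm(n * p, sd = 0.05), n, p)
  y <- latent %*% c(1, -2, 1.5) + rnorm(n, sd = 0.1)
  cols <- paste0("p", rep(1:9, length.out = p), "_l", sprintf("%02d", 1:p))
  fml <- decoyrank:::new_feature_matrix(dplyr::bind_cols(
    tibble::tibble(decoy_id = sprintf("d%03d", 1:n), target_ha_rmsd = as.numeric(y)),
    tibble::as_tibble(`colnames<-`(X, cols))
  ))
  cv <- vapply(1:5, function(nc) {
    cross_validate(fml, "pls", list(ncomp = nc), k = 5, seed = 1)
  }, numeric(1))
  expect_gt(cv[1], cv[3])
  expect_gt(cv[2], cv[3])
  expect_lt(abs(cv[4] - cv[3]), 0.25 * cv[3])  # plateau past the true rank
})

test_that("epsilon-SVR solves planted problems and degenerates gracefully", {
  # noiseless linear: near-exact weight recovery
  fm <- toy_feature_matrix(120, coefs = c(1, 0, 0), seed = 6)
  m <- fit_svr(fm, kernel = "linear", C = 1e4, epsilon = 0.01)
  w_raw <- tidy(m)$estimate[-1]
  expect_gt(w_raw[1], 0.99); expect_lt(w_raw[1], 1.01)
  expect_lt(max(abs(w_raw[-1])), 0.01)

  # all |y - const| < eps: no support vectors, constant prediction
  fm_flat <- toy_feature_matrix(30, coefs = c(0, 0), seed = 7)
  fm_flat$target_ha_rmsd <- 1.5 + runif(30, -0.01, 0.01)
  m_flat <- fit_svr(fm_flat, kernel = "linear", C = 1, epsilon = 0.1)
  expect_equal(m_flat$training_meta$n_support, 0)
  pr <- predict(m_flat, fm_flat)
  expect_lt(diff(range(pr)), 1e-12)
  expect_lt(max(abs(pr - 1.5)), 0.1)

  # sin(x): rbf succeeds where linear cannot
  withr::local_seed(1)
  n <- 200
  x1 <- runif(n, -3, 3)
  fm_sin <- decoyrank:::new_feature_matrix(tibble::tibble(
    decoy_id = sprintf("d%03d", 1:n), target_ha_rmsd = sin(x1),
    p1_x = x1, p2_z = rnorm(n)
  ))
  te <- fm_sin[151:200, ]
  tr <- decoyrank:::new_feature_matrix(fm_sin[1:150, ])
  m_rbf <- fit_svr(tr, kernel = "rbf", C = 10, gamma = 1, epsilon = 0.01)
  m_lin <- fit_svr(tr, kernel = "linear", C = 10, epsilon = 0.01)
  rmse <- function(mod) sqrt(mean((predict(mod, te) - te$target_ha_rmsd)^2))
  expect_lt(rmse(m_rbf), 0.05)
  expect_gt(rmse(m_lin), 0.3)

  expect_error(fit_svr(fm, C = -1), "positive")
})

test_that("linSVR approaches OLS in the C -> Inf, eps -> 0 limit", {
  fm <- toy_feature_matrix(80, coefs = c(2, -1, 0.5), intercept = 0.3, seed = 8)
  m_ols <- fit_ols(fm)
  m_svr <- fit_svr(fm, kernel = "linear", C = 1e6, epsilon = 1e-4)
  grid_rows <- toy_feature_matrix(40, coefs = c(2, -1, 0.5), seed = 9)
  expect_lt(max(abs(predict(m_svr, grid_rows) - predict(m_ols, grid_rows))), 1e-3)
})

test_that("scaling equivariance: rescaling a raw feature leaves predictions
           unchanged for all four kinds", {
  fm <- toy_feature_matrix(80, coefs = c(1, -2, 0.7), noise_sd = 0.05, seed = 10)
  raw10 <- tibble::as_tibble(as.data.frame(fm))
  raw10[[3]] <- raw10[[3]] * 10
  fm10 <- decoyrank:::new_feature_matrix(raw10)
  fits <- list(
    ols = list(fit_ols(fm), fit_ols(fm10)),
    pls = list(fit_pls(fm, ncomp = 3), fit_pls(fm10, ncomp = 3)),
    linsvr = list(fit_svr(fm, kernel = "linear", C = 5), fit_svr(fm10, kernel = "linear", C = 5)),
    radsvr = list(fit_svr(fm, kernel = "rbf", C = 5, gamma = 0.3),
                  fit_svr(fm10, kernel = "rbf", C = 5, gamma = 0.3))
  )
  for (kind in names(fits)) {
    # exact solvers agree to numerical precision; SMO solutions agree to the
    # solver's KKT tolerance
    tol <- if (grepl("svr", kind)) 1e-3 else 1e-8
    expect_equal(predict(fits[[kind]][[1]], fm), predict(fits[[kind]][[2]], fm10),
                 tolerance = tol, label = kind)
  }
})

test_that("prediction is name-matched, pure, and survives serialization", {
  fm <- toy_feature_matrix(50, coefs = c(1.2, -0.8), noise_sd = 0.02, seed = 11)
  for (maker in list(
    function() fit_ols(fm),
    function() fit_pls(fm, ncomp = 2),
    function() fit_svr(fm, kernel = "linear", C = 2),
    function() fit_svr(fm, kernel = "rbf", C = 2, gamma = 0.5)
  )) {
    m <- maker()
    base <- predict(m, fm)
    # permuted columns
    perm <- fm[, rev(names(fm))]
    expect_equal(predict(m, perm), base, tolerance = 1e-14)
    # JSON round-trip
    f <- withr::local_tempfile(fileext = ".json")
    save_model(m, f)
    expect_equal(predict(load_model(f), fm), base, tolerance = 1e-12)
  }
  m <- fit_ols(fm)
  expect_error(predict(m, fm[, 1:2]), "missing model column")
  # training rows through their own noiseless OLS: tiny residuals
  fm0 <- toy_feature_matrix(50, coefs = c(1, 1), seed = 12)
  expect_lt(max(abs(predict(fit_ols(fm0), fm0) - fm0$target_ha_rmsd)), 1e-8)
})

test_that("model JSON errors are clean", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version": "1", "kind"', f)
  expect_error(load_model(f), "cannot parse")
  fm <- toy_feature_matrix(20, coefs = c(1), seed = 13)
  m <- fit_ols(fm)
  ok <- withr::local_tempfile(fileext = ".json")
  save_model(m, ok)
  js <- jsonlite::read_json(ok)
  js$kind <- "forest"
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(js, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(bad), "unsupported model kind")
  js$kind <- "ols"; js$schema_version <- "99"
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(js, bad2, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(bad2), "schema version mismatch")
})

test_that("cross_validate is exact for perfect predictors, null-calibrated,
           and bit-reproducible", {
  # y duplicated as sole feature
  y <- rnorm(100, 2, 0.5)
  fm <- decoyrank:::new_feature_matrix(tibble::tibble(
    decoy_id = sprintf("d%03d", 1:100), target_ha_rmsd = y, p1_y = y))
  expect_lt(cross_validate(fm, "ols", k = 5, seed = 1), 1e-8)

  # pure-noise target: CV RMSE ~ sd(y), averaged over 20 seeds, within 15%
  cvs <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      fmn <- toy_feature_matrix(80, coefs = c(0, 0, 0), seed = 2000 + s)
      fmn$target_ha_rmsd <- rnorm(80)
      cross_validate(fmn, "ols", k = 5, seed = s) / sd(fmn$target_ha_rmsd)
    })
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 1), 0.15)

  fm3 <- toy_feature_matrix(60, coefs = c(1, -1), noise_sd = 0.2, seed = 14)
  expect_identical(cross_validate(fm3, "linsvr", list(C = 1), k = 5, seed = 9),
                   cross_validate(fm3, "linsvr", list(C = 1), k = 5, seed = 9))
})

test_that("grid_search is deterministic, honors the default grids, and ties
           break toward the simplest model", {
  expect_equal(default_grid("linsvr")$C, 10^seq(-8, 8))
  gr <- default_grid("radsvr")
  expect_setequal(unique(gr$C), 10^seq(-4, 10))
  expect_setequal(unique(gr$gamma), 10^seq(-11, 2))

  fm <- toy_feature_matrix(80, coefs = c(1, -0.5), noise_sd = 0.1, seed = 15)
  one <- grid_search(fm, "linsvr", grid = tibble::tibble(C = 1), k = 5, seed = 1)
  expect_equal(one$best$C, 1)
  expect_equal(nrow(one$cv), 1)

  gs1 <- grid_search(fm, "linsvr", grid = tibble::tibble(C = c(0.1, 1, 10)),
                     k = 5, seed = 3)
  gs2 <- grid_search(fm, "linsvr", grid = tibble::tibble(C = c(0.1, 1, 10)),
                     k = 5, seed = 3)
  expect_identical(gs1$best, gs2$best)
  expect_identical(gs1$cv$rmse, gs2$cv$rmse)

  # duplicated grid point: exact RMSE tie resolved to the smallest C listed
  dup <- grid_search(fm, "linsvr", grid = tibble::tibble(C = c(5, 5)), k = 5, seed = 1)
  expect_equal(dup$best$C, 5)
  y <- fm$target_ha_rmsd
  # a real tie across C values: constant target makes every C equivalent
  fm_c <- fm
  fm_c$target_ha_rmsd <- rep(1.4, nrow(fm))
  tie <- grid_search(fm_c, "linsvr", grid = tibble::tibble(C = c(0.01, 1, 100)),
                     k = 5, seed = 1)
  expect_equal(tie$best$C, 0.01)
})

test_that("radSVR prediction collapse triggers the overfitting guard", {
  withr::local_seed(3)
  n <- 120
  x <- matrix(rnorm(n * 2), n, 2)
  fm <- decoyrank:::new_feature_matrix(dplyr::bind_cols(
    tibble::tibble(decoy_id = sprintf("d%03d", 1:n),
                   target_ha_rmsd = runif(n, 0.5, 3.5)),
    tibble::as_tibble(`colnames<-`(x, c("p1_a", "p2_b")))
  ))
  # enormous gamma + tiny C: every prediction collapses onto the intercept
  expect_warning(
    fit_svr(fm, kernel = "rbf", C = 0.01, gamma = 1e6, epsilon = 0.01),
    "collapse"
  )
})
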