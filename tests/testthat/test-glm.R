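# 200-cell design with one effectively binary driver and 15 noise layers,
# used for the closed-form logit oracle
binary_design <- function(seed = 10) {
  g <- fire_grid(20, 10)
  X <- generate_predictors(g, seed = seed, spatial_scale = 1)
  X[, "crop"] <- rep(c(0, 1), each = 100)
  X
}

test_that("a constant response collapses to the saturated intercept mean", {
  X <- binary_design()
  m <- fit_fire_glm(X, rep(0.2, 200), "BA")
  expect_equal(plogis(m$beta[["(Intercept)"]]), 0.2, tolerance = 1e-10)
  expect_equal(max(abs(m$beta[-1])), 0, tolerance = 1e-8)
})

test_that("a binary predictor recovers the closed-form log odds ratio of the group means", {
  X <- binary_design()
  y <- ifelse(X[, "crop"] == 1, 0.6, 0.2)   # exact group means
  m <- fit_fire_glm(X, y, "BA")
  slope_raw <- m$beta[["crop"]] / m$scale[["crop"]]
  oracle <- (qlogis(0.6) - qlogis(0.2))     # 2x2 mean-table log odds ratio
  expect_equal(slope_raw, oracle, tolerance = 1e-6)
  expect_equal(plogis(m$beta[["(Intercept)"]] -
                        m$beta[["crop"]] * m$center[["crop"]] /
                        m$scale[["crop"]]), 0.2, tolerance = 1e-6)
})

test_that("quasi and plain families share coefficients while SEs scale with the dispersion", {
  d <- fixture_dataset()
  m <- fixture_ba_model()
  plain <- suppressWarnings(
    stats::glm(d$fire$BA ~ ., family = binomial(),
               data = as.data.frame(scale(d$predictors))))
  expect_equal(unname(m$beta), unname(coef(plain)), tolerance = 1e-8)
  se_plain <- summary(plain)$coefficients[, "Std. Error"]
  expect_equal(unname(m$se / se_plain),
               rep(sqrt(m$dispersion), length(m$se)), tolerance = 1e-6)
  expect_equal(unname(m$t_values), unname(m$beta / m$se))
})

test_that("permuting cell order leaves fitted quantities unchanged", {
  d <- fixture_dataset()
  set.seed(9)
  perm <- sample(nrow(d$predictors))
  m1 <- fixture_ba_model()
  m2 <- fit_fire_glm(d$predictors[perm, ], d$fire$BA[perm], "BA")
  expect_equal(m1$beta, m2$beta, tolerance = 1e-9)
  expect_equal(m1$dispersion, m2$dispersion, tolerance = 1e-9)
})

test_that("degenerate designs fail loudly", {
  d <- fixture_dataset()
  X <- d$predictors
  X[, "TPI"] <- 2 * X[, "VPD"]   # collinear after z-scoring
  expect_error(fit_fire_glm(X, d$fire$BA, "BA"), "TPI|collinear")
  expect_error(fit_fire_glm(d$predictors[1:100, ], d$fire$BA[1:100], "BA"),
               "at least")
  expect_error(fit_fire_glm(d$predictors, d$fire$BA[-1], "BA"), "length")
})

test_that("predictions equal fitted values on training data and the intercept at the predictor means", {
  d <- fixture_dataset()
  m <- fixture_ba_model()
  expect_equal(predict(m, d$predictors), unname(fitted(m$fit)),
               tolerance = 1e-12)
  at_center <- matrix(m$center, nrow = 1,
                      dimnames = list(NULL, names(m$center)))
  expect_equal(predict(m, at_center), plogis(m$beta[["(Intercept)"]]),
               ignore_attr = TRUE)
})

test_that("increasing a positive-coefficient predictor strictly increases the prediction", {
  m <- fixture_ba_model()
  probe <- matrix(m$center, nrow = 1,
                  dimnames = list(NULL, names(m$center)))
  j <- names(which.max(m$beta[predictor_names()]))
  probe2 <- probe; probe2[, j] <- probe2[, j] + m$scale[[j]]
  expect_gt(predict(m, probe2), predict(m, probe))
})

test_that("predictive intervals bracket the fit, stay in (0,1) for BA, and shrink with sample size", {
  d <- fixture_dataset()
  m <- fixture_ba_model()
  ci <- predictive_interval(m, d$predictors)
  expect_true(all(ci$lower <= ci$fit & ci$fit <= ci$upper))
  expect_true(all(ci$lower > 0 & ci$upper < 1))
  expect_error(predictive_interval(m, d$predictors, level = 1.2), "level")

  big <- generate_dataset(fire_grid(80, 40), seed = 7,
                          truth = recovery_truth())
  small <- generate_dataset(fire_grid(20, 10), seed = 7,
                            truth = recovery_truth())
  mb <- fit_fire_glm(big$predictors, big$fire$BA, "BA")
  ms <- fit_fire_glm(small$predictors, small$fire$BA, "BA")
  probe <- matrix(mb$center, nrow = 1,
                  dimnames = list(NULL, names(mb$center)))
  wb <- with(predictive_interval(mb, probe), upper - lower)
  ws <- with(predictive_interval(ms, probe), upper - lower)
  expect_lt(wb, ws)
})

test_that("zero standard errors collapse the interval onto the fit", {
  m <- fixture_ba_model()
  m$vcov[] <- 0
  ci <- predictive_interval(m, fixture_dataset()$predictors[1:5, ])
  expect_equal(ci$lower, ci$fit)
  expect_equal(ci$upper, ci$fit)
  ci2 <- predictive_interval(m, fixture_dataset()$predictors[1:5, ],
                             method = "multiplicative")
  expect_equal(ci2$lower, ci2$fit)
})

test_that("partial residuals recover the coefficient as their least-squares slope", {
  m <- fixture_ba_model()
  for (j in c("VPD", "GPP", "roads")) {
    pr <- partial_residuals(m, j)
    slope <- coef(lm(partial_residual ~ z, data = pr,
                     weights = weight))[["z"]]
    expect_equal(slope, m$beta[[j]], tolerance = 1e-6)
  }
  expect_error(partial_residuals(m, "unknown"), "unknown")
})

test_that("FS responses round-trip through min-max normalisation and the response-scale dispersion matches a raw-count quasi-Poisson fit", {
  d <- fixture_dataset()
  m <- fit_fire_glm(d$predictors, d$fire$FS, "FS")
  expect_identical(m$norm_min, min(d$fire$FS))
  expect_identical(m$norm_max, max(d$fire$FS))
  mu_norm <- predict(m, d$predictors, denormalise = FALSE)
  mu_raw <- predict(m, d$predictors)
  expect_equal(mu_raw, mu_norm * (m$norm_max - m$norm_min) + m$norm_min)
  expect_true(all(mu_norm > 0))

  raw <- stats::glm(d$fire$FS ~ ., family = quasipoisson(),
                    data = as.data.frame(scale(d$predictors)))
  expect_equal(dispersion(m, "response"), summary(raw)$dispersion,
               tolerance = 0.02)
})

test_that("models survive a JSON round trip with identical predictions and intervals", {
  d <- fixture_dataset()
  m <- fit_fire_glm(d$predictors, d$fire$FI, "FI")
  path <- withr::local_tempfile(fileext = ".json")
  write_fire_glm(m, path)
  m2 <- read_fire_glm(path)
  X <- d$predictors[1:20, ]
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(predictive_interval(m2, X), predictive_interval(m, X),
               tolerance = 1e-12)
  expect_equal(m2$dispersion, m$dispersion)
})
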