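toy_climatology <- function(n = 6, value = 10) {
  vars <- climate_monthly_vars()
  out <- lapply(vars, function(v) matrix(value, n, 12))
  names(out) <- vars
  structure(out, class = "fire_climatology")
}

test_that("anomalies difference out shared state and round-trip through application", {
  a <- toy_climatology()
  d0 <- compute_anomaly(a, a)
  expect_true(all(sapply(d0, function(m) all(m == 0))))
  expect_identical(apply_anomaly(a, d0), a)

  b <- a; for (v in names(b)) b[[v]] <- b[[v]] + 2
  d2 <- compute_anomaly(a, b)
  expect_true(all(sapply(d2, function(m) all(m == 2))))

  short <- a; short$DD <- short$DD[, 1:11]
  expect_error(compute_anomaly(a, short), "month")
})

test_that("anomaly application clips to physical ranges and demands a rule per variable", {
  a <- toy_climatology(value = 30)
  d <- toy_climatology(value = 0)
  d$DD[] <- 5          # 30 + 5 = 35 dry days
  d$VPD[] <- -40       # negative after addition
  out <- apply_anomaly(a, d)
  expect_equal(out$DD[1, 1], 31)    # January cap
  expect_equal(out$DD[1, 2], 28)    # February cap
  expect_true(all(out$VPD == 0))
  rules <- default_clip_rules(); rules$tas <- NULL
  expect_error(apply_anomaly(a, d, rules), "tas")
})

test_that("climatology summarisation picks the prescribed months and seasonality", {
  n <- 4
  clim <- toy_climatology(n = n, value = 5)
  out <- summarise_climatology(clim)
  expect_equal(unname(out[, "DD"]), rep(5, n))
  expect_equal(unname(out[, "DD_s"]), rep(0, n))
  expect_equal(unname(out[, "wind"]), rep(5, n))

  # single-peak VPD in July is selected by the argmax rule
  clim$VPD[, 7] <- 9
  expect_equal(unname(summarise_climatology(clim)[, "VPD"]), rep(9, n))

  # hand oracle for dry-day seasonality
  dd <- c(10, 20, 30, 10, 20, 30, 10, 20, 30, 10, 20, 30)
  clim$DD <- matrix(dd, n, 12, byrow = TRUE)
  out2 <- summarise_climatology(clim)
  expect_equal(unname(out2[, "DD_s"]), rep((30 - 10) / 20, n))

  bad <- clim; bad$DTR <- bad$DTR[, 1:10]
  expect_error(summarise_climatology(bad), "10 months")
})

test_that("summarising the synthetic baseline climatology recovers the climate predictors", {
  X <- generate_predictors(small_grid(), seed = 21)
  cs <- summarise_climatology(baseline_climatology(X))
  expect_equal(unname(cs[, "DD"]), unname(X[, "DD"]), tolerance = 1e-8)
  expect_equal(unname(cs[, "VPD"]), unname(X[, "VPD"]), tolerance = 1e-8)
  expect_equal(unname(cs[, "wind"]), unname(X[, "wind"]), tolerance = 1e-8)
  expect_equal(unname(cs[, "light"]), unname(X[, "light"]), tolerance = 1e-8)
})

test_that("scenario bundles recover requested shifts and leave unshifted groups untouched", {
  X <- generate_predictors(small_grid(), seed = 22)
  sh <- list(climate = c(VPD = 0.5))
  b <- generate_scenario(X, shifts = sh, seed = 5, gcms = c("m1", "m2"))
  for (g in c("m1", "m2")) for (r in rcp_labels <- c("RCP2.6", "RCP6.0")) {
    run <- b$runs[[r]][[g]]
    delta <- compute_anomaly(run$picontrol, run$future)
    expect_equal(mean(delta$VPD), 0.5, tolerance = 0.02)
    expect_equal(mean(delta$DD), 0, tolerance = 0.02)
    # climate-only shifts leave the human layers bit-exact
    expect_identical(run$human_future,
                     b$baseline[, c("popd", "crop", "roads")])
  }
  expect_identical(generate_scenario(X, shifts = sh, seed = 5,
                                     gcms = c("m1", "m2"))$runs,
                   b$runs)
  expect_error(generate_scenario(X, shifts = list(climate = c(bogus = 1))),
               "bogus")

  b0 <- generate_scenario(X, shifts = list(), seed = 5, gcms = "m1")
  d0 <- compute_anomaly(b0$runs[["RCP2.6"]][["m1"]]$picontrol,
                        b0$runs[["RCP2.6"]][["m1"]]$future)
  expect_lt(max(abs(sapply(d0, mean))), 0.05)
})

test_that("the factorial design emits 40 isolated experiments with unique keys", {
  X <- generate_predictors(small_grid(), seed = 23)
  b <- generate_scenario(X, seed = 6)
  em <- build_experiment_matrix(b)
  expect_length(em, 40)
  keys <- sapply(em, function(e) paste(e$label, e$rcp, e$gcm))
  expect_length(unique(keys), 40)

  clim_cols <- c("DD", "DD_s", "VPD", "DTR", "wind")
  veg_cols <- c("GPP", "GPP_s", "grass", "shrub", "tree")
  human_cols <- c("popd", "crop", "roads")
  const_cols <- c("VRM", "TPI", "light")
  base <- b$baseline
  for (e in em) {
    expect_identical(e$predictors[, const_cols], base[, const_cols])
    if (!"climate" %in% e$vary)
      expect_identical(e$predictors[, clim_cols], base[, clim_cols])
    if (!"human" %in% e$vary)
      expect_identical(e$predictors[, human_cols], base[, human_cols])
    if (!any(c("climate", "co2") %in% e$vary))
      expect_identical(e$predictors[, veg_cols], base[, veg_cols])
    if (identical(e$vary, "human"))
      expect_identical(e$predictors[, c(clim_cols, veg_cols)],
                       base[, c(clim_cols, veg_cols)])
  }

  # climate_co2 differs from climate_only only through CO2-driven vegetation
  for (r in b$rcps) for (g in b$gcms) {
    pick <- function(lab) Filter(function(e)
      e$label == lab && e$rcp == r && e$gcm == g, em)[[1]]$predictors
    dif <- pick("climate_co2") != pick("climate_only")
    changed <- colnames(base)[apply(dif, 2, any)]
    expect_true(all(changed %in% veg_cols))
    expect_true(length(changed) > 0)
  }

  incomplete <- b; incomplete$runs[["RCP2.6"]][["MIROC5"]] <- NULL
  expect_error(build_experiment_matrix(incomplete), "MIROC5")
})

test_that("road-density projection reproduces noiseless linear truth and scales linearly in area", {
  set.seed(31)
  n <- 80
  popd <- runif(n, 1, 100); gdp_pc <- runif(n, 1e3, 5e4)
  oecd <- rbinom(n, 1, 0.4); area <- runif(n, 2000, 3000)
  beta <- c("(Intercept)" = 0.05, popd = 0.002, gdp_pc = 1e-6,
            oecd = 0.1, area = 1e-5)
  roads <- beta[1] + beta[2] * popd + beta[3] * gdp_pc + beta[4] * oecd +
    beta[5] * area
  gdp_total <- gdp_pc * popd * area
  fit <- project_road_density(popd, gdp_total, oecd, area,
                              baseline_roads = roads)
  expect_equal(unname(fit$coefficients), unname(beta), tolerance = 1e-8)
  expect_equal(fit$roads, unname(roads), tolerance = 1e-8)

  p1 <- project_road_density(popd, gdp_total, oecd, area,
                             coefficients = beta)$roads
  p2 <- project_road_density(popd, gdp_pc * popd * (2 * area), oecd,
                             2 * area, coefficients = beta)$roads
  expect_equal(p2 - p1, unname(beta["area"] * area), tolerance = 1e-10)

  popd0 <- popd; popd0[1] <- 0
  expect_message(z <- project_road_density(popd0, gdp_total, oecd, area,
                                           coefficients = beta),
                 "zero-population")
  expect_true(z$flagged[1])
  expect_equal(z$gdp_pc[1], median(z$gdp_pc[-1][order(z$gdp_pc[-1])]),
               tolerance = 1e-6)
})

test_that("human-activity anomalies are additive, clipped, and vanish when simulations agree", {
  base <- cbind(popd = c(5, 10), crop = c(0.95, 0.4), roads = c(0.1, 0.2))
  sim_m <- base + 1
  expect_identical(apply_human_anomaly(base, sim_m, sim_m), base)
  sim_f <- sim_m; sim_f[, "crop"] <- sim_f[, "crop"] + 0.1
  out <- apply_human_anomaly(base, sim_m, sim_f)
  expect_equal(unname(out[1, "crop"]), 1)  # 0.95 + 0.1 clipped
  expect_equal(unname(out[2, "crop"]), 0.5)
  # additivity: two sequential anomalies equal their sum (within clip-free range)
  d1 <- sim_m; d1[, "popd"] <- d1[, "popd"] + 2
  d2 <- sim_m; d2[, "popd"] <- d2[, "popd"] + 3
  step <- apply_human_anomaly(apply_human_anomaly(base, sim_m, d1), sim_m, d2)
  both <- sim_m; both[, "popd"] <- both[, "popd"] + 5
  expect_equal(step, apply_human_anomaly(base, sim_m, both))
  expect_error(apply_human_anomaly(base, sim_m[1, , drop = FALSE], sim_f),
               "mismatch")
})
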