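test_that("contributions sum exactly to the linear-predictor change and isolate single drivers", {
  d <- fixture_dataset()
  m <- fixture_ba_model()
  X <- d$predictors[1:100, ]

  # no change, no contribution, null labels
  a0 <- predictor_contributions(m, X, X)
  expect_true(all(a0$contributions == 0))
  expect_true(all(a0$delta_eta == 0))
  expect_true(all(is.na(a0$top_positive)))

  # single-predictor perturbation attributes everything to that predictor
  Xf <- X; Xf[, "VPD"] <- Xf[, "VPD"] + 0.7
  a1 <- predictor_contributions(m, X, Xf)
  expect_identical(a1$delta_eta, unname(a1$contributions[, "VPD"]))
  expect_true(all(a1$contributions[, colnames(X) != "VPD"] == 0))

  # random perturbation: conservation at machine precision against the
  # linear-predictor oracle
  set.seed(77)
  Xr <- X + matrix(rnorm(length(X), sd = 0.3), nrow(X))
  Xr <- pmax(Xr, 0)
  colnames(Xr) <- colnames(X)
  a2 <- predictor_contributions(m, X, Xr)
  eta_oracle <- predict(m, Xr, type = "link") - predict(m, X, type = "link")
  expect_equal(max(abs(rowSums(a2$contributions) - a2$delta_eta)), 0)
  expect_equal(a2$delta_eta, eta_oracle, tolerance = 1e-10)
})

test_that("dominant-driver labels break exact ties by canonical predictor order and counts conserve", {
  # a stub model with unit standardisation makes the tie exact in binary:
  # DD moves by 1 at beta 0.5, VPD by 2 at beta 0.25 -> both contribute 0.5
  nm <- predictor_names()
  stub <- structure(list(
    beta = c("(Intercept)" = 0, stats::setNames(rep(0.1, 16), nm)),
    center = stats::setNames(rep(0, 16), nm),
    scale = stats::setNames(rep(1, 16), nm)), class = "fire_glm")
  stub$beta[c("DD", "VPD")] <- c(0.5, 0.25)
  X0 <- matrix(0, 2, 16, dimnames = list(NULL, nm))
  Xf <- X0; Xf[, "DD"] <- 1; Xf[, "VPD"] <- 2
  a <- predictor_contributions(stub, X0, Xf)
  expect_identical(unname(a$contributions[1, "DD"]),
                   unname(a$contributions[1, "VPD"]))
  expect_equal(unique(a$top_positive), "DD")  # DD precedes VPD in the layout
  expect_true(all(is.na(a$top_negative)))     # zero contributions never win

  m <- fixture_ba_model()

  d <- fixture_dataset()
  set.seed(3)
  Xm <- d$predictors
  Xr <- pmax(Xm + matrix(rnorm(length(Xm), sd = 0.2), nrow(Xm)), 0)
  colnames(Xr) <- colnames(Xm)
  res <- predictor_contributions(m, Xm, Xr)
  dd <- dominant_driver_map(res, region = d$biome)
  expect_equal(sum(dd$frequency$positive$count),
               sum(!is.na(res$top_positive)))
  expect_equal(sum(dd$frequency$negative$count),
               sum(!is.na(res$top_negative)))
})

test_that("biome aggregation reproduces hand-computed areas, shares and merges additively", {
  g <- fire_grid(nlon = 4, nlat = 1, resolution = 0.5, lat_min = 0)
  area <- g$cells$area_km2
  BA <- c(1, 1, 0.5, 0.25)
  biome <- c("f", "f", "s", "s")
  tab <- biome_aggregate(BA, biome, g)
  expect_equal(tab$burnt_area_km2[tab$biome_id == "f"], sum(area[1:2]))
  expect_equal(tab$burnt_area_km2[tab$biome_id == "s"],
               0.5 * area[3] + 0.25 * area[4])
  expect_equal(sum(tab$global_pct), 100)
  expect_equal(tab$global_pct,
               100 * tab$burnt_area_km2 / sum(tab$burnt_area_km2))

  merged <- biome_aggregate(BA, rep("all", 4), g)
  expect_equal(merged$burnt_area_km2, sum(tab$burnt_area_km2))

  fut <- BA * c(1.2, 1.2, 0.8, 0.8)
  tab2 <- biome_aggregate(BA, biome, g, BA_future = fut)
  expect_equal(tab2$pct_change[tab2$biome_id == "f"], 20)
  expect_equal(tab2$pct_change[tab2$biome_id == "s"], -20)
  expect_error(biome_aggregate(BA, c("f", NA, "s", "s"), g), "unmapped")
})

test_that("threshold-crossing counts, northern shares and their antisymmetry behave on hand-built fields", {
  g <- fire_grid(nlon = 5, nlat = 2, resolution = 10, lat_min = 10)
  # row 1 at lat 15 (tropics for band 23.5), row 2 at lat 25 (northern)
  modern <- c(0.002, 0.0005, 0.0005, 0.002, 0.0005,
              0.0005, 0.0005, 0.002, 0.0005, 0.0005)
  future <- c(0.002, 0.0005, 0.0005, 0.0005, 0.0005,
              0.002, 0.002, 0.002, 0.0005, 0.0005)
  out <- ignition_expansion(modern, future, 0.001, g)
  expect_equal(out$n_new_crossings, 2)      # both newly crossing cells northern
  expect_equal(out$northern_share, 1)
  expect_equal(out$n_lost, 1)
  expect_equal(out$pct_change, 100 * (4 - 3) / 3)

  same <- ignition_expansion(modern, modern, 0.001, g)
  expect_equal(same$pct_change, 0)
  expect_equal(same$n_new_crossings, 0)

  swapped <- ignition_expansion(future, modern, 0.001, g)
  expect_equal(swapped$n_new_crossings, out$n_lost)
  expect_equal(swapped$n_lost, out$n_new_crossings)
  expect_error(ignition_expansion(modern, future, 0.001, g,
                                  tropics_band = 95), "band")
})

test_that("change maps apply the 5% relative-change rule per property and jointly", {
  modern <- list(BA = c(0.1, 0.1, 0.1, 0, 0.1),
                 FS = c(10, 10, 10, 5, 10),
                 FI = c(20, 20, 20, 8, 20))
  future <- list(BA = c(0.11, 0.104, 0.11, 1, 0.08),
                 FS = c(11, 10.4, 11, 6, 8),
                 FI = c(22, 20.8, 18, 9, 16))
  cm <- change_map(modern, future)
  expect_equal(as.character(cm$BA), c("increase", "none", "increase", NA,
                                      "decrease"))
  expect_equal(as.character(cm$combined[1]), "increase")  # all three +10%
  expect_equal(as.character(cm$combined[2]), "none")      # +4% below cutoff
  expect_equal(as.character(cm$combined[3]), "none")      # FI decreases
  expect_true(is.na(cm$combined[4]))                      # modern BA = 0
  expect_equal(as.character(cm$combined[5]), "decrease")
  expect_equal(cm$n_excluded, 1)
})
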