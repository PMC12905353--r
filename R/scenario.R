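#' @name climatology
#' @title Monthly climatologies
#'
#' @description
#' A climatology is a named list of `n_cells x 12` matrices, one per monthly
#' variable (`DD` dry days, `VPD`, `DTR`, `wind`, `tas` mean temperature,
#' `light`), as produced by [baseline_climatology()] and consumed by the
#' anomaly and summarisation operations.
#'
#' `baseline_climatology()` expands a predictor field into a consistent
#' monthly cycle: dry days follow a cosine seasonal cycle whose amplitude
#' reproduces the cell's dry-day seasonality (capped where the monthly value
#' would exceed the days in a month), VPD and DTR peak in the month of their
#' annual maximum, temperature peaks mid-year, and wind and lightning are
#' carried as constant monthly fields. Summarising this climatology with
#' [summarise_climatology()] recovers the single-layer climate predictors.
NULL

days_in_month <- function() c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

climate_monthly_vars <- function() c("DD", "VPD", "DTR", "wind", "tas", "light")

#' @rdname climatology
#' @param predictors `n x 16` predictor matrix.
#' @return Named list of `n x 12` matrices (class `fire_climatology`).
#' @export
baseline_climatology <- function(predictors) {
  X <- check_predictor_layout(predictors)
  m <- 1:12
  s <- cos(2 * pi * (m - 7) / 12)            # zero-mean, peak in July
  shape_peak <- 0.6 + 0.4 * (1 + s) / 2      # in [0.6, 1], max = 1 in July
  n <- nrow(X)
  # amplitude capped so no monthly value exceeds 31 dry days: the seasonal
  # cycle then reproduces each cell's annual-mean dry days exactly
  amp <- pmin(X[, "DD_s"] / 2, pmax(31 / pmax(X[, "DD"], 1e-12) - 1, 0))
  DD <- pmin(pmax(X[, "DD"] * (1 + outer(amp, s)), 0), 31)
  out <- list(
    DD = DD,
    VPD = outer(X[, "VPD"], shape_peak),
    DTR = outer(X[, "DTR"], shape_peak),
    wind = matrix(X[, "wind"], n, 12),
    tas = matrix(15, n, 12) + outer(rep(10, n), s),
    light = matrix(X[, "light"], n, 12)
  )
  structure(out, class = "fire_climatology")
}

check_climatology <- function(x, what = "climatology") {
  if (!is.list(x) || is.null(names(x))) stop(what, " must be a named list")
  for (v in names(x)) {
    if (ncol(x[[v]]) != 12)
      stop(what, ": variable ", v, " has ", ncol(x[[v]]),
           " months (need 12)")
  }
  x
}

#' Anomaly between two monthly climatologies
#'
#' The delta method: per-variable, per-month difference future - piControl.
#' Because any shared model bias cancels in the difference, adding the
#' anomaly to an observed baseline isolates the simulated change.
#'
#' @param picontrol,future Climatologies (same variables, 12 months).
#' @return Climatology of deltas.
#' @export
compute_anomaly <- function(picontrol, future) {
  picontrol <- check_climatology(picontrol, "picontrol")
  future <- check_climatology(future, "future")
  if (!setequal(names(picontrol), names(future)))
    stop("variable mismatch between piControl and future climatologies")
  out <- lapply(names(picontrol), function(v) {
    if (!identical(dim(picontrol[[v]]), dim(future[[v]])))
      stop("month/cell mismatch for variable ", v)
    future[[v]] - picontrol[[v]]
  })
  names(out) <- names(picontrol)
  structure(out, class = "fire_climatology")
}

#' Default clip rules for anomaly-forced climatologies
#'
#' Physical bounds applied after adding anomalies: dry days within
#' `[0, days-in-month]`, VPD/DTR/wind/lightning non-negative, temperature
#' unbounded. Each rule is `function(x, month)`.
#'
#' @return Named list of clip functions.
#' @export
default_clip_rules <- function() {
  nonneg <- function(x, month) pmax(x, 0)
  list(
    DD = function(x, month) pmin(pmax(x, 0), days_in_month()[month]),
    VPD = nonneg, DTR = nonneg, wind = nonneg, light = nonneg,
    tas = function(x, month) x
  )
}

#' Add an anomaly to a baseline climatology
#'
#' `baseline + delta`, then clipped to physical ranges. Every variable in
#' the baseline must have a clip rule (use an identity rule for unbounded
#' variables); a missing rule is an error rather than silently unclipped.
#'
#' @param baseline,delta Climatologies.
#' @param clip_rules Named list of `function(x, month)` rules.
#' @return Forced climatology.
#' @export
apply_anomaly <- function(baseline, delta, clip_rules = default_clip_rules()) {
  baseline <- check_climatology(baseline, "baseline")
  delta <- check_climatology(delta, "delta")
  missing_rule <- setdiff(names(baseline), names(clip_rules))
  if (length(missing_rule))
    stop("missing clip rule for variable(s): ",
         paste(missing_rule, collapse = ", "))
  out <- lapply(names(baseline), function(v) {
    if (is.null(delta[[v]])) return(baseline[[v]])
    x <- baseline[[v]] + delta[[v]]
    for (mo in 1:12) x[, mo] <- clip_rules[[v]](x[, mo], mo)
    x
  })
  names(out) <- names(baseline)
  structure(out, class = "fire_climatology")
}

#' Summarise a monthly climatology into single-layer climate predictors
#'
#' Collapses the 12-month cycle to the layers the GLMs consume: dry days
#' and lightning as annual means; dry-day seasonality as the per-cell
#' (max - min) / mean of monthly dry days; DTR and VPD as the cell values of
#' the month with the largest spatial-mean DTR and VPD respectively; wind
#' from the hottest month (largest spatial-mean temperature).
#'
#' @param monthly A climatology with `DD`, `VPD`, `DTR`, `wind`, `light`.
#' @param tas_monthly `n x 12` temperature matrix (defaults to
#'   `monthly$tas`).
#' @return Matrix `n x 6` with columns `DD`, `DD_s`, `VPD`, `DTR`, `wind`,
#'   `light`.
#' @export
summarise_climatology <- function(monthly, tas_monthly = monthly$tas) {
  monthly <- check_climatology(monthly)
  need <- c("DD", "VPD", "DTR", "wind")
  miss <- setdiff(need, names(monthly))
  if (length(miss)) stop("climatology lacks variable(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(tas_monthly)) stop("temperature climatology required for wind")
  dd <- monthly$DD
  dd_mean <- rowMeans(dd)
  dd_s <- ifelse(dd_mean > 0,
                 (apply(dd, 1, max) - apply(dd, 1, min)) / dd_mean, 0)
  m_dtr <- which.max(colMeans(monthly$DTR))
  m_vpd <- which.max(colMeans(monthly$VPD))
  m_hot <- which.max(colMeans(tas_monthly))
  light <- if (!is.null(monthly$light)) rowMeans(monthly$light) else
    rep(NA_real_, nrow(dd))
  cbind(DD = dd_mean, DD_s = dd_s,
        VPD = monthly$VPD[, m_vpd], DTR = monthly$DTR[, m_dtr],
        wind = monthly$wind[, m_hot], light = light)
}

# ---- scenario bundle -------------------------------------------------------

gcm_members <- function() c("GFDL-ESM2M", "HadGEM2-ES", "IPSL-CM5A-LR", "MIROC5")
rcp_labels <- function() c("RCP2.6", "RCP6.0")
experiment_labels <- function() {
  c("realistic", "climate_only", "co2_only", "climate_co2", "human_only")
}

#' Default scenario shift table
#'
#' The prescribed forcing deltas of the synthetic study conditions, per RCP:
#' warming, drying and VPD increase (larger under low mitigation, RCP6.0),
#' CO2-fertilisation gains in GPP with woody-cover shifts, a climate-driven
#' vegetation response, and SSP2-style human-activity growth (identical
#' under both RCPs, as the socioeconomic pathway is shared).
#'
#' @param rcp `"RCP2.6"` or `"RCP6.0"`.
#' @return List with components `climate`, `climate_veg`, `co2_veg`,
#'   `human` (named delta vectors).
#' @export
default_scenario_shifts <- function(rcp = c("RCP2.6", "RCP6.0")) {
  rcp <- match.arg(rcp)
  f <- if (rcp == "RCP2.6") 1 else 2.5   # low-mitigation amplification
  list(
    climate = c(DD = 1.2 * f, VPD = 0.25 * f, DTR = 0.2 * f,
                wind = 0.1 * f, tas = 1.4 * f),
    climate_veg = c(GPP = 60 * f, GPP_s = 0.05 * f, tree = -0.01 * f,
                    grass = 0.01 * f, shrub = 0),
    co2_veg = c(GPP = 120 * f, GPP_s = 0, tree = 0.02 * f,
                grass = -0.015 * f, shrub = -0.005 * f),
    human = c(popd = 4, crop = 0.04, roads = 0.05)
  )
}

check_shifts <- function(shifts) {
  allowed <- list(climate = climate_monthly_vars(),
                  climate_veg = predictor_group("vegetation"),
                  co2_veg = predictor_group("vegetation"),
                  human = predictor_group("human"))
  unknown_grp <- setdiff(names(shifts), names(allowed))
  if (length(unknown_grp))
    stop("unknown shift group(s): ", paste(unknown_grp, collapse = ", "))
  for (g in names(shifts)) {
    bad <- setdiff(names(shifts[[g]]), allowed[[g]])
    if (length(bad))
      stop("shift for unknown predictor in ", g, ": ",
           paste(bad, collapse = ", "))
  }
  shifts
}

#' Generate a synthetic scenario bundle
#'
#' Builds paired piControl-like and future-like monthly climatologies for
#' each GCM member and RCP, plus the vegetation and human-activity layers
#' the sensitivity experiments need. Each GCM member carries its own bias
#' field, shared bit-exactly between its piControl and future climatologies,
#' so the anomaly (future - piControl) removes it -- the property the delta
#' method relies on. The cell-mean anomaly of each shifted climate variable
#' equals the requested shift up to the Monte-Carlo noise (`noise_sd`).
#' Shifts restricted to climate variables leave the human layers untouched
#' bit-exactly.
#'
#' @param predictors Baseline `n x 16` predictor field.
#' @param shifts Shift table per RCP: either a single list (applied to both
#'   RCPs) or a named list `list("RCP2.6" = ..., "RCP6.0" = ...)`; see
#'   [default_scenario_shifts()].
#' @param seed Integer RNG seed.
#' @param gcms,rcps Ensemble member and scenario labels.
#' @param gcm_bias_sd,noise_sd Standard deviations of the per-GCM bias and
#'   of the future-minus-control noise.
#' @param co2 Named CO2 levels (ppm): `modern` plus one per RCP.
#' @return Object of class `scenario_bundle`.
#' @export
generate_scenario <- function(predictors,
                              shifts = list("RCP2.6" = default_scenario_shifts("RCP2.6"),
                                            "RCP6.0" = default_scenario_shifts("RCP6.0")),
                              seed = 1,
                              gcms = gcm_members(), rcps = rcp_labels(),
                              gcm_bias_sd = 0.3, noise_sd = 0.05,
                              co2 = c(modern = 400, "RCP2.6" = 445,
                                      "RCP6.0" = 670)) {
  X <- check_predictor_layout(predictors)
  if (!all(rcps %in% names(shifts))) {
    shifts <- stats::setNames(rep(list(shifts), length(rcps)), rcps)
  }
  for (r in rcps) shifts[[r]] <- check_shifts(shifts[[r]])
  set.seed(as.integer(seed))
  n <- nrow(X)

  base_monthly <- baseline_climatology(X)
  # baseline climate layers re-derived from the monthly cycle so experiment
  # deltas are measured against a self-consistent modern state
  baseline <- X
  cs <- summarise_climatology(base_monthly)
  baseline[, colnames(cs)] <- cs

  veg_cols <- predictor_group("vegetation")
  human_cols <- predictor_group("human")
  runs <- list()
  for (r in rcps) {
    sh <- shifts[[r]]
    runs[[r]] <- list()
    for (g in gcms) {
      # per-GCM bias field, shared by piControl and future
      bias <- lapply(names(base_monthly), function(v) {
        matrix(stats::rnorm(n, sd = gcm_bias_sd), n, 12)
      })
      names(bias) <- names(base_monthly)
      picontrol <- lapply(names(base_monthly), function(v)
        base_monthly[[v]] + bias[[v]])
      names(picontrol) <- names(base_monthly)
      future <- lapply(names(base_monthly), function(v) {
        d <- if (!is.null(sh$climate) && v %in% names(sh$climate))
          sh$climate[[v]] else 0
        picontrol[[v]] + d + matrix(stats::rnorm(n * 12, sd = noise_sd), n, 12)
      })
      names(future) <- names(base_monthly)

      veg_noise <- matrix(stats::rnorm(n * length(veg_cols),
                                       sd = noise_sd), n,
                          dimnames = list(NULL, veg_cols))
      veg_climate <- shift_layers(baseline[, veg_cols, drop = FALSE],
                                  sh$climate_veg, veg_noise)
      veg_both <- shift_layers(veg_climate, sh$co2_veg, NULL)
      veg_co2 <- shift_layers(baseline[, veg_cols, drop = FALSE],
                              sh$co2_veg, NULL)

      human_future <- baseline[, human_cols, drop = FALSE]
      if (!is.null(sh$human) && length(sh$human)) {
        modern_sim <- human_future +
          matrix(stats::rnorm(n * length(human_cols), sd = gcm_bias_sd), n)
        future_sim <- modern_sim
        for (v in names(sh$human)) future_sim[, v] <- future_sim[, v] + sh$human[[v]]
        human_future <- apply_human_anomaly(human_future, modern_sim, future_sim)
      }

      runs[[r]][[g]] <- list(
        picontrol = structure(picontrol, class = "fire_climatology"),
        future = structure(future, class = "fire_climatology"),
        veg_climate = veg_climate, veg_co2 = veg_co2, veg_both = veg_both,
        human_future = human_future
      )
    }
  }
  structure(list(baseline = baseline, baseline_monthly = base_monthly,
                 runs = runs, gcms = gcms, rcps = rcps, shifts = shifts,
                 co2 = co2, seed = as.integer(seed)),
            class = "scenario_bundle")
}

# add named deltas (and optional noise matrix) to layer columns, with
# fractional covers clipped to [0, 1]
shift_layers <- function(layers, deltas, noise) {
  out <- layers
  if (!is.null(deltas)) {
    for (v in names(deltas)) out[, v] <- out[, v] + deltas[[v]]
  }
  if (!is.null(noise)) out <- out + noise[, colnames(out), drop = FALSE]
  info <- predictor_info()
  for (v in colnames(out)) {
    b <- info[info$name == v, ]
    out[, v] <- clip_to_bounds(out[, v], b$lower, b$upper)
  }
  out
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf("scenario_bundle: %d cells, %d GCM member(s) x %d RCP(s), seed %d\n",
              nrow(x$baseline), length(x$gcms), length(x$rcps), x$seed))
  invisible(x)
}

#' Build the factorial experiment matrix
#'
#' Assembles the full experimental design: a realistic experiment (climate,
#' CO2 and human activity all change) and four sensitivity experiments
#' (climate only; CO2 only; climate and CO2; human activity only), each run
#' for every RCP and GCM member -- 5 x 2 x 4 = 40 experiments with the
#' default ensemble. In every sensitivity experiment the held-constant
#' factor groups are bit-identical to the modern baseline. Future climate
#' layers are built by adding the GCM's piControl-to-future anomaly to the
#' baseline monthly climatology and re-summarising; vegetation layers come
#' from the bundle's climate-response, CO2-response or combined branch;
#' human layers from the anomaly-forced SSP2 projection.
#'
#' @param bundle A [generate_scenario()] bundle.
#' @return Object of class `experiment_matrix`: list of experiments, each
#'   with `label`, `rcp`, `gcm`, `vary` (character subset of
#'   climate/co2/human) and the `n x 16` `predictors` matrix.
#' @export
build_experiment_matrix <- function(bundle) {
  if (!inherits(bundle, "scenario_bundle")) stop("not a scenario_bundle")
  for (r in bundle$rcps) {
    missing <- setdiff(bundle$gcms, names(bundle$runs[[r]]))
    if (length(missing))
      stop("incomplete bundle: ", r, " lacks member(s) ",
           paste(missing, collapse = ", "))
  }
  vary_sets <- list(
    realistic = c("climate", "co2", "human"),
    climate_only = "climate",
    co2_only = "co2",
    climate_co2 = c("climate", "co2"),
    human_only = "human"
  )
  clim_cols <- c("DD", "DD_s", "VPD", "DTR", "wind")
  veg_cols <- predictor_group("vegetation")
  human_cols <- predictor_group("human")

  out <- list()
  for (r in bundle$rcps) for (g in bundle$gcms) {
    run <- bundle$runs[[r]][[g]]
    delta <- compute_anomaly(run$picontrol, run$future)
    forced <- apply_anomaly(bundle$baseline_monthly, delta)
    clim_future <- summarise_climatology(forced)
    for (lab in experiment_labels()) {
      vary <- vary_sets[[lab]]
      X <- bundle$baseline
      if ("climate" %in% vary) {
        X[, clim_cols] <- clim_future[, clim_cols]
        X[, "light"] <- bundle$baseline[, "light"]  # lightning held constant
      }
      veg <- if (all(c("climate", "co2") %in% vary)) run$veg_both
             else if ("climate" %in% vary) run$veg_climate
             else if ("co2" %in% vary) run$veg_co2
             else NULL
      if (!is.null(veg)) X[, veg_cols] <- as.matrix(veg)[, veg_cols]
      if ("human" %in% vary)
        X[, human_cols] <- as.matrix(run$human_future)[, human_cols]
      out[[length(out) + 1L]] <- list(label = lab, rcp = r, gcm = g,
                                      vary = vary, predictors = X)
    }
  }
  structure(out, class = "experiment_matrix", baseline = bundle$baseline)
}

#' @export
print.experiment_matrix <- function(x, ...) {
  keys <- vapply(x, function(e) paste(e$label, e$rcp, e$gcm, sep = " / "), "")
  cat(sprintf("experiment_matrix: %d experiments\n", length(x)))
  cat(" ", paste(utils::head(keys, 5), collapse = "\n  "), "\n  ...\n")
  invisible(x)
}

#' Project road density from socioeconomic predictors
#'
#' Road density is simulated from a linear model on population density, GDP
#' per capita, OECD membership and cell area. GDP per capita is total GDP
#' divided by the population count (population density times cell area);
#' cells with zero population get the grid-median GDP per capita (flagged),
#' avoiding division blow-ups. Coefficients are either supplied or fitted by
#' least squares on baseline road density; predictions are clamped at zero.
#'
#' @param popd Population density, persons km^-2.
#' @param gdp_total Total GDP per cell.
#' @param oecd Logical/0-1 OECD membership field.
#' @param area Cell area, km^2.
#' @param coefficients Named vector `(Intercept, popd, gdp_pc, oecd, area)`,
#'   or `NULL` to fit from `baseline_roads`.
#' @param baseline_roads Observed road density used when fitting.
#' @return List with `roads` (km km^-2, >= 0), `coefficients`, `gdp_pc` and
#'   the `flagged` zero-population mask.
#' @export
project_road_density <- function(popd, gdp_total, oecd, area,
                                 coefficients = NULL, baseline_roads = NULL) {
  pop_count <- popd * area
  flagged <- pop_count <= 0
  gdp_pc <- ifelse(flagged, NA_real_, gdp_total / pop_count)
  if (any(flagged)) {
    gdp_pc[flagged] <- stats::median(gdp_pc, na.rm = TRUE)
    message(sum(flagged), " zero-population cell(s): GDP per capita set to ",
            "the grid median")
  }
  M <- cbind("(Intercept)" = 1, popd = popd, gdp_pc = gdp_pc,
             oecd = as.numeric(oecd), area = area)
  if (is.null(coefficients)) {
    if (is.null(baseline_roads))
      stop("supply either coefficients or baseline_roads to fit them")
    fit <- stats::lm.fit(M, baseline_roads)
    coefficients <- fit$coefficients
  }
  pred <- pmax(drop(M %*% coefficients[colnames(M)]), 0)
  list(roads = pred, coefficients = coefficients, gdp_pc = gdp_pc,
       flagged = flagged)
}

#' Anomaly-force the human-activity layers
#'
#' Adds the simulated change (future simulation minus modern simulation) to
#' the observed modern baseline, so model bias in the socioeconomic
#' simulations cancels. Results are clipped to physical ranges (population
#' and road density >= 0, cropland fraction in `[0, 1]`).
#'
#' @param baseline_human,modern_sim,future_sim Matrices/data.frames with
#'   columns `popd`, `crop`, `roads` (co-registered).
#' @return Forced human layers, same shape as `baseline_human`.
#' @export
apply_human_anomaly <- function(baseline_human, modern_sim, future_sim) {
  b <- as.matrix(baseline_human)
  m <- as.matrix(modern_sim); f <- as.matrix(future_sim)
  if (!identical(dim(b), dim(m)) || !identical(dim(b), dim(f)))
    stop("shape mismatch between baseline and simulated human layers")
  out <- b + (f - m)
  info <- predictor_info()
  for (v in intersect(colnames(out), info$name)) {
    row <- info[info$name == v, ]
    out[, v] <- clip_to_bounds(out[, v], row$lower, row$upper)
  }
  out
}
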