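#' Per-cell predictor contributions to a change in the linear predictor
#'
#' First-order decomposition of the change in a fire property between two
#' experiments: for each predictor the difference in the (standardised)
#' model input, future minus modern, is multiplied by the corresponding GLM
#' coefficient. The contributions are signed values on the linear-predictor
#' (link) scale and sum, per cell, exactly to the total change in the
#' linear predictor -- a linearised, additive attribution of the simulated
#' change to its drivers.
#'
#' @param model A [fit_fire_glm()] model (its training standardisation is
#'   applied to both fields).
#' @param X_modern,X_future `n x 16` predictor matrices.
#' @return Object of class `attribution_result`: list with `contributions`
#'   (`n x 16` matrix), `delta_eta` (row sums), and per-cell
#'   `top_positive` / `top_negative` predictor labels (`NA` where no
#'   contribution of that sign exists; exact ties resolve to the
#'   lowest-index predictor in the canonical order).
#' @export
#' @examples
#' d <- generate_dataset(fire_grid(20, 10), seed = 5)
#' m <- fit_fire_glm(d$predictors, d$fire$BA, "BA")
#' Xf <- d$predictors; Xf[, "VPD"] <- Xf[, "VPD"] + 0.5
#' a <- predictor_contributions(m, d$predictors, Xf)
#' table(a$top_positive)
predictor_contributions <- function(model, X_modern, X_future) {
  Zm <- standardise_predictors(check_predictor_layout(X_modern),
                               model$center, model$scale)$Z
  Zf <- standardise_predictors(check_predictor_layout(X_future),
                               model$center, model$scale)$Z
  if (!identical(dim(Zm), dim(Zf)))
    stop("modern and future fields must be co-registered")
  beta <- model$beta[predictor_names()]
  contrib <- sweep(Zf - Zm, 2, beta, "*")
  delta_eta <- unname(rowSums(contrib))
  structure(list(
    contributions = contrib,
    delta_eta = delta_eta,
    top_positive = extreme_label(contrib, positive = TRUE),
    top_negative = extreme_label(contrib, positive = FALSE)
  ), class = "attribution_result")
}

# label of the largest positive (or most negative) contribution per cell;
# NA when no contribution of that sign exists; ties -> lowest column index
extreme_label <- function(contrib, positive) {
  s <- if (positive) contrib else -contrib
  idx <- apply(s, 1, which.max)
  best <- s[cbind(seq_len(nrow(s)), idx)]
  lab <- colnames(contrib)[idx]
  lab[best <= 0] <- NA_character_
  lab
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("attribution_result: %d cells x %d predictors\n",
              nrow(x$contributions), ncol(x$contributions)))
  cat(sprintf("  mean delta eta %.4f; top positive drivers: %s\n",
              mean(x$delta_eta),
              paste(names(sort(table(x$top_positive), decreasing = TRUE))[1:3],
                    collapse = ", ")))
  invisible(x)
}

#' Dominant-driver maps and frequency tables
#'
#' Extracts the per-cell labels of the predictors contributing the largest
#' increase and the largest decrease, plus their frequency tables (overall
#' or within regions).
#'
#' @param result An [predictor_contributions()] result.
#' @param region Optional factor of region labels per cell.
#' @return List with `top_positive`, `top_negative` label vectors and
#'   `frequency` (data.frame of counts per predictor, by region when
#'   given; counts sum to the number of attributed cells).
#' @export
dominant_driver_map <- function(result, region = NULL) {
  stopifnot(inherits(result, "attribution_result"))
  tab <- function(lab) {
    if (is.null(region)) {
      as.data.frame(table(predictor = factor(lab, predictor_names()),
                          useNA = "no"), responseName = "count")
    } else {
      as.data.frame(table(predictor = factor(lab, predictor_names()),
                          region = region, useNA = "no"),
                    responseName = "count")
    }
  }
  list(top_positive = result$top_positive,
       top_negative = result$top_negative,
       frequency = list(positive = tab(result$top_positive),
                        negative = tab(result$top_negative)))
}

#' Aggregate burnt area to biomes
#'
#' Per-biome total burnt area (the area-weighted sum of burnt-area fraction
#' times cell area, km^2), its share of the global total, and optionally the
#' percentage change of a future field relative to the modern one.
#'
#' @param BA Burnt-area fraction per cell.
#' @param biome_map Factor/character biome labels per cell (no unmapped
#'   cells).
#' @param grid The matching [fire_grid()].
#' @param BA_future Optional future burnt-area field for `pct_change`.
#' @return data.frame with `biome_id`, `burnt_area_km2`, `global_pct` and,
#'   when `BA_future` is given, `burnt_area_km2_future` and `pct_change`.
#'   Global percentages sum to 100.
#' @export
biome_aggregate <- function(BA, biome_map, grid, BA_future = NULL) {
  biome_map <- as.character(biome_map)
  if (anyNA(biome_map))
    stop("unmapped biome cells at id(s): ",
         paste(utils::head(which(is.na(biome_map))), collapse = ", "))
  area <- grid$cells$area_km2
  if (length(BA) != length(area) || length(biome_map) != length(area))
    stop("BA, biome map and grid must be co-registered")
  km2 <- tapply(BA * area, biome_map, sum)
  out <- data.frame(biome_id = names(km2),
                    burnt_area_km2 = as.numeric(km2),
                    global_pct = 100 * as.numeric(km2) / sum(km2),
                    row.names = NULL)
  if (!is.null(BA_future)) {
    km2f <- tapply(BA_future * area, biome_map, sum)
    out$burnt_area_km2_future <- as.numeric(km2f[out$biome_id])
    out$pct_change <- 100 * (out$burnt_area_km2_future - out$burnt_area_km2) /
      out$burnt_area_km2
  }
  out[order(out$biome_id), , drop = FALSE]
}

#' Ignition-threshold crossings between two burnt-area fields
#'
#' Counts cells whose predicted burning probability crosses the ignition
#' threshold upward (future at/above the threshold, modern below), the
#' percentage change in the number of above-threshold cells, and the share
#' of the newly crossing cells lying north of the tropics.
#'
#' @param BA_modern,BA_future Predicted burnt-area fields.
#' @param threshold Ignition threshold (> 0).
#' @param grid The matching [fire_grid()].
#' @param tropics_band Latitude of the tropical boundary, degrees (the
#'   northern extra-tropics start north of `+tropics_band`).
#' @return List with `n_above_modern`, `n_above_future`, `pct_change`,
#'   `n_new_crossings`, `n_lost`, `northern_share` (fraction of new
#'   crossings north of the band; `NaN` when there are none).
#' @export
ignition_expansion <- function(BA_modern, BA_future, threshold, grid,
                               tropics_band = 23.5) {
  if (threshold <= 0) stop("threshold must be positive")
  if (tropics_band <= 0 || tropics_band >= 90)
    stop("tropics_band must lie in (0, 90) degrees")
  above_m <- BA_modern >= threshold
  above_f <- BA_future >= threshold
  new_cross <- above_f & !above_m
  lost <- above_m & !above_f
  northern <- grid$cells$lat > tropics_band
  list(
    n_above_modern = sum(above_m),
    n_above_future = sum(above_f),
    pct_change = 100 * (sum(above_f) - sum(above_m)) / sum(above_m),
    n_new_crossings = sum(new_cross),
    n_lost = sum(lost),
    northern_share = sum(new_cross & northern) / sum(new_cross)
  )
}

#' Classify cells by relative change in the fire properties
#'
#' Labels each cell `"increase"`, `"decrease"` or `"none"` per property
#' according to whether the relative change (future - modern)/modern exceeds
#' the minimum change (5% by default), plus a combined label that is
#' `"increase"`/`"decrease"` only where all three properties agree in sign
#' above the threshold. Cells with a modern value of zero have no defined
#' relative change and are excluded (`NA`, with a count reported).
#'
#' @param modern,future data.frames/lists with `BA`, `FS`, `FI` fields.
#' @param min_change Minimum relative change (0.05 = 5%).
#' @return List with per-property label factors (`BA`, `FS`, `FI`),
#'   `combined`, and `n_excluded` (cells with any modern zero).
#' @export
change_map <- function(modern, future, min_change = 0.05) {
  props <- c("BA", "FS", "FI")
  labs <- list()
  excluded <- rep(FALSE, length(modern[[props[1]]]))
  for (p in props) {
    m <- modern[[p]]; f <- future[[p]]
    if (length(m) != length(f)) stop("co-registration mismatch for ", p)
    rel <- (f - m) / m
    lab <- ifelse(rel > min_change, "increase",
                  ifelse(rel < -min_change, "decrease", "none"))
    lab[m == 0] <- NA
    excluded <- excluded | m == 0
    labs[[p]] <- factor(lab, levels = c("increase", "decrease", "none"))
  }
  agree <- function(which) {
    Reduce(`&`, lapply(labs, function(l) !is.na(l) & l == which))
  }
  combined <- rep("none", length(excluded))
  combined[agree("increase")] <- "increase"
  combined[agree("decrease")] <- "decrease"
  combined[excluded] <- NA
  labs$combined <- factor(combined, levels = c("increase", "decrease", "none"))
  labs$n_excluded <- sum(excluded)
  labs
}
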