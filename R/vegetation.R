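#' fAPAR from leaf-area index (Beer--Lambert law)
#'
#' The fraction of absorbed photosynthetically active radiation follows
#' light extinction through the canopy: \eqn{fAPAR = 1 - e^{-k \cdot LAI}},
#' with a constant extinction coefficient \eqn{k \approx 0.5}. Output lies in
#' `[0, 1)` for finite LAI and increases strictly in both LAI and k.
#'
#' @param LAI Leaf-area index (one-sided leaf area per ground area), >= 0.
#' @param k Extinction coefficient, > 0.
#' @return fAPAR, element-wise over `LAI`.
#' @export
#' @examples
#' fapar_from_lai(2)        # 1 - exp(-1)
fapar_from_lai <- function(LAI, k = 0.5) {
  if (any(!is.finite(LAI)) || any(LAI < 0))
    stop("LAI must be finite and >= 0 (negative LAI is an error, not clamped)")
  if (k <= 0) stop("extinction coefficient k must be positive")
  1 - exp(-k * LAI)
}

#' Rescale simulated fAPAR to an observational reference
#'
#' Vegetation-model fAPAR is biased relative to satellite products; each
#' experiment's simulated fAPAR is multiplied by the per-cell ratio between
#' reference (observed) fAPAR and the baseline-period simulated fAPAR, then
#' clipped to `[0, 1)`. The ratio is computed once on the baseline and
#' applied to every experiment. Cells where the baseline simulation is zero
#' but the reference is not cannot be rescaled: the ratio is set to 1 there
#' and the cells are flagged with a warning.
#'
#' @param simulated fAPAR field to rescale (any experiment).
#' @param reference Observational baseline fAPAR.
#' @param baseline_simulated Simulated fAPAR over the same baseline period.
#' @return Rescaled fAPAR, clipped to `[0, 1 - 1e-9]` (open upper interval
#'   preserved so downstream logs stay finite).
#' @export
rescale_fapar <- function(simulated, reference, baseline_simulated) {
  ratio <- reference / baseline_simulated
  bad <- baseline_simulated == 0 & reference > 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with zero baseline-simulated fAPAR but ",
            "nonzero reference; ratio set to 1 there")
    ratio[bad] <- 1
  }
  ratio[baseline_simulated == 0 & reference == 0] <- 1
  pmin(pmax(simulated * ratio, 0), 1 - 1e-9)
}

#' PPFD from shortwave radiation
#'
#' Converts downwelling shortwave radiation to photosynthetic photon flux
#' density: \eqn{PPFD = 60 \cdot 60 \cdot 24 \cdot 10^{-6} \cdot kEC \cdot rsds},
#' i.e. seconds-per-day times the energy-to-photon conversion factor
#' kEC = 2.04 umol J^-1.
#'
#' @param rsds Shortwave radiation, W m^-2 (>= 0).
#' @param kEC Energy-to-photon conversion, umol J^-1.
#' @return PPFD, mol m^-2 day^-1.
#' @export
#' @examples
#' ppfd_from_shortwave(100)   # 17.6256
ppfd_from_shortwave <- function(rsds, kEC = 2.04) {
  if (any(rsds < 0)) stop("rsds must be >= 0")
  60 * 60 * 24 * 1e-6 * kEC * rsds
}

#' Combine C3 and C4 GPP
#'
#' Monthly total GPP is the cover-weighted convex combination
#' \eqn{GPP = GPP_{C3}(1 - C4_{frac}) + GPP_{C4} \cdot C4_{frac}}, so the
#' output always lies between the two inputs. Units are whatever units the
#' inputs carry ("training units"): the GLMs consume standardised predictors,
#' so absolute GPP units cancel.
#'
#' @param GPP_c3,GPP_c4 C3 / C4 productivity fields (>= 0, same units).
#' @param C4_fraction Fractional C4 cover in `[0, 1]`.
#' @return Combined GPP field.
#' @export
combine_gpp <- function(GPP_c3, GPP_c4, C4_fraction) {
  if (any(C4_fraction < 0 | C4_fraction > 1))
    stop("C4_fraction must lie in [0, 1]")
  GPP_c3 * (1 - C4_fraction) + GPP_c4 * C4_fraction
}

#' Fit the cloud-cover--shortwave relationship
#'
#' Future cloud cover is approximated from shortwave radiation through a
#' linear model fitted on paired baseline monthly means (least squares);
#' predictions are the fitted line clipped to `[0, 1]`.
#'
#' @param rsds_baseline,cloud_baseline Paired baseline monthly means (>= 3
#'   pairs; rsds must not be constant).
#' @return List with `slope`, `intercept`.
#' @export
fit_cloud_cover <- function(rsds_baseline, cloud_baseline) {
  if (length(rsds_baseline) < 3 || length(cloud_baseline) != length(rsds_baseline))
    stop("need >= 3 paired baseline (rsds, cloud cover) values")
  if (stats::sd(rsds_baseline) == 0)
    stop("degenerate design: baseline rsds is constant")
  fit <- stats::lm(cloud_baseline ~ rsds_baseline)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' @rdname fit_cloud_cover
#' @param rsds_monthly Shortwave field to convert to cloud cover.
#' @param model Fit from `fit_cloud_cover()` (or a list with `slope`,
#'   `intercept`).
#' @export
cloud_cover_from_rsds <- function(rsds_monthly, model) {
  pmin(pmax(model$slope * rsds_monthly + model$intercept, 0), 1)
}

#' Assign per-biome mean fractional covers
#'
#' Every cell receives the mean tree, grass and shrub cover of its biome
#' (within-biome variance of the output is exactly zero); a biome map change
#' between experiments therefore changes a cell's covers to the other
#' biome's row exactly.
#'
#' @param biome_map Factor/character vector of biome ids, one per cell.
#' @param cover_table data.frame with columns `biome_id`, `tree`, `grass`,
#'   `shrub` (one row per biome present in the map).
#' @return data.frame with columns `tree`, `grass`, `shrub`, one row per
#'   cell.
#' @export
biome_cover_assignment <- function(biome_map, cover_table) {
  biome_map <- as.character(biome_map)
  missing <- setdiff(unique(biome_map), cover_table$biome_id)
  if (length(missing))
    stop("unmapped biome id(s): ", paste(missing, collapse = ", "))
  i <- match(biome_map, cover_table$biome_id)
  data.frame(tree = cover_table$tree[i],
             grass = cover_table$grass[i],
             shrub = cover_table$shrub[i])
}

#' @rdname biome_cover_assignment
#' @param tree,grass,shrub Observed per-cell cover fields used to build the
#'   per-biome mean table.
#' @export
biome_cover_table <- function(biome_map, tree, grass, shrub) {
  agg <- stats::aggregate(cbind(tree, grass, shrub),
                          by = list(biome_id = as.character(biome_map)), mean)
  agg[order(agg$biome_id), , drop = FALSE]
}
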