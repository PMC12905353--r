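#' The sixteen fire-regime predictors
#'
#' All three fire-property GLMs share a common set of sixteen gridded
#' predictors covering climate (dry days, dry-day seasonality, vapour
#' pressure deficit, diurnal temperature range, wind speed of the hottest
#' month), vegetation (annual GPP, GPP seasonality, fractional grass, shrub
#' and tree cover), human activity (population density, cropland fraction,
#' road density), topography (vector ruggedness metric, topographic position
#' index) and ignitions (lightning ground-strike rate).
#'
#' `predictor_names()` returns the canonical layer names in their fixed
#' order; this order also resolves ties when ranking per-cell driver
#' contributions.
#'
#' @return Character vector of the 16 predictor names.
#' @export
#' @examples
#' predictor_names()
predictor_names <- function() {
  c("DD", "DD_s", "VPD", "DTR", "wind",
    "GPP", "GPP_s", "grass", "shrub", "tree",
    "popd", "crop", "roads", "VRM", "TPI", "light")
}

#' Predictor metadata table
#'
#' Units, factor-group membership (used by the sensitivity-experiment
#' engine) and physical bounds (used by the anomaly clip rules) for each
#' predictor.
#'
#' @return A data.frame with one row per predictor: `name`, `unit`,
#'   `group` (one of `"climate"`, `"vegetation"`, `"human"`, `"constant"`),
#'   `lower`, `upper` (physical bounds; `NA` = unbounded).
#' @export
predictor_info <- function() {
  data.frame(
    name  = predictor_names(),
    unit  = c("days", "-", "kPa", "degC", "m s-1",
              "training units", "-", "fraction", "fraction", "fraction",
              "persons km-2", "fraction", "km km-2", "-", "-",
              "strikes month-1"),
    group = c("climate", "climate", "climate", "climate", "climate",
              "vegetation", "vegetation", "vegetation", "vegetation",
              "vegetation",
              "human", "human", "human", "constant", "constant", "constant"),
    lower = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, NA, 0),
    upper = c(31, NA, NA, NA, NA, NA, NA, 1, 1, 1, NA, 1, NA, 1, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' @rdname predictor_info
#' @param group Factor group to select.
#' @export
predictor_group <- function(group = c("climate", "vegetation", "human",
                                      "constant")) {
  group <- match.arg(group)
  info <- predictor_info()
  info$name[info$group == group]
}

# Internal: check that a predictor matrix conforms to the 16-layer layout.
# Returns the matrix with columns in canonical order.
check_predictor_layout <- function(X, what = "predictor field") {
  nm <- predictor_names()
  if (is.data.frame(X)) X <- as.matrix(X[, intersect(names(X), nm), drop = FALSE])
  if (is.null(colnames(X))) {
    stop(what, " must have named columns matching the 16 predictors")
  }
  missing <- setdiff(nm, colnames(X))
  if (length(missing)) {
    stop(what, " is missing predictor layer(s): ",
         paste(missing, collapse = ", "))
  }
  X[, nm, drop = FALSE]
}

clip_to_bounds <- function(x, lower, upper) {
  if (!is.na(lower)) x <- pmax(x, lower)
  if (!is.na(upper)) x <- pmin(x, upper)
  x
}
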