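#' Fit a fire-property GLM
#'
#' Fits one of the three fire-regime models on the common 16-predictor
#' layout:
#' \itemize{
#'   \item \strong{BA} (burnt-area fraction, interpreted as the probability
#'     of burning): quasi-binomial family, logit link;
#'   \item \strong{FS} (median fire size) and \strong{FI} (median fire
#'     intensity): quasi-Poisson family, log link, with the response min-max
#'     normalised to `[0, 1]` before fitting (normalisation constants are
#'     stored with the model for exact round-trip to physical units).
#' }
#'
#' Predictors are z-scored on the training set (constants persisted with the
#' model) so the t-values -- coefficient divided by standard error -- are
#' unitless and comparable across predictors. Coefficients are estimated by
#' iteratively reweighted least squares; the dispersion is the Pearson
#' chi-square divided by the residual degrees of freedom, and standard
#' errors scale with its square root (point estimates are identical to the
#' corresponding non-quasi family).
#'
#' @param predictors `n x 16` matrix (columns per [predictor_names()]).
#' @param y Response vector: BA fraction in `[0, 1]`, or FS/FI >= 0.
#' @param response One of `"BA"`, `"FS"`, `"FI"`.
#' @param epsilon,maxit IRLS convergence tolerance on the deviance change
#'   and iteration cap.
#' @return Object of class `fire_glm`: coefficients (`beta`), `se`,
#'   `t_values`, `dispersion`, dispersion-scaled `vcov`, link metadata,
#'   standardisation (`center`, `scale`) and normalisation (`norm_min`,
#'   `norm_max`) constants, plus the underlying `stats::glm` fit.
#' @export
#' @examples
#' d <- generate_dataset(fire_grid(20, 10), seed = 3)
#' m <- fit_fire_glm(d$predictors, d$fire$BA, "BA")
#' head(t_values(m))
fit_fire_glm <- function(predictors, y, response = c("BA", "FS", "FI"),
                         epsilon = 1e-8, maxit = 100) {
  response <- match.arg(response)
  X <- check_predictor_layout(predictors)
  if (length(y) != nrow(X)) stop("length(y) must match nrow(predictors)")
  if (anyNA(X) || anyNA(y)) stop("missing values in predictors or response")
  p <- ncol(X) + 1L
  if (nrow(X) < 10 * p)
    stop("need at least ", 10 * p, " cells to fit ", p, " parameters")

  norm_min <- norm_max <- NA_real_
  if (response == "BA") {
    if (any(y < 0 | y > 1)) stop("BA must lie in [0, 1]")
    fam <- stats::quasibinomial(link = "logit")
    yfit <- y
  } else {
    if (any(y < 0)) stop(response, " must be >= 0")
    norm_min <- min(y); norm_max <- max(y)
    if (norm_max == norm_min) stop("constant response: cannot min-max normalise")
    fam <- stats::quasipoisson(link = "log")
    yfit <- (y - norm_min) / (norm_max - norm_min)
  }

  std <- standardise_predictors(X)
  dat <- as.data.frame(std$Z)
  dat$.y <- yfit
  fit <- stats::glm(.y ~ ., data = dat, family = fam,
                    control = stats::glm.control(epsilon = epsilon,
                                                 maxit = maxit))
  if (!fit$converged)
    stop("IRLS did not converge in ", maxit,
         " iterations (deviance ", format(fit$deviance), ")")
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  sm <- summary(fit)
  beta <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  structure(list(
    response = response,
    family = fam$family, link = fam$link,
    beta = beta, se = se, t_values = beta / se,
    dispersion = sm$dispersion,
    vcov = sm$cov.scaled,
    norm_min = norm_min, norm_max = norm_max,
    center = std$center, scale = std$scale,
    n = nrow(X), fit = fit
  ), class = "fire_glm")
}

#' @export
print.fire_glm <- function(x, ...) {
  cat(sprintf("fire_glm [%s]: %s, %s link, n = %d, dispersion = %.3f\n",
              x$response, x$family, x$link, x$n, x$dispersion))
  ord <- order(abs(x$t_values[-1]), decreasing = TRUE)[1:3]
  top <- names(x$beta[-1])[ord]
  cat("  top |t| predictors:",
      paste(sprintf("%s (%.1f)", top, x$t_values[-1][ord]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.fire_glm <- function(object, ...) object$beta

#' Coefficient t-values
#'
#' Coefficient divided by standard error -- the unitless, scale-invariant
#' measure used to rank predictor importance.
#'
#' @param model A `fire_glm`.
#' @return Named numeric vector (intercept first).
#' @export
t_values <- function(model) model$t_values

#' Model dispersion
#'
#' Pearson-based dispersion of a fitted model. For FS/FI models fitted on
#' the min-max-normalised response, `scale = "response"` rescales the
#' dispersion back to the physical response scale: for a response divided by
#' `c = norm_max - norm_min` (with the minimum at zero, which holds whenever
#' the smallest observed value is zero), Pearson dispersion scales exactly
#' as 1/c, so the response-scale value is `dispersion * c`.
#'
#' @param model A `fire_glm`.
#' @param scale `"normalised"` (the scale the model was fitted on) or
#'   `"response"`.
#' @return Dispersion estimate (> 0).
#' @export
dispersion <- function(model, scale = c("normalised", "response")) {
  scale <- match.arg(scale)
  if (scale == "normalised" || model$response == "BA") return(model$dispersion)
  model$dispersion * (model$norm_max - model$norm_min)
}

# eta and its standard error on new data
linear_predictor_se <- function(model, X) {
  X <- check_predictor_layout(X)
  Z <- standardise_predictors(X, model$center, model$scale)$Z
  M <- cbind("(Intercept)" = 1, Z)
  eta <- drop(M %*% model$beta)
  se <- sqrt(rowSums((M %*% model$vcov) * M))
  list(eta = unname(eta), se = unname(se))
}

inverse_link <- function(model, eta) {
  if (model$link == "logit") stats::plogis(eta) else exp(eta)
}

#' Predict fire properties from a fitted model
#'
#' @param object A `fire_glm`.
#' @param newdata `n x 16` predictor matrix; defaults to the training data.
#' @param type `"response"` (inverse-link scale) or `"link"`.
#' @param denormalise For FS/FI, map predictions back to physical units via
#'   the stored min-max constants (ignored for BA and for `type = "link"`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.fire_glm <- function(object, newdata = NULL,
                             type = c("response", "link"),
                             denormalise = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$fit$linear.predictors
  } else {
    eta <- linear_predictor_se(object, newdata)$eta
  }
  if (type == "link") return(eta)
  mu <- inverse_link(object, eta)
  if (object$response != "BA" && denormalise) {
    mu <- mu * (object$norm_max - object$norm_min) + object$norm_min
  }
  mu
}

#' 95% predictive confidence intervals
#'
#' Interval bounds are the fitted value plus and minus the normal quantile
#' (1.96 at the default 95% level) times the standard error of the fit. By
#' default (`method = "link"`) the band is built on the linear-predictor
#' scale and transformed through the inverse link, which keeps burnt-area
#' intervals inside (0, 1) and FS/FI intervals positive on the normalised
#' scale. `method = "multiplicative"` instead takes
#' `fitted * (1 +/- z * se)` on the response scale (the literal reading of
#' "plus and minus the fitted value multiplied by 1.96 times the standard
#' error").
#'
#' @param model A `fire_glm`.
#' @param newdata Predictor matrix; defaults to training data.
#' @param level Coverage level in (0, 1).
#' @param method `"link"` or `"multiplicative"`.
#' @param denormalise Map FS/FI bounds to physical units.
#' @return data.frame with `fit`, `lower`, `upper` (lower <= fit <= upper).
#' @export
predictive_interval <- function(model, newdata = NULL, level = 0.95,
                                method = c("link", "multiplicative"),
                                denormalise = TRUE) {
  method <- match.arg(method)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  if (is.null(newdata)) newdata <- model_training_X(model)
  ls <- linear_predictor_se(model, newdata)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "link") {
    fit <- inverse_link(model, ls$eta)
    lower <- inverse_link(model, ls$eta - z * ls$se)
    upper <- inverse_link(model, ls$eta + z * ls$se)
  } else {
    fit <- inverse_link(model, ls$eta)
    # response-scale se by the delta method: d mu/d eta * se(eta)
    dmu <- if (model$link == "logit") fit * (1 - fit) else fit
    lower <- fit * (1 - z * dmu * ls$se / pmax(fit, .Machine$double.eps))
    upper <- fit * (1 + z * dmu * ls$se / pmax(fit, .Machine$double.eps))
    lower <- pmax(lower, 0)
  }
  if (model$response != "BA" && denormalise) {
    c0 <- model$norm_min; c1 <- model$norm_max - model$norm_min
    fit <- fit * c1 + c0; lower <- lower * c1 + c0; upper <- upper * c1 + c0
  }
  data.frame(fit = fit, lower = lower, upper = upper)
}

model_training_X <- function(model) {
  Z <- as.matrix(model$fit$model[, predictor_names(), drop = FALSE])
  sweep(sweep(Z, 2, model$scale[colnames(Z)], "*"), 2,
        model$center[colnames(Z)], "+")
}

#' Partial residuals for one predictor
#'
#' Working residuals plus the predictor's own linear contribution
#' (`beta_j * z_j`), showing the effect of a predictor while all others are
#' held constant. Regressing the partial residuals on the standardised
#' predictor with the model's IRLS working weights recovers `beta_j`
#' exactly (orthogonality of working residuals holds in the weighted
#' metric); the returned frame carries the weights for that purpose.
#'
#' @param model A `fire_glm`.
#' @param predictor One of [predictor_names()].
#' @return data.frame with the raw predictor value (`x`), its standardised
#'   value (`z`) and the `partial_residual`.
#' @export
partial_residuals <- function(model, predictor) {
  if (!predictor %in% predictor_names())
    stop("unknown predictor: ", predictor)
  z <- model$fit$model[[predictor]]
  pr <- stats::residuals(model$fit, type = "working") +
    model$beta[predictor] * z
  data.frame(x = z * model$scale[predictor] + model$center[predictor],
             z = z, partial_residual = unname(pr),
             weight = unname(model$fit$weights))
}

#' Serialise / restore a fitted fire GLM
#'
#' Writes the model's portable parts (coefficients, standard errors,
#' covariance, dispersion, link metadata, standardisation and normalisation
#' constants) to a JSON document. A restored model supports `predict()` and
#' `predictive_interval()`; residual-based diagnostics require the original
#' fit.
#'
#' @param model A `fire_glm`.
#' @param path File path.
#' @return `read_fire_glm` returns a `fire_glm` (without the internal glm
#'   fit); `write_fire_glm` returns `path` invisibly.
#' @export
write_fire_glm <- function(model, path) {
  doc <- list(
    response = model$response, family = model$family, link = model$link,
    layout = predictor_names(),
    beta = as.list(model$beta), se = as.list(model$se),
    dispersion = model$dispersion,
    vcov = model$vcov,
    norm_min = model$norm_min, norm_max = model$norm_max,
    center = as.list(model$center), scale = as.list(model$scale),
    n = model$n
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fire_glm
#' @export
read_fire_glm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(doc$beta); se <- unlist(doc$se)
  vc <- as.matrix(doc$vcov)
  dimnames(vc) <- list(names(beta), names(beta))
  structure(list(
    response = doc$response, family = doc$family, link = doc$link,
    beta = beta, se = se, t_values = beta / se,
    dispersion = doc$dispersion, vcov = vc,
    norm_min = if (is.null(doc$norm_min)) NA_real_ else doc$norm_min,
    norm_max = if (is.null(doc$norm_max)) NA_real_ else doc$norm_max,
    center = unlist(doc$center), scale = unlist(doc$scale),
    n = doc$n, fit = NULL
  ), class = "fire_glm")
}
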