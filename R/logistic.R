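#' Logistic models: fitting, scoring, and the published nodal-risk vector
#'
#' The pipeline uses logistic regression in two ways: fitting models by
#' maximum likelihood on cohort data, and scoring patients with a fixed
#' published coefficient vector. Both paths share the `logit_model`
#' container: an intercept plus a named coefficient vector.
#'
#' @name logistic
NULL

#' Construct a logistic model from fixed coefficients
#'
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector of covariate coefficients.
#' @return object of class `logit_model`.
#' @export
logit_model <- function(intercept, coefficients) {
  if (length(coefficients) &&
      (is.null(names(coefficients)) || anyDuplicated(names(coefficients))))
    stop("coefficients must have unique names", call. = FALSE)
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 se = NULL, p = NULL, converged = TRUE, separation = FALSE),
            class = "logit_model")
}

#' @export
print.logit_model <- function(x, ...) {
  cat("Logistic model: logit(pr) =", format(x$intercept, digits = 3))
  for (nm in names(x$coefficients))
    cat(sprintf(" + (%s x %s)", format(x$coefficients[[nm]], digits = 3), nm))
  cat("\n")
  if (isTRUE(x$separation))
    cat("warning: complete/quasi-complete separation detected\n")
  invisible(x)
}

#' Fit a logistic regression by maximum likelihood
#'
#' Wald standard errors, p-values, odds ratios with 95% CI. Separation is
#' flagged (not an error) when coefficients diverge.
#'
#' @param y binary 0/1 outcome vector.
#' @param X data.frame or matrix of covariates (named columns).
#' @return `logit_model` with `se`, `p`, `or` (odds ratio + CI) components.
#' @export
fit_logistic <- function(y, X = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) stop("y must contain both classes", call. = FALSE)
  if (is.null(X) || NCOL(X) == 0) {  # intercept-only
    X <- data.frame(row.names = seq_along(y))
  } else {
    X <- as.data.frame(X)
    if (nrow(X) <= ncol(X))
      stop("need more observations than covariates", call. = FALSE)
  }
  dat <- cbind(.y = y, X)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separation <- any(abs(cf) > 15) || !fit$converged
  if (separation)
    warning("possible separation: coefficients diverging", call. = FALSE)
  z <- cf / se
  p <- 2 * stats::pnorm(-abs(z))
  m <- logit_model(cf[1], cf[-1])
  m$se <- se
  m$p <- p
  m$or <- cbind(or = exp(cf), lo = exp(cf - 1.96 * se), hi = exp(cf + 1.96 * se))
  m$converged <- fit$converged
  m$separation <- separation
  m$fit <- fit
  m
}

#' Score a logistic model on a covariate vector or table
#'
#' Evaluates pr = exp(z) / (1 + exp(z)) with
#' z = intercept + sum(beta * covariate). Every named coefficient must be
#' matched by a covariate; extras are ignored.
#'
#' @param model a `logit_model`.
#' @param covariates named numeric vector, or data.frame with one column per
#'   covariate (one probability per row).
#' @return numeric probability vector in (0, 1).
#' @export
score_logistic <- function(model, covariates) {
  stopifnot(inherits(model, "logit_model"))
  need <- names(model$coefficients)
  if (is.data.frame(covariates)) {
    miss <- setdiff(need, colnames(covariates))
    if (length(miss))
      stop("missing covariates: ", paste(miss, collapse = ", "), call. = FALSE)
    z <- model$intercept +
      as.matrix(covariates[, need, drop = FALSE]) %*% model$coefficients
    return(as.numeric(stats::plogis(z)))
  }
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop("missing covariates: ", paste(miss, collapse = ", "), call. = FALSE)
  z <- model$intercept + sum(model$coefficients * covariates[need])
  stats::plogis(z)
}

#' Published multivariable nodal-metastasis risk model
#'
#' The fixed multivariable logistic coefficient vector relating preoperative
#' clinicopathologic and genomic covariates to pathologic lymph-node
#' metastasis: intercept -3.07; nodule type (solid = 0, subsolid = 1) -1.28;
#' tumor size -0.035 (note the printed odds ratio for size, 1.036, implies the
#' opposite sign -- the printed coefficient is kept verbatim); histologic
#' subtype 0.69; STAS -0.46; visceral pleural invasion 0.72; lymphovascular
#' invasion 1.35; and mutation indicators for EGFR 0.084, TP53 -0.34,
#' RBM10 -0.83, STK11 0.17, ATM 0.75, HGF 1.33, KEAP1 0.97, PIK3CG 2.66.
#'
#' @return a `logit_model` ready for [score_logistic()].
#' @examples
#' score_logistic(pn_risk_model(), setNames(
#'   numeric(14), names(pn_risk_model()$coefficients)))  # ~0.0444
#' @export
pn_risk_model <- function() {
  logit_model(-3.07, c(
    Nodule_type = -1.28, Tumor_size = -0.035, Histologic_subtype = 0.69,
    Path_STAS = -0.46, Path_VPI = 0.72, Path_LVI = 1.35,
    EGFR = 0.084, TP53 = -0.34, RBM10 = -0.83, STK11 = 0.17,
    ATM = 0.75, HGF = 1.33, KEAP1 = 0.97, PIK3CG = 2.66))
}
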