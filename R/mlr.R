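# Fixed-timepoint multilinear AUC regression: stepwise model building with
# collinearity screening, application of a fitted equation, and the
# published four-point equation.

#' Construct a multilinear AUC model
#'
#' @param timepoints Sampling times (h) of the predictors.
#' @param coefficients Regression coefficients (mg.h/L per mg/L), one per
#'   timepoint.
#' @param intercept Intercept (mg.h/L) or `NULL` when absent.
#' @param r2 Coefficient of determination.
#' @param vif Variance inflation factors per predictor (optional).
#' @param n_fit Number of subjects the model was fitted on.
#' @return An object of class `mlr_model`.
#' @export
mlr_model <- function(timepoints, coefficients, intercept = NULL, r2 = NA,
                      vif = NULL, n_fit = NA) {
  if (length(timepoints) != length(coefficients)) {
    stop("one coefficient per timepoint is required", call. = FALSE)
  }
  structure(list(timepoints = as.numeric(timepoints),
                 coefficients = as.numeric(coefficients),
                 intercept = intercept, r2 = r2, vif = vif, n_fit = n_fit),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  terms <- paste(sprintf("%.3f x C%s", x$coefficients,
                         format(x$timepoints, trim = TRUE)),
                 collapse = " + ")
  if (!is.null(x$intercept)) {
    terms <- paste(sprintf("%.3f", x$intercept), "+", terms)
  }
  cat("AUC_0-12h =", terms, "\n")
  if (is.finite(x$r2)) cat(sprintf("  r2 = %.4f\n", x$r2))
  if (!is.null(x$vif)) {
    cat("  VIF:", paste(sprintf("%.2f", x$vif), collapse = ", "), "\n")
  }
  invisible(x)
}

# variance inflation factors of a predictor matrix (intercept included in
# the auxiliary regressions); Inf for aliased columns
vif_of <- function(X) {
  p <- ncol(X)
  if (p < 2) return(stats::setNames(rep(1, p), colnames(X)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, j] - mean(X[, j]))^2)
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(out, colnames(X))
}

#' Stepwise multilinear AUC regression
#'
#' Builds a fixed-timepoint linear predictor of the reference AUC from
#' concentrations on a grid restricted to the sampling window. Forward
#' steps add the candidate timepoint with the largest adjusted r2 among
#' those passing the entry test (partial-F p below `p_enter`) and not
#' inflating any variance inflation factor to `vif_max` or above; backward
#' steps drop terms whose p exceeds `p_remove`. The intercept is retained
#' only when its t-test p-value is at most `intercept_p`.
#'
#' @param conc Numeric matrix of concentrations, one row per subject, with
#'   column names giving the sampling times in hours (e.g. `"0"`, `"0.5"`).
#' @param auc_ref Reference AUC per subject (mg.h/L).
#' @param max_terms Maximum number of concentration terms.
#' @param window Latest admissible sampling time (h).
#' @param p_enter,p_remove Entry and stay p-value thresholds.
#' @param vif_max Collinearity bound; candidate predictors pushing any VIF
#'   to this value or beyond are inadmissible.
#' @param intercept_p Significance level for keeping the intercept.
#' @return An `mlr_model`.
#' @export
stepwise_mlr <- function(conc, auc_ref, max_terms = 4, window = 6,
                         p_enter = 0.05, p_remove = 0.10, vif_max = 10,
                         intercept_p = 0.05) {
  conc <- as.matrix(conc)
  if (is.null(colnames(conc))) {
    stop("`conc` must have timepoint column names", call. = FALSE)
  }
  times <- as.numeric(colnames(conc))
  keep <- !is.na(times) & times <= window
  conc <- conc[, keep, drop = FALSE]
  times <- times[keep]
  n <- nrow(conc)
  if (n != length(auc_ref)) stop("row/AUC length mismatch", call. = FALSE)
  if (n <= 10 * max_terms) {
    stop("need more than 10 subjects per term (n = ", n, ")", call. = FALSE)
  }
  selected <- integer(0)
  repeat {
    if (length(selected) >= max_terms) break
    cand <- setdiff(seq_along(times), selected)
    best <- NULL
    for (j in cand) {
      X <- conc[, c(selected, j), drop = FALSE]
      if (any(vif_of(X) >= vif_max)) next
      fit <- stats::lm(auc_ref ~ X)
      # exact constructions are legitimate input; silence the perfect-fit note
      sm <- suppressWarnings(summary(fit))
      cf <- stats::coef(sm)
      if (nrow(cf) != ncol(X) + 1) next    # aliased column
      p <- cf[nrow(cf), "Pr(>|t|)"]        # the newly added predictor
      if (is.na(p) || p >= p_enter) next
      adj <- sm$adj.r.squared
      if (is.null(best) || adj > best$adj) best <- list(j = j, adj = adj)
    }
    if (is.null(best)) break
    selected <- c(selected, best$j)
    # backward pass at the stay threshold
    repeat {
      if (length(selected) < 2) break
      X <- conc[, selected, drop = FALSE]
      sm <- suppressWarnings(summary(stats::lm(auc_ref ~ X)))
      pv <- stats::coef(sm)[-1, "Pr(>|t|)"]
      worst <- which.max(pv)
      if (pv[worst] > p_remove) selected <- selected[-worst] else break
    }
  }
  if (!length(selected)) {
    stop("no admissible predictor (collinear exhaustion or no signal)",
         call. = FALSE)
  }
  selected <- selected[order(times[selected])]
  X <- conc[, selected, drop = FALSE]
  fit_i <- stats::lm(auc_ref ~ X)
  cf_i <- stats::coef(suppressWarnings(summary(fit_i)))
  p_int <- cf_i["(Intercept)", "Pr(>|t|)"]
  # an intercept that is significant only because the fit is numerically
  # exact (estimate ~ machine precision) is still dropped
  use_intercept <- is.finite(p_int) && p_int <= intercept_p &&
    abs(cf_i["(Intercept)", "Estimate"]) > 1e-8 * stats::sd(auc_ref)
  fit <- if (use_intercept) fit_i else stats::lm(auc_ref ~ X - 1)
  coefs <- stats::coef(fit)
  beta <- coefs[grepl("^X", names(coefs))]
  vif <- vif_of(X)
  if (any(vif >= vif_max)) {
    stop("final model fails the collinearity screen (VIF >= ", vif_max, ")",
         call. = FALSE)
  }
  fitted_vals <- stats::fitted(fit)
  r2 <- 1 - sum((auc_ref - fitted_vals)^2) / sum((auc_ref - mean(auc_ref))^2)
  mlr_model(timepoints = times[selected],
            coefficients = as.numeric(beta),
            intercept = if (use_intercept)
              unname(coefs["(Intercept)"]) else NULL,
            r2 = r2, vif = vif, n_fit = n)
}

#' Apply a multilinear AUC equation
#'
#' @param model An `mlr_model`.
#' @param conc Named numeric vector of concentrations (mg/L); names are
#'   times in hours and must cover every model timepoint.
#' @return Estimated AUC (mg.h/L).
#' @export
apply_mlr <- function(model, conc) {
  stopifnot(inherits(model, "mlr_model"))
  have <- as.numeric(names(conc))
  sel <- match(model$timepoints, have)
  if (anyNA(sel)) {
    stop("missing concentration at t = ",
         paste(model$timepoints[is.na(sel)], collapse = ", "),
         " h; with missing fixed timepoints, estimate the AUC by the MAP ",
         "Bayesian pathway instead (see `map_fit()`)", call. = FALSE)
  }
  base <- if (is.null(model$intercept)) 0 else model$intercept
  base + sum(model$coefficients * as.numeric(conc[sel]))
}

#' The published four-point AUC equation
#'
#' The fixed-timepoint equation derived for EMIT-measured MPA in adult
#' heart-transplant recipients:
#' `AUC_0-12h = 3.539 C0 + 0.288 C0.5 + 1.349 C1 + 6.773 C4.5`
#' (no intercept, reported r2 = 0.999).
#'
#' @return An `mlr_model`.
#' @export
published_equation <- function() {
  mlr_model(timepoints = c(0, 0.5, 1, 4.5),
            coefficients = c(3.539, 0.288, 1.349, 6.773),
            intercept = NULL, r2 = 0.999)
}
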