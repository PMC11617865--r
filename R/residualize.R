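#' Remove covariate effects from every ROI by linear regression
#'
#' Fits, for each ROI column, an ordinary-least-squares regression of the
#' measurement on an intercept plus the named covariates, and returns the
#' residuals. These residuals are the "raw" values from which structural
#' covariance matrices are computed, so that edges reflect shared
#' morphometric variation beyond age and head-size effects.
#'
#' Covariates are mean-centered internally for numerical conditioning; this
#' does not change the residuals. With `fit_scope = "pooled"` (default) one
#' regression per ROI is fit across all subjects in the cohort, which keeps
#' group contrasts in the residuals; `"per-group"` fits each group
#' separately.
#'
#' @param cohort A `cohort` from [assemble_cohort()] or [generate_cohort()].
#' @param covariate_names Columns of `cohort$subjects` to regress out
#'   (default `c("age", "icv")`).
#' @param fit_scope `"pooled"` or `"per-group"`.
#' @return An object of class `residual_matrix`: `subject_ids`, `residuals`
#'   (subjects x ROIs, columns mean zero), `group_labels`, `covariates_used`,
#'   `fit_scope`, `atlas`.
#' @export
residualize <- function(cohort, covariate_names = c("age", "icv"),
                        fit_scope = c("pooled", "per-group")) {
  stopifnot(inherits(cohort, "cohort"))
  fit_scope <- match.arg(fit_scope)
  miss <- setdiff(covariate_names, colnames(cohort$subjects))
  if (length(miss) > 0L) {
    stop("covariate(s) not in cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  Y <- cohort$values
  groups <- cohort$subjects$group
  res <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  scopes <- if (fit_scope == "pooled") list(seq_len(nrow(Y)))
            else split(seq_len(nrow(Y)), groups)
  for (rows in scopes) {
    Z <- as.matrix(cohort$subjects[rows, covariate_names, drop = FALSE])
    storage.mode(Z) <- "double"
    if (anyNA(Z) || any(!is.finite(Z))) {
      stop("non-finite covariate values", call. = FALSE)
    }
    X <- cbind(`(Intercept)` = 1, scale(Z, center = TRUE, scale = FALSE))
    if (length(rows) <= ncol(X)) {
      stop("fewer subjects (", length(rows), ") than regression parameters (",
           ncol(X), ") in fit scope", call. = FALSE)
    }
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      stop("degenerate regression design: covariates are collinear or ",
           "constant within a fit scope", call. = FALSE)
    }
    res[rows, ] <- qr.resid(qx, Y[rows, , drop = FALSE])
  }
  structure(list(subject_ids = cohort$subjects$subject_id,
                 residuals = res,
                 group_labels = groups,
                 covariates_used = covariate_names,
                 fit_scope = fit_scope,
                 atlas = cohort$atlas),
            class = "residual_matrix")
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat("<residual_matrix> ", nrow(x$residuals), " subjects x ",
      ncol(x$residuals), " ROIs; covariates: ",
      paste(x$covariates_used, collapse = ", "), " (", x$fit_scope, ")\n",
      sep = "")
  invisible(x)
}
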