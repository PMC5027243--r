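# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a count regression
#'
#' @param x A `radsig_glm` from [count_glm()].
#' @param ... Unused.
#' @return Tibble of coefficients (log rate ratios).
#' @export
tidy.radsig_glm <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.radsig_glm
#' @export
glance.radsig_glm <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    dispersion = x$dispersion,
    overdispersed = x$overdispersed,
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    df_residual = x$fit$df.residual,
    nobs = length(x$fit$y)
  )
}

#' Tidy a mutation-type x group mixed model
#'
#' @param x A `radsig_mixed` from [mixed_interaction_model()].
#' @param interactions_only Return only the type-by-group interaction terms
#'   (default `TRUE`).
#' @param ... Unused.
#' @return Tibble of fixed-effect estimates with Satterthwaite p-values.
#' @export
tidy.radsig_mixed <- function(x, interactions_only = TRUE, ...) {
  if (interactions_only) x$interactions else x$coefficients
}

#' @rdname tidy.radsig_mixed
#' @export
glance.radsig_mixed <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(
    sigma_sample = vc$sdcor[vc$grp == "sample_id"][1L],
    sigma_residual = vc$sdcor[vc$grp == "Residual"][1L],
    logLik = as.numeric(stats::logLik(x$fit)),
    nobs = stats::nobs(x$fit)
  )
}

#' Tidy a feature-association battery
#'
#' @param x A `radsig_feature_tests` tibble from
#'   [test_feature_associations()].
#' @param ... Unused.
#' @return Plain tibble without the list-column of contingency tables.
#' @export
tidy.radsig_feature_tests <- function(x, ...) {
  out <- dplyr::select(tibble::as_tibble(x), -dplyr::any_of("tables"))
  class(out) <- class(tibble::tibble())
  out
}
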