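#' Standardize a trait vector
#'
#' Centers and scales to zero mean and unit standard deviation using the
#' sample (n - 1) standard deviation; the convention is recorded in the
#' `"scaling"` attribute.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return The standardized vector with attributes `center` and `scale`.
#' @examples
#' standardize(c(1, 2, 3)) # -1, 0, 1
#' @export
standardize <- function(x) {
  ok <- is.finite(x)
  if (length(unique(x[ok])) < 2L) {
    abort("cannot standardize a constant vector")
  }
  mu <- mean(x[ok])
  sigma <- sd(x[ok])
  out <- (x - mu) / sigma
  attr(out, "center") <- mu
  attr(out, "scale") <- sigma
  attr(out, "scaling") <- "sample sd (n-1)"
  out
}

#' Rank-based inverse normal (inverse-Gaussian) transform
#'
#' Maps a vector onto standard-normal quantiles by rank:
#' `qnorm((rank - 0.5) / n)`, with average ranks for ties. The result is a
#' monotone, rank-preserving map with mean ~0 following a standard normal
#' distribution; it makes skewed EV-abundance vectors usable as linear-model
#' exposures.
#'
#' @param x Numeric vector with at least 3 values and at least two distinct
#'   values; `NA`s are propagated (ranks computed among non-missing values).
#' @return Transformed numeric vector.
#' @examples
#' inverse_normal_transform(c(3, 1, 2)) # 0.967, -0.967, 0
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3L) abort("need at least 3 non-missing values")
  if (length(unique(x[ok])) < 2L) abort("cannot transform an all-tied vector")
  out <- rep(NA_real_, length(x))
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / n)
  out
}

#' Fit the EV-trait association model with sex interaction
#'
#' Ordinary least squares fit of
#' \deqn{Y^* = \mu + X^* \beta_{EV} + Sex\,\beta_{Sex} + Age\,\beta_{Age} +
#'   X^* Sex\,\beta_{EV\times Sex} + \varepsilon}
#' where \eqn{Y^*} is the standardized trait, \eqn{X^*} the inverse-normal
#' transformed exposure (an EV-type abundance or a total protein level) and
#' sex is coded male = 1, female = 0 — so a positive interaction means the
#' exposure's effect is weaker in men than in women. Rows with missing
#' values in any model variable are dropped (listwise per pair) and the n
#' used is reported.
#'
#' @param data Data frame holding the model variables.
#' @param trait,exposure,sex,age Column names (strings) in `data`.
#' @param standardize_trait Standardize the trait first (default TRUE; set
#'   FALSE if it is already on the analysis scale).
#' @param transform_exposure Apply [inverse_normal_transform()] to the
#'   exposure first (default TRUE).
#' @return An object of class `ev_association`; see [tidy.ev_association()]
#'   and [glance.ev_association()].
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(bmi = rnorm(96), ev = runif(96),
#'                     sex = rep(0:1, 48), age = runif(96, 20, 80))
#' fit <- fit_association(d, "bmi", "ev")
#' tidy(fit)
#' @export
fit_association <- function(data, trait, exposure, sex = "sex", age = "age",
                            standardize_trait = TRUE,
                            transform_exposure = TRUE) {
  cols <- c(trait, exposure, sex, age)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("columns not in data: ", paste(missing_cols, collapse = ", ")))
  }
  d <- data[cols]
  names(d) <- c(".y", ".x", ".sex", ".age")
  d <- d[complete.cases(d), ]
  n <- nrow(d)
  if (n <= 5L) abort("need n > 5 for the 5-parameter interaction model")
  y <- if (standardize_trait) as.numeric(standardize(d$.y)) else d$.y
  x <- if (transform_exposure) inverse_normal_transform(d$.x) else d$.x
  X <- cbind(`(Intercept)` = 1, ev = x, sex = d$.sex, age = d$.age,
             `ev:sex` = x * d$.sex)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("singular design; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  fit <- lm(y ~ x + d$.sex + d$.age + x:d$.sex)
  sm <- summary(fit)
  ct <- sm$coefficients
  rownames(ct) <- c("(Intercept)", "beta_EV", "beta_Sex", "beta_Age",
                    "beta_EV_by_sex")
  # squared semi-partial correlation of the EV main-effect term
  fit_red <- lm(y ~ d$.sex + d$.age + x:d$.sex)
  sst <- sum((y - mean(y))^2)
  partial_r2 <- (sum(residuals(fit_red)^2) - sum(residuals(fit)^2)) / sst
  structure(
    list(
      trait = trait, exposure = exposure, n = n,
      coefficients = ct,
      confint = stats::confint(fit),
      partial_r2 = partial_r2,
      r_squared = sm$r.squared,
      sigma = sm$sigma,
      df_residual = fit$df.residual,
      fit = fit
    ),
    class = "ev_association"
  )
}

#' @export
print.ev_association <- function(x, ...) {
  cat(sprintf("<ev_association> %s ~ %s (n = %d)\n", x$trait, x$exposure, x$n))
  cat(sprintf("  beta_EV = %.4g (p = %.3g), beta_EV_by_sex = %.4g (p = %.3g), partial R2 = %.3f\n",
              x$coefficients["beta_EV", 1], x$coefficients["beta_EV", 4],
              x$coefficients["beta_EV_by_sex", 1],
              x$coefficients["beta_EV_by_sex", 4], x$partial_r2))
  invisible(x)
}

#' Tidy an EV association fit
#'
#' @param x An `ev_association` from [fit_association()].
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.ev_association <- function(x, ...) {
  ct <- x$coefficients
  tibble(
    term = rownames(ct),
    estimate = ct[, 1], std.error = ct[, 2],
    statistic = ct[, 3], p.value = ct[, 4],
    conf.low = x$confint[, 1], conf.high = x$confint[, 2]
  )
}

#' @rdname tidy.ev_association
#' @return For `glance`: a one-row tibble with `trait`, `exposure`, `n`,
#'   `r.squared` (full model), `partial.r2` (EV term), `sigma`,
#'   `df.residual`.
#' @export
glance.ev_association <- function(x, ...) {
  tibble(
    trait = x$trait, exposure = x$exposure, n = x$n,
    r.squared = x$r_squared, partial.r2 = x$partial_r2,
    sigma = x$sigma, df.residual = x$df_residual
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Test every exposure against every trait
#'
#' Runs [fit_association()] over the cross of traits and exposures and
#' returns a flat results table, optionally BH-FDR adjusted across the whole
#' family via [fdr_adjust()].
#'
#' @param data Data frame with trait, exposure and covariate columns.
#' @param traits,exposures Character vectors of column names.
#' @param sex,age Covariate column names.
#' @param adjust Apply pooled BH adjustment across all main-effect and
#'   interaction P-values (default TRUE).
#' @param ... Passed to [fit_association()].
#' @return A tibble with one row per trait-exposure pair: `exposure`,
#'   `trait`, `n`, `beta_ev`, `se`, `p`, `beta_int`, `se_int`, `p_int`,
#'   `partial_r2`, and `q`/`q_int` when `adjust` is TRUE.
#' @export
associate_all <- function(data, traits, exposures, sex = "sex", age = "age",
                          adjust = TRUE, ...) {
  grid <- tidyr::expand_grid(exposure = exposures, trait = traits)
  res <- purrr::pmap(grid, function(exposure, trait) {
    f <- fit_association(data, trait, exposure, sex = sex, age = age, ...)
    tibble(
      exposure = exposure, trait = trait, n = f$n,
      beta_ev = f$coefficients["beta_EV", 1],
      se = f$coefficients["beta_EV", 2],
      p = f$coefficients["beta_EV", 4],
      beta_int = f$coefficients["beta_EV_by_sex", 1],
      se_int = f$coefficients["beta_EV_by_sex", 2],
      p_int = f$coefficients["beta_EV_by_sex", 4],
      partial_r2 = f$partial_r2
    )
  }) %>% bind_rows()
  if (adjust) res <- fdr_adjust(res)
  res
}

#' Benjamini-Hochberg FDR adjustment of association results
#'
#' Step-up BH q-values. With `family = "pooled"` (default, matching an
#' analysis where total-protein and EV-specific tests are corrected
#' together) the main-effect and interaction P-value columns are adjusted
#' within one shared family each across all rows; `"per_analysis"` adjusts
#' within each trait separately.
#'
#' @param results Tibble with columns `p` (and optionally `p_int`), e.g.
#'   from [associate_all()].
#' @param family `"pooled"` or `"per_analysis"`.
#' @return `results` with `q` (and `q_int`) columns appended.
#' @export
fdr_adjust <- function(results, family = c("pooled", "per_analysis")) {
  family <- match.arg(family)
  check_p <- function(p) {
    if (any(!is.na(p) & (p < 0 | p > 1))) abort("P-values must lie in [0, 1]")
    p
  }
  adjust_one <- function(df) {
    df$q <- p.adjust(check_p(df$p), method = "BH")
    if ("p_int" %in% names(df)) {
      df$q_int <- p.adjust(check_p(df$p_int), method = "BH")
    }
    df
  }
  if (family == "pooled") {
    adjust_one(results)
  } else {
    results %>%
      group_by(.data$trait) %>%
      dplyr::group_modify(~ adjust_one(.x)) %>%
      ungroup()
  }
}
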