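sig_flags <- function(p) {
  tibble::tibble(sig_05 = !is.na(p) & p < .05, sig_01 = !is.na(p) & p < .01)
}

#' Independent two-sample t test
#'
#' Two-sided pooled-variance t test by default (the convention of classic
#' case-control tables); Welch's unequal-variance form behind `var_equal =
#' FALSE`.
#'
#' @param x,y Numeric samples, each of length >= 2 (NAs dropped).
#' @param var_equal Pool the variances; default TRUE.
#' @param label Optional label carried into the result.
#' @return A one-row tibble: `label`, `estimate` (mean of `x` minus mean of
#'   `y`), `statistic`, `df`, `p_value`, `sig_05`, `sig_01`, `method`.
#' @export
ttest_independent <- function(x, y, var_equal = TRUE, label = NA_character_) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    abort("each sample needs at least 2 non-missing values")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    abort("both samples have zero variance; t test undefined")
  }
  fit <- stats::t.test(x, y, var.equal = var_equal)
  dplyr::bind_cols(
    tibble::tibble(label = label,
                   estimate = mean(x) - mean(y),
                   statistic = unname(fit$statistic),
                   df = unname(fit$parameter),
                   p_value = fit$p.value),
    sig_flags(fit$p.value)) |>
    dplyr::mutate(method = if (var_equal) "t (pooled)" else "t (Welch)")
}

# Build and rank-check the design; errors name the offending columns.
check_full_rank <- function(fit, data_names) {
  al <- stats::alias(fit)$Complete
  if (!is.null(al) && nrow(al) > 0L) {
    abort(sprintf("rank-deficient design: aliased term(s) %s",
                  paste(rownames(al), collapse = ", ")))
  }
  invisible(fit)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Fits the linear model `outcome ~ group + covariates` and reports the
#' adjusted group effect (the coefficient of the non-reference group level)
#' with the p value of its t statistic. For a factor `group` the reference is
#' its first level; a character column is converted using order of
#' appearance (never locale-dependent sorting), and the `contrast` column of
#' `tidy()` states the direction explicitly. With no covariates this reduces
#' exactly to the pooled-variance independent t test. Character or factor
#' covariates (e.g. gender) are coded 0/1 through the model matrix.
#'
#' @param data A data frame.
#' @param outcome,group Column names (strings) of the outcome and the
#'   two-level grouping factor.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return An object of class `ancova_fit`; use [generics::tidy()] for the
#'   adjusted group contrast and [generics::glance()] for model-level
#'   summaries.
#' @export
ancova <- function(data, outcome, group, covariates = character()) {
  stopifnot(is.data.frame(data))
  need <- c(outcome, group, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  df <- data[, need, drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  if (!is.factor(df[[group]])) {
    # order of appearance, not locale-dependent sorting
    df[[group]] <- factor(df[[group]], levels = unique(as.character(df[[group]])))
  } else {
    df[[group]] <- droplevels(df[[group]])
  }
  if (nlevels(df[[group]]) != 2L) abort("`group` must have exactly 2 levels")
  if (nrow(df) <= length(covariates) + 2L) {
    abort("too few complete observations for the requested model")
  }
  if (anyDuplicated(covariates)) {
    abort(sprintf("rank-deficient design: duplicated covariate(s) %s",
                  paste(unique(covariates[duplicated(covariates)]), collapse = ", ")))
  }
  fml <- stats::reformulate(c(group, covariates), response = outcome)
  fit <- lm(fml, data = df)
  check_full_rank(fit)
  structure(list(fit = fit, outcome = outcome, group = group,
                 covariates = covariates,
                 levels = levels(df[[group]]), n = nrow(df)),
            class = "ancova_fit")
}

#' @export
#' @method tidy ancova_fit
#' @rdname ancova
#' @param x An `ancova_fit`.
#' @param ... Unused.
tidy.ancova_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  term <- paste0(x$group, x$levels[2])
  row <- sm[term, ]
  p <- unname(row["Pr(>|t|)"])
  dplyr::bind_cols(
    tibble::tibble(
      label = x$outcome,
      contrast = sprintf("%s - %s", x$levels[2], x$levels[1]),
      estimate = unname(row["Estimate"]),
      std_error = unname(row["Std. Error"]),
      statistic = unname(row["t value"]),
      df = x$fit$df.residual,
      p_value = p,
      covariates = paste(x$covariates, collapse = ",")),
    sig_flags(p))
}

#' @export
#' @method glance ancova_fit
#' @rdname ancova
glance.ancova_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 sigma = sm$sigma,
                 df_residual = x$fit$df.residual,
                 nobs = x$n)
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("ANCOVA: %s ~ %s%s (n = %d)\n", x$outcome, x$group,
              if (length(x$covariates) > 0)
                paste0(" + ", paste(x$covariates, collapse = " + ")) else "",
              x$n))
  print(tidy.ancova_fit(x))
  invisible(x)
}

#' Pearson correlation with test
#'
#' Pearson's r with the exact t-based p value
#' (`t = r sqrt((n-2)/(1-r^2))`, df = n - 2). Binary 0/1 columns are handled
#' as numeric, giving the point-biserial correlation. Pairs with a missing
#' value in either column are dropped.
#'
#' @param data A data frame.
#' @param x,y Column names (strings).
#' @return A one-row tibble: `x`, `y`, `r`, `statistic`, `df`, `p_value`,
#'   `n`, `sig_05`, `sig_01`.
#' @export
pearson_cor <- function(data, x, y) {
  xv <- as.numeric(data[[x]])
  yv <- as.numeric(data[[y]])
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) abort("Pearson correlation needs at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) abort("zero variance: correlation undefined")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  dplyr::bind_cols(
    tibble::tibble(x = x, y = y, r = unname(ct$estimate),
                   statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p_value = ct$p.value, n = n),
    sig_flags(ct$p.value))
}

#' Partial correlation adjusted for covariates
#'
#' Correlation of the residuals of `x` and `y` after linear regression on
#' the covariates (with intercept); the p value uses
#' `t = r sqrt(df / (1 - r^2))` with `df = n - 2 - k` for `k` covariates.
#' With no covariates this equals [pearson_cor()].
#'
#' @param data A data frame.
#' @param x,y Column names (strings).
#' @param covariates Character vector of covariate column names. Character
#'   or factor covariates are coded through the model matrix.
#' @return A one-row tibble like [pearson_cor()], plus a `covariates`
#'   column.
#' @export
partial_cor <- function(data, x, y, covariates = character()) {
  if (length(covariates) == 0L) {
    return(dplyr::mutate(pearson_cor(data, x, y), covariates = ""))
  }
  need <- c(x, y, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  df <- data[, need, drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  k <- length(covariates)
  if (n < k + 3L) abort("too few complete observations for partial correlation")
  zf <- stats::reformulate(covariates)
  Z <- stats::model.matrix(zf, data = df)
  if (qr(Z)$rank < ncol(Z)) {
    abort(sprintf("rank-deficient covariates: %s",
                  paste(covariates, collapse = ", ")))
  }
  rx <- stats::lm.fit(Z, as.numeric(df[[x]]))$residuals
  ry <- stats::lm.fit(Z, as.numeric(df[[y]]))$residuals
  tol_x <- 1e-10 * max(sd(df[[x]]), 1)
  tol_y <- 1e-10 * max(sd(df[[y]]), 1)
  if (sd(rx) <= tol_x || sd(ry) <= tol_y) {
    abort("zero residual variance: partial correlation undefined")
  }
  r <- cor(rx, ry)
  dfree <- n - 2L - k
  tstat <- r * sqrt(dfree / (1 - r^2))
  p <- 2 * pt(-abs(tstat), dfree)
  dplyr::bind_cols(
    tibble::tibble(x = x, y = y, r = r, statistic = tstat, df = dfree,
                   p_value = p, n = n),
    sig_flags(p)) |>
    dplyr::mutate(covariates = paste(covariates, collapse = ","))
}

#' Chi-square test for a categorical baseline row
#'
#' Group-by-category chi-square test (for rows such as gender, where a mean
#' comparison is not meaningful).
#'
#' @param data A data frame.
#' @param variable,group Column names (strings).
#' @return A one-row tibble: `label`, `statistic`, `df`, `p_value`,
#'   `sig_05`, `sig_01`, `method`.
#' @export
chisq_row <- function(data, variable, group) {
  tab <- table(data[[group]], data[[variable]])
  if (any(dim(tab) < 2L)) abort("chi-square needs >= 2 levels in both factors")
  ct <- suppressWarnings(stats::chisq.test(tab))
  dplyr::bind_cols(
    tibble::tibble(label = variable, statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p_value = ct$p.value),
    sig_flags(ct$p.value)) |>
    dplyr::mutate(method = "chi-square")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
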