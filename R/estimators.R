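# Design-based linear estimators: weighted least squares with the
# stratum/PSU sandwich variance, covariate-adjusted (least-squares) means,
# age-trend regression, population-ratio contributions, and the weighted
# paired t test. All variances share the Taylor machinery in design.R.

# Weighted LS fit with design-based sandwich vcov.
#   beta = (X'WX)^-1 X'Wy,  V = A^-1 M A^-1,
# M the stratified between-PSU covariance of the weighted score totals
# u_i = w_i x_i e_i. Aliased (collinear) columns are dropped with a note.
svy_lm <- function(y, X, design) {
  if (design_df(design) <= 0) {
    stop("design has no degrees of freedom: #PSUs must exceed #strata",
         call. = FALSE)
  }
  w <- design$w
  Xw <- X * sqrt(w)
  qx <- qr(Xw)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    message("dropping aliased model column(s): ",
            paste(dropped, collapse = ", "))
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    X <- X[, keep, drop = FALSE]
  }
  A <- crossprod(X, w * X)
  beta <- solve(A, crossprod(X, w * y))
  e <- as.numeric(y - X %*% beta)
  U <- X * (w * e)
  M <- taylor_vcov(U, design)
  Ainv <- solve(A)
  V <- Ainv %*% M %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  list(beta = stats::setNames(as.numeric(beta), colnames(X)), vcov = V,
       columns = colnames(X), df = design_df(design))
}

covariate_frame <- function(covariates, n) {
  if (is.null(covariates) || length(covariates) == 0) {
    return(data.frame(row.names = seq_len(n)))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  covariates[] <- lapply(covariates, function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  })
  constant <- vapply(covariates, function(col) {
    is.factor(col) && nlevels(droplevels(col)) < 2
  }, logical(1))
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(names(covariates)[constant], collapse = ", "))
    covariates <- covariates[!constant]
  }
  covariates
}

#' Survey-weighted age-trend regression
#'
#' Weighted least squares of an outcome on continuous age (years) plus
#' categorical covariates, with the stratum/PSU sandwich variance. The age
#' coefficient is the modeled change per year of age across the range;
#' degrees of freedom for the t test are the number of PSUs minus the
#' number of strata, the survey-regression convention.
#'
#' @param y Per-subject outcome.
#' @param age Age in years (continuous).
#' @param design A [survey_design()].
#' @param covariates Optional data frame of categorical covariates
#'   (typically sex, ethnicity and poverty-income ratio level). Collinear
#'   indicator columns are dropped with a note.
#' @return An object of class `trend_fit`: list with `beta` (age slope),
#'   `se`, `t`, `p` (two-sided), `df`, plus the full `coefficients` and
#'   `vcov`.
#' @export
trend_regression <- function(y, age, design, covariates = NULL) {
  stopifnot(length(y) == design$n, length(age) == design$n)
  d <- covariate_frame(covariates, design$n)
  d <- cbind(data.frame(age = as.numeric(age)), d)
  X <- stats::model.matrix(~ ., data = d)
  fit <- svy_lm(y, X, design)
  if (!("age" %in% fit$columns)) {
    stop("age term was aliased; trend is not identifiable", call. = FALSE)
  }
  beta <- fit$beta[["age"]]
  se <- sqrt(fit$vcov["age", "age"])
  tval <- beta / se
  structure(
    list(beta = beta, se = se, t = tval,
         p = 2 * stats::pt(-abs(tval), df = fit$df), df = fit$df,
         coefficients = fit$beta, vcov = fit$vcov),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> beta = %.4g (SE %.4g) per year, t = %.3g, df = %d, p = %.3g\n",
              x$beta, x$se, x$t, x$df, x$p))
  invisible(x)
}

#' Covariate-adjusted (least-squares) means by age group
#'
#' Fits a weighted linear model of the outcome on age-group indicators plus
#' categorical covariates and reports, for each age group, the predicted
#' marginal mean obtained by averaging model predictions over the pooled
#' weighted covariate distribution (observed-margins convention). Standard
#' errors come from the sandwich variance of the corresponding linear
#' combination of coefficients.
#'
#' @param y Per-subject outcome.
#' @param age_group Factor of age-group labels, aligned with the design.
#' @param design A [survey_design()].
#' @param covariates Optional data frame of categorical covariates; empty
#'   cells yield aliased indicators which are dropped with a note.
#' @param quantity Label stored in the output's `quantity` column.
#' @return An estimate-table tibble: `quantity`, `age_group`, `estimate`,
#'   `se`, `n`.
#' @export
lsmeans_by_age_group <- function(y, age_group, design, covariates = NULL,
                                 quantity = "outcome") {
  age_group <- as.factor(age_group)
  stopifnot(length(y) == design$n, length(age_group) == design$n)
  multi_group <- nlevels(droplevels(age_group)) >= 2
  d <- covariate_frame(covariates, design$n)
  if (multi_group) d <- cbind(data.frame(.age_group = age_group), d)
  intercept_only <- ncol(d) == 0
  if (intercept_only) {
    X <- matrix(1, design$n, 1, dimnames = list(NULL, "(Intercept)"))
    tt <- NULL; mf <- NULL
  } else {
    mf <- stats::model.frame(~ ., data = d)
    tt <- attr(mf, "terms")
    X <- stats::model.matrix(tt, mf)
  }
  fit <- svy_lm(y, X, design)
  w <- design$w
  W <- sum(w)
  lev <- levels(age_group)
  out <- vector("list", length(lev))
  xlev <- if (is.null(tt)) NULL else stats::.getXlevels(tt, mf)
  for (k in seq_along(lev)) {
    if (multi_group) {
      dg <- d
      dg$.age_group <- factor(lev[k], levels = lev)
      Xg <- stats::model.matrix(tt, stats::model.frame(tt, dg, xlev = xlev))
    } else {
      Xg <- X
    }
    Xg <- Xg[, fit$columns, drop = FALSE]
    cg <- colSums(w * Xg) / W
    est <- sum(cg * fit$beta)
    v <- as.numeric(t(cg) %*% fit$vcov %*% cg)
    n_g <- sum(age_group == lev[k])
    out[[k]] <- tibble::tibble(
      quantity = quantity, age_group = lev[k], estimate = est,
      se = sqrt(max(v, 0)), n = n_g
    )
  }
  do.call(rbind, out)
}

#' Population-ratio nutrient contribution
#'
#' The contribution of a food source to a nutrient as a percentage of the
#' population's total intake: `100 * sum(w * source) / sum(w * total)`, the
#' recommended population ratio method. The linearized SE treats the
#' quantity as a ratio estimator.
#'
#' @param source Per-subject intake of the nutrient from the source group.
#' @param total Per-subject total intake of the nutrient.
#' @param design A [survey_design()].
#' @return A list: `estimate` (percent), `se`, `n`.
#' @export
population_ratio <- function(source, total, design) {
  stopifnot(length(source) == design$n, length(total) == design$n)
  w <- design$w
  Tw <- sum(w * total)
  if (Tw == 0) {
    stop("population ratio undefined: weighted total intake is zero",
         call. = FALSE)
  }
  if (any(source > total + 1e-8)) {
    warning("source intake exceeds total intake for some subjects",
            call. = FALSE)
  }
  R <- sum(w * source) / Tw
  z <- 100 * w * (source - R * total) / Tw
  v <- taylor_vcov(z, design)[1L, 1L]
  list(estimate = 100 * R, se = sqrt(v), n = design$n)
}

#' Design-weighted paired t test
#'
#' Tests the mean within-subject difference (adjusted minus baseline) using
#' the survey-weighted mean of differences and its Taylor-linearized SE;
#' degrees of freedom are PSUs minus strata. An unweighted classical
#' variant is available for sensitivity checks.
#'
#' @param baseline,adjusted Per-subject values on the same subjects.
#' @param design A [survey_design()].
#' @param weighted If `FALSE`, the classical unweighted paired t test.
#' @return A list: `mean_difference`, `se`, `t`, `p`, `df`, and `flagged`
#'   (`TRUE` when the SE is zero with a nonzero mean, in which case the
#'   p value is reported as the smallest representable double).
#' @export
paired_t <- function(baseline, adjusted, design, weighted = TRUE) {
  stopifnot(length(baseline) == length(adjusted))
  d <- adjusted - baseline
  if (weighted) {
    m <- svy_mean(d, design)
    est <- m$estimate; se <- m$se; df <- m$df
  } else {
    est <- mean(d); se <- stats::sd(d) / sqrt(length(d))
    df <- length(d) - 1L
  }
  flagged <- FALSE
  if (se == 0) {
    if (est == 0) {
      tval <- 0; p <- 1
    } else {
      tval <- sign(est) * Inf; p <- .Machine$double.xmin; flagged <- TRUE
    }
  } else {
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), df = df)
  }
  list(mean_difference = est, se = se, t = tval, p = p, df = df,
       flagged = flagged)
}

#' Assign age-group labels
#'
#' Cuts integer ages into the standard reporting groups. The groups must
#' partition the 6-18 year range without overlap.
#'
#' @param age Ages in years.
#' @param groups Named list of integer age vectors.
#' @return Factor of group labels (NA outside all groups).
#' @export
age_group_factor <- function(age,
                             groups = list("6-8" = 6:8, "9-13" = 9:13,
                                           "14-18" = 14:18)) {
  all_ages <- sort(unlist(groups))
  if (anyDuplicated(all_ages) || !identical(as.integer(all_ages), 6:18)) {
    stop("age groups must partition ages 6-18 without overlap",
         call. = FALSE)
  }
  lab <- rep(NA_character_, length(age))
  for (g in names(groups)) lab[age %in% groups[[g]]] <- g
  factor(lab, levels = names(groups))
}
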