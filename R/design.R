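#' Complex survey design
#'
#' Bundles per-subject analysis weights with the stratified, clustered
#' sampling structure (PSUs nested in strata) used for Taylor-linearized
#' variance estimation. The first stage is treated as sampled with
#' replacement (no finite-population correction), the standard choice for
#' NHANES-style designs. When several survey cycles are pooled, the
#' released day-1 weight is divided by the number of cycles.
#'
#' @param weights Nonnegative per-subject weights (e.g. day-1 dietary
#'   weights). Zero weights are allowed; such subjects contribute nothing.
#' @param strata Stratum identifiers, one per subject.
#' @param psu PSU identifiers, nested within strata.
#' @param n_cycles Number of pooled survey cycles; the analysis weight is
#'   `weights / n_cycles`.
#' @return An object of class `survey_design`.
#' @export
#' @examples
#' d <- survey_design(weights = rep(1, 6), strata = rep(1:2, each = 3),
#'                    psu = c(1, 1, 2, 1, 2, 2))
#' svy_mean(rnorm(6), d)
survey_design <- function(weights, strata, psu, n_cycles = 1) {
  n <- length(weights)
  if (length(strata) != n || length(psu) != n) {
    stop("weights, strata and psu must have equal length", call. = FALSE)
  }
  weights <- as.numeric(weights)
  if (any(is.na(weights)) || any(weights < 0)) {
    stop("weights must be nonnegative and non-missing", call. = FALSE)
  }
  if (sum(weights) <= 0) stop("total weight must be positive", call. = FALSE)
  structure(
    list(w = weights / n_cycles,
         stratum = as.character(strata),
         psu = paste(strata, psu, sep = "//"),
         n = n, n_cycles = n_cycles),
    class = "survey_design"
  )
}

#' @description `subject_design()` builds the design directly from a
#'   subject table's `day1_weight`, `stratum_id` and `psu_id` columns.
#' @param subjects Subject table (see [read_subjects()]).
#' @rdname survey_design
#' @export
subject_design <- function(subjects, n_cycles = 1) {
  survey_design(subjects$day1_weight, subjects$stratum_id, subjects$psu_id,
                n_cycles = n_cycles)
}

#' @export
print.survey_design <- function(x, ...) {
  cat("<survey_design>", x$n, "subjects,",
      length(unique(x$stratum)), "strata,",
      length(unique(x$psu)), "PSUs,",
      "total weight", format(sum(x$w)), "\n")
  invisible(x)
}

#' Restrict a design to a domain of subjects
#'
#' Domain (subpopulation) estimation, e.g. one age group: weights outside
#' the domain are set to zero while every stratum and PSU is retained, so
#' the variance correctly reflects that domain membership varies over
#' hypothetical samples and no stratum spuriously loses its second PSU.
#' Estimators applied to the result must be given full-length outcome
#' vectors.
#'
#' @param design A [survey_design()].
#' @param idx Logical or integer subject index defining the domain.
#' @export
design_subset <- function(design, idx) {
  if (!is.logical(idx)) idx <- seq_len(design$n) %in% idx
  w <- design$w
  w[!idx] <- 0
  structure(
    list(w = w, stratum = design$stratum, psu = design$psu,
         n = design$n, n_cycles = design$n_cycles),
    class = "survey_design"
  )
}

design_df <- function(design) {
  length(unique(design$psu)) - length(unique(design$stratum))
}

# Stratified between-PSU covariance of per-observation score contributions
# under the with-replacement approximation:
#   Var = sum_h n_h/(n_h - 1) * sum_j (z_hj - zbar_h)(z_hj - zbar_h)'
# with z_hj the PSU totals of the scores. `z` may be a vector or an
# n x p matrix; returns a p x p matrix (1 x 1 for vectors). Strata that
# carry any positive weight must contain at least two PSUs; a lone-PSU
# stratum is an error naming the stratum, never silently collapsed.
taylor_vcov <- function(z, design) {
  z <- as.matrix(z)
  psu_tot <- rowsum(z, design$psu, reorder = FALSE)
  psu_str <- sub("//.*$", "", rownames(psu_tot))
  active <- tapply(design$w, design$stratum, sum) > 0
  lone <- names(which(table(psu_str) < 2))
  lone <- lone[active[lone]]
  if (length(lone) > 0) {
    stop("stratum with a single PSU cannot contribute to variance: ",
         paste(lone, collapse = ", "), call. = FALSE)
  }
  V <- matrix(0, ncol(z), ncol(z))
  for (h in unique(psu_str)) {
    zh <- psu_tot[psu_str == h, , drop = FALSE]
    nh <- nrow(zh)
    if (nh < 2) next  # zero-weight stratum
    d <- sweep(zh, 2L, colMeans(zh))
    V <- V + nh / (nh - 1) * crossprod(d)
  }
  V
}

#' Survey-weighted mean with Taylor-linearized SE
#'
#' Point estimate `sum(w*y)/sum(w)` and its design-based standard error by
#' first-order Taylor linearization: per-subject scores
#' `z_i = w_i (y_i - est) / sum(w)` are totalled within PSUs and their
#' stratified between-PSU variance taken under the with-replacement
#' approximation.
#'
#' @param y Per-subject values, aligned with the design.
#' @param design A [survey_design()].
#' @return A list: `estimate`, `se`, `n`, `df` (PSUs minus strata),
#'   `n_psu`, `n_strata`.
#' @export
svy_mean <- function(y, design) {
  stopifnot(length(y) == design$n)
  W <- sum(design$w)
  est <- sum(design$w * y) / W
  z <- design$w * (y - est) / W
  v <- taylor_vcov(z, design)[1L, 1L]
  list(estimate = est, se = sqrt(v), n = design$n, df = design_df(design),
       n_psu = length(unique(design$psu)),
       n_strata = length(unique(design$stratum)))
}
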