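#' z-transform a score vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1, so raw
#' scores from different reading tests become comparable.
#'
#' @param values numeric vector, length >= 2, nonzero variance.
#' @return standardized numeric vector.
#' @export
z_transform <- function(values) {
  if (length(values) < 2 || anyNA(values)) {
    stop("`values` must be complete with length >= 2", call. = FALSE)
  }
  s <- sd(values)
  if (s == 0) stop("`values` has zero variance", call. = FALSE)
  (values - mean(values)) / s
}

#' Composite score from correlation-matrix PCA
#'
#' Principal component analysis of the Pearson correlation matrix of
#' three test scores. The first component's loadings are reported on the
#' correlation scale (eigenvector times the square root of its
#' eigenvalue, i.e. the correlation of each test with the component) and
#' oriented so the loadings are positive — a higher composite means
#' better performance. Scores are the z-scored variables projected on
#' the unit-norm first eigenvector (zero mean by construction).
#'
#' @param reading_raw data frame or matrix with 3 numeric columns and
#'   more than 3 rows, no constant columns.
#' @return an object of class `pca_composite`: `loadings` (PC1,
#'   correlation scale), `eigenvalues` (descending, summing to 3),
#'   `pct_variance_pc1`, `scores` and the unit eigenvector `rotation`.
#' @export
pca_composite <- function(reading_raw) {
  x <- as.matrix(reading_raw)
  if (ncol(x) != 3) stop("expected exactly 3 score columns", call. = FALSE)
  if (nrow(x) <= 3) stop("need more than 3 observations", call. = FALSE)
  if (anyNA(x)) stop("missing values in scores", call. = FALSE)
  if (any(apply(x, 2, sd) == 0)) {
    stop("constant score column", call. = FALSE)
  }
  r <- cor(x)
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) < 1e-10) {
    warning("singular correlation matrix: some score columns are ",
            "(numerically) perfectly correlated")
  }
  v1 <- e$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  z <- scale(x)
  structure(list(
    loadings = as.numeric(v1 * sqrt(e$values[1])),
    eigenvalues = e$values,
    pct_variance_pc1 = variance_explained(e$values[1], 3),
    scores = as.numeric(z %*% v1),
    rotation = v1
  ), class = "pca_composite")
}

#' Percentage of variance explained by an eigenvalue
#'
#' For a correlation-matrix PCA the eigenvalues sum to the number of
#' variables, so one component explains `eigenvalue / n_vars * 100`
#' percent of the total variance.
#'
#' @param eigenvalue eigenvalue in \[0, n_vars\].
#' @param n_vars number of variables entered into the PCA.
#' @return percentage (exact; round for display).
#' @export
variance_explained <- function(eigenvalue, n_vars) {
  stop_if_not_scalar_number(eigenvalue, "eigenvalue", 0, n_vars)
  eigenvalue / n_vars * 100
}

#' Normality gate for correlation-method choice
#'
#' Shapiro-Wilk test on an outcome variable: variables that violate
#' normality at `alpha` are analysed with rank-based (Spearman)
#' correlations, the rest parametrically (Pearson).
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @param alpha gate criterion (default 0.05).
#' @return list with `method` (`"parametric"` or `"rank"`) and `p` (the
#'   Shapiro-Wilk p-value, `NA` for constant input, which gates to rank
#'   with a warning).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("need 3 <= n <= 5000", call. = FALSE)
  if (sd(values) == 0) {
    warning("constant input: gating to rank-based analysis")
    return(list(method = "rank", p = NA_real_))
  }
  p <- shapiro.test(values)$p.value
  list(method = if (p < alpha) "rank" else "parametric", p = p)
}

#' Semipartial correlation
#'
#' Correlation between an outcome `y` and the part of a predictor `x`
#' that is unique with respect to a set of covariates: `x` is
#' residualized on the covariates by ordinary least squares (with
#' intercept) and the residual is correlated with the raw outcome. For
#' `method = "spearman"` all variables (predictor, outcome, covariates)
#' are rank-transformed first, giving a rank-based semipartial
#' coefficient. The p-value uses the t approximation with
#' `n - 2 - n_covariates` degrees of freedom.
#'
#' @param x predictor vector.
#' @param y outcome vector.
#' @param covariates optional matrix/data frame of covariates (full
#'   column rank after adding an intercept); `NULL` gives the plain
#'   correlation.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `p_value`, `df`, `method` and
#'   `degenerate` (`TRUE` when the predictor residual is numerically
#'   zero, in which case the estimate is 0).
#' @export
semipartial <- function(x, y, covariates = NULL,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` lengths differ", call. = FALSE)
  z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(z) && nrow(z) != n) {
    stop("covariate rows must match `x`", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
    if (!is.null(z)) z <- apply(z, 2, rank)
  }
  k <- if (is.null(z)) 0L else ncol(z)
  if (k > 0) {
    design <- cbind(1, z)
    qrz <- qr(design)
    if (qrz$rank < ncol(design)) {
      stop("rank-deficient covariate matrix", call. = FALSE)
    }
    xr <- qr.resid(qrz, x)
  } else {
    xr <- x - mean(x)
  }
  degenerate <- sd(xr) < 1e-12 * max(sd(x), 1)
  if (degenerate) {
    return(list(estimate = 0, p_value = NA_real_, df = n - 2L - k,
                method = method, degenerate = TRUE))
  }
  r <- cor(xr, y)
  df <- n - 2L - k
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(tt), df)
  }
  list(estimate = r, p_value = p, df = df, method = method,
       degenerate = FALSE)
}

# outcome columns of a cohort table, in reporting order
.cohort_outcomes <- function() {
  c("motion_acuity_s", "motion_knee_s", "motion_asymptote_pct",
    "motion_slope", "form_acuity_s", "form_knee_s",
    "form_asymptote_pct", "form_slope")
}

#' Full cohort correlation analysis
#'
#' The study's statistical pipeline on a participant table: (1) a
#' composite reading score from correlation-matrix PCA of the three
#' reading tests (NART, TOWRE Sight Word Efficiency, TOWRE Phonemic
#' Decoding Efficiency); (2) a Shapiro-Wilk normality gate per visual
#' outcome choosing Pearson or Spearman; (3) semipartial correlations of
#' the composite with each of the eight visual outcomes (temporal acuity
#' limit, knee-point, asymptotic threshold and slope, for the motion and
#' form tasks) controlling gender and nonverbal IQ; and (4) semipartial
#' correlations of nonverbal IQ with the two asymptotic thresholds
#' controlling the reading composite and gender. No multiple-testing
#' correction is applied.
#'
#' @param cohort a cohort data frame (see [generate_cohort()]) with
#'   columns `gender`, `nonverbal_iq`, `nart_raw`, `towre_swe_raw`,
#'   `towre_pde_raw` and the eight visual outcome columns.
#' @param gate_alpha normality-gate criterion.
#' @return list with `report` (10-row data frame: predictor, outcome,
#'   task, method, estimate, p_value, normality_p) and `pca` (the
#'   [pca_composite()] object).
#' @export
analyze_cohort <- function(cohort, gate_alpha = 0.05) {
  needed <- c("gender", "nonverbal_iq", "nart_raw", "towre_swe_raw",
              "towre_pde_raw", .cohort_outcomes())
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cohort) < 4) stop("need at least 4 participants", call. = FALSE)
  if (anyNA(cohort[needed])) stop("missing values in cohort", call. = FALSE)

  pca <- pca_composite(cohort[c("nart_raw", "towre_swe_raw",
                                "towre_pde_raw")])
  composite <- pca$scores
  covs <- cbind(gender = cohort$gender, iq = cohort$nonverbal_iq)

  rows <- lapply(.cohort_outcomes(), function(oc) {
    yv <- cohort[[oc]]
    gate <- normality_gate(yv, gate_alpha)
    meth <- if (gate$method == "rank") "spearman" else "pearson"
    sp <- semipartial(composite, yv, covs, method = meth)
    data.frame(predictor = "reading_composite", outcome = oc,
               task = sub("_.*", "", oc), method = meth,
               estimate = sp$estimate, p_value = sp$p_value,
               normality_p = gate$p)
  })
  iq_rows <- lapply(c("motion_asymptote_pct", "form_asymptote_pct"),
                    function(oc) {
    yv <- cohort[[oc]]
    gate <- normality_gate(yv, gate_alpha)
    meth <- if (gate$method == "rank") "spearman" else "pearson"
    sp <- semipartial(cohort$nonverbal_iq, yv,
                      cbind(reading = composite, gender = cohort$gender),
                      method = meth)
    data.frame(predictor = "nonverbal_iq", outcome = oc,
               task = sub("_.*", "", oc), method = meth,
               estimate = sp$estimate, p_value = sp$p_value,
               normality_p = gate$p)
  })
  report <- do.call(rbind, c(rows, iq_rows))
  rownames(report) <- NULL
  list(report = report, pca = pca)
}
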