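#' Build a design matrix for modality x age analyses
#'
#' Assembles the mass-univariate design from per-observation metadata
#' (one row per subject x modality). Available terms:
#'
#' * `"modality"`: one indicator column per modality (cell means).
#' * `"age"`: mean-centred age (centred across observations).
#' * `"age2"`: square of the *centred* age, itself mean-centred
#'   (centring applied before squaring).
#' * `"sex"`: indicator for the second sex level.
#' * `"subject"`: one indicator per subject (subject-mean removal for
#'   paired modality contrasts).
#' * `"modality_age"`: modality x centred-age interaction columns.
#'
#' The matrix is checked for full column rank; a rank-deficient design
#' raises an error naming the collinear columns.
#'
#' @param metadata data.frame with columns `subject`, `modality`, and
#'   as needed `age`, `sex`.
#' @param terms Character vector of terms, in the vocabulary above.
#' @return Numeric matrix with named columns and attributes
#'   `modalities`, `terms`.
#' @export
build_design <- function(metadata,
                         terms = c("modality", "age", "age2", "sex")) {
  assert_that(all(c("subject", "modality") %in% names(metadata)),
              "metadata needs subject and modality columns")
  n <- nrow(metadata)
  cols <- list()
  modalities <- unique(as.character(metadata$modality))
  if ("modality" %in% terms) {
    # with subject indicators also present, cell-mean coding is singular:
    # use treatment coding (first modality as baseline)
    mm <- if ("subject" %in% terms) modalities[-1] else modalities
    for (m in mm)
      cols[[paste0("modality_", m)]] <- as.numeric(metadata$modality == m)
  }
  if (any(c("age", "age2", "modality_age") %in% terms)) {
    assert_that("age" %in% names(metadata), "metadata needs an age column")
    assert_that(is.numeric(metadata$age), "ages must be numeric")
    age_c <- metadata$age - mean(metadata$age)
  }
  if ("age" %in% terms) cols[["age_c"]] <- age_c
  if ("age2" %in% terms) cols[["age_c2"]] <- age_c^2 - mean(age_c^2)
  if ("sex" %in% terms) {
    assert_that("sex" %in% names(metadata), "metadata needs a sex column")
    lev <- sort(unique(as.character(metadata$sex)))
    if (length(lev) > 1)
      cols[[paste0("sex_", lev[2])]] <- as.numeric(metadata$sex == lev[2])
  }
  if ("subject" %in% terms) {
    for (s in unique(metadata$subject))
      cols[[paste0("subject_", s)]] <- as.numeric(metadata$subject == s)
  }
  if ("modality_age" %in% terms) {
    for (m in modalities[-1])  # first modality is the interaction baseline
      cols[[paste0("age_x_", m)]] <- age_c * (metadata$modality == m)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_invalid("design matrix is rank deficient; collinear columns: ",
                 paste(dep, collapse = ", "))
  }
  structure(X, modalities = modalities, terms = terms)
}

#' Fit a mass-univariate ordinary least-squares GLM
#'
#' Per-site OLS of a response matrix on a common design:
#' `beta = (X'X)^-1 X' y` for every site, residual variance with
#' `n - rank` degrees of freedom.
#'
#' @param design Design matrix from [build_design()] (or any full-rank
#'   numeric matrix).
#' @param response Numeric matrix, observations x sites (a vector is
#'   treated as a single site).
#' @return Object of class `glm_fit`: `beta` (coefficients x sites),
#'   `sigma2` (per site), `df`, `xtx_inv`, `design`, `n_sites`.
#' @export
fit_glm <- function(design, response) {
  X <- as.matrix(design)
  if (is.vector(response)) response <- matrix(response, ncol = 1)
  Y <- as.matrix(response)
  assert_that(nrow(Y) == nrow(X), "response rows must match design rows")
  r <- qr(X)$rank
  assert_that(nrow(X) > r, "need more observations than design rank")
  xtx_inv <- solve(crossprod(X))
  beta <- xtx_inv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - r
  sigma2 <- colSums(res^2) / df
  rownames(beta) <- colnames(X)
  # scale reference for the zero-residual-variance sentinel
  response_ms <- colMeans(Y^2)
  structure(list(beta = beta, sigma2 = sigma2, df = df,
                 xtx_inv = xtx_inv, design = X, n_sites = ncol(Y),
                 response_ms = response_ms),
            class = "glm_fit")
}

#' One-tailed t contrast on a fitted GLM
#'
#' For a contrast vector `c`, computes per site
#' `t = c'beta / sqrt(sigma2 c'(X'X)^-1 c)` and the one-tailed p value
#' `P(T > t)` (the direction of the test is supplied by the sign of the
#' contrast). Sites with zero residual variance are reported with an
#' infinite-t sentinel and flagged.
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Numeric vector (length = number of coefficients) or
#'   the name of a single coefficient.
#' @return data.frame with `estimate`, `t`, `p` (one-tailed), and
#'   logical `zero_variance` per site.
#' @export
glm_contrast <- function(fit, contrast) {
  if (is.character(contrast)) {
    assert_that(contrast %in% rownames(fit$beta),
                paste0("unknown coefficient '", contrast, "'"))
    cv <- as.numeric(rownames(fit$beta) == contrast)
  } else {
    cv <- as.numeric(contrast)
    assert_that(length(cv) == nrow(fit$beta),
                "contrast length must match the number of coefficients")
  }
  est <- drop(crossprod(cv, fit$beta))
  q <- drop(crossprod(cv, fit$xtx_inv %*% cv))
  zero_var <- fit$sigma2 <= .Machine$double.eps * pmax(fit$response_ms, 1e-300)
  se <- sqrt(fit$sigma2 * q)
  t <- ifelse(zero_var, ifelse(est == 0, 0, Inf * sign(est)), est / se)
  p <- ifelse(is.infinite(t), ifelse(t > 0, 0, 1),
              stats::pt(t, df = fit$df, lower.tail = FALSE))
  data.frame(estimate = est, t = t, p = p, zero_variance = zero_var)
}

#' Bonferroni multiple-comparison decisions
#'
#' Familywise error control by Bonferroni: reject site i iff
#' `p_i <= alpha / m`, with `m` the number of sites tested. A
#' conservative, exactly testable replacement for random-field-theory
#' familywise correction.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @param method Only `"bonferroni"`.
#' @param alpha Familywise error level.
#' @return data.frame with `p`, `p_adjusted` (via [stats::p.adjust()]),
#'   and logical `reject`.
#' @export
correct_multiple <- function(p, method = "bonferroni", alpha = 0.05) {
  method <- match.arg(method, "bonferroni")
  assert_that(all(p >= 0 & p <= 1), "p values must lie in [0, 1]")
  padj <- stats::p.adjust(p, method = method)
  data.frame(p = p, p_adjusted = padj, reject = padj <= alpha)
}
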