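#' Multivariate multiple regression of condition-wise HLM(alpha)
#'
#' Fits several outcome columns (by default the four condition-wise
#' HLM(alpha) values) on a shared regressor design (intercept always
#' included). The coefficient matrix is the column-wise least-squares
#' solution, so each outcome's coefficients, standard errors and t tests
#' coincide exactly with an independent univariate fit; the residual
#' covariance (cross-products divided by `n - k - 1`) and the inverse
#' design cross-product are retained for the multivariate tests.
#'
#' @param data Data frame with outcomes and regressors.
#' @param outcomes Character vector of outcome column names (>= 1).
#' @param regressors Character vector of regressor column names; may be
#'   empty for an intercept-only (null) model.
#' @return Object of class `hemilat_mmr`: list with `B` ((k+1) x p
#'   coefficient matrix), `se`, `tstat`, `pval` (same shape), `sigma`
#'   (p x p residual covariance), `xtx_inv`, `residuals`, `n`, `k`,
#'   `outcomes`, `regressors`.
#' @export
#' @examples
#' d <- tibble::as_tibble(as.data.frame(matrix(rnorm(60), 10)))
#' names(d) <- c("y1", "y2", "y3", "x1", "x2", "x3")
#' fit <- fit_mmr(d, c("y1", "y2", "y3"), c("x1", "x2"))
#' tidy(fit)
fit_mmr <- function(data, outcomes, regressors = character()) {
  stopifnot(is.data.frame(data), length(outcomes) >= 1,
            all(c(outcomes, regressors) %in% names(data)))
  Y <- as.matrix(data[, outcomes, drop = FALSE])
  n <- nrow(Y)
  k <- length(regressors)
  if (n <= k + 1) {
    abort(sprintf("Need n > k + 1 observations (n = %d, k = %d).", n, k))
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, regressors, drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("Design matrix is rank deficient.")
  B <- qr.coef(qx, Y)
  res <- Y - X %*% B
  ve <- n - k - 1
  sigma <- crossprod(res) / ve
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(outer(diag(xtx_inv), diag(sigma)))
  dimnames(se) <- dimnames(B)
  tstat <- B / se
  pval <- 2 * pt(abs(tstat), df = ve, lower.tail = FALSE)
  structure(list(B = B, se = se, tstat = tstat, pval = pval,
                 sigma = sigma, xtx_inv = xtx_inv, residuals = res,
                 n = n, k = k, outcomes = outcomes,
                 regressors = regressors),
            class = "hemilat_mmr")
}

#' @export
print.hemilat_mmr <- function(x, ...) {
  cat(sprintf("<hemilat_mmr> %d outcomes ~ %s  (n = %d)\n",
              length(x$outcomes),
              if (x$k == 0) "1" else paste(x$regressors, collapse = " + "),
              x$n))
  print(round(x$B, 4))
  invisible(x)
}

#' @rdname fit_mmr
#' @param x A `hemilat_mmr` object.
#' @param ... Unused.
#' @export
tidy.hemilat_mmr <- function(x, ...) {
  tibble::tibble(
    outcome = rep(x$outcomes, each = nrow(x$B)),
    term = rep(rownames(x$B), times = length(x$outcomes)),
    estimate = as.vector(x$B),
    std.error = as.vector(x$se),
    statistic = as.vector(x$tstat),
    p.value = as.vector(x$pval)
  )
}

#' @rdname fit_mmr
#' @export
glance.hemilat_mmr <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, n_outcomes = length(x$outcomes),
                 df.residual = x$n - x$k - 1,
                 det.sigma = det(x$sigma))
}

#' Test one regressor across all outcomes (Hotelling T-squared)
#'
#' Tests whether a regressor's coefficient row is zero simultaneously for
#' all outcomes: `T^2 = b_j' S^-1 b_j / c_jj`, with `S` the residual
#' covariance and `c_jj` the regressor's diagonal entry of the inverse
#' design cross-product. The statistic is converted to an F with degrees
#' of freedom `(p, ve - p + 1)` via `F = (ve - p + 1) / (ve p) T^2`, where
#' `p` is the number of outcomes and `ve = n - k - 1` (for n = 33, k = 3
#' and four outcomes: F on (4, 26)).
#'
#' @param fit A `hemilat_mmr`.
#' @param term Regressor name (not the intercept).
#' @return One-row tibble: `term`, `t2`, `statistic` (F), `df1`, `df2`,
#'   `p.value`.
#' @export
test_regressor_across_outcomes <- function(fit, term) {
  stopifnot(inherits(fit, "hemilat_mmr"))
  if (!term %in% fit$regressors) {
    abort(sprintf("`%s` is not a non-intercept regressor of the fit.", term))
  }
  p <- length(fit$outcomes)
  ve <- fit$n - fit$k - 1
  if (ve - p + 1 <= 0) abort("Too few residual df for the multivariate test.")
  b <- fit$B[term, ]
  sinv <- tryCatch(solve(fit$sigma),
                   error = function(e) {
                     abort("Residual covariance is singular.")
                   })
  t2 <- drop(t(b) %*% sinv %*% b) / fit$xtx_inv[term, term]
  fstat <- (ve - p + 1) / (ve * p) * t2
  tibble::tibble(term = term, t2 = t2, statistic = fstat,
                 df1 = p, df2 = ve - p + 1,
                 p.value = pf(fstat, p, ve - p + 1, lower.tail = FALSE))
}

#' Compare nested multivariate regressions (Wilks' Lambda)
#'
#' Likelihood-ratio comparison of two multivariate fits on the same
#' outcomes and subjects, where the reduced design's regressors are a
#' subset of the full design's. `Lambda = det(E_full) / det(E_reduced)`
#' from the residual cross-product matrices, converted to an F statistic
#' by Rao's approximation; the reported degrees of freedom follow that
#' approximation (`df1 = p q` with `q` the number of dropped regressors).
#'
#' @param full,reduced `hemilat_mmr` fits.
#' @return One-row tibble: `wilks`, `statistic` (F), `df1`, `df2`,
#'   `p.value`.
#' @export
compare_nested_mmr <- function(full, reduced) {
  stopifnot(inherits(full, "hemilat_mmr"), inherits(reduced, "hemilat_mmr"))
  if (!identical(full$outcomes, reduced$outcomes) ||
      full$n != reduced$n) {
    abort("Fits must share the same outcomes and subjects.")
  }
  if (!all(reduced$regressors %in% full$regressors)) {
    abort("The reduced design must be nested within the full design.")
  }
  q <- full$k - reduced$k
  p <- length(full$outcomes)
  ve <- full$n - full$k - 1
  e_full <- crossprod(full$residuals)
  e_red <- crossprod(reduced$residuals)
  lambda <- det(e_full) / det(e_red)
  if (q == 0) {
    return(tibble::tibble(wilks = 1, statistic = 0, df1 = 0, df2 = ve,
                          p.value = 1))
  }
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- ve + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * tt - (p * q - 2) / 2
  if (df2 <= 0) {
    abort("Too few residual df for Rao's F approximation.")
  }
  lam_t <- lambda^(1 / tt)
  fstat <- (1 - lam_t) / lam_t * df2 / df1
  tibble::tibble(wilks = lambda, statistic = fstat, df1 = df1, df2 = df2,
                 p.value = pf(fstat, df1, df2, lower.tail = FALSE))
}

#' Full / reduced / null model comparisons for the condition-wise analysis
#'
#' Convenience driver reproducing the three standard comparisons: (a) the
#' full model with all seven structures against the reduced model without
#' the structures of interest, and (b) the model containing only the
#' structures of interest against the intercept-only null, plus the
#' per-regressor Hotelling tests on the model of interest.
#'
#' @param data Data frame with the four `hlm_c*` outcomes and all LV
#'   columns.
#' @param outcomes Outcome columns.
#' @param key_regressors The structures of interest.
#' @param all_regressors All candidate structures.
#' @return A list: `fit` (`hemilat_mmr` on the key regressors),
#'   `full_vs_reduced`, `key_vs_null` (tibbles from
#'   [compare_nested_mmr()]), `per_regressor` (tibble of Hotelling tests).
#' @export
mmr_condition_analysis <- function(data,
                                   outcomes = paste0("hlm_c", 1:4),
                                   key_regressors = c("Th", "CN", "GP"),
                                   all_regressors = subcortical_structures()) {
  fit_key <- fit_mmr(data, outcomes, key_regressors)
  fit_full <- fit_mmr(data, outcomes, all_regressors)
  fit_reduced <- fit_mmr(data, outcomes,
                         setdiff(all_regressors, key_regressors))
  fit_null <- fit_mmr(data, outcomes, character())
  per_reg <- purrr::map_dfr(key_regressors, function(r) {
    test_regressor_across_outcomes(fit_key, r)
  })
  list(fit = fit_key,
       full_vs_reduced = compare_nested_mmr(fit_full, fit_reduced),
       key_vs_null = compare_nested_mmr(fit_key, fit_null),
       per_regressor = per_reg)
}
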