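#' Ordinary least-squares fit with full inference report
#'
#' Fits `response ~ regressors` (intercept always included) by least
#' squares and packages coefficients, standard errors, t statistics on
#' `n - k - 1` residual degrees of freedom, the overall F test against the
#' intercept-only model, R^2 / adjusted R^2, and Gaussian-likelihood AIC /
#' BIC (counting the intercept and the residual variance among the
#' parameters, as `stats::AIC()` does).
#'
#' @param data A data frame containing the response and regressors.
#' @param response Name of the response column.
#' @param regressors Character vector of regressor column names.
#' @return An object of class `hemilat_ols` wrapping the underlying
#'   [stats::lm] fit; use [tidy()] for the coefficient table and
#'   [glance()] for model-level statistics.
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:6, y = 3 + 2 * (1:6))
#' glance(fit_ols(d, "y", "x"))$r.squared  # 1
fit_ols <- function(data, response, regressors) {
  stopifnot(is.data.frame(data), all(c(response, regressors) %in% names(data)))
  n <- nrow(data)
  k <- length(regressors)
  if (n <= k + 1) {
    abort(sprintf("Need n > k + 1 observations (n = %d, k = %d).", n, k))
  }
  f <- stats::reformulate(regressors, response = response)
  fit <- lm(f, data = data)
  if (fit$rank < k + 1) {
    abort("Design matrix is rank deficient (collinear regressors).")
  }
  structure(list(fit = fit, response = response, regressors = regressors,
                 n = n, k = k),
            class = "hemilat_ols")
}

#' @export
print.hemilat_ols <- function(x, ...) {
  cat(sprintf("<hemilat_ols> %s ~ %s  (n = %d)\n", x$response,
              paste(x$regressors, collapse = " + "), x$n))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_ols
#' @param x A `hemilat_ols` object.
#' @param ... Unused.
#' @export
tidy.hemilat_ols <- function(x, ...) {
  ct <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(ct), estimate = ct[, 1],
                 std.error = ct[, 2], statistic = ct[, 3],
                 p.value = ct[, 4])
}

#' @rdname fit_ols
#' @export
glance.hemilat_ols <- function(x, ...) {
  s <- summary(x$fit)
  fstat <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(fstat[1]),
    p.value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    df = unname(fstat[2]),
    df.residual = x$fit$df.residual,
    logLik = as.numeric(logLik(x$fit)),
    AIC = AIC(x$fit),
    BIC = BIC(x$fit),
    nobs = x$n
  )
}

#' @export
residuals.hemilat_ols <- function(object, ...) resid(object$fit)

#' @export
coef.hemilat_ols <- function(object, ...) coef(object$fit)

# Fast information criteria for one regressor subset, matching stats::AIC
# on the equivalent lm fit (Gaussian log-likelihood, k + 2 parameters).
subset_ic <- function(X, y, cols, n) {
  Xs <- cbind(1, X[, cols, drop = FALSE])
  z <- stats::.lm.fit(Xs, y)
  if (z$rank < ncol(Xs)) abort("Rank-deficient subset design.")
  rss <- sum(z$residuals^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  k <- length(cols)
  tss <- sum((y - mean(y))^2)
  c(aic = -2 * ll + 2 * (k + 2),
    bic = -2 * ll + log(n) * (k + 2),
    loglik = ll,
    r.squared = 1 - rss / tss,
    adj.r.squared = 1 - (rss / (n - k - 1)) / (tss / (n - 1)))
}

#' Exhaustive information-criterion search over regressor subsets
#'
#' Fits an intercept-plus-subset linear model for every non-empty subset
#' of the candidate regressors (`2^p - 1` models; 127 for the seven
#' subcortical structures) and ranks them by AIC, reporting BIC alongside
#' for confirmation. The winning model is refit with [fit_ols()] for full
#' inference.
#'
#' @param data Data frame with the response and all candidate regressors.
#' @param response Name of the response column (default `"hlm"`).
#' @param candidates Candidate regressor names; default the seven
#'   structure labels.
#' @param criterion `"aic"` (default) or `"bic"`: which criterion picks
#'   the winner.
#' @return An object of class `hemilat_search`: list with `table` (tibble
#'   of all subsets with `subset`, `k`, `aic`, `bic`, `loglik`,
#'   `r.squared`, `adj.r.squared`, sorted by the chosen criterion),
#'   `winner` (character vector of regressors), `winner_bic`, `fit`
#'   (the refit `hemilat_ols`), `criterion`.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 40, seed = 2)
#' gv <- generate_volumes(cfg)
#' d <- draw_hlm_targets(gv$lv, cfg, seed = 5) |>
#'   dplyr::left_join(gv$lv, by = "subject_id")
#' sr <- model_search(d)
#' sr$winner
model_search <- function(data, response = "hlm",
                         candidates = subcortical_structures(),
                         criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  stopifnot(all(c(response, candidates) %in% names(data)))
  X <- as.matrix(data[, candidates, drop = FALSE])
  y <- data[[response]]
  n <- length(y)
  p <- length(candidates)
  if (n <= p + 1) abort("Need more observations than the largest subset + 1.")
  zerovar <- apply(X, 2, var) == 0
  if (any(zerovar)) {
    abort(sprintf("Constant candidate regressor(s): %s",
                  paste(candidates[zerovar], collapse = ", ")))
  }
  subsets <- unlist(lapply(seq_len(p), function(k) {
    asplit(combn(p, k), 2)
  }), recursive = FALSE)
  stats_mat <- t(vapply(subsets, function(cols) subset_ic(X, y, cols, n),
                        numeric(5)))
  tab <- tibble::tibble(
    subset = vapply(subsets, function(cols) {
      paste(candidates[cols], collapse = "+")
    }, character(1)),
    k = lengths(subsets)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(stats_mat))
  ord <- order(tab[[criterion]])
  tab <- tab[ord, ]
  winner <- candidates[subsets[[ord[1]]]]
  winner_bic <- candidates[subsets[[which.min(stats_mat[, "bic"])]]]
  fit <- fit_ols(data, response, winner)
  structure(list(table = tab, winner = winner, winner_bic = winner_bic,
                 fit = fit, criterion = criterion, response = response),
            class = "hemilat_search")
}

#' @export
print.hemilat_search <- function(x, ...) {
  cat(sprintf("<hemilat_search> %d models; %s winner: %s\n",
              nrow(x$table), toupper(x$criterion),
              paste(x$winner, collapse = " + ")))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' @rdname model_search
#' @param x A `hemilat_search` object.
#' @param ... Unused.
#' @export
tidy.hemilat_search <- function(x, ...) x$table

#' @rdname model_search
#' @export
glance.hemilat_search <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(winner = paste(x$winner, collapse = "+"),
                   winner_bic = paste(x$winner_bic, collapse = "+"),
                   n_models = nrow(x$table),
                   criterion = x$criterion),
    glance(x$fit)
  )
}

#' Variance inflation factors
#'
#' For each regressor `j`, `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes
#' from regressing column `j` on the remaining regressors (with
#' intercept). Values near 1 indicate independent predictors; values above
#' 10 flag problematic collinearity.
#'
#' @param data Data frame containing the regressors.
#' @param regressors Character vector of at least two column names.
#' @return A tibble with columns `term` and `vif`.
#' @export
vif <- function(data, regressors) {
  stopifnot(length(regressors) >= 2,
            all(regressors %in% names(data)))
  out <- purrr::map_dfr(regressors, function(r) {
    others <- setdiff(regressors, r)
    f <- stats::reformulate(others, response = r)
    r2 <- summary(lm(f, data = data))$r.squared
    if (1 - r2 < 1e-12) {
      abort(sprintf("Regressor `%s` is exactly collinear with the others.", r))
    }
    tibble::tibble(term = r, vif = 1 / (1 - r2))
  })
  out
}

#' One-sample t test against zero
#'
#' Tests whether the mean of a sample differs from zero:
#' `t = mean / (sd / sqrt(n))` on `n - 1` degrees of freedom, two-sided.
#' Used to assess group-level lateralization of LV and HLM(alpha)
#' distributions.
#'
#' @param values Numeric vector, `n >= 3`, non-constant.
#' @return A one-row tibble: `estimate`, `statistic`, `df`, `p.value`,
#'   `conf.low`, `conf.high`.
#' @export
one_sample_test <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) abort("Need at least 3 observations.")
  if (sd(values) == 0) abort("Zero variance: the t statistic is undefined.")
  tt <- t.test(values, mu = 0)
  tibble::tibble(estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p.value = tt$p.value,
                 conf.low = tt$conf.int[1],
                 conf.high = tt$conf.int[2])
}

#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector with 3 to 5000 observations.
#' @return A one-row tibble with `statistic` (W) and `p.value`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000) {
    abort("The Shapiro-Wilk test needs between 3 and 5000 observations.")
  }
  sw <- shapiro.test(values)
  tibble::tibble(statistic = unname(sw$statistic), p.value = sw$p.value)
}
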