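# Random-intercept Gaussian mixed model of food-loss percentage, fitted by
# maximum likelihood. The model for one stratum (commodity group or
# supply-chain stage) is
#
#   flp_{c,t} = b0 + b1 * developing_c + b2 * (t - 2000) + u_c + e_{c,t}
#
# with u_c ~ N(0, sigma_u^2) per country and e ~ N(0, sigma_e^2). The
# likelihood is profiled over the variance ratio theta = sigma_u^2 /
# sigma_e^2: for fixed theta the GLS estimate of beta and the ML estimate of
# sigma_e^2 are closed-form, leaving a one-dimensional optimization in
# log(theta) solved by Brent search over several spread brackets, with the
# theta = 0 boundary checked explicitly.

# sufficient statistics of the profiled deviance at a given theta;
# exploits the block structure: V_c^{-1} = I - theta/(1 + n_c theta) J
profiled_gls <- function(X, y, group, theta) {
  p <- ncol(X)
  A <- matrix(0, p, p)
  b <- numeric(p)
  yy <- 0
  logdet <- 0
  for (g in unique(group)) {
    idx <- which(group == g)
    Xg <- X[idx, , drop = FALSE]
    yg <- y[idx]
    n_g <- length(idx)
    shrink <- theta / (1 + n_g * theta)
    sx <- colSums(Xg)
    sy <- sum(yg)
    A <- A + crossprod(Xg) - shrink * tcrossprod(sx)
    b <- b + crossprod(Xg, yg) - shrink * sx * sy
    yy <- yy + sum(yg^2) - shrink * sy^2
    logdet <- logdet + log1p(n_g * theta)
  }
  beta <- solve(A, b)
  rss <- max(yy - sum(b * beta), 0)
  list(beta = drop(beta), A = A, rss = rss, logdet = logdet)
}

profiled_deviance <- function(X, y, group, theta) {
  n <- length(y)
  gls <- profiled_gls(X, y, group, theta)
  if (gls$rss <= 0) return(-Inf)
  n * (log(2 * pi * gls$rss / n) + 1) + gls$logdet
}

#' Fit the random-intercept food-loss model by maximum likelihood
#'
#' Fits `flp ~ developing + I(year - center) + (1 | country)` with Gaussian
#' errors by ML (profiled likelihood over the variance ratio; see the
#' package vignette). Wald t statistics use the ML variance estimate;
#' p-values use the normal approximation by default, with a residual-df t
#' variant available. A fit whose country variance lands on the zero
#' boundary is returned and flagged, not errored.
#'
#' @param data data.frame with columns `flp` (0-100), `country`, `year`,
#'   and a development indicator: either `developing` (0/1) or a `label`
#'   column of `"developed"`/`"developing"` (developed is the reference
#'   category). Rows with missing values in any model variable are removed
#'   listwise (counted in the result).
#' @param center centering constant for the year covariate (default 2000).
#' @param p_method `"normal"` (default) or `"residual"` (t with n - p df).
#' @param force_sigma_u_zero if `TRUE`, fixes the country variance at zero,
#'   which reduces the model to ordinary least squares (reported with the
#'   usual unbiased residual variance, exactly as `lm()` would).
#' @param stratum optional stratum id stored in the result.
#' @return Object of class `flp_lmm`: `coefficients` (data.frame with
#'   `estimate, se, t, p` for `(Intercept)`, `developing`,
#'   `year_centered`), `sigma_u`, `sigma_e`, `theta`, `logLik`, `n`,
#'   `n_countries`, `n_dropped_na`, `converged`, `boundary`, `r2_marginal`,
#'   `r2_conditional`, `center`, `vcov`.
#' @export
fit_random_intercept_lmm <- function(data, center = 2000,
                                     p_method = c("normal", "residual"),
                                     force_sigma_u_zero = FALSE,
                                     stratum = NA_character_) {
  p_method <- match.arg(p_method)
  assert_columns(data, c("flp", "country", "year"), "model data")
  if (!"developing" %in% names(data)) {
    if ("label" %in% names(data)) {
      data$developing <- as.numeric(data$label == "developing")
    } else {
      stop("model data needs a 'developing' (0/1) or 'label' column",
           call. = FALSE)
    }
  }
  keep <- stats::complete.cases(data[, c("flp", "country", "year",
                                         "developing")])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  group <- as.character(d$country)
  n_countries <- length(unique(group))
  if (!force_sigma_u_zero && n_countries < 2L) {
    stop("a random country intercept is unidentifiable with a single ",
         "country", call. = FALSE)
  }
  if (n < 4L) stop("too few observations to fit the model", call. = FALSE)

  X <- cbind("(Intercept)" = 1, developing = d$developing,
             year_centered = d$year - center)
  y <- d$flp
  coef_names <- colnames(X)
  # drop constant non-intercept columns (e.g. a single development group)
  keep_col <- c(TRUE, vapply(2:ncol(X), function(j) stats::sd(X[, j]) > 0,
                             logical(1)))
  Xf <- X[, keep_col, drop = FALSE]
  p <- ncol(Xf)

  if (force_sigma_u_zero) {
    fit0 <- profiled_gls(Xf, y, group, 0)
    sigma2_ols <- fit0$rss / (n - p)
    vc <- sigma2_ols * solve(fit0$A)
    se <- sqrt(diag(vc))
    theta_hat <- 0
    sigma_e <- sqrt(sigma2_ols)
    sigma_u <- 0
    logLik <- -0.5 * profiled_deviance(Xf, y, group, 0)
    boundary <- TRUE
    converged <- TRUE
    beta <- fit0$beta
  } else {
    dev0 <- profiled_deviance(Xf, y, group, 0)
    if (!is.finite(dev0)) {
      # degenerate noiseless data: exact fit, both variances at zero
      fit0 <- profiled_gls(Xf, y, group, 0)
      return(build_lmm_fit(fit0$beta, rep(0, p), coef_names,
                           sigma_u = 0, sigma_e = 0, theta = 0,
                           logLik = Inf, n = n, n_countries = n_countries,
                           n_dropped = n_dropped, converged = TRUE,
                           boundary = TRUE, X = Xf, vcov = matrix(0, p, p),
                           center = center, p_method = p_method,
                           stratum = stratum))
    }
    brackets <- list(c(-20, -4), c(-6, 6), c(4, 20))
    opts <- lapply(brackets, function(br) {
      stats::optimize(function(lt) profiled_deviance(Xf, y, group, exp(lt)),
                      interval = br, tol = 1e-10)
    })
    best <- opts[[which.min(vapply(opts, `[[`, numeric(1), "objective"))]]
    if (dev0 <= best$objective) {
      theta_hat <- 0
      dev_hat <- dev0
      boundary <- TRUE
    } else {
      theta_hat <- exp(best$minimum)
      dev_hat <- best$objective
      boundary <- theta_hat < 1e-8
    }
    fit <- profiled_gls(Xf, y, group, theta_hat)
    sigma_e2 <- fit$rss / n
    sigma_e <- sqrt(sigma_e2)
    sigma_u <- sqrt(theta_hat * sigma_e2)
    vc <- sigma_e2 * solve(fit$A)
    se <- sqrt(diag(vc))
    logLik <- -0.5 * dev_hat
    converged <- TRUE
    beta <- fit$beta
  }

  build_lmm_fit(beta, se, coef_names, sigma_u, sigma_e,
                theta = if (force_sigma_u_zero) 0 else theta_hat,
                logLik = logLik, n = n, n_countries = n_countries,
                n_dropped = n_dropped, converged = converged,
                boundary = if (force_sigma_u_zero) TRUE else boundary,
                X = Xf, vcov = vc, center = center, p_method = p_method,
                stratum = stratum)
}

build_lmm_fit <- function(beta, se, coef_names, sigma_u, sigma_e,
                          theta, logLik, n, n_countries, n_dropped,
                          converged, boundary, X, vcov, center, p_method,
                          stratum) {
  p <- length(beta)
  t_val <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  p_val <- switch(p_method,
                  normal = 2 * stats::pnorm(-abs(t_val)),
                  residual = 2 * stats::pt(-abs(t_val), df = max(n - p, 1)))
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                      t = t_val, p = p_val, row.names = NULL,
                      stringsAsFactors = FALSE)
  # report dropped (constant) terms as NA rows so the table shape is stable
  missing_terms <- setdiff(coef_names, coefs$term)
  if (length(missing_terms) > 0L) {
    coefs <- rbind(coefs, data.frame(term = missing_terms, estimate = NA_real_,
                                     se = NA_real_, t = NA_real_, p = NA_real_,
                                     stringsAsFactors = FALSE))
    coefs <- coefs[match(coef_names, coefs$term), ]
    rownames(coefs) <- NULL
  }
  fitted_fixed <- drop(X %*% beta)
  fit <- list(coefficients = coefs, sigma_u = sigma_u, sigma_e = sigma_e,
              theta = theta, logLik = logLik, n = n,
              n_countries = n_countries, n_dropped_na = n_dropped,
              converged = converged, boundary = boundary,
              fitted_fixed = fitted_fixed, vcov = vcov, center = center,
              p_method = p_method, stratum = stratum)
  class(fit) <- "flp_lmm"
  r2 <- tryCatch(r2_nakagawa(fit), error = function(e) c(NA_real_, NA_real_))
  fit$r2_marginal <- r2[[1]]
  fit$r2_conditional <- r2[[2]]
  fit
}

#' @export
print.flp_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (ML)%s\n",
              if (!is.na(x$stratum)) paste0(" - ", x$stratum) else ""))
  cat(sprintf("  n = %d observations, %d countries%s\n", x$n, x$n_countries,
              if (x$boundary) " [variance boundary]" else ""))
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat(sprintf("  sigma_u = %.4f, sigma_e = %.4f, logLik = %.4f\n",
              x$sigma_u, x$sigma_e, x$logLik))
  cat(sprintf("  marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Marginal and conditional R-squared for a random-intercept fit
#'
#' Variance-components decomposition in the Nakagawa-Schielzeth style for a
#' Gaussian model with identity link: with `var_f` the variance of the
#' fixed-effect linear predictor over the estimation sample,
#' marginal R2 = `var_f / (var_f + sigma_u^2 + sigma_e^2)` and
#' conditional R2 = `(var_f + sigma_u^2) / (var_f + sigma_u^2 + sigma_e^2)`.
#'
#' @param fit an [fit_random_intercept_lmm()] object.
#' @return named numeric vector `c(marginal, conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "flp_lmm"))
  mu <- fit$fitted_fixed
  var_f <- mean((mu - mean(mu))^2)
  total <- var_f + fit$sigma_u^2 + fit$sigma_e^2
  if (total <= 0) stop("zero total variance; R-squared undefined",
                       call. = FALSE)
  c(marginal = var_f / total,
    conditional = (var_f + fit$sigma_u^2) / total)
}

#' Fit the model separately for every stratum
#'
#' One random-intercept fit per commodity group or per activity group.
#' Strata that cannot be fit (a single country, too few observations) are
#' flagged in the output and do not abort the batch.
#'
#' @param records screened FLP records with group columns filled.
#' @param labels named vector country -> `"developed"`/`"developing"`.
#' @param by `"commodity"` or `"activity"`.
#' @param ... passed to [fit_random_intercept_lmm()].
#' @return Object of class `flp_lmm_table`: `table` (one row per stratum
#'   shaped like a per-group results table: n, countries, random-intercept
#'   SD, the three coefficients with SE/t/p, marginal and conditional R2,
#'   fit status) and `fits` (named list of `flp_lmm` objects or `NULL`).
#' @export
fit_all_strata <- function(records, labels, by = c("commodity", "activity"),
                           ...) {
  by <- match.arg(by)
  col <- paste0(by, "_group")
  assert_columns(records, c("country", "year", "flp", col), "records")
  rec <- records[!is.na(records[[col]]) & !is.na(records$flp), , drop = FALSE]
  rec$developing <- as.numeric(labels[rec$country] == "developing")
  if (anyNA(rec$developing)) {
    missing <- sort(unique(rec$country[is.na(rec$developing)]))
    stop("no development label for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  strata <- sort(unique(rec[[col]]))
  fits <- stats::setNames(vector("list", length(strata)), strata)
  rows <- lapply(strata, function(s) {
    d <- rec[rec[[col]] == s, , drop = FALSE]
    fit <- tryCatch(fit_random_intercept_lmm(d, stratum = s, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(stratum = s, n_obs = nrow(d),
                        n_countries = length(unique(d$country)),
                        sigma_u = NA_real_, sigma_e = NA_real_,
                        beta0 = NA_real_, beta1 = NA_real_, beta2 = NA_real_,
                        se0 = NA_real_, se1 = NA_real_, se2 = NA_real_,
                        t1 = NA_real_, t2 = NA_real_,
                        p1 = NA_real_, p2 = NA_real_,
                        r2_marginal = NA_real_, r2_conditional = NA_real_,
                        fitted = FALSE, note = conditionMessage(fit),
                        stringsAsFactors = FALSE))
    }
    fits[[s]] <<- fit
    cf <- fit$coefficients
    grab <- function(term, what) cf[[what]][cf$term == term]
    data.frame(stratum = s, n_obs = fit$n, n_countries = fit$n_countries,
               sigma_u = fit$sigma_u, sigma_e = fit$sigma_e,
               beta0 = grab("(Intercept)", "estimate"),
               beta1 = grab("developing", "estimate"),
               beta2 = grab("year_centered", "estimate"),
               se0 = grab("(Intercept)", "se"),
               se1 = grab("developing", "se"),
               se2 = grab("year_centered", "se"),
               t1 = grab("developing", "t"), t2 = grab("year_centered", "t"),
               p1 = grab("developing", "p"), p2 = grab("year_centered", "p"),
               r2_marginal = fit$r2_marginal,
               r2_conditional = fit$r2_conditional,
               fitted = TRUE,
               note = if (fit$boundary) "variance boundary" else "",
               stringsAsFactors = FALSE)
  })
  out <- list(table = do.call(rbind, rows), fits = fits, by = by)
  class(out) <- "flp_lmm_table"
  out
}

#' @export
print.flp_lmm_table <- function(x, ...) {
  cat(sprintf("Random-intercept fits per %s group\n", x$by))
  print(x$table[, c("stratum", "n_obs", "n_countries", "sigma_u", "beta1",
                    "se1", "p1", "beta2", "se2", "p2", "r2_marginal",
                    "r2_conditional", "fitted")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Hypothesis decisions per stratum
#'
#' Two-sided Wald tests at level `alpha` on the development contrast
#' (is mean FLP different between developing and developed countries?) and
#' on the year trend (does FLP change over time?), with the direction of
#' any significant effect.
#'
#' @param fits an [fit_all_strata()] result.
#' @param alpha test level (default 0.05).
#' @return data.frame with one row per fitted stratum: decisions and
#'   directions for both hypotheses, with the underlying estimates and
#'   p-values.
#' @export
hypothesis_report <- function(fits, alpha = 0.05) {
  stopifnot(inherits(fits, "flp_lmm_table"), alpha > 0, alpha < 1)
  tab <- fits$table[fits$table$fitted, , drop = FALSE]
  data.frame(
    stratum = tab$stratum,
    beta_development = tab$beta1, p_development = tab$p1,
    reject_development_null = !is.na(tab$p1) & tab$p1 < alpha,
    direction_development = ifelse(is.na(tab$p1) | tab$p1 >= alpha, "none",
                                   ifelse(tab$beta1 < 0, "developing lower",
                                          "developing higher")),
    beta_year = tab$beta2, p_year = tab$p2,
    reject_year_null = !is.na(tab$p2) & tab$p2 < alpha,
    direction_year = ifelse(is.na(tab$p2) | tab$p2 >= alpha, "none",
                            ifelse(tab$beta2 < 0, "decreasing", "increasing")),
    stringsAsFactors = FALSE)
}
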