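# Environment-length stage: Pearson screening, random-intercept LMM with
# Wald-t inference, and model ranking.

#' Pearson correlation with test
#'
#' Product-moment correlation after pairwise deletion of missing values,
#' with the two-sided t test on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `r`, `t`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       p = ct$p.value, n = length(x))
}

#' Fixed-effects formula presets for the length model
#'
#' Model 5 is the full specification: stratum, SIC, SST, Chla and the
#' SST x Chla interaction; the others are the nested candidates used for
#' ranking.
#'
#' @param model Integer 1-5.
#' @return A one-sided fixed-effects formula for [fit_lmm].
#' @export
lmm_formula <- function(model = 5) {
  switch(as.character(model),
    "1" = ~ stratum,
    "2" = ~ stratum + sic,
    "3" = ~ stratum + sic + sst,
    "4" = ~ stratum + sic + sst + chla,
    "5" = ~ stratum + sic + sst + chla + sst:chla,
    stop("unknown model preset: ", model, call. = FALSE))
}

#' Random-intercept linear mixed model for mean length
#'
#' Fits `mean_length ~ fixed + (1 | year)` by REML, the standard treatment
#' for interannual variability in an unbalanced stratum x year x month panel
#' (missing cells need no imputation). Wald-t confidence intervals and
#' p-values use the residual degrees of freedom `n - p` — a documented
#' approximation. A year-level variance estimated at the boundary (0) is
#' flagged, not an error. With as many year levels as rows the year and
#' residual variances are not separable and the fit aborts with a classed
#' error (`krillspr_lmm_nonidentifiable`).
#'
#' @param panel Tibble with `mean_length`, `stratum`, `year` and the
#'   covariates named in `fixed` (`sic`, `sst`, `chla`).
#' @param fixed One-sided fixed-effects formula; default [lmm_formula]`(5)`.
#' @param name Label used in ranking tables.
#' @return An object of class `lmm_fit`: `beta` tibble (estimate, se, df,
#'   ci_low, ci_high, t, p), `var_year`, `var_resid`, `var_year_boundary`,
#'   `loglik`, `aic`, `bic`, `r2`, `rmse`, `n`, and the underlying `lmer`
#'   fit.
#' @export
fit_lmm <- function(panel, fixed = lmm_formula(5), name = "model") {
  stopifnot(is.data.frame(panel), "mean_length" %in% names(panel))
  if (length(unique(panel$year)) < 2)
    stop("need >= 2 distinct years", call. = FALSE)
  if (length(unique(panel$year)) >= nrow(panel))
    stop(structure(class = c("krillspr_lmm_nonidentifiable", "error",
                             "condition"),
                   list(message = paste("one observation per year: year and",
                                        "residual variances are not",
                                        "separable"),
                        call = sys.call())))
  fml <- stats::as.formula(paste("mean_length ~",
                                 paste(deparse(fixed[[2]]), collapse = ""),
                                 "+ (1 | year)"))
  # full-rank check on the fixed-effects design
  X <- stats::model.matrix(fixed, data = panel)
  if (qr(X)$rank < ncol(X)) {
    stop("singular fixed-effects design; aliased columns: ",
         paste(colnames(X)[-seq_len(qr(X)$rank)], collapse = ", "),
         call. = FALSE)
  }
  fit <- lme4::lmer(fml, data = panel, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n <- stats::nobs(fit)
  p <- length(beta)
  df <- n - p
  tval <- beta / se
  crit <- stats::qt(0.975, df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_year <- vc$vcov[vc$grp == "year"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  resid_fit <- stats::resid(fit)
  fitted_v <- stats::fitted(fit)
  obs <- stats::model.response(stats::model.frame(fit))
  ml <- lme4::refitML(fit) # AIC/BIC compare fixed effects, so use ML
  structure(
    list(
      name = name, formula = fml,
      beta = tibble::tibble(
        term = names(beta), estimate = unname(beta), se = se, df = df,
        ci_low = unname(beta - crit * se), ci_high = unname(beta + crit * se),
        t = unname(tval), p = unname(2 * stats::pt(-abs(tval), df))),
      var_year = var_year, var_resid = var_resid,
      var_year_boundary = var_year < 1e-10,
      loglik = as.numeric(stats::logLik(fit)),
      aic = stats::AIC(ml), bic = stats::BIC(ml),
      r2 = stats::cor(fitted_v, obs)^2,
      rmse = sqrt(mean(resid_fit^2)),
      n = n, fit = fit),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM", paste0("(", x$name, "):"), "n =", x$n,
      "| var(year) =", signif(x$var_year, 4),
      "| var(resid) =", signif(x$var_resid, 4),
      if (x$var_year_boundary) "[year variance at boundary]", "\n")
  print(x$beta)
  invisible(x)
}

#' Rank candidate models
#'
#' @param fits List of [fit_lmm] objects on the same response rows.
#' @return Tibble sorted by AIC (ties by BIC) with `rank`, `name`, `aic`,
#'   `bic`, `rmse`, `r2`, `loglik`.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1)
    stop("fits are not comparable: differing row sets", call. = FALSE)
  tab <- dplyr::bind_rows(lapply(fits, function(f) tibble::tibble(
    name = f$name, aic = f$aic, bic = f$bic, rmse = f$rmse, r2 = f$r2,
    loglik = f$loglik)))
  tab <- tab[order(tab$aic, tab$bic), ]
  tab$rank <- seq_len(nrow(tab))
  tab[c("rank", "name", "aic", "bic", "rmse", "r2", "loglik")]
}
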