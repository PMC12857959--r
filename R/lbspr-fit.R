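# Maximum-likelihood fitting of (SL50, SL95, F/M) to one binned composition.

#' Binned length composition for one stratum-year cell
#'
#' @param counts Non-negative integer counts per bin, aligned to `grid`.
#' @param grid A [length_grid].
#' @param stratum Stratum id (e.g. "BS", "EI", "GS", "JOIN", "SSWI").
#' @param year Calendar year.
#' @param month Optional month 1-12.
#' @return An object of class `length_composition`.
#' @export
length_composition <- function(counts, grid, stratum = NA_character_,
                               year = NA_integer_, month = NA_integer_) {
  stopifnot(length(counts) == length(grid$edges), all(counts >= 0))
  n <- sum(counts)
  if (n <= 0) stop("composition has zero total count", call. = FALSE)
  structure(
    list(stratum = stratum, year = year, month = month,
         counts = as.numeric(counts), n = n, grid = grid),
    class = "length_composition"
  )
}

#' @export
print.length_composition <- function(x, ...) {
  cat("Length composition:", x$stratum, x$year,
      if (!is.na(x$month)) paste0("m", x$month) else "",
      "- n =", x$n, "in", length(x$counts), "bins\n")
  invisible(x)
}

#' Negative log-likelihood of fleet parameters given a composition
#'
#' Multinomial likelihood over the length bins:
#' `NLL = -sum(counts * log(p + 1e-12))` with `p` the model's expected catch
#' proportions. Parameter sets whose expected composition is degenerate
#' return `+Inf` so optimizers treat them as infeasible.
#'
#' @param fleet A [fleet_pars].
#' @param comp A [length_composition].
#' @param lh A [life_history].
#' @param setup Optional precomputed model setup (internal reuse).
#' @return Scalar NLL (up to an additive constant).
#' @export
negloglik <- function(fleet, comp, lh, setup = NULL) {
  if (is.null(setup)) setup <- lbspr_setup(lh, comp$grid)
  nll_from_setup(setup, comp$counts, fleet$sl50, fleet$sl95, fleet$fm)
}

nll_from_setup <- function(setup, counts, sl50, sl95, fm) {
  if (!(sl50 > 0 && sl50 < sl95) || fm < 0 || !is.finite(fm)) return(Inf)
  st <- lbspr_state(setup, sl50, sl95, fm)
  catch <- colSums(st$stock) * st$sel
  tot <- sum(catch)
  if (!is.finite(tot) || tot <= 0) return(Inf)
  -sum(counts * log(catch / tot + 1e-12))
}

#' Fitting options
#'
#' @param min_n Minimum sample size per cell (default 100); smaller cells are
#'   skipped with an explicit record.
#' @param n_gtg Number of growth-type groups used by the model.
#' @param maxit Maximum Nelder-Mead iterations.
#' @return A list of options for [fit_lbspr].
#' @export
fit_control <- function(min_n = 100, n_gtg = 13, maxit = 500) {
  list(min_n = min_n, n_gtg = n_gtg, maxit = maxit)
}

# composition quantile on the length scale (linear within bins)
comp_quantile <- function(comp, p) {
  cum <- cumsum(comp$counts) / comp$n
  i <- which(cum >= p)[1]
  comp$grid$edges[i] + comp$grid$bin_width / 2
}

#' Fit the LBSPR model to one length composition
#'
#' Minimises the multinomial negative log-likelihood over the transformed
#' parameters `(sl50, log(sl95 - sl50), log(fm))` by Nelder-Mead, restarting
#' once from a 25% larger `F/M` if the first run does not converge (lowest
#' NLL wins). SPR is evaluated at the optimum; its standard deviation comes
#' from the delta method on the numerical Hessian in transformed space. A
#' non-positive-definite Hessian yields `spr_sd = NA` with `sd_ok = FALSE`.
#'
#' @param comp A [length_composition] with `n >= control$min_n`.
#' @param lh A [life_history].
#' @param start Optional [fleet_pars] starting point; default starts
#'   selectivity at the 25th/75th percentiles of the data and `F/M = 1`.
#' @param control A [fit_control] list.
#' @return An object of class `spr_estimate`: point estimates, `spr_sd`,
#'   `nll`, `converged`, `sd_ok` and sample size.
#' @export
fit_lbspr <- function(comp, lh, start = NULL, control = fit_control()) {
  stopifnot(inherits(comp, "length_composition"))
  if (comp$n < control$min_n) {
    return(spr_estimate(comp, spr = NA_real_, spr_sd = NA_real_,
                        sl50 = NA_real_, sl95 = NA_real_, fm = NA_real_,
                        nll = NA_real_, converged = FALSE, sd_ok = FALSE,
                        skipped = TRUE, reason = "insufficient sample"))
  }
  comp <- extend_grid(comp, lh, control$n_gtg)
  setup <- lbspr_setup(lh, comp$grid, n_gtg = control$n_gtg)
  if (is.null(start)) {
    q25 <- comp_quantile(comp, 0.25)
    q75 <- comp_quantile(comp, 0.75)
    if (q75 <= q25) q75 <- q25 + comp$grid$bin_width # mass in one bin
    start <- fleet_pars(q25, q75, fm = 1)
  }
  obj <- function(th) {
    nll_from_setup(setup, comp$counts, th[1], th[1] + exp(th[2]), exp(th[3]))
  }
  th0 <- c(start$sl50, log(start$sl95 - start$sl50), log(start$fm))
  run <- function(th) {
    stats::optim(th, obj, method = "Nelder-Mead",
                 control = list(maxit = control$maxit, reltol = 1e-10))
  }
  o <- run(th0)
  if (o$convergence != 0) {
    o2 <- run(th0 + c(0, 0, log(1.25)))
    if (o2$value < o$value) o <- o2
  }
  th <- o$par
  sl50 <- th[1]
  sl95 <- th[1] + exp(th[2])
  fm <- exp(th[3])
  spr_hat <- spr_from_setup(setup, sl50, sl95, fm)
  # delta method in transformed space
  spr_sd <- NA_real_
  sd_ok <- FALSE
  H <- tryCatch(stats::optimHess(th, obj), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    V <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
    if (!is.null(V)) {
      eps <- 1e-4
      g <- vapply(1:3, function(i) {
        d <- numeric(3); d[i] <- eps
        (spr_from_setup(setup, (th + d)[1], (th + d)[1] + exp((th + d)[2]),
                        exp((th + d)[3])) -
         spr_from_setup(setup, (th - d)[1], (th - d)[1] + exp((th - d)[2]),
                        exp((th - d)[3]))) / (2 * eps)
      }, numeric(1))
      v <- drop(t(g) %*% V %*% g)
      if (is.finite(v) && v >= 0) {
        spr_sd <- sqrt(v)
        sd_ok <- TRUE
      }
    }
  }
  spr_estimate(comp, spr = min(max(spr_hat, 0), 1), spr_sd = spr_sd,
               sl50 = sl50, sl95 = sl95, fm = fm, nll = o$value,
               converged = o$convergence == 0, sd_ok = sd_ok)
}

# pad a composition with empty upper bins when the assumed life history
# implies growth-type groups beyond the data grid
extend_grid <- function(comp, lh, n_gtg) {
  need <- max(build_gtg(lh, n_gtg = n_gtg)$linfs)
  g <- comp$grid
  top <- max(g$edges) + g$bin_width
  if (top >= need) return(comp)
  extra <- ceiling((need - top) / g$bin_width)
  g2 <- length_grid(lh$linf, bin_width = g$bin_width,
                    l_max = top + extra * g$bin_width)
  length_composition(c(comp$counts, numeric(extra)), g2,
                     comp$stratum, comp$year, comp$month)
}

spr_estimate <- function(comp, spr, spr_sd, sl50, sl95, fm, nll,
                         converged, sd_ok, skipped = FALSE,
                         reason = NA_character_) {
  structure(
    list(stratum = comp$stratum, year = comp$year, month = comp$month,
         spr = spr, spr_sd = spr_sd, sl50_hat = sl50, sl95_hat = sl95,
         fm_hat = fm, nll = nll, converged = converged, sd_ok = sd_ok,
         skipped = skipped, reason = reason, n = comp$n),
    class = "spr_estimate"
  )
}

#' @export
print.spr_estimate <- function(x, ...) {
  if (x$skipped) {
    cat("SPR estimate (skipped:", x$reason, ") -", x$stratum, x$year, "\n")
  } else {
    cat(sprintf("SPR estimate %s %s: SPR = %.3f (sd %.3f), F/M = %.2f, SL50/SL95 = %.1f/%.1f, n = %d\n",
                x$stratum, x$year, x$spr, x$spr_sd, x$fm_hat, x$sl50_hat,
                x$sl95_hat, x$n))
  }
  invisible(x)
}

as_tibble_row_est <- function(e) {
  tibble::tibble(
    stratum = e$stratum, year = e$year, spr = e$spr, spr_sd = e$spr_sd,
    sl50_hat = e$sl50_hat, sl95_hat = e$sl95_hat, fm_hat = e$fm_hat,
    nll = e$nll, converged = e$converged, skipped = e$skipped, n = e$n
  )
}

#' Fit the model across a set of compositions
#'
#' Pools monthly compositions to stratum x year (the annual reporting unit)
#' unless `monthly = TRUE`, fits each cell, and returns one row per
#' stratum x year of the full crossing; cells without data appear as explicit
#' gap rows (`NA` estimates), mirroring the dashes of an annual report table.
#'
#' @param comps List of [length_composition] objects.
#' @param lh A [life_history].
#' @param control A [fit_control] list.
#' @param monthly If `TRUE`, fit month-level cells instead of pooling.
#' @return A tibble ordered by stratum then year.
#' @export
fit_series <- function(comps, lh, control = fit_control(), monthly = FALSE) {
  empty <- tibble::tibble(
    stratum = character(), year = integer(), spr = numeric(),
    spr_sd = numeric(), sl50_hat = numeric(), sl95_hat = numeric(),
    fm_hat = numeric(), nll = numeric(), converged = logical(),
    skipped = logical(), n = numeric()
  )
  if (length(comps) == 0) return(empty)
  if (!monthly) comps <- pool_monthly(comps)
  rows <- dplyr::bind_rows(lapply(comps, function(cm) {
    as_tibble_row_est(fit_lbspr(cm, lh, control = control))
  }))
  # explicit gaps over the full stratum x year crossing
  full <- expand.grid(stratum = sort(unique(rows$stratum)),
                      year = sort(unique(rows$year)),
                      stringsAsFactors = FALSE)
  out <- dplyr::left_join(tibble::as_tibble(full), rows,
                          by = c("stratum", "year"))
  out[order(out$stratum, out$year), ]
}

# pool monthly compositions into stratum x year cells
pool_monthly <- function(comps) {
  key <- vapply(comps, function(cm) paste(cm$stratum, cm$year, sep = "\r"),
                character(1))
  lapply(split(comps, key), function(grp) {
    counts <- Reduce(`+`, lapply(grp, `[[`, "counts"))
    length_composition(counts, grp[[1]]$grid, grp[[1]]$stratum,
                       grp[[1]]$year)
  })
}
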