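# Synthetic observer-like length records and environmental panels with known
# ground truth, so every pipeline stage can be exercised without the
# access-restricted fishery data.

#' Ground-truth configuration for the synthetic generator
#'
#' Defaults emulate the monitored krill fishery: five management strata with
#' the JOIN stratum observed only in 2016-2017, per-stratum fleet truths
#' spanning low to high exploitation, an environmental panel at
#' stratum x year x month resolution with corr(Chla, SST) = -0.73, and
#' length-environment coefficients anchored at GS +4.07, JOIN +0.49,
#' SIC -0.0086 and SST x Chla -0.11 on the cell mean-length scale.
#'
#' @param strata Stratum ids.
#' @param years Named list of observation years per stratum; default
#'   2001-2020 with JOIN restricted to 2016-2017.
#' @param n_per_stratum_year Measured animals per stratum-year.
#' @param lh A [life_history] shared by all strata (truth).
#' @param fleets Named list of [fleet_pars] truths per stratum.
#' @param env_means,env_sds Named vectors (`sst` degC, `sic` %, `chla`
#'   mg m-3).
#' @param rho_chla_sst Target correlation between Chla and SST.
#' @param beta Named coefficient vector for the cell mean-length model:
#'   `intercept`, one offset per non-reference stratum, `sic`, `sst`,
#'   `chla`, `sst_chla`.
#' @param var_year,var_resid Year random-intercept and residual variances,
#'   mm^2.
#' @param seed Mandatory integer seed; expanded into independent substreams
#'   for environment, compositions and noise.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(
    strata = c("BS", "EI", "GS", "JOIN", "SSWI"),
    years = NULL,
    n_per_stratum_year = 2000,
    lh = lh_preset("base"),
    fleets = list(BS = fleet_pars(38, 45, 2.5),
                  EI = fleet_pars(38, 45, 1.0),
                  GS = fleet_pars(38, 45, 2.0),
                  JOIN = fleet_pars(38, 45, 0.5),
                  SSWI = fleet_pars(38, 45, 0.8)),
    env_means = c(sst = 0.5, sic = 30, chla = 1.0),
    env_sds = c(sst = 1.0, sic = 15, chla = 0.6),
    rho_chla_sst = -0.73,
    beta = c(intercept = 40, EI = 0.8, GS = 4.07, JOIN = 0.49, SSWI = -0.6,
             sic = -0.0086, sst = -0.5, chla = -1.2, sst_chla = -0.11),
    var_year = 1, var_resid = 1,
    seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(years)) {
    years <- stats::setNames(rep(list(2001:2020), length(strata)), strata)
    if ("JOIN" %in% strata) years$JOIN <- 2016:2017
  }
  stopifnot(n_per_stratum_year > 0, abs(rho_chla_sst) < 1,
            var_year >= 0, var_resid >= 0)
  structure(
    list(strata = strata, years = years,
         n_per_stratum_year = n_per_stratum_year, lh = lh, fleets = fleets,
         env_means = env_means, env_sds = env_sds,
         rho_chla_sst = rho_chla_sst, beta = beta,
         var_year = var_year, var_resid = var_resid, seed = as.integer(seed)),
    class = "truth_config"
  )
}

#' Sample a length composition from the model
#'
#' Draws bin counts multinomially from the equilibrium model's expected
#' catch proportions.
#'
#' @param lh A [life_history].
#' @param fleet A [fleet_pars] (truth).
#' @param n Number of measured animals, `>= 1`.
#' @param seed Integer seed.
#' @param grid Optional [length_grid].
#' @param stratum,year,month Cell labels attached to the composition.
#' @return A [length_composition].
#' @export
simulate_length_composition <- function(lh, fleet, n, seed, grid = NULL,
                                        stratum = NA_character_,
                                        year = NA_integer_,
                                        month = NA_integer_) {
  stopifnot(n >= 1)
  if (is.null(grid)) grid <- length_grid(lh$linf)
  p <- expected_catch_composition(equilibrium_numbers(lh, fleet, grid))
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, n, p))
  length_composition(counts, grid, stratum = stratum, year = year,
                     month = month)
}

# split one seed into named substreams (all below 2^31)
seed_streams <- function(seed, names) {
  set.seed(seed)
  stats::setNames(sample.int(2147483646L, length(names)), names)
}

#' Simulate a full observer-like panel
#'
#' Produces (i) per-animal length records drawn from each stratum's
#' equilibrium catch composition (lengths jittered uniformly within their
#' 2-mm bin, dated mid-month), (ii) an environmental panel at
#' stratum x year x month cells where SST and Chla are drawn jointly with
#' the configured correlation, SIC independently, and the cell mean length
#' follows the linear predictor plus a year random intercept and residual
#' noise, and (iii) a truth ledger with every parameter and seed.
#'
#' Environmental effects act on the cell mean-length scale only; they do not
#' distort the within-cell composition shape, which keeps the per-stratum
#' SPR truth interpretable.
#'
#' @param cfg A [truth_config].
#' @param months Months sampled per year (default all 12).
#' @param records Generate per-animal records? Set `FALSE` when only the
#'   environmental panel is needed (e.g. mixed-model simulations).
#' @return A list with `records` (tibble or `NULL`), `env` (tibble),
#'   `truth` (list).
#' @export
simulate_panel <- function(cfg, months = 1:12, records = TRUE) {
  stopifnot(inherits(cfg, "truth_config"))
  ss <- seed_streams(cfg$seed, c("env", "comps", "noise"))
  grid <- length_grid(cfg$lh$linf)
  all_years <- sort(unique(unlist(cfg$years)))

  # --- environmental panel -------------------------------------------------
  set.seed(ss[["env"]])
  cells <- do.call(rbind, lapply(cfg$strata, function(st)
    expand.grid(stratum = st, year = cfg$years[[st]], month = months,
                stringsAsFactors = FALSE)))
  nc <- nrow(cells)
  z1 <- stats::rnorm(nc)
  z2 <- stats::rnorm(nc)
  rho <- cfg$rho_chla_sst
  sst <- cfg$env_means[["sst"]] + cfg$env_sds[["sst"]] * z1
  chla <- cfg$env_means[["chla"]] +
    cfg$env_sds[["chla"]] * (rho * z1 + sqrt(1 - rho^2) * z2)
  chla <- pmax(chla, 0.01)
  sic <- pmin(pmax(cfg$env_means[["sic"]] +
                     cfg$env_sds[["sic"]] * stats::rnorm(nc), 0), 100)

  set.seed(ss[["noise"]])
  b_year <- stats::setNames(
    stats::rnorm(length(all_years), 0, sqrt(cfg$var_year)), all_years)
  eps <- stats::rnorm(nc, 0, sqrt(cfg$var_resid))
  off <- vapply(cells$stratum, function(st) {
    if (st %in% names(cfg$beta)) cfg$beta[[st]] else 0
  }, numeric(1))
  mean_length <- cfg$beta[["intercept"]] + off +
    cfg$beta[["sic"]] * sic + cfg$beta[["sst"]] * sst +
    cfg$beta[["chla"]] * chla + cfg$beta[["sst_chla"]] * sst * chla +
    b_year[as.character(cells$year)] + eps
  env <- tibble::tibble(
    stratum = cells$stratum, year = as.integer(cells$year),
    month = as.integer(cells$month), mean_length = unname(mean_length),
    sst = sst, sic = sic, chla = chla,
    n_obs = as.integer(round(cfg$n_per_stratum_year / length(months)))
  )

  # --- per-animal records --------------------------------------------------
  if (!records) {
    return(list(records = NULL, env = env,
                truth = list(config = cfg, grid = grid, b_year = b_year,
                             seeds = ss)))
  }
  comp_seeds <- seed_streams(ss[["comps"]],
                             unlist(lapply(cfg$strata, function(st)
                               paste(st, cfg$years[[st]], sep = ":"))))
  recs <- list()
  for (st in cfg$strata) {
    p <- expected_catch_composition(
      equilibrium_numbers(cfg$lh, cfg$fleets[[st]], grid))
    for (yr in cfg$years[[st]]) {
      set.seed(comp_seeds[[paste(st, yr, sep = ":")]])
      counts <- as.vector(stats::rmultinom(1, cfg$n_per_stratum_year, p))
      lens <- rep(grid$edges, counts) +
        stats::runif(sum(counts), 0, grid$bin_width)
      mo <- sample(months, length(lens), replace = TRUE)
      recs[[paste(st, yr)]] <- tibble::tibble(
        length = lens,
        date = as.Date(sprintf("%d-%02d-15", yr, mo)),
        lat = NA_real_, lon = NA_real_, stratum = st,
        vessel = NA_character_, nationality = NA_character_)
    }
  }
  records <- dplyr::bind_rows(recs)

  truth <- list(config = cfg, grid = grid,
                spr = vapply(cfg$strata, function(st)
                  spr(cfg$lh, cfg$fleets[[st]], grid), numeric(1)),
                b_year = b_year, seeds = ss)
  list(records = records, env = env, truth = truth)
}
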