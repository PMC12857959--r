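#' Life-history parameter set
#'
#' Bundles the biological parameters that drive the length-structured
#' per-recruit model. Only the ratio `M/K` (and the fleet's `F/M`) enters the
#' model equations; absolute `m` and `k` are kept for bookkeeping and for
#' deriving `mk` when both are supplied.
#'
#' @param linf Von Bertalanffy asymptotic length, mm.
#' @param cv_linf Coefficient of variation of asymptotic length across
#'   growth-type groups (dimensionless).
#' @param mk Ratio of natural mortality to the von Bertalanffy growth
#'   coefficient, `M/K`. Either give `mk` directly or both `m` and `k`.
#' @param l50_mat,l95_mat Lengths at 50% and 95% maturity, mm.
#' @param fec_exp Fecundity-length exponent `b`: egg output is taken
#'   proportional to `L^b`. Default 3 (egg production scales with body volume).
#' @param m Natural mortality rate, 1/yr (bookkeeping only).
#' @param k Von Bertalanffy growth coefficient, 1/yr (bookkeeping only).
#'
#' @return An object of class `life_history`.
#' @examples
#' lh <- life_history(linf = 60, cv_linf = 0.1, m = 0.4, k = 0.45,
#'                    l50_mat = 35, l95_mat = 40)
#' lh$mk
#' @export
life_history <- function(linf, cv_linf = 0.1, mk = NULL,
                         l50_mat, l95_mat, fec_exp = 3,
                         m = NULL, k = NULL) {
  if (is.null(mk)) {
    if (is.null(m) || is.null(k))
      stop("supply `mk`, or both `m` and `k`", call. = FALSE)
    mk <- m / k
  } else if (!is.null(m) && !is.null(k) && abs(mk - m / k) >= 1e-9) {
    stop("`mk` is inconsistent with `m`/`k`", call. = FALSE)
  }
  stopifnot(linf > 0, cv_linf >= 0, mk > 0, fec_exp > 0)
  if (!(0 < l50_mat && l50_mat < l95_mat && l95_mat < linf))
    stop("need 0 < l50_mat < l95_mat < linf", call. = FALSE)
  structure(
    list(linf = linf, cv_linf = cv_linf, mk = mk,
         l50_mat = l50_mat, l95_mat = l95_mat, fec_exp = fec_exp,
         m = m, k = k),
    class = "life_history"
  )
}

#' @export
print.life_history <- function(x, ...) {
  cat("Life history: Linf =", x$linf, "mm (CV", x$cv_linf, "), M/K =",
      round(x$mk, 4), "\n  maturity L50/L95 =", x$l50_mat, "/", x$l95_mat,
      "mm, fecundity exponent =", x$fec_exp, "\n")
  invisible(x)
}

#' Named life-history presets for Antarctic krill
#'
#' Three anchors in common use for krill in Subarea 48.1: the base
#' configuration (`m = 0.4`, `k = 0.45`, `M/K ~ 0.89`), the parameterisation
#' used in current krill management (`k = 0.7`), and the type-I life-strategy
#' anchor (`k = 0.43`, `M/K ~ 0.93`). All share `Linf = 60` mm, maturity at
#' 35/40 mm and a cubic fecundity law.
#'
#' @param name One of `"base"`, `"management"`, `"type1"`.
#' @return A [life_history] object.
#' @export
lh_preset <- function(name = c("base", "management", "type1")) {
  name <- match.arg(name)
  k <- switch(name, base = 0.45, management = 0.7, type1 = 0.43)
  life_history(linf = 60, cv_linf = 0.1, m = 0.4, k = k,
               l50_mat = 35, l95_mat = 40, fec_exp = 3)
}

#' Fleet (fishery) parameters
#'
#' Logistic selectivity-at-length and the relative fishing pressure `F/M`.
#'
#' @param sl50,sl95 Lengths at 50% and 95% selectivity, mm.
#' @param fm Fishing-to-natural mortality ratio, dimensionless, `>= 0`.
#' @return An object of class `fleet_pars`.
#' @export
fleet_pars <- function(sl50, sl95, fm) {
  if (!(sl50 > 0 && sl50 < sl95))
    stop("need 0 < sl50 < sl95", call. = FALSE)
  stopifnot(fm >= 0)
  structure(list(sl50 = sl50, sl95 = sl95, fm = fm), class = "fleet_pars")
}

#' @export
print.fleet_pars <- function(x, ...) {
  cat("Fleet: SL50 =", x$sl50, "mm, SL95 =", x$sl95, "mm, F/M =", x$fm, "\n")
  invisible(x)
}

#' Uniform length grid
#'
#' Half-open bins `[edge, edge + bin_width)` anchored at 0 mm. The default
#' upper limit, `1.3 * linf` rounded up to a whole bin, covers the largest
#' growth-type group for the truncation and CV ranges used here.
#'
#' @param linf Asymptotic length used to size the grid, mm.
#' @param bin_width Bin width, mm (default 2, the resolution of the observer
#'   data).
#' @param l_max Optional explicit upper limit, mm; overrides the
#'   `1.3 * linf` rule.
#' @return An object of class `length_grid` with lower `edges`, `mids` and
#'   `bin_width`.
#' @export
length_grid <- function(linf, bin_width = 2, l_max = NULL) {
  stopifnot(bin_width > 0)
  if (is.null(l_max)) l_max <- 1.3 * linf
  upper <- ceiling(l_max / bin_width) * bin_width
  edges <- seq(0, upper - bin_width, by = bin_width)
  structure(
    list(bin_width = bin_width, edges = edges, mids = edges + bin_width / 2),
    class = "length_grid"
  )
}

#' Two-parameter logistic ogive
#'
#' The standard maturity/selectivity curve parameterised by the lengths at
#' 50% and 95%: `1 / (1 + exp(-log(19) * (L - x50) / (x95 - x50)))`.
#'
#' @param length Length(s), mm.
#' @param x50,x95 Lengths at 50% and 95%, mm, with `x50 < x95`.
#' @return Proportion(s) in `[0, 1]`.
#' @export
logistic_ogive <- function(length, x50, x95) {
  if (x50 >= x95) stop("need x50 < x95", call. = FALSE)
  1 / (1 + exp(-log(19) * (length - x50) / (x95 - x50)))
}

#' Growth-type-group structure
#'
#' Discretises individual variability in asymptotic length into `n_gtg`
#' sub-cohorts with asymptotic lengths equally spaced over
#' `linf * (1 +/- trunc * cv_linf)` and recruitment weights proportional to a
#' Normal(`linf`, `cv_linf * linf`) density at those points.
#'
#' @param lh A [life_history] object.
#' @param n_gtg Odd number of growth-type groups (default 13).
#' @param trunc Truncation in SD units (default 2.5).
#' @return An object of class `gtg_structure` with `linfs` and `weights`.
#' @export
build_gtg <- function(lh, n_gtg = 13, trunc = 2.5) {
  if (lh$cv_linf < 0) stop("cv_linf must be >= 0", call. = FALSE)
  if (n_gtg < 1 || n_gtg %% 2 == 0)
    stop("n_gtg must be odd and >= 1", call. = FALSE)
  if (lh$cv_linf == 0 || n_gtg == 1) {
    linfs <- lh$linf
    weights <- 1
  } else {
    sd <- lh$cv_linf * lh$linf
    linfs <- seq(lh$linf - trunc * sd, lh$linf + trunc * sd,
                 length.out = n_gtg)
    weights <- stats::dnorm(linfs, lh$linf, sd)
    weights <- weights / sum(weights)
  }
  structure(list(n_gtg = length(linfs), linfs = linfs, weights = weights),
            class = "gtg_structure")
}
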