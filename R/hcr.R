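# SPR reference points, status classification, hockey-stick harvest control
# rule.

#' Harvest-control-rule configuration
#'
#' SPR 20% is the limit reference point and SPR 75% the target; the target is
#' also used as the SPR_MSY proxy when forming the ratio SPR / SPR_MSY. The
#' `"printed"` variant reproduces the published piecewise rule verbatim,
#' whose middle branch divides by 0.75 and is therefore discontinuous at the
#' target; `"continuous"` divides by (target - limit) instead, closing the
#' jump.
#'
#' @param spr_limit Limit reference point (default 0.20).
#' @param spr_target Target reference point and SPR_MSY proxy (default 0.75).
#' @param fmsy Fishing-mortality scale returned at or above the target.
#' @param variant `"printed"` or `"continuous"`.
#' @return An object of class `hcr_config`.
#' @export
hcr_config <- function(spr_limit = 0.20, spr_target = 0.75, fmsy = 1,
                       variant = c("printed", "continuous")) {
  variant <- match.arg(variant)
  if (!(0 < spr_limit && spr_limit < spr_target && spr_target <= 1))
    stop("need 0 < spr_limit < spr_target <= 1", call. = FALSE)
  stopifnot(fmsy >= 0)
  structure(list(spr_limit = spr_limit, spr_target = spr_target,
                 fmsy = fmsy, variant = variant),
            class = "hcr_config")
}

#' Classify stock status from SPR (or an SPR ratio)
#'
#' @param spr SPR value(s), `>= 0` (values above 1 can arise when
#'   classifying the ratio SPR / SPR_MSY and count as above target).
#' @param cfg An [hcr_config].
#' @return `"below_limit"` if `spr < spr_limit`, `"at_or_above_target"` if
#'   `spr >= spr_target`, else `"intermediate"`.
#' @export
classify_status <- function(spr, cfg = hcr_config()) {
  stopifnot(all(spr >= 0))
  ifelse(spr < cfg$spr_limit, "below_limit",
         ifelse(spr >= cfg$spr_target, "at_or_above_target", "intermediate"))
}

#' Hockey-stick harvest control rule
#'
#' Maps the ratio SPR / SPR_MSY to a recommended fishing mortality:
#' `fmsy` at or above 0.75, zero below 0.2, and a linear ramp
#' `fmsy * (ratio - 0.2) / 0.75` between (printed variant; the continuous
#' variant ramps over `/ (0.75 - 0.2)`).
#'
#' @param spr_ratio SPR over SPR_MSY, `>= 0`.
#' @param cfg An [hcr_config].
#' @return Recommended F on the `fmsy` scale.
#' @export
hcr_f <- function(spr_ratio, cfg = hcr_config()) {
  stopifnot(all(spr_ratio >= 0))
  denom <- switch(cfg$variant,
                  printed = cfg$spr_target,
                  continuous = cfg$spr_target - cfg$spr_limit)
  ifelse(spr_ratio >= cfg$spr_target, cfg$fmsy,
         ifelse(spr_ratio < cfg$spr_limit, 0,
                cfg$fmsy * (spr_ratio - cfg$spr_limit) / denom))
}

#' Status and HCR table for a series of SPR estimates
#'
#' @param estimates Tibble from [fit_series] (needs `stratum`, `year`,
#'   `spr`).
#' @param cfg An [hcr_config].
#' @return A tibble with `spr_ratio = spr / spr_target`, `status` (the
#'   classification of the ratio, so that `recommended_f = 0` exactly when
#'   status is `below_limit`), `recommended_f` and `variant`; rows with
#'   missing SPR keep `NA`s.
#' @export
status_table <- function(estimates, cfg = hcr_config()) {
  stopifnot(nrow(estimates) > 0)
  ratio <- estimates$spr / cfg$spr_target
  ok <- !is.na(ratio)
  status <- rep(NA_character_, length(ratio))
  recf <- rep(NA_real_, length(ratio))
  status[ok] <- classify_status(ratio[ok], cfg)
  recf[ok] <- hcr_f(ratio[ok], cfg)
  tibble::tibble(
    stratum = estimates$stratum, year = estimates$year,
    spr = estimates$spr, spr_ratio = ratio, status = status,
    recommended_f = recf, variant = cfg$variant
  )
}
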