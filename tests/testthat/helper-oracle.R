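# Independent age-structured per-recruit oracle. Integrates survivorship,
# maturity and fecundity over age on a fine time step, sharing only the
# parameter definitions (logistic ogives, growth-type-group layout) with the
# length-based implementation -- never its code path.

oracle_gtg <- function(linf, cv, n = 13, trunc = 2.5) {
  if (cv == 0 || n == 1) return(list(linfs = linf, w = 1))
  sd <- cv * linf
  xs <- seq(linf - trunc * sd, linf + trunc * sd, length.out = n)
  w <- dnorm(xs, linf, sd)
  list(linfs = xs, w = w / sum(w))
}

oracle_logi <- function(L, x50, x95) {
  1 / (1 + exp(-log(19) * (L - x50) / (x95 - x50)))
}

# SPR by brute-force age integration; time unit 1/K so step dt corresponds
# to dt/K years (dt = 0.005 is finer than 0.01/K years for any K >= 1)
oracle_spr_age <- function(linf, cv, mk, fm, sl50, sl95, l50, l95, b = 3,
                           dt = 0.005) {
  g <- oracle_gtg(linf, cv)
  tt <- seq(0, 25 / mk, by = dt)
  epr <- function(f_rel) {
    tot <- 0
    for (i in seq_along(g$linfs)) {
      L <- g$linfs[i] * (1 - exp(-tt))
      z <- mk * (1 + f_rel * oracle_logi(L, sl50, sl95))
      surv <- exp(-c(0, cumsum(z[-length(z)] * dt)))
      tot <- tot + g$w[i] * sum(surv * oracle_logi(L, l50, l95) * L^b * dt)
    }
    tot
  }
  epr(fm) / epr(0)
}

# modal 2-mm catch bin from the same age-structured simulator: catch density
# at age is selectivity-weighted standing stock, accumulated into bins
oracle_modal_catch_bin <- function(linf, cv, mk, fm, sl50, sl95, bw = 2,
                                   dt = 0.005) {
  g <- oracle_gtg(linf, cv)
  tt <- seq(0, 25 / mk, by = dt)
  edges <- seq(0, ceiling(1.3 * linf / bw) * bw - bw, by = bw)
  catch <- numeric(length(edges))
  for (i in seq_along(g$linfs)) {
    L <- g$linfs[i] * (1 - exp(-tt))
    S <- oracle_logi(L, sl50, sl95)
    z <- mk * (1 + fm * S)
    surv <- exp(-c(0, cumsum(z[-length(z)] * dt)))
    bin <- pmin(floor(L / bw) + 1, length(edges))
    dens <- g$w[i] * surv * S * dt
    for (lvl in unique(bin)) catch[lvl] <- catch[lvl] + sum(dens[bin == lvl])
  }
  edges[which.max(catch)]
}
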