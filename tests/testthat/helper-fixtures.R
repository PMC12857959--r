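base_lh <- function() lh_preset("base")
base_fleet <- function(fm = 1) fleet_pars(38, 45, fm)

# small truth configuration for end-to-end tests: all five strata, three
# years (JOIN keeps its two-year window)
small_truth <- function(seed, n = 5000) {
  truth_config(
    years = list(BS = 2015:2017, EI = 2015:2017, GS = 2015:2017,
                 JOIN = 2016:2017, SSWI = 2015:2017),
    n_per_stratum_year = n, seed = seed
  )
}

write_records_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# unit-square strata map fixture: two adjacent squares sharing the x = 1 edge
two_squares_map <- function() {
  sq <- function(x0) cbind(c(x0, x0 + 1, x0 + 1, x0, x0),
                           c(0, 0, 1, 1, 0))
  stratum_map(A = sq(0), B = sq(1))
}
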