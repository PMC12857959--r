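# Pipeline driver behind the command-line entry point: configuration,
# subcommands, tables, figures, run manifest.

run_config_keys <- c("records", "strata_geojson", "env_panel", "out_dir",
                     "life_history", "fleet_start", "fit", "scenario_preset",
                     "hcr", "simulate", "seed", "log_level")

#' Read and validate a run configuration
#'
#' YAML with the blocks: `records` (CSV path), `strata_geojson`, `env_panel`
#' (CSV path), `out_dir`, `life_history` (either `preset:` or explicit
#' fields), `fit`, `scenario_preset`, `hcr`, `simulate`, `seed`,
#' `log_level`. Unknown top-level keys are rejected.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "krillspr-out"
  structure(cfg, class = "run_config")
}

config_lh <- function(cfg) {
  b <- cfg$life_history
  if (is.null(b)) return(lh_preset("base"))
  if (!is.null(b$preset)) return(lh_preset(b$preset))
  do.call(life_history, b)
}

config_hcr <- function(cfg) {
  if (is.null(cfg$hcr)) hcr_config() else do.call(hcr_config, cfg$hcr)
}

write_manifest <- function(out_dir, cfg, outputs, warnings = character()) {
  manifest <- list(
    package = "krillspr",
    version = as.character(utils::packageVersion("krillspr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = digest_config(cfg),
    reference_lines = list(limit = config_hcr(cfg)$spr_limit,
                           target = config_hcr(cfg)$spr_target),
    outputs = outputs,
    warnings = warnings,
    timestamp = NULL # omitted so reruns are byte-identical
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  path
}

# order-stable hash of the config (no digest package: use a serialized sum)
digest_config <- function(cfg) {
  raw <- serialize(unclass(cfg)[order(names(cfg))], NULL, version = 2)
  sprintf("%08x-%d", sum(as.integer(raw)) %% 4294967291, length(raw))
}

load_compositions <- function(cfg) {
  rec <- read_length_records(cfg$records)
  if (!is.null(cfg$strata_geojson)) {
    rec <- assign_stratum(rec, read_strata_geojson(cfg$strata_geojson))
  }
  grid <- length_grid(config_lh(cfg)$linf)
  bin_composition(rec, grid = grid)
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (write synthetic records + environmental panel),
#' `fit` (SPR by stratum and year -> `spr_by_stratum_year.csv`),
#' `sensitivity` (growth-scenario sweep -> `sensitivity.csv`), `hcr`
#' (status and recommended F -> `status_hcr.csv`), `enviro` (LMM
#' coefficients and model ranking), `report` (fit + hcr + figures). Every
#' run writes a machine-readable `manifest.json` (config hash, seed,
#' versions, warnings); per-cell fit failures are warnings in the manifest,
#' not errors.
#'
#' @param cfg A `run_config` (path or list accepted).
#' @param subcommand One of simulate, fit, sensitivity, hcr, enviro, report.
#' @return Invisibly, a list of output paths.
#' @export
run_pipeline <- function(cfg, subcommand = c("simulate", "fit",
                                             "sensitivity", "hcr", "enviro",
                                             "report")) {
  subcommand <- match.arg(subcommand)
  if (!inherits(cfg, "run_config")) cfg <- read_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  warns <- character()
  lh <- config_lh(cfg)

  if (subcommand == "simulate") {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    sim_args$lh <- lh
    tc <- do.call(truth_config, sim_args)
    sim <- simulate_panel(tc)
    out$records <- file.path(cfg$out_dir, "records.csv")
    utils::write.csv(sim$records, out$records, row.names = FALSE)
    out$env_panel <- file.path(cfg$out_dir, "env_panel.csv")
    utils::write.csv(sim$env, out$env_panel, row.names = FALSE)
    out$truth <- file.path(cfg$out_dir, "truth.json")
    jsonlite::write_json(
      list(spr = as.list(sim$truth$spr), seed = tc$seed),
      out$truth, auto_unbox = TRUE, digits = NA)
  }

  if (subcommand %in% c("fit", "report", "hcr")) {
    comps <- load_compositions(cfg)
    fits <- fit_series(comps, lh,
                       control = do.call(fit_control,
                                         as.list(cfg$fit %||% list())))
    bad <- fits$stratum[!is.na(fits$converged) & !fits$converged]
    if (length(bad))
      warns <- c(warns, paste("non-converged cells:",
                              paste(bad, collapse = ", ")))
    out$spr <- file.path(cfg$out_dir, "spr_by_stratum_year.csv")
    utils::write.csv(format_spr_table(fits), out$spr, row.names = FALSE)
    if (subcommand %in% c("hcr", "report")) {
      st <- status_table(fits, config_hcr(cfg))
      out$status <- file.path(cfg$out_dir, "status_hcr.csv")
      utils::write.csv(st, out$status, row.names = FALSE)
    }
    if (subcommand == "report") {
      out$spr_plot <- file.path(cfg$out_dir, "spr_timeseries.png")
      plot_spr_series(fits, config_hcr(cfg), out$spr_plot)
    }
  }

  if (subcommand == "sensitivity") {
    comps <- load_compositions(cfg)
    grid <- scenario_grid(preset = cfg$scenario_preset %||% "default",
                          base = lh)
    sens <- run_sensitivity(grid, comps)
    out$sensitivity <- file.path(cfg$out_dir, "sensitivity.csv")
    utils::write.csv(sens[setdiff(names(sens), "spr_by_year")],
                     out$sensitivity, row.names = FALSE)
  }

  if (subcommand == "enviro") {
    if (is.null(cfg$env_panel))
      stop("enviro subcommand needs an `env_panel` CSV", call. = FALSE)
    panel <- tibble::as_tibble(utils::read.csv(cfg$env_panel,
                                               stringsAsFactors = FALSE))
    fits <- lapply(1:5, function(m)
      fit_lmm(panel, lmm_formula(m), name = paste0("model", m)))
    out$lmm <- file.path(cfg$out_dir, "lmm_coefficients.csv")
    utils::write.csv(fits[[5]]$beta, out$lmm, row.names = FALSE)
    out$ranking <- file.path(cfg$out_dir, "lmm_ranking.csv")
    utils::write.csv(rank_models(fits), out$ranking, row.names = FALSE)
  }

  out$manifest <- write_manifest(cfg$out_dir, cfg, out, warns)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annual report table: 3-decimal SPR with SD in its own column, explicit
# empty cells for missing stratum-years
format_spr_table <- function(fits) {
  data.frame(
    stratum = fits$stratum, year = fits$year,
    spr = ifelse(is.na(fits$spr), "", sprintf("%.3f", fits$spr)),
    spr_sd = ifelse(is.na(fits$spr_sd), "", sprintf("%.3f", fits$spr_sd)),
    fm = ifelse(is.na(fits$fm_hat), "", sprintf("%.3f", fits$fm_hat)),
    n = ifelse(is.na(fits$n), "", fits$n)
  )
}

# SPR time series per stratum with the 20% limit (red) and 75% target
# (green, dashed) reference lines
plot_spr_series <- function(fits, cfg_hcr, path) {
  df <- fits[!is.na(fits$spr), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = year, y = spr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = cfg_hcr$spr_target,
                        linetype = "dashed", colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = cfg_hcr$spr_limit, colour = "red") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Year", y = "SPR") +
    ggplot2::theme_bw()
  ggplot2::ggsave(path, p, width = 8, height = 5, dpi = 120)
  invisible(p)
}
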