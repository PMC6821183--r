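# Orchestration: centralized defaults, scenario runner, YAML config loading.

#' Centralized default configuration
#'
#' All model defaults in one versioned list: lux reaction constants,
#' promoter parameters (2% basal leak for inducible promoters), copy-number
#' scale factors folded into vmax (LCP/MCP/HCP = 1/5/20), the stress
#' parameter sets of the katG and recA biosensors, IFFL parameters, and the
#' canonical wide log-spaced dose grid spanning 1e-3..1e3.
#'
#' @return A named list of defaults; override via `run_scenario(overrides=)`.
#' @export
lux_defaults <- function() {
  list(
    config_version = "1",
    lux = list(K_F = 1, K_R = 1, K_d = 1, S_T = 1, Y_T = 1, I_scale = 1),
    promoter = list(vmax = 1, K = 1, n = 1, basal = 0.02),
    copy_number = list(LCP = 1, MCP = 5, HCP = 20),
    dose_grid = list(lo = 1e-3, hi = 1e3, n = 200),
    gate = list(hi_factor = 100, K_AB = 1),
    comparator = list(ahl_levels = c(0.1, 0.3, 1, 3, 10), luxB_const = 1),
    stress = list(X0 = 50000),
    iffl = list(tau_delay = 60, K_tetr = 0.2, h_tetr = 2, sender_scale = 1,
                er_scale = 1e-5, t_max = 600),
    noise = list(cv = 0.1, replicates = 3, cadence = 15, horizon = 240)
  )
}

scenario_names <- c("fig1_sim", "wildtype_powerlaw", "min_gate", "pp_gate",
                    "comparator", "stress_fits", "iffl")

dose_grid_from <- function(cfg)
  10^seq(log10(cfg$dose_grid$lo), log10(cfg$dose_grid$hi),
         length.out = cfg$dose_grid$n)

lux_from <- function(cfg) do.call(lux_params, cfg$lux)
prom_from <- function(cfg, vmax_scale = 1) {
  p <- cfg$promoter
  promoter_params(vmax = p$vmax * vmax_scale, K = p$K, n = p$n,
                  basal = p$basal)
}

#' Run a named analysis scenario
#'
#' Executes one of the package's end-to-end analyses with centralized
#' defaults plus overrides, deterministically for a given seed. Scenarios:
#'
#' * `fig1_sim` — steady-state product and signal vs forward-enzyme level at
#'   several reverse-enzyme levels (threshold/intensity programming).
#' * `wildtype_powerlaw` — the intact-operon transfer function, its local
#'   log-log slopes, and a mid-range power-law fit.
#' * `min_gate`, `pp_gate` — truth table and output dynamic range of the
#'   split-operon soft-minimum gate and the protein-protein gate.
#' * `comparator` — both comparator designs across AHL levels: transfer
#'   curves, detection thresholds, ON/OFF fold changes.
#' * `stress_fits` — katG/recA stress time courses, crosstalk-by-summation,
#'   peak counts.
#' * `iffl` — the crosstalk-compensating circuit for each dose combination,
#'   with peak counts and times.
#'
#' @param scenario one of the scenario names above.
#' @param overrides named list merged over [lux_defaults()].
#' @param out_dir optional directory; when given, tables are written as CSV
#'   and the summary (plus the effective config) as JSON.
#' @param seed integer seed used for any randomness in the scenario.
#' @return List with `scenario`, `seed`, `config` (effective), `tables`
#'   (named list of data frames), `summary` (named list of statistics), and
#'   `elapsed` (seconds).
#' @export
run_scenario <- function(scenario, overrides = list(), out_dir = NULL,
                         seed = 1) {
  if (!scenario %in% scenario_names)
    stop("unknown scenario: ", scenario,
         " (expected one of ", paste(scenario_names, collapse = ", "), ")")
  t0 <- proc.time()[["elapsed"]]
  cfg <- modifyList(lux_defaults(), overrides)
  set.seed(as.integer(seed))
  res <- switch(scenario,
    fig1_sim = scenario_fig1(cfg),
    wildtype_powerlaw = scenario_wildtype(cfg),
    min_gate = scenario_gate(cfg, "min"),
    pp_gate = scenario_gate(cfg, "pp"),
    comparator = scenario_comparator(cfg),
    stress_fits = scenario_stress(cfg),
    iffl = scenario_iffl(cfg))
  out <- list(scenario = scenario, seed = seed, config = cfg,
              tables = res$tables, summary = res$summary,
              elapsed = proc.time()[["elapsed"]] - t0)
  if (!is.null(out_dir)) write_bundle(out, out_dir)
  out
}

write_bundle <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  for (nm in names(out$tables))
    write.csv(out$tables[[nm]],
              file.path(out_dir, paste0(out$scenario, "_", nm, ".csv")),
              row.names = FALSE)
  jsonlite::write_json(
    list(scenario = out$scenario, seed = out$seed, summary = out$summary,
         elapsed_sec = out$elapsed),
    file.path(out_dir, paste0(out$scenario, "_summary.json")),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(out$config,
                       file.path(out_dir, paste0(out$scenario, "_config.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

scenario_fig1 <- function(cfg) {
  lux <- lux_from(cfg)
  ef <- dose_grid_from(cfg)
  er_levels <- c(0.3, 1, 3)
  tab <- do.call(rbind, lapply(er_levels, function(er) {
    data.frame(E_F = ef, E_R = er,
               P_frac = steady_state_product(lux, ef, er) / lux$S_T,
               I = bioluminescence_signal(lux, ef, er))
  }))
  thr <- data.frame(E_R = er_levels, K_deff = k_deff(lux, er_levels))
  list(tables = list(curves = tab, thresholds = thr),
       summary = list(E_R_levels = er_levels,
                      K_deff = thr$K_deff,
                      plateau_I = vapply(er_levels, function(er)
                        bioluminescence_signal(lux, 1e9, er), numeric(1))))
}

scenario_wildtype <- function(cfg) {
  lux <- lux_from(cfg)
  x <- dose_grid_from(cfg)
  dr <- wildtype_operon_response(x, lux)
  sl <- local_loglog_slope(dr)
  mid <- dr$input >= 0.1 & dr$input <= 10
  pl <- fit_power_law(dr$input[mid], dr$output[mid])
  list(tables = list(transfer = data.frame(x = dr$input, I = dr$output),
                     slopes = data.frame(x = dr$input[-c(1, nrow(dr))],
                                         slope = sl)),
       summary = list(min_slope = min(sl), max_slope = max(sl),
                      midrange_exponent = pl$n, midrange_r2 = pl$r2))
}

scenario_gate <- function(cfg, kind) {
  lux <- lux_from(cfg)
  p_arab <- prom_from(cfg, cfg$copy_number$MCP)
  p_ahl <- prom_from(cfg, cfg$copy_number$HCP)
  gate_fun <- if (kind == "min") {
    function(a, b) min_gate_output(a, b, p_arab, p_ahl, lux)
  } else {
    gp <- pp_gate_params(cfg$gate$K_AB)
    p_ahl_mcp <- prom_from(cfg, cfg$copy_number$MCP)
    function(a, b) pp_gate_output(a, b, p_arab, p_ahl_mcp, gp)
  }
  tt <- evaluate_truth_table(gate_fun, p_arab, p_ahl,
                             hi_factor = cfg$gate$hi_factor)
  tab <- data.frame(arab = c(0, 0, 1, 1), ahl = c(0, 1, 0, 1),
                    I = unlist(tt))
  list(tables = list(truth_table = tab),
       summary = list(truth_table = unclass(tt), odr = odr(tt)))
}

scenario_comparator <- function(cfg) {
  lux <- lux_from(cfg)
  p_arab <- prom_from(cfg, cfg$copy_number$MCP)
  p_ahl <- prom_from(cfg, cfg$copy_number$HCP)
  arab <- dose_grid_from(cfg)
  designs <- c("luxCDE-luxAB", "luxA-luxC")
  tabs <- list(); summaries <- list()
  for (d in designs) {
    curves <- lapply(cfg$comparator$ahl_levels, function(a)
      comparator_transfer(arab, a, d, p_arab, p_ahl, lux,
                          luxB_const = cfg$comparator$luxB_const))
    thr <- threshold_series(curves)
    fold <- vapply(curves, function(cv)
      max(cv$output) / min(cv$output), numeric(1))
    key <- gsub("-", "_", d)
    tabs[[paste0(key, "_curves")]] <- do.call(rbind, lapply(curves,
      function(cv) data.frame(arab = cv$input,
                              ahl = attr(cv, "metadata")$ahl,
                              I = cv$output)))
    tabs[[paste0(key, "_thresholds")]] <-
      cbind(thr, fold_change = fold)
    summaries[[key]] <- list(thresholds = thr$threshold,
                             ahl = thr$co_input, fold_change = fold)
  }
  list(tables = tabs, summary = summaries)
}

scenario_stress <- function(cfg) {
  t_grid <- 0:600
  katg <- biosensor_params("katG", X0 = cfg$stress$X0)
  na <- biosensor_params("recA_NA", X0 = cfg$stress$X0)
  h2 <- biosensor_params("recA_H2O2", X0 = cfg$stress$X0)
  traces <- list(
    katG_H2O2 = stress_response(katg, t_grid),
    recA_NA = stress_response(na, t_grid),
    recA_H2O2 = stress_response(h2, t_grid),
    recA_both = combined_response(list(na, h2), t_grid))
  tab <- do.call(rbind, lapply(names(traces), function(nm)
    data.frame(trace = nm, t_min = traces[[nm]]$t_min, I = traces[[nm]]$I)))
  pk <- lapply(traces, count_peaks)
  list(tables = list(time_courses = tab),
       summary = list(peaks = lapply(pk, as.integer),
                      peak_times = lapply(pk, attr, "peak_times")))
}

scenario_iffl <- function(cfg) {
  ip <- iffl_params(tau_delay = cfg$iffl$tau_delay,
                    K_tetr = cfg$iffl$K_tetr, h_tetr = cfg$iffl$h_tetr,
                    sender_scale = cfg$iffl$sender_scale)
  lux <- lux_from(cfg)
  t_grid <- 0:cfg$iffl$t_max
  combos <- list(none = character(0), NA_only = "NA", H2O2_only = "H2O2",
                 both = c("NA", "H2O2"))
  traces <- lapply(combos, function(d)
    iffl_simulate(d, katg_params = biosensor_params("katG",
                                                    X0 = cfg$stress$X0),
                  ip = ip, params = lux, t_grid = t_grid,
                  er_scale = cfg$iffl$er_scale))
  tab <- do.call(rbind, lapply(names(traces), function(nm)
    data.frame(condition = nm, t_min = traces[[nm]]$t_min,
               I = traces[[nm]]$I)))
  pk <- lapply(traces, count_peaks)
  list(tables = list(time_courses = tab),
       summary = list(peaks = lapply(pk, as.integer),
                      peak_times = lapply(pk, attr, "peak_times")))
}

#' Read a run configuration from YAML
#'
#' Expects top-level fields `scenario` (required), `overrides`, `out_dir`
#' and `seed`; returns them as a list suitable for
#' `do.call(run_scenario, cfg)`.
#'
#' @param path path to a YAML file.
#' @return Named list with `scenario`, `overrides`, `out_dir`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$scenario)) stop("config must name a scenario")
  list(scenario = raw$scenario,
       overrides = if (is.null(raw$overrides)) list() else raw$overrides,
       out_dir = raw$out_dir,
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}
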