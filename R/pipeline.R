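#' Load and validate a pipeline run configuration
#'
#' YAML configuration with fields: `task` (one of `simulate`,
#' `fit-binding`, `fit-threestate`, `fit-melting`, `cooperativity`,
#' `chow`, `bicelle`, `solvation`, `report`), `inputs` (named paths),
#' `output_dir`, `seed`, `thermo` (optional `temperature`,
#' `gas_constant` overrides) and `options` (task-specific, mirroring the
#' function arguments of the stage). Validation happens before any
#' computation; referenced input files must exist.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return validated config (class `run_config`).
#' @export
load_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  tasks <- c("simulate", "fit-binding", "fit-threestate", "fit-melting",
             "cooperativity", "chow", "bicelle", "solvation", "report")
  if (is.null(cfg$task) || !cfg$task %in% tasks)
    stop("config error: task must be one of ", paste(tasks, collapse = ", "))
  if (is.null(cfg$output_dir)) stop("config error: output_dir is required")
  for (nm in names(cfg$inputs %||% list())) {
    if (!file.exists(cfg$inputs[[nm]]))
      stop(sprintf("config error: input '%s' (%s) does not exist", nm,
                   cfg$inputs[[nm]]))
  }
  cfg$options <- cfg$options %||% list()
  cfg$seed <- cfg$seed %||% 1L
  class(cfg) <- "run_config"
  cfg
}

pipeline_log <- function(con, msg) {
  writeLines(sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), msg), con)
}

config_context <- function(cfg, default_temp = 297.65) {
  th <- cfg$thermo %||% list()
  thermo_context(th$temperature %||% default_temp,
                 th$gas_constant %||% 1.987e-3)
}

#' Run one pipeline stage
#'
#' Executes the configured task deterministically (given `seed`), writes
#' its result files and a machine-readable summary (`summary.yaml`) into
#' `output_dir`, and appends to `run.log` a line for every default that
#' was applied. Inputs are never modified.
#'
#' @param config a [load_run_config()] result, a config list, or a YAML
#'   path.
#' @return invisibly, a list of the stage's results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else load_run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(cfg$output_dir, "run.log"), "a")
  on.exit(close(logcon))
  pipeline_log(logcon, sprintf("task=%s seed=%d", cfg$task, cfg$seed))
  opt <- cfg$options
  out <- switch(cfg$task,
    "simulate" = stage_simulate(cfg, opt, logcon),
    "fit-binding" = stage_fit_binding(cfg, opt, logcon),
    "fit-threestate" = stage_fit_threestate(cfg, opt, logcon),
    "fit-melting" = stage_fit_melting(cfg, opt, logcon),
    "cooperativity" = stage_cooperativity(cfg, opt, logcon),
    "chow" = stage_chow(cfg, opt, logcon),
    "bicelle" = stage_bicelle(cfg, opt, logcon),
    "solvation" = stage_solvation(cfg, opt, logcon),
    "report" = list(report = pipeline_report(cfg$output_dir)))
  yaml::write_yaml(summarize_results(out),
                   file.path(cfg$output_dir, "summary.yaml"))
  pipeline_log(logcon, sprintf("task=%s done", cfg$task))
  invisible(out)
}

summarize_results <- function(x) {
  f <- function(v) {
    if (inherits(v, c("binding_fit", "melting_fit", "three_state_fit")))
      lapply(as.list(v$estimate), as.numeric)
    else if (is.numeric(v)) as.list(v)
    else if (is.data.frame(v)) list(rows = nrow(v))
    else if (is.list(v) && !is.null(v$dg_solv)) list(dg_solv = v$dg_solv)
    else NULL
  }
  out <- lapply(x, f)
  out[!vapply(out, is.null, TRUE)]
}

stage_simulate <- function(cfg, opt, logcon) {
  model <- opt$model %||% "second"
  pipeline_log(logcon, sprintf("simulate model=%s", model))
  if (model %in% c("first", "competition", "second")) {
    truth <- opt$truth %||% {
      pipeline_log(logcon, "default truth applied: K_D 1e-4, Kd,biotin 2e-5 uM, plateaus 1 -> 0.1")
      list(k_denat = 1e-4, kd_biotin = 2e-5, f0 = 1, f_inf = 0.1, protein_total = 1)
    }
    sim <- sim_binding_titration(model, truth,
                                 n_points = opt$n_points %||% 12,
                                 noise_sigma = opt$noise_sigma %||% 0.01,
                                 seed = cfg$seed)
    data_path <- file.path(cfg$output_dir, sprintf("sim_%s.csv", model))
    write_titration_csv(sim$titration, data_path, model = model)
    write_sidecar_yaml(sim, paste0(data_path, ".yaml"))
    return(list(sim = sim$titration, path = data_path))
  }
  if (model == "melting") {
    truth <- opt$truth %||% list(tm = 24, b = 1.5, m1 = 0, r1_0 = -0.2,
                                 m2 = 0, r2_0 = 0.3)
    sim <- sim_melting_curve(truth, n_points = opt$n_points %||% 40,
                             noise_sigma = opt$noise_sigma %||% 0.005,
                             seed = cfg$seed)
    data_path <- file.path(cfg$output_dir, "sim_melting.csv")
    write_melting_csv(sim$temperature, sim$anisotropy, data_path)
    write_sidecar_yaml(sim, paste0(data_path, ".yaml"))
    return(list(sim = data.frame(temp_C = sim$temperature,
                                 anisotropy = sim$anisotropy),
                path = data_path))
  }
  if (model == "denaturation") {
    tr <- opt$truth %||% list(dg_ni = -5.4, dg_iu = -26.4, m_ni = 2, m_iu = 7.2)
    truth <- three_state_params(tr$dg_ni, tr$dg_iu, tr$m_ni, tr$m_iu)
    sim <- sim_denaturation_titration(truth, n_points = opt$n_points %||% 17,
                                      noise_sigma = opt$noise_sigma %||% 0.01,
                                      seed = cfg$seed)
    data_path <- file.path(cfg$output_dir, "sim_denaturation.csv")
    write_denaturation_csv(sim$denaturant, sim$signal, data_path)
    write_sidecar_yaml(sim, paste0(data_path, ".yaml"))
    return(list(sim = data.frame(gdnhcl_M = sim$denaturant,
                                 norm_fluor = sim$signal),
                path = data_path))
  }
  if (model == "contacts") {
    sim <- sim_contact_traces(k_on = opt$k_on %||% 0.0125,
                              k_off = opt$k_off %||% 0.025,
                              n_molecules = opt$n_molecules %||% 20,
                              duration = opt$duration %||% 1000,
                              frame_interval = opt$frame_interval %||% 0.5,
                              seed = cfg$seed)
    data_path <- file.path(cfg$output_dir, "sim_contacts.tsv")
    write_contact_tsv(sim$traces, data_path)
    write_sidecar_yaml(sim, paste0(data_path, ".yaml"))
    return(list(sim = sim$traces, path = data_path))
  }
  if (model == "panel") {
    sim <- sim_mutant_panel(n_mutants = opt$n_mutants %||% 37,
                            true_slope = opt$true_slope %||% 1,
                            noise_sigma = opt$noise_sigma %||% 0.3,
                            seed = cfg$seed)
    data_path <- file.path(cfg$output_dir, "sim_panel.csv")
    write_panel_csv(sim$panel, data_path)
    write_sidecar_yaml(sim, paste0(data_path, ".yaml"))
    return(list(sim = sim$panel, path = data_path))
  }
  stop("config error: unknown simulate model '", model, "'")
}

stage_fit_binding <- function(cfg, opt, logcon) {
  titr <- read_titration_csv(cfg$inputs$titration)
  model <- opt$model %||% attr(titr, "metadata")$model %||% "first"
  ctx <- config_context(cfg)
  fixed <- opt$fixed %||% list()
  fit <- fit_binding_model(titr, model, fixed = fixed, context = ctx)
  write_fit_csv(fit, file.path(cfg$output_dir, "binding_fit.csv"))
  pipeline_log(logcon, sprintf("fit-binding model=%s rss=%.4g", model, fit$rss))
  list(fit = fit)
}

stage_fit_threestate <- function(cfg, opt, logcon) {
  df <- read_denaturation_csv(cfg$inputs$titration)
  ctx <- config_context(cfg, default_temp = 310.15)
  fixed_m <- if (!is.null(opt$fixed_m)) as.numeric(opt$fixed_m) else NULL
  fit <- fit_three_state(df$gdnhcl_M, df$norm_fluor, fixed_m = fixed_m,
                         baseline = opt$baseline %||% "linear", context = ctx)
  write_fit_csv(fit, file.path(cfg$output_dir, "threestate_fit.csv"))
  ls <- landscape_summary(fit)
  utils::write.csv(data.frame(state = names(ls$levels),
                              level_kcal_per_mol = unname(ls$levels)),
                   file.path(cfg$output_dir, "landscape.csv"), row.names = FALSE,
                   quote = FALSE)
  pipeline_log(logcon, sprintf("fit-threestate total=%.2f kcal/mol", ls$total))
  list(fit = fit, landscape = ls)
}

stage_fit_melting <- function(cfg, opt, logcon) {
  df <- read_melting_csv(cfg$inputs$curve)
  fit <- fit_melting(df$temp_C, df$anisotropy)
  write_fit_csv(fit, file.path(cfg$output_dir, "melting_fit.csv"))
  pipeline_log(logcon, sprintf("fit-melting Tm=%.2f C", fit$estimate["tm"]))
  list(fit = fit)
}

stage_cooperativity <- function(cfg, opt, logcon) {
  panel <- read_panel_csv(cfg$inputs$panel)
  ctx <- config_context(cfg)
  calls <- cooperativity_calls(panel, ctx, scheme = opt$scheme %||% "standard",
                               rt_cutoff = opt$rt_cutoff)
  utils::write.csv(calls, file.path(cfg$output_dir, "cooperativity_calls.csv"),
                   row.names = FALSE, quote = FALSE)
  if (isTRUE(opt$residue_attributes) && "residue_number" %in% names(panel)) {
    utils::write.table(data.frame(residue_number = panel$residue_number,
                                  label = calls$label),
                       file.path(cfg$output_dir, "residue_labels.txt"),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  pipeline_log(logcon, sprintf("cooperativity n=%d scheme=%s", nrow(calls),
                               opt$scheme %||% "standard"))
  list(calls = calls)
}

stage_chow <- function(cfg, opt, logcon) {
  panel <- read_panel_csv(cfg$inputs$panel)
  missing_f <- sum(is.na(panel$f_asa))
  if (missing_f > 0)
    pipeline_log(logcon, sprintf("excluded %d rows with missing f_asa", missing_f))
  panel <- panel[!is.na(panel$f_asa), ]
  panel$burial <- burial_class(panel$f_asa)
  groups <- opt$groups %||% c("buried", "exposed")
  g1 <- panel[panel$burial == groups[1], ]
  g2 <- panel[panel$burial == groups[2], ]
  res <- chow_test(g1$ddg_C, g1$ddg_N, g2$ddg_C, g2$ddg_N)
  write_results_csv(list(chow_F = res$chow_F %||% NA_real_,
                         chow_p = res$chow_p %||% NA_real_,
                         slope1 = res$group1$slope, slope2 = res$group2$slope,
                         n1 = res$group1$n, n2 = res$group2$n,
                         degenerate = as.numeric(res$degenerate)),
                    file.path(cfg$output_dir, "chow.csv"))
  pipeline_log(logcon, sprintf("chow groups=%s/%s F=%.4g", groups[1], groups[2],
                               res$chow_F %||% NA))
  list(chow = res)
}

stage_bicelle <- function(cfg, opt, logcon) {
  out <- list()
  if (!is.null(opt$lipid_total)) {
    cbc <- opt$cbc %||% {
      pipeline_log(logcon, "default CBC applied: 2.5 mM (CHAPS)")
      default_cbc[["CHAPS"]]
    }
    out$q_eff <- q_eff_fixed_cbc(opt$lipid_total, opt$detergent_total, cbc)
  }
  if (!is.null(opt$chi_lipid))
    out$cbc_ideal <- cbc_ideal_mixing(opt$chi_lipid, opt$cmc_lipid %||% 6e-6,
                                      opt$cmc_detergent %||% 6)
  if (!is.null(cfg$inputs$spectrum)) {
    sp <- read_spectrum_csv(cfg$inputs$spectrum)
    out$gp <- as.numeric(gp_laurdan(sp$wavelength_nm, sp$intensity))
  }
  if (!is.null(cfg$inputs$curve)) {
    df <- read_melting_csv(cfg$inputs$curve)
    out$tm <- unname(fit_melting(df$temp_C, df$anisotropy)$estimate["tm"])
  }
  if (!is.null(opt$q_second_max))
    out$thickness_A <- thickness_from_peak(opt$q_second_max)
  if (!length(out)) stop("config error: bicelle stage received nothing to compute")
  write_results_csv(out, file.path(cfg$output_dir, "bicelle.csv"))
  list(bicelle = unlist(out))
}

stage_solvation <- function(cfg, opt, logcon) {
  traces <- read_contact_tsv(cfg$inputs$contacts)
  roles <- vapply(traces, function(tr) tr$role, "")
  ctx <- config_context(cfg, default_temp = 310)
  max_lag <- opt$max_lag %||% {
    dt <- traces[[1]]$frame_interval
    0.5 * min(vapply(traces, function(tr) length(tr$q), 1L)) * dt
  }
  gap <- opt$gap_threshold %||% 0
  tau_of <- function(role) {
    acr <- contact_autocorr(traces[roles == role], max_lag = max_lag,
                            gap_threshold = gap)
    residence_time(fit_triple_exp(acr))$tau_r
  }
  tau_p <- tau_of("protein_contact")
  tau_b <- tau_of("bulk_pair")
  sol <- solvation_dg(tau_p, tau_b, ctx)
  write_results_csv(list(
    tau_r_protein = list(value = tau_p, units = "ns"),
    tau_r_bulk = list(value = tau_b, units = "ns"),
    dg_solv = list(value = sol$dg_solv, units = "kcal/mol")),
    file.path(cfg$output_dir, "solvation.csv"))
  pipeline_log(logcon, sprintf("solvation dg=%.3f kcal/mol (gap=%.3g ns)",
                               sol$dg_solv, gap))
  list(solvation = sol)
}

#' Assemble a human-readable report from stage outputs
#'
#' Collects the result CSVs a set of [run_pipeline()] calls wrote into
#' `dir` and formats one consolidated plain-text report (no
#' recomputation). Errors if the directory holds no recognizable
#' results.
#'
#' @param dir output directory of previous stages.
#' @return character vector of report lines (also written to
#'   `report.txt` in `dir`), invisibly.
#' @export
pipeline_report <- function(dir) {
  known <- c("binding_fit.csv", "melting_fit.csv", "threestate_fit.csv",
             "landscape.csv", "cooperativity_calls.csv", "chow.csv",
             "bicelle.csv", "solvation.csv")
  present <- known[file.exists(file.path(dir, known))]
  if (!length(present)) stop("no stage results found in ", dir)
  lines <- c("Pipeline report", strrep("=", 15), "")
  for (f in present) {
    df <- utils::read.csv(file.path(dir, f))
    lines <- c(lines, f, strrep("-", nchar(f)))
    if (all(c("param", "estimate") %in% names(df))) {
      se <- if ("se" %in% names(df)) df$se else NA
      lines <- c(lines, sprintf("  %-14s %10.4g +/- %.3g", df$param, df$estimate, se))
    } else if (all(c("quantity", "value") %in% names(df))) {
      lines <- c(lines, sprintf("  %-14s %10.4g %s", df$quantity, df$value,
                                ifelse(is.na(df$units) | df$units == "", "",
                                       as.character(df$units))))
    } else {
      lines <- c(lines, utils::capture.output(print(utils::head(df, 10))))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(lines)
}
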