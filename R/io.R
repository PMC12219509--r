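# CSV/TSV dialects shared by the generators and the fitting stages.
# Titration-style files carry `# key=value` metadata header lines before
# the column header; readers parse them into an attribute.

read_metadata_lines <- function(path) {
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(kv, 1, eq - 1))
      val <- trimws(substr(kv, eq + 1, nchar(kv)))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

#' Read and write titration CSV files
#'
#' The titration dialect has columns `conc_uM, signal` preceded by
#' metadata header lines such as `# protein_total_uM=1`, `# model=second`
#' and (for competition data) `# labeled_total_uM=`. `read_titration_csv()`
#' returns the matching titration object with the metadata in
#' `attr(, "metadata")`.
#'
#' @param path file path.
#' @return [binding_titration()] or [competition_titration()] depending
#'   on `# model=`.
#' @export
read_titration_csv <- function(path) {
  meta <- read_metadata_lines(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("conc_uM", "signal") %in% names(df)))
    stop(sprintf("parse error in %s: expected columns conc_uM, signal", path))
  if (is.null(meta$protein_total_uM))
    stop(sprintf("parse error in %s: missing '# protein_total_uM=' header", path))
  model <- meta$model %||% "first"
  obj <- if (identical(model, "competition")) {
    if (is.null(meta$labeled_total_uM))
      stop(sprintf("parse error in %s: competition data need '# labeled_total_uM='", path))
    competition_titration(df$conc_uM, df$signal, meta$labeled_total_uM,
                          meta$protein_total_uM, label = meta$label %||% "")
  } else {
    binding_titration(df$conc_uM, df$signal, meta$protein_total_uM,
                      label = meta$label %||% "")
  }
  attr(obj, "metadata") <- meta
  obj
}

#' @rdname read_titration_csv
#' @param titration a titration object.
#' @param model model tag written to the `# model=` header.
#' @export
write_titration_csv <- function(titration, path, model = "first") {
  if (inherits(titration, "competition_titration")) {
    header <- c(sprintf("# protein_total_uM=%.10g", titration$protein_total),
                sprintf("# labeled_total_uM=%.10g", titration$labeled_total),
                "# model=competition",
                sprintf("# label=%s", titration$label))
    df <- data.frame(conc_uM = titration$competitor_total, signal = titration$signal)
  } else {
    header <- c(sprintf("# protein_total_uM=%.10g", titration$protein_total),
                sprintf("# model=%s", model),
                sprintf("# label=%s", titration$label))
    df <- data.frame(conc_uM = titration$msa_total, signal = titration$signal)
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit result as flat key-value CSV
#'
#' Rows of `param, estimate, se` for any fit object exposing `estimate`
#' and `se` vectors (binding, melting, three-state fits).
#'
#' @param fit a fit object. @param path output file.
#' @export
write_fit_csv <- function(fit, path) {
  est <- fit$estimate
  se <- fit$se[names(est)]
  se[is.na(se)] <- NA_real_
  df <- data.frame(param = names(est), estimate = unname(est), se = unname(se))
  if (!is.null(fit$dg_nd))
    df <- rbind(df, data.frame(param = c("dg_nd"), estimate = fit$dg_nd,
                               se = fit$dg_se))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write mutant-panel CSV files
#'
#' Layout `mutation, ddg_N, se_N, ddg_C, se_C, f_asa, environment`;
#' empty `f_asa` cells are missing values.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("mutation", "ddg_N", "ddg_C")
  if (!all(need %in% names(df)))
    stop(sprintf("parse error in %s: expected columns %s", path,
                 paste(need, collapse = ", ")))
  df
}

#' @rdname read_panel_csv
#' @param panel data.frame in the panel layout.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write melting-curve CSV files (`temp_C, anisotropy`)
#' @param path file path.
#' @return data.frame with `temp_C`, `anisotropy`.
#' @export
read_melting_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("temp_C", "anisotropy") %in% names(df)))
    stop(sprintf("parse error in %s: expected columns temp_C, anisotropy", path))
  df
}

#' @rdname read_melting_csv
#' @param temperature,anisotropy curve vectors.
#' @export
write_melting_csv <- function(temperature, anisotropy, path) {
  utils::write.csv(data.frame(temp_C = temperature, anisotropy = anisotropy),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an emission-spectrum CSV (`wavelength_nm, intensity`)
#' @param path file path.
#' @return data.frame.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop(sprintf("parse error in %s: expected columns wavelength_nm, intensity", path))
  df
}

#' Read and write denaturation-titration CSV files
#'
#' Layout `gdnhcl_M, norm_fluor, direction` with direction in
#' `folding`/`unfolding`/`pooled`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_denaturation_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gdnhcl_M", "norm_fluor") %in% names(df)))
    stop(sprintf("parse error in %s: expected columns gdnhcl_M, norm_fluor", path))
  df
}

#' @rdname read_denaturation_csv
#' @param denaturant,signal titration vectors.
#' @param direction direction label(s).
#' @export
write_denaturation_csv <- function(denaturant, signal, path,
                                   direction = "pooled") {
  utils::write.csv(data.frame(gdnhcl_M = denaturant, norm_fluor = signal,
                              direction = direction),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write contact-trace TSV files
#'
#' Long layout `molecule_id, role, part, frame, q` with a
#' `# frame_interval_ns=` header line.
#'
#' @param path file path.
#' @return list of [contact_trace()]s.
#' @export
read_contact_tsv <- function(path) {
  meta <- read_metadata_lines(path)
  if (is.null(meta$frame_interval_ns))
    stop(sprintf("parse error in %s: missing '# frame_interval_ns=' header", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("molecule_id", "role", "part", "frame", "q")
  if (!all(need %in% names(df)))
    stop(sprintf("parse error in %s: expected columns %s", path,
                 paste(need, collapse = ", ")))
  key <- paste(df$molecule_id, df$role, df$part, sep = "\r")
  split_df <- split(df, factor(key, levels = unique(key)))
  lapply(split_df, function(d) {
    d <- d[order(d$frame), ]
    contact_trace(d$q, meta$frame_interval_ns, molecule_id = d$molecule_id[1],
                  role = d$role[1], part = d$part[1])
  })
}

#' @rdname read_contact_tsv
#' @param traces list of [contact_trace()]s.
#' @export
write_contact_tsv <- function(traces, path) {
  if (inherits(traces, "contact_trace")) traces <- list(traces)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# frame_interval_ns=%.10g", traces[[1]]$frame_interval), con)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(molecule_id = tr$molecule_id, role = tr$role, part = tr$part,
               frame = seq_along(tr$q), q = tr$q)
  }))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a named list of results as key-value CSV
#'
#' Rows of `quantity, value` (plus optional `units`/`flag` columns when
#' the entries are lists with those fields).
#'
#' @param results named list or named numeric vector.
#' @param path output file.
#' @export
write_results_csv <- function(results, path) {
  if (is.numeric(results)) results <- as.list(results)
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    if (is.list(x)) {
      data.frame(quantity = nm, value = x$value,
                 units = x$units %||% "", flag = x$flag %||% "")
    } else {
      data.frame(quantity = nm, value = x, units = "", flag = "")
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generator sidecar metadata file (YAML)
#'
#' Records the generator spec (seed, grid, noise model) and the
#' ground-truth parameter set next to a simulated data file.
#'
#' @param sim a generator result (list with `truth` and `spec`).
#' @param path output `.yaml` path.
#' @export
write_sidecar_yaml <- function(sim, path) {
  truth <- sim$truth
  if (inherits(truth, "three_state_params"))
    truth <- list(dg_ni = truth$dg_ni, dg_iu = truth$dg_iu,
                  m_ni = truth$m_ni, m_iu = truth$m_iu,
                  baselines = truth$baselines)
  yaml::write_yaml(list(truth = truth, spec = sim$spec), path)
  invisible(path)
}
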