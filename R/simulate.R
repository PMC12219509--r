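# All generators draw from R's Mersenne-Twister stream seeded per call and
# restore the caller's RNG state, so a fixed (seed, spec) pair is
# bit-reproducible and never perturbs the session stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate a steric-trapping binding titration
#'
#' Forward-models one of the three isotherms ([eval_first_binding()],
#' [eval_competition()], [eval_second_binding()]) on a log-spaced mSA
#' grid (default 0-60 uM, zero point included, matching the plate
#' design) and adds independent homoscedastic Gaussian noise.
#'
#' @param model `"first"`, `"competition"` or `"second"`.
#' @param truth named list of ground-truth parameters:
#'   first: `kd_biotin`, `amplitude`, `offset`, `protein_total`;
#'   competition: `k_ratio`, `amplitude`, `offset`, `protein_total`,
#'   `labeled_total`; second: `k_denat`, `kd_biotin`, `f0`, `f_inf`,
#'   `protein_total`.
#' @param n_points number of titration points (>= 4), including the
#'   zero-concentration point.
#' @param noise_sigma Gaussian noise SD in signal units (>= 0).
#' @param seed RNG seed.
#' @param conc_range range of the positive log-spaced grid (uM).
#' @param include_zero prepend a zero-concentration point.
#' @return list with `titration` (a [binding_titration()] or
#'   [competition_titration()]), `truth`, and `spec` (the generator
#'   settings, including seed and noise model).
#' @export
sim_binding_titration <- function(model = c("first", "competition", "second"),
                                  truth, n_points = 12, noise_sigma = 0.01,
                                  seed = NULL, conc_range = c(0.05, 60),
                                  include_zero = TRUE) {
  model <- match.arg(model)
  stopifnot(n_points >= 4, noise_sigma >= 0, conc_range[1] > 0,
            conc_range[2] > conc_range[1])
  n_pos <- n_points - as.integer(include_zero)
  conc <- exp(seq(log(conc_range[1]), log(conc_range[2]), length.out = n_pos))
  if (include_zero) conc <- c(0, conc)
  pt <- truth$protein_total %||% 1
  clean <- switch(model,
    first = eval_first_binding(conc, truth$kd_biotin, truth$amplitude,
                               truth$offset, pt),
    competition = eval_competition(conc, truth$k_ratio, truth$amplitude,
                                   truth$offset, pt, truth$labeled_total),
    second = eval_second_binding(conc, truth$k_denat, truth$kd_biotin,
                                 truth$f0, truth$f_inf))
  noisy <- with_local_seed(seed, clean + stats::rnorm(length(clean), 0, noise_sigma))
  titr <- if (model == "competition") {
    competition_titration(conc, noisy, truth$labeled_total, pt,
                          label = sprintf("sim-%s", model))
  } else {
    binding_titration(conc, noisy, pt, label = sprintf("sim-%s", model))
  }
  list(titration = titr, truth = truth,
       spec = list(model = model, n_points = n_points, noise_sigma = noise_sigma,
                   seed = seed, grid = "log", conc_range = conc_range,
                   noise = "additive independent homoscedastic Gaussian"))
}

#' Simulate a chemical-denaturation titration
#'
#' Forward-models the three-state observable ([predict_observable()]) on
#' a linear GdnHCl grid (default 1-5 M) with Gaussian signal noise. If a
#' transition midpoint falls outside the grid the output carries
#' `spec$midpoint_warning = TRUE`.
#'
#' @param truth a [three_state_params()].
#' @param n_points number of points (>= 8). @param d_range grid (M).
#' @param noise_sigma Gaussian noise SD (signal units).
#' @param seed RNG seed. @param context a [thermo_context()].
#' @return list with `denaturant`, `signal`, `truth`, `spec`.
#' @export
sim_denaturation_titration <- function(truth, n_points = 17, d_range = c(1, 5),
                                       noise_sigma = 0.01, seed = NULL,
                                       context = thermo_context(310.15)) {
  stopifnot(inherits(truth, "three_state_params"), n_points >= 8, noise_sigma >= 0)
  d <- seq(d_range[1], d_range[2], length.out = n_points)
  clean <- predict_observable(truth, d, context)$signal
  noisy <- with_local_seed(seed, clean + stats::rnorm(length(clean), 0, noise_sigma))
  mids <- landscape_summary(truth)$midpoints
  warn <- any(mids < d_range[1]) || any(mids > d_range[2])
  list(denaturant = d, signal = noisy, truth = truth,
       spec = list(n_points = n_points, d_range = d_range,
                   noise_sigma = noise_sigma, seed = seed, grid = "linear",
                   midpoint_warning = warn,
                   noise = "additive independent homoscedastic Gaussian"))
}

#' Simulate a DPH anisotropy melting curve
#'
#' Forward-models the sloped-baseline sigmoid ([eval_melting()]) on an
#' even temperature grid (default 3.0-42.5 C, the experimental sweep)
#' with Gaussian anisotropy noise.
#'
#' @param truth named list: `tm`, `b`, `m1`, `r1_0`, `m2`, `r2_0`.
#' @param n_points number of temperatures (>= 8).
#' @param t_range temperature range (deg C); must contain `truth$tm`.
#' @param noise_sigma anisotropy noise SD. @param seed RNG seed.
#' @return list with `temperature`, `anisotropy`, `truth`, `spec`.
#' @export
sim_melting_curve <- function(truth, n_points = 40, t_range = c(3, 42.5),
                              noise_sigma = 0.005, seed = NULL) {
  stopifnot(n_points >= 8, noise_sigma >= 0)
  if (truth$tm < t_range[1] || truth$tm > t_range[2])
    stop("truth$tm must lie inside t_range")
  tt <- seq(t_range[1], t_range[2], length.out = n_points)
  clean <- eval_melting(tt, truth$tm, truth$b, truth$m1 %||% 0, truth$r1_0,
                        truth$m2 %||% 0, truth$r2_0)
  noisy <- with_local_seed(seed, clean + stats::rnorm(length(clean), 0, noise_sigma))
  list(temperature = tt, anisotropy = noisy, truth = truth,
       spec = list(n_points = n_points, t_range = t_range,
                   noise_sigma = noise_sigma, seed = seed,
                   noise = "additive independent homoscedastic Gaussian"))
}

#' Simulate two-state contact traces
#'
#' Continuous-time two-state (bound/unbound) kinetics per molecule with
#' exponential dwell times (unbinding rate `k_off`, rebinding rate
#' `k_on`), discretized onto the frame grid (a frame is in contact when
#' its midpoint time lies in a bound interval). Bound frames carry a
#' constant contact count or Poisson-distributed counts
#' (`count_model = "poisson"`, zero-truncated so bound frames stay in
#' contact). Molecules start bound so `k_on = 0` yields exactly one
#' event per molecule.
#'
#' @param k_on rebinding rate (1/ns), >= 0.
#' @param k_off unbinding rate (1/ns), > 0.
#' @param n_molecules number of independent molecules.
#' @param duration trace length (ns). @param frame_interval ns, > 0;
#'   a warning is raised when it reaches the mean bound dwell 1/k_off
#'   (aliasing).
#' @param seed RNG seed.
#' @param count_model `"constant"` or `"poisson"`.
#' @param count_mean contact count while bound (constant value or
#'   Poisson mean).
#' @param role,part passed to [contact_trace()].
#' @return list with `traces` (list of [contact_trace()]), `truth`
#'   (rates and the implied residence time 1/k_off), `spec`.
#' @export
sim_contact_traces <- function(k_on, k_off, n_molecules = 50, duration = 2000,
                               frame_interval = 0.5, seed = NULL,
                               count_model = c("constant", "poisson"),
                               count_mean = 8,
                               role = "protein_contact", part = "whole") {
  count_model <- match.arg(count_model)
  stopifnot(k_on >= 0, k_off > 0, n_molecules >= 1, duration > 0,
            frame_interval > 0)
  if (frame_interval >= 1 / k_off)
    warning("frame_interval >= mean bound dwell (1/k_off): events will alias")
  n_frames <- floor(duration / frame_interval)
  t_mid <- (seq_len(n_frames) - 0.5) * frame_interval
  traces <- with_local_seed(seed, {
    lapply(seq_len(n_molecules), function(mol) {
      q <- numeric(n_frames)
      t_cur <- 0; bound <- TRUE
      while (t_cur < duration) {
        dwell <- if (bound) stats::rexp(1, k_off)
                 else if (k_on > 0) stats::rexp(1, k_on) else Inf
        t_next <- min(t_cur + dwell, duration)
        if (bound) {
          idx <- which(t_mid > t_cur & t_mid <= t_next)
          if (length(idx)) {
            q[idx] <- if (count_model == "constant") count_mean
                      else pmax(1, stats::rpois(length(idx), count_mean))
          }
        }
        if (is.infinite(dwell)) break
        t_cur <- t_next; bound <- !bound
      }
      contact_trace(q, frame_interval, molecule_id = mol, role = role, part = part)
    })
  })
  list(traces = traces,
       truth = list(k_on = k_on, k_off = k_off, tau_r = 1 / k_off),
       spec = list(n_molecules = n_molecules, duration = duration,
                   frame_interval = frame_interval, seed = seed,
                   count_model = count_model, count_mean = count_mean,
                   noise = "exponential dwell times; counts constant or Poisson"))
}

#' Simulate a mutant panel for cooperativity and slope analyses
#'
#' Generates paired subdomain stability changes with a prescribed linear
#' relationship: `ddg_C` drawn uniformly over `x_range`, then
#' `ddg_N = intercept + true_slope * ddg_C + noise`. Burial classes are
#' assigned per `burial_mix` with representative f_ASA values (buried:
#' exactly 0; partially buried: (0, 0.1]; exposed: (0.1, 1]). Supports
#' the null scenario (slope 1, zero intercept) and alternatives for
#' Chow-test power studies.
#'
#' @param n_mutants number of mutations (>= 6).
#' @param true_slope slope of ddg_N on ddg_C. @param intercept offset.
#' @param noise_sigma Gaussian noise SD on ddg_N (kcal/mol).
#' @param burial_mix named proportions for `buried`,
#'   `partially_buried`, `exposed` (normalized internally).
#' @param x_range range of ddg_C draws (kcal/mol).
#' @param se measurement SE attached to each value.
#' @param seed RNG seed. @param environment environment label.
#' @return list with `panel` (data.frame in the panel-CSV layout),
#'   `truth`, `spec`.
#' @export
sim_mutant_panel <- function(n_mutants = 37, true_slope = 1, intercept = 0,
                             noise_sigma = 0.3,
                             burial_mix = c(buried = 1/3, partially_buried = 1/3,
                                            exposed = 1/3),
                             x_range = c(-0.5, 3), se = 0.2, seed = NULL,
                             environment = "bicelle") {
  stopifnot(n_mutants >= 6, noise_sigma >= 0, se >= 0)
  burial_mix <- burial_mix / sum(burial_mix)
  panel <- with_local_seed(seed, {
    x <- stats::runif(n_mutants, x_range[1], x_range[2])
    y <- intercept + true_slope * x + stats::rnorm(n_mutants, 0, noise_sigma)
    cls <- sample(names(burial_mix), n_mutants, replace = TRUE, prob = burial_mix)
    f_asa <- ifelse(cls == "buried", 0,
             ifelse(cls == "partially_buried", stats::runif(n_mutants, 0.001, 0.1),
                    stats::runif(n_mutants, 0.101, 1)))
    data.frame(mutation = sprintf("M%03d", seq_len(n_mutants)),
               ddg_N = y, se_N = se, ddg_C = x, se_C = se,
               f_asa = f_asa, environment = environment,
               stringsAsFactors = FALSE)
  })
  list(panel = panel,
       truth = list(true_slope = true_slope, intercept = intercept,
                    noise_sigma = noise_sigma),
       spec = list(n_mutants = n_mutants, burial_mix = as.list(burial_mix),
                   x_range = x_range, se = se, seed = seed,
                   noise = "additive independent homoscedastic Gaussian"))
}
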