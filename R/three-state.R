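#' Three-state folding parameter set
#'
#' Parameters of the N <-> I <-> U chemical-denaturation model: two
#' transition free energies at zero denaturant (folding sign convention,
#' negative for favorable folding), two m-values (denaturant dependence
#' of the transition free energies), and three linear signal baselines.
#'
#' Equilibrium constants are unfolding constants built from the
#' magnitudes of the transition free energies,
#' \eqn{K = \exp(-(|\Delta G| - m [D]) / RT)}, so that the native state
#' dominates at zero denaturant for a stable protein while the reported
#' parameters keep the folding sign of the landscape.
#'
#' @param dg_ni,dg_iu transition free energies (kcal/mol), reported with
#'   the folding sign (typically negative).
#' @param m_ni,m_iu m-values (kcal mol^-1 M^-1), > 0.
#' @param baselines named list of `(intercept, slope)` pairs for the
#'   `N`, `I` and `U` states: `list(N = c(i, s), I = c(i, s),
#'   U = c(i, s))`.
#' @return An object of class `three_state_params`.
#' @examples
#' dc12pc <- three_state_params(-5.4, -26.4, 2.0, 7.2)
#' landscape_summary(dc12pc)
#' @export
three_state_params <- function(dg_ni, dg_iu, m_ni, m_iu,
                               baselines = list(N = c(0, 0), I = c(0.5, 0),
                                                U = c(1, 0))) {
  stopifnot(is.finite(dg_ni), is.finite(dg_iu))
  if (!is.finite(m_ni) || m_ni <= 0 || !is.finite(m_iu) || m_iu <= 0)
    stop("m values must be > 0")
  if (!all(c("N", "I", "U") %in% names(baselines)) ||
      !all(vapply(baselines[c("N", "I", "U")], length, 1L) == 2L))
    stop("baselines must be a list with length-2 (intercept, slope) entries N, I, U")
  structure(list(dg_ni = dg_ni, dg_iu = dg_iu, m_ni = m_ni, m_iu = m_iu,
                 baselines = baselines[c("N", "I", "U")]),
            class = "three_state_params")
}

#' @export
print.three_state_params <- function(x, ...) {
  cat(sprintf("Three-state folding parameters:\n  dG(N-I) = %.2f, dG(I-U) = %.2f kcal/mol\n  m(N-I) = %.2f, m(I-U) = %.2f kcal/(mol M)\n",
              x$dg_ni, x$dg_iu, x$m_ni, x$m_iu))
  invisible(x)
}

#' Unfolding equilibrium constants at a denaturant concentration
#'
#' \deqn{K_{N-I} = e^{-(|\Delta G_{N-I}| - m_{N-I} [D])/RT}, \quad
#'   K_{I-U} = e^{-(|\Delta G_{I-U}| - m_{I-U} [D])/RT}.}
#' Both are monotone increasing in denaturant; K = 1 at the transition
#' midpoint \eqn{C_m = |\Delta G|/m}. Returned on the log scale as well,
#' for overflow-safe downstream use.
#'
#' @param params a [three_state_params()].
#' @param d denaturant concentration(s) (M).
#' @param context a [thermo_context()]; the denaturation experiments
#'   equilibrate at 37 C (310.15 K).
#' @return list with `k_ni`, `k_iu` and `log_k_ni`, `log_k_iu`.
#' @export
equilibrium_constants <- function(params, d, context = thermo_context(310.15)) {
  stopifnot(inherits(params, "three_state_params"))
  ctx <- as_thermo_context(context)
  log_k_ni <- -(abs(params$dg_ni) - params$m_ni * d) / ctx$rt
  log_k_iu <- -(abs(params$dg_iu) - params$m_iu * d) / ctx$rt
  list(k_ni = exp(log_k_ni), k_iu = exp(log_k_iu),
       log_k_ni = log_k_ni, log_k_iu = log_k_iu)
}

#' Predict the three-state folding observable
#'
#' \deqn{Y_{obs} = \frac{Y_N + Y_I K_{N-I} + Y_U K_{N-I} K_{I-U}}
#'   {1 + K_{N-I} + K_{N-I} K_{I-U}}, \qquad Y_X = I_X + S_X [D],}
#' evaluated in log space (log-sum-exp) so extreme exponents cannot
#' overflow. State populations are the normalized Boltzmann weights of
#' the same denominator and sum to one.
#'
#' @param params a [three_state_params()].
#' @param d denaturant concentrations (M), >= 0.
#' @param context a [thermo_context()].
#' @return list with `signal` (predicted observable) and `populations`
#'   (data.frame `f_N`, `f_I`, `f_U`).
#' @export
predict_observable <- function(params, d, context = thermo_context(310.15)) {
  stopifnot(inherits(params, "three_state_params"))
  if (any(!is.finite(d)) || any(d < 0)) stop("denaturant must be finite and >= 0")
  ks <- equilibrium_constants(params, d, context)
  lw <- cbind(0, ks$log_k_ni, ks$log_k_ni + ks$log_k_iu)  # N, I, U log weights
  mx <- apply(lw, 1, max)
  w <- exp(lw - mx)
  tot <- rowSums(w)
  pops <- w / tot
  colnames(pops) <- c("f_N", "f_I", "f_U")
  bl <- params$baselines
  y_states <- cbind(bl$N[1] + bl$N[2] * d, bl$I[1] + bl$I[2] * d,
                    bl$U[1] + bl$U[2] * d)
  list(signal = rowSums(pops * y_states),
       populations = as.data.frame(pops))
}

#' Fit the three-state model to a denaturation titration
#'
#' Least squares on a pooled folding/unfolding titration (path
#' independence after equilibration). m-values can be held fixed
#' (`fixed_m`, the workflow when they are known from prior global fits)
#' or floated. Transition free energies are fitted as magnitudes and
#' reported with the folding sign (negative). Baselines are linear by
#' default; `baseline = "flat"` fits intercepts only.
#'
#' The titration must bracket both transition midpoints; if the fitted
#' (or initial) midpoints fall outside the denaturant range, or the two
#' transitions merge (C_m(N-I) >= C_m(I-U)), the fit stops with a
#' diagnostic suggesting a two-state treatment rather than silently
#' switching model.
#'
#' @param denaturant GdnHCl concentrations (M), length >= 8.
#' @param signal normalized fluorescence, same length.
#' @param fixed_m optional numeric `c(m_ni, m_iu)` to hold fixed.
#' @param init optional list with `dg_ni`, `dg_iu` (folding sign or
#'   magnitudes), `m_ni`, `m_iu`.
#' @param baseline `"linear"` or `"flat"`.
#' @param context a [thermo_context()].
#' @return An object of class `three_state_fit` with `params`
#'   (a [three_state_params()]), `estimate`, `se`, `rss`, `fitted`,
#'   `residuals`.
#' @export
fit_three_state <- function(denaturant, signal, fixed_m = NULL, init = NULL,
                            baseline = c("linear", "flat"),
                            context = thermo_context(310.15)) {
  baseline <- match.arg(baseline)
  ctx <- as_thermo_context(context)
  if (length(denaturant) != length(signal)) stop("array lengths differ")
  if (length(denaturant) < 8L) stop("need at least 8 points")
  if (any(!is.finite(denaturant)) || any(denaturant < 0) || any(!is.finite(signal)))
    stop("inputs must be finite, denaturant >= 0")
  df <- data.frame(d = denaturant, y = signal)
  rng <- range(denaturant)

  # initial magnitudes: put the two midpoints at the terciles of the range
  m_ni0 <- as.numeric(if (!is.null(fixed_m)) fixed_m[1] else (init$m_ni %||% 2))
  m_iu0 <- as.numeric(if (!is.null(fixed_m)) fixed_m[2] else (init$m_iu %||% 5))
  cm1 <- rng[1] + diff(rng) / 3; cm2 <- rng[1] + 2 * diff(rng) / 3
  g1 <- abs(as.numeric(init$dg_ni %||% (m_ni0 * cm1)))
  g2 <- abs(as.numeric(init$dg_iu %||% (m_iu0 * cm2)))
  if (g1 / m_ni0 <= rng[1] && g2 / m_iu0 <= rng[1])
    stop("titration covers only denaturant above both midpoints; ",
         "no transition in range")

  predict_y <- function(g1, g2, m1, m2, iN, sN, iI, sI, iU, sU, d) {
    p <- three_state_params(-g1, -g2, m1, m2,
                            baselines = list(N = c(iN, sN), I = c(iI, sI),
                                             U = c(iU, sU)))
    predict_observable(p, d, ctx)$signal
  }
  start <- list(lg1 = log(g1), lg2 = log(g2),
                iN = df$y[which.min(df$d)], iI = mean(range(df$y)),
                iU = df$y[which.max(df$d)])
  if (is.null(fixed_m)) start <- c(start, list(lm1 = log(m_ni0), lm2 = log(m_iu0)))
  if (baseline == "linear") start <- c(start, list(sN = 0, sI = 0, sU = 0))

  rhs <- function(lg1, lg2, lm1, lm2, iN, sN, iI, sI, iU, sU, d)
    predict_y(exp(lg1), exp(lg2), exp(lm1), exp(lm2), iN, sN, iI, sI, iU, sU, d)
  form <- if (is.null(fixed_m)) {
    if (baseline == "linear")
      y ~ rhs(lg1, lg2, lm1, lm2, iN, sN, iI, sI, iU, sU, d)
    else
      y ~ rhs(lg1, lg2, lm1, lm2, iN, 0, iI, 0, iU, 0, d)
  } else {
    lm1f <- log(fixed_m[1]); lm2f <- log(fixed_m[2])
    if (baseline == "linear")
      y ~ rhs(lg1, lg2, lm1f, lm2f, iN, sN, iI, sI, iU, sU, d)
    else
      y ~ rhs(lg1, lg2, lm1f, lm2f, iN, 0, iI, 0, iU, 0, d)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 600,
                                                           ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("three-state fit did not converge: ", conditionMessage(e)))
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  g1h <- exp(est["lg1"]); g2h <- exp(est["lg2"])
  m1h <- if (is.null(fixed_m)) exp(est["lm1"]) else fixed_m[1]
  m2h <- if (is.null(fixed_m)) exp(est["lm2"]) else fixed_m[2]
  cm <- c(g1h / m1h, g2h / m2h)
  if (cm[1] >= cm[2])
    stop("transitions merged (midpoint of N-I at or above I-U): ",
         "intermediate unresolved; consider a two-state treatment")
  if (any(cm < rng[1]) || any(cm > rng[2]))
    warning(sprintf("fitted midpoint(s) %.2f / %.2f M outside the titrated range [%.2f, %.2f] M",
                    cm[1], cm[2], rng[1], rng[2]))
  getp <- function(nm, default = 0) if (nm %in% names(est)) unname(est[nm]) else default
  params <- three_state_params(
    -unname(g1h), -unname(g2h), unname(m1h), unname(m2h),
    baselines = list(N = c(getp("iN"), getp("sN")), I = c(getp("iI"), getp("sI")),
                     U = c(getp("iU"), getp("sU"))))
  estimate <- c(dg_ni = -unname(g1h), dg_iu = -unname(g2h),
                m_ni = unname(m1h), m_iu = unname(m2h),
                midpoint_ni = unname(cm[1]), midpoint_iu = unname(cm[2]))
  ses <- c(dg_ni = unname(g1h * se["lg1"]), dg_iu = unname(g2h * se["lg2"]),
           m_ni = if (is.null(fixed_m)) unname(m1h * se["lm1"]) else 0,
           m_iu = if (is.null(fixed_m)) unname(m2h * se["lm2"]) else 0)
  res <- stats::residuals(fit)
  structure(list(params = params, estimate = estimate, se = ses,
                 rss = sum(res^2), fitted = stats::fitted(fit), residuals = res,
                 fixed_m = fixed_m, baseline = baseline, context = ctx),
            class = "three_state_fit")
}

#' @export
print.three_state_fit <- function(x, ...) {
  cat(sprintf("Three-state denaturation fit (%s baselines%s):\n", x$baseline,
              if (!is.null(x$fixed_m)) ", m fixed" else ""))
  cat(sprintf("  dG(N-I) = %.2f +/- %.2f, dG(I-U) = %.2f +/- %.2f kcal/mol\n",
              x$estimate["dg_ni"], x$se["dg_ni"], x$estimate["dg_iu"], x$se["dg_iu"]))
  cat(sprintf("  m(N-I) = %.2f, m(I-U) = %.2f kcal/(mol M); midpoints %.2f / %.2f M\n",
              x$estimate["m_ni"], x$estimate["m_iu"],
              x$estimate["midpoint_ni"], x$estimate["midpoint_iu"]))
  invisible(x)
}

#' @export
coef.three_state_fit <- function(object, ...) object$estimate

#' Free-energy landscape summary
#'
#' State free-energy levels relative to the unfolded reference (U = 0):
#' I at \eqn{\Delta G_{I-U}}, N at \eqn{\Delta G_{N-I} + \Delta G_{I-U}}
#' (folding sign, negative below U for a stable protein), the two
#' transition midpoints \eqn{C_m = |\Delta G|/m}, and the total N-U
#' folding free energy.
#'
#' @param params a [three_state_params()] or a `three_state_fit`.
#' @return list with `levels` (named: U, I, N; kcal/mol), `midpoints`
#'   (named: ni, iu; M), and `total` (kcal/mol).
#' @export
landscape_summary <- function(params) {
  if (inherits(params, "three_state_fit")) params <- params$params
  stopifnot(inherits(params, "three_state_params"))
  list(levels = c(U = 0, I = params$dg_iu, N = params$dg_ni + params$dg_iu),
       midpoints = c(ni = abs(params$dg_ni) / params$m_ni,
                     iu = abs(params$dg_iu) / params$m_iu),
       total = params$dg_ni + params$dg_iu)
}
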