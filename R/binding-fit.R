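#' Fit a steric-trapping binding model to a titration
#'
#' Least-squares front end for the three isotherm models:
#' `"first"` (quadratic tight binding, [eval_first_binding()]),
#' `"competition"` (two-ligand displacement closed form,
#' [eval_competition()]) and `"second"` (denaturation-attenuated second
#' binding, [eval_second_binding()]).  Dissociation/equilibrium constants
#' are fitted in log space so positivity is structural; signal plateaus
#' are unbounded.  Initial guesses come from the data extremes and the
#' half-transition point unless supplied.
#'
#' For the `"second"` model the biotin affinity of the mSA variant must
#' be supplied in `fixed` (`kd_biotin`, uM), mirroring the experimental
#' workflow in which it is measured independently; the fit then returns
#' the denaturation constant K_D and the folding free energy
#' \eqn{\Delta G^\circ_{N-D} = RT \ln K_D} with a delta-method standard
#' error.
#'
#' @param data a [binding_titration()] (models `"first"`/`"second"`) or
#'   [competition_titration()] (model `"competition"`).
#' @param model one of `"first"`, `"competition"`, `"second"`.
#' @param fixed named list of parameters to hold fixed (e.g.
#'   `list(kd_biotin = 2e-5)` for the second-binding fit).
#' @param init optional named list of initial guesses on the natural
#'   scale (e.g. `kd_biotin`, `k_denat`, `k_ratio`, `amplitude`,
#'   `offset`, `f0`, `f_inf`).
#' @param context a [thermo_context()]; sets RT for the free-energy
#'   conversion of second-binding fits.
#' @return An object of class `binding_fit` with elements `model`,
#'   `estimate` (named vector on the natural scale), `se`, `rss`,
#'   `fitted`, `residuals`, `data`, `context`, `convergence`, and for
#'   `model = "second"` also `dg_nd` and `dg_se` (kcal/mol).
#' @examples
#' ctx <- thermo_context()
#' sim <- sim_binding_titration("second",
#'   truth = list(k_denat = 1e-4, kd_biotin = 2e-5, f0 = 1, f_inf = 0.1),
#'   n_points = 12, noise_sigma = 0, seed = 1)
#' fit <- fit_binding_model(sim$titration, "second",
#'                          fixed = list(kd_biotin = 2e-5), context = ctx)
#' fit$dg_nd   # recovers RT * log(1e-4)
#' @export
fit_binding_model <- function(data, model = c("first", "competition", "second"),
                              fixed = list(), init = NULL,
                              context = thermo_context()) {
  model <- match.arg(model)
  ctx <- as_thermo_context(context)
  spec <- binding_model_spec(model, data, fixed)
  n_free <- length(spec$free)
  if (length(spec$y) < n_free + 2L)
    stop(sprintf("need at least %d points for %d free parameters", n_free + 2L, n_free))

  start <- spec$init(init)
  fit <- tryCatch(
    minpack.lm::nlsLM(spec$formula, data = spec$df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14,
                                                           ptol = 1e-14)),
    error = function(e) {
      stop(structure(class = c("sterictrap_fit_error", "error", "condition"),
                     list(message = paste0("binding fit did not converge: ",
                                           conditionMessage(e)),
                          call = sys.call(-1), start = start, model = model)))
    })
  co <- summary(fit)$coefficients
  est_t <- co[, "Estimate"]; se_t <- co[, "Std. Error"]
  out <- spec$back_transform(est_t, se_t)
  res <- stats::residuals(fit)
  ans <- list(model = model, estimate = out$estimate, se = out$se,
              rss = sum(res^2), fitted = stats::fitted(fit), residuals = res,
              fixed = fixed, data = data, context = ctx,
              vcov_transformed = stats::vcov(fit),
              convergence = fit$convInfo$isConv %||% TRUE)
  if (model == "second") {
    # dg = RT * log(K_D); K_D fitted as log-parameter -> delta method is exact
    ans$dg_nd <- ctx$rt * log(out$estimate[["k_denat"]])
    ans$dg_se <- ctx$rt * se_t[["log_k_denat"]]
  }
  class(ans) <- "binding_fit"
  ans
}

`%||%` <- function(a, b) if (is.null(a)) b else a

binding_model_spec <- function(model, data, fixed) {
  if (model == "first") {
    stopifnot(inherits(data, "binding_titration"))
    df <- data.frame(x = data$msa_total, y = data$signal)
    pt <- data$protein_total
    list(
      y = df$y, df = df, free = c("log_kd_biotin", "amplitude", "offset"),
      formula = y ~ eval_first_binding(x, exp(log_kd_biotin), amplitude, offset, pt),
      init = function(init) {
        a2 <- init$offset %||% df$y[which.min(df$x)]
        a1 <- init$amplitude %||% (df$y[which.max(df$x)] - a2)
        kd <- init$kd_biotin %||% max(half_transition_conc(df$x, df$y), pt / 10)
        list(log_kd_biotin = log(max(kd, 1e-12)), amplitude = a1, offset = a2)
      },
      back_transform = function(est, se) {
        list(estimate = c(kd_biotin = unname(exp(est["log_kd_biotin"])),
                          amplitude = unname(est["amplitude"]),
                          offset = unname(est["offset"])),
             se = c(kd_biotin = unname(exp(est["log_kd_biotin"]) * se["log_kd_biotin"]),
                    amplitude = unname(se["amplitude"]),
                    offset = unname(se["offset"])))
      })
  } else if (model == "competition") {
    stopifnot(inherits(data, "competition_titration"))
    df <- data.frame(x = data$competitor_total, y = data$signal)
    pt <- data$protein_total; ct <- data$labeled_total
    list(
      y = df$y, df = df, free = c("log_k_ratio", "amplitude", "offset"),
      formula = y ~ eval_competition(x, exp(log_k_ratio), amplitude, offset, pt, ct),
      init = function(init) {
        a2 <- init$offset %||% df$y[which.min(df$x)]
        a1 <- init$amplitude %||% (df$y[which.max(df$x)] - a2)
        kr <- init$k_ratio %||% 1
        list(log_k_ratio = log(kr), amplitude = a1, offset = a2)
      },
      back_transform = function(est, se) {
        list(estimate = c(k_ratio = unname(exp(est["log_k_ratio"])),
                          amplitude = unname(est["amplitude"]),
                          offset = unname(est["offset"])),
             se = c(k_ratio = unname(exp(est["log_k_ratio"]) * se["log_k_ratio"]),
                    amplitude = unname(se["amplitude"]),
                    offset = unname(se["offset"])))
      })
  } else { # second
    stopifnot(inherits(data, "binding_titration"))
    if (is.null(fixed$kd_biotin))
      stop("the second-binding fit requires fixed$kd_biotin (uM), measured independently")
    kdb <- fixed$kd_biotin
    if (!is.finite(kdb) || kdb <= 0) stop("fixed$kd_biotin must be > 0")
    df <- data.frame(x = data$msa_total, y = data$signal)
    list(
      y = df$y, df = df, free = c("log_k_denat", "f0", "f_inf"),
      formula = y ~ eval_second_binding(x, exp(log_k_denat), kdb, f0, f_inf),
      init = function(init) {
        f0 <- init$f0 %||% df$y[which.min(df$x)]
        fi <- init$f_inf %||% df$y[which.max(df$x)]
        kd0 <- init$k_denat %||% {
          half <- half_transition_conc(df$x, df$y)
          r <- half / kdb - 1
          if (is.finite(r) && r > 0) 1 / r else 1e-4
        }
        list(log_k_denat = log(kd0), f0 = f0, f_inf = fi)
      },
      back_transform = function(est, se) {
        list(estimate = c(k_denat = unname(exp(est["log_k_denat"])),
                          f0 = unname(est["f0"]), f_inf = unname(est["f_inf"])),
             se = c(k_denat = unname(exp(est["log_k_denat"]) * se["log_k_denat"]),
                    f0 = unname(se["f0"]), f_inf = unname(se["f_inf"])))
      })
  }
}

# concentration at which the signal crosses halfway between its extremes
half_transition_conc <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  y_half <- (y[1] + y[length(y)]) / 2
  cross <- which(diff(sign(y - y_half)) != 0)
  if (!length(cross)) return(stats::median(x[x > 0]))
  i <- cross[1]
  # linear interpolation between bracketing points
  x[i] + (y_half - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Steric-trapping '%s' binding fit (%d points, RSS = %.3g)\n",
              x$model, length(x$fitted), x$rss))
  tab <- data.frame(estimate = x$estimate, se = x$se)
  print(tab, digits = 4)
  if (!is.null(x$dg_nd))
    cat(sprintf("dG_N-D = %.2f +/- %.2f kcal/mol (T = %.2f K)\n",
                x$dg_nd, x$dg_se, x$context$temperature))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) object$estimate
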