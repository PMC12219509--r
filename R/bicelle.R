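#' Effective lipid-to-detergent ratio of a bicelle
#'
#' Corrects the nominal molar ratio q for the detergent that partitions
#' into the aqueous phase at its critical bicelle concentration (CBC):
#' \deqn{q_{eff} = \frac{[lipid]_{total}}{[detergent]_{total} - CBC}.}
#' Fixed experimentally derived CBCs are 6.5 mM for DHPC and 2.5 mM for
#' CHAPS (see [default_cbc]).
#'
#' @param lipid_total total lipid concentration (mM), >= 0.
#' @param detergent_total total detergent concentration (mM).
#' @param cbc critical bicelle concentration (mM); must be strictly
#'   below `detergent_total`.
#' @return Dimensionless q_eff (>= the nominal q).
#' @examples
#' q_eff_fixed_cbc(28, 18, cbc = 2.5)  # DMPC:CHAPS, q = 1.56 -> q_eff ~1.81
#' @export
q_eff_fixed_cbc <- function(lipid_total, detergent_total, cbc) {
  stopifnot(is.finite(lipid_total), lipid_total >= 0,
            is.finite(detergent_total), is.finite(cbc), cbc >= 0)
  if (any(detergent_total <= cbc))
    stop("detergent_total must exceed cbc for q_eff to be defined")
  lipid_total / (detergent_total - cbc)
}

#' Fixed critical bicelle concentrations (mM)
#'
#' Experimentally derived aqueous-phase detergent concentrations used by
#' default in [q_eff_fixed_cbc()]: DHPC 6.5 mM, CHAPS 2.5 mM.
#' @format named numeric vector.
#' @export
default_cbc <- c(DHPC = 6.5, CHAPS = 2.5)

#' Critical bicelle concentration under ideal mixing
#'
#' Harmonic (ideal-mixing) combination of the component critical micelle
#' concentrations:
#' \deqn{\frac{1}{CBC} = \frac{\chi_{lipid}}{CMC_{lipid}} +
#'   \frac{\chi_{detergent}}{CMC_{detergent}},}
#' with \eqn{\chi} the mole fractions of lipid and detergent out of the
#' total amphiphile.  Reference CMCs: DMPC 6e-6 mM, DHPC 15 mM,
#' CHAPS 6 mM.
#'
#' @param chi_lipid lipid mole fraction in \[0, 1\];
#'   `chi_detergent = 1 - chi_lipid`.
#' @param cmc_lipid,cmc_detergent component CMCs (mM), > 0.
#' @return CBC (mM), always between the two CMCs.
#' @export
cbc_ideal_mixing <- function(chi_lipid, cmc_lipid, cmc_detergent) {
  stopifnot(is.finite(chi_lipid), chi_lipid >= 0, chi_lipid <= 1)
  if (!is.finite(cmc_lipid) || cmc_lipid <= 0 ||
      !is.finite(cmc_detergent) || cmc_detergent <= 0)
    stop("CMCs must be finite and > 0")
  1 / (chi_lipid / cmc_lipid + (1 - chi_lipid) / cmc_detergent)
}

#' Laurdan generalized polarization
#'
#' \deqn{GP = \frac{I_{440} - I_{490}}{I_{440} + I_{490}}} from an
#' emission spectrum; GP reports amphiphile packing/hydration (+1 fully
#' ordered/dehydrated, -1 fully disordered). Intensities at 440 and
#' 490 nm are taken from the nearest sample within 1 nm, else by linear
#' interpolation (recorded in the `lookup` attribute).
#'
#' @param wavelength emission wavelengths (nm), must cover 440 and 490.
#' @param intensity emission intensities (>= 0), same length.
#' @return GP in \[-1, 1\].
#' @export
gp_laurdan <- function(wavelength, intensity) {
  stopifnot(length(wavelength) == length(intensity))
  if (any(!is.finite(wavelength)) || any(!is.finite(intensity)))
    stop("spectrum must be finite")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (min(wavelength) > 440 || max(wavelength) < 490)
    stop("spectrum must cover 440 and 490 nm")
  lookup <- function(target) {
    i <- which.min(abs(wavelength - target))
    if (abs(wavelength[i] - target) <= 1) {
      list(value = intensity[i], method = "nearest")
    } else {
      list(value = stats::approx(wavelength, intensity, xout = target)$y,
           method = "interpolated")
    }
  }
  i440 <- lookup(440); i490 <- lookup(490)
  denom <- i440$value + i490$value
  if (denom == 0) stop("I440 + I490 = 0: GP undefined")
  structure((i440$value - i490$value) / denom,
            lookup = c(I440 = i440$method, I490 = i490$method))
}

#' Fit a gel-fluid melting curve
#'
#' Fits temperature-dependent fluorescence anisotropy to a sigmoid with
#' linearly sloped baselines,
#' \deqn{r(T) = r_1(T) \frac{1}{1 + e^{-(T - T_m)/B}} + r_2(T),}
#' with \eqn{r_1 = m_1 T + r_{1,0}} (total anisotropy change across the
#' transition) and \eqn{r_2 = m_2 T + r_{2,0}} (fluid-phase base
#' anisotropy). The inflection point \eqn{T_m} is the gel-fluid phase
#' transition temperature; `B` (in degrees C, constrained positive) sets
#' the transition steepness. Unweighted least squares.
#'
#' @param temperature temperatures (deg C), strictly increasing,
#'   length >= 8.
#' @param anisotropy measured anisotropy values, same length.
#' @param init optional named list of starting values (`tm`, `b`, `m1`,
#'   `r1_0`, `m2`, `r2_0`).
#' @return An object of class `melting_fit` with `estimate` (`tm`, `b`,
#'   `m1`, `r1_0`, `m2`, `r2_0`), `se`, `rss`, `fitted`, `residuals`.
#' @export
fit_melting <- function(temperature, anisotropy, init = NULL) {
  if (length(temperature) != length(anisotropy)) stop("array lengths differ")
  if (length(temperature) < 8L) stop("need at least 8 points")
  if (any(diff(temperature) <= 0)) stop("temperatures must be strictly increasing")
  if (any(!is.finite(temperature)) || any(!is.finite(anisotropy)))
    stop("values must be finite")
  df <- data.frame(tt = temperature, r = anisotropy)
  n <- nrow(df)
  # data-driven starts: anisotropy falls through the transition (gel high,
  # fluid low); Tm from the steepest descent of a smoothed difference
  dr <- diff(df$r) / diff(df$tt)
  tm0 <- init$tm %||% mean(df$tt[which.max(abs(dr)) + 0:1])
  b0 <- init$b %||% (diff(range(df$tt)) / 10)
  head_i <- seq_len(max(3L, n %/% 4L)); tail_i <- seq(n - max(3L, n %/% 4L) + 1L, n)
  low <- mean(df$r[head_i])   # low-T level: logistic ~ 0, so r2 alone
  high <- mean(df$r[tail_i])  # high-T level: r1 + r2
  start <- list(tm = tm0, log_b = log(b0),
                m1 = init$m1 %||% 0, r1_0 = init$r1_0 %||% (high - low),
                m2 = init$m2 %||% 0, r2_0 = init$r2_0 %||% low)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ (m1 * tt + r1_0) / (1 + exp(-(tt - tm) / exp(log_b))) + (m2 * tt + r2_0),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) stop("melting fit did not converge (no inflection in range?): ",
                             conditionMessage(e)))
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  estimate <- c(tm = unname(est["tm"]), b = unname(exp(est["log_b"])),
                m1 = unname(est["m1"]), r1_0 = unname(est["r1_0"]),
                m2 = unname(est["m2"]), r2_0 = unname(est["r2_0"]))
  ses <- c(tm = unname(se["tm"]), b = unname(exp(est["log_b"]) * se["log_b"]),
           m1 = unname(se["m1"]), r1_0 = unname(se["r1_0"]),
           m2 = unname(se["m2"]), r2_0 = unname(se["r2_0"]))
  res <- stats::residuals(fit)
  structure(list(estimate = estimate, se = ses, rss = sum(res^2),
                 fitted = stats::fitted(fit), residuals = res,
                 data = df),
            class = "melting_fit")
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("Melting fit: Tm = %.2f +/- %.2f C, B = %.2f C (RSS = %.3g)\n",
              x$estimate["tm"], x$se["tm"], x$estimate["b"], x$rss))
  invisible(x)
}

#' @export
coef.melting_fit <- function(object, ...) object$estimate

#' Predict a melting sigmoid
#'
#' Evaluates the sloped-baseline sigmoid of [fit_melting()] at given
#' temperatures; also the forward model of [sim_melting_curve()].
#'
#' @param temperature temperatures (deg C).
#' @param tm inflection point (deg C). @param b steepness (deg C), > 0.
#' @param m1,r1_0 slope and intercept of the transition amplitude
#'   \eqn{r_1(T)}.
#' @param m2,r2_0 slope and intercept of the base anisotropy
#'   \eqn{r_2(T)}.
#' @return anisotropy values.
#' @export
eval_melting <- function(temperature, tm, b, m1 = 0, r1_0, m2 = 0, r2_0) {
  if (!is.finite(b) || b <= 0) stop("b must be > 0")
  (m1 * temperature + r1_0) / (1 + exp(-(temperature - tm) / b)) +
    (m2 * temperature + r2_0)
}

#' Bilayer thickness from a SAXS peak position
#'
#' The dominant headgroup-to-headgroup distance across the short bicelle
#' dimension from the position Q of the second scattering maximum, via
#' the Bragg-like relation \eqn{L = 2\pi / Q}.
#'
#' @param q_second_max peak position (inverse angstrom), > 0.
#' @return thickness L (angstrom).
#' @export
thickness_from_peak <- function(q_second_max) {
  if (any(!is.finite(q_second_max)) || any(q_second_max <= 0))
    stop("q must be finite and > 0")
  2 * pi / q_second_max
}
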