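#' Differential mutational effect between subdomains
#'
#' \deqn{\Delta\Delta\Delta G = \Delta\Delta G^{N}_{WT-Mut} -
#'   \Delta\Delta G^{C}_{WT-Mut},}
#' the difference between a mutation's destabilization of the N-subdomain
#' and of the C-subdomain; near-zero values mean the perturbation
#' propagates to both subdomains alike (a cooperative residue). Standard
#' errors combine in quadrature.
#'
#' @param ddg_n,ddg_c mutation-induced stability changes (kcal/mol) for
#'   the N- and C-subdomain constructs.
#' @param se_n,se_c their standard errors (kcal/mol).
#' @return list with `dddg` and `se`.
#' @export
compute_dddg <- function(ddg_n, ddg_c, se_n = 0, se_c = 0) {
  if (any(!is.finite(c(ddg_n, ddg_c)))) stop("both subdomain ddG values are required")
  if (any(c(se_n, se_c) < 0)) stop("standard errors must be >= 0")
  list(dddg = ddg_n - ddg_c, se = sqrt(se_n^2 + se_c^2))
}

coop_levels <- c("localized_N", "moderately_localized_N", "cooperative",
                 "moderately_localized_C", "localized_C")

#' Five-way cooperativity classification
#'
#' Applies the cutoff partition to a vector of \eqn{\Delta\Delta\Delta G}
#' values. With thresholds \eqn{(t_1, t_2)} = (RT, 2RT) for the standard
#' scheme or (RT/2, RT) for the narrow scheme:
#' \itemize{
#'   \item \eqn{\Delta\Delta\Delta G > t_2}: `localized_N`
#'   \item \eqn{t_1 < \Delta\Delta\Delta G \le t_2}: `moderately_localized_N`
#'   \item \eqn{-t_1 \le \Delta\Delta\Delta G \le t_1}: `cooperative`
#'   \item \eqn{-t_2 \le \Delta\Delta\Delta G < -t_1}: `moderately_localized_C`
#'   \item \eqn{\Delta\Delta\Delta G < -t_2}: `localized_C`
#' }
#' The cooperative interval is closed on both sides (boundary values
#' classify as cooperative); the outer boundaries belong to the moderate
#' classes.
#'
#' @param dddg numeric vector (kcal/mol); must be finite.
#' @param context a [thermo_context()] supplying RT, or a temperature.
#' @param scheme `"standard"` (cutoffs at RT and 2RT) or `"narrow"`
#'   (RT/2 and RT).
#' @param rt_cutoff optional explicit RT to use for the cutoffs, e.g. the
#'   rounded 0.6 kcal/mol; default is the context's exact RT.
#' @return factor with levels `localized_N`, `moderately_localized_N`,
#'   `cooperative`, `moderately_localized_C`, `localized_C`.
#' @examples
#' classify_cooperativity(c(0, 0.59, 1.5), scheme = "standard")
#' @export
classify_cooperativity <- function(dddg, context = thermo_context(),
                                   scheme = c("standard", "narrow"),
                                   rt_cutoff = NULL) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(dddg))) stop("dddg must be finite")
  rt <- rt_cutoff %||% as_thermo_context(context)$rt
  thr <- if (scheme == "standard") c(rt, 2 * rt) else c(rt / 2, rt)
  lab <- ifelse(dddg > thr[2], "localized_N",
         ifelse(dddg > thr[1], "moderately_localized_N",
         ifelse(dddg >= -thr[1], "cooperative",
         ifelse(dddg >= -thr[2], "moderately_localized_C", "localized_C"))))
  factor(lab, levels = coop_levels)
}

#' Residue burial class from fractional solvent accessibility
#'
#' `buried` when the fraction of solvent-accessible residue surface area
#' is exactly 0; `partially_buried` for 0 < f_ASA <= 0.1; `exposed` for
#' f_ASA > 0.1.
#'
#' @param f_asa numeric vector in \[0, 1\] (NA allowed, propagated).
#' @return factor with levels `buried`, `partially_buried`, `exposed`.
#' @export
burial_class <- function(f_asa) {
  bad <- !is.na(f_asa) & (!is.finite(f_asa) | f_asa < 0 | f_asa > 1)
  if (any(bad)) stop("f_asa must lie in [0, 1]")
  lab <- ifelse(is.na(f_asa), NA_character_,
         ifelse(f_asa == 0, "buried",
         ifelse(f_asa <= 0.1, "partially_buried", "exposed")))
  factor(lab, levels = c("buried", "partially_buried", "exposed"))
}

#' Ordinary least-squares slope summary
#'
#' OLS of `y` on `x` with Pearson correlation and residual sum of
#' squares; the summary used for micelle-vs-bicelle mutational
#' correlations.
#'
#' @param x,y numeric vectors, length >= 3, finite; `x` must vary.
#' @return list with `slope`, `intercept`, `pearson_r`, `sse`, `n`.
#' @export
slope_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::var(x) == 0) stop("degenerate input: x has zero variance")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       pearson_r = stats::cor(x, y), sse = sum(stats::residuals(fit)^2),
       n = length(x))
}

#' Chow's test for equality of regression coefficients in two subgroups
#'
#' Tests whether two subgroups share the same linear relationship
#' (intercept and slope) by comparing the pooled residual sum of squares
#' with the subgroup fits:
#' \deqn{F = \frac{(S_C - (S_1 + S_2))/k}{(S_1 + S_2)/(N_1 + N_2 - 2k)},
#'   \quad k = 2,}
#' with the p-value from the upper tail of the F distribution on
#' \eqn{(k, N_1 + N_2 - 2k)} degrees of freedom. When both subgroup fits
#' are perfect (\eqn{S_1 + S_2 = 0}) the statistic is undefined and the
#' result carries `degenerate = TRUE` with `chow_F = NA`.
#'
#' @param x1,y1 subgroup 1 data (n >= 3).
#' @param x2,y2 subgroup 2 data (n >= 3).
#' @return An object of class `chow_test` with per-group slope summaries
#'   (`group1`, `group2`), `chow_F`, `chow_p`, `dof`, `degenerate`.
#' @export
chow_test <- function(x1, y1, x2, y2) {
  g1 <- slope_regression(x1, y1)
  g2 <- slope_regression(x2, y2)
  pooled <- slope_regression(c(x1, x2), c(y1, y2))
  k <- 2L
  n1 <- length(x1); n2 <- length(x2)
  df2 <- n1 + n2 - 2L * k
  s12 <- g1$sse + g2$sse
  yy <- c(y1, y2)
  tss <- sum((yy - mean(yy))^2)
  if (s12 <= .Machine$double.eps^0.75 * max(tss, 1)) {
    f_stat <- NA_real_; p <- NA_real_; degenerate <- TRUE
  } else {
    f_stat <- ((pooled$sse - s12) / k) / (s12 / df2)
    p <- stats::pf(f_stat, k, df2, lower.tail = FALSE)
    degenerate <- FALSE
  }
  structure(list(group1 = g1, group2 = g2, pooled = pooled,
                 chow_F = f_stat, chow_p = p, dof = c(k = k, df2 = df2),
                 degenerate = degenerate),
            class = "chow_test")
}

#' @export
print.chow_test <- function(x, ...) {
  cat(sprintf("Chow's test: slopes %.3f (n=%d) vs %.3f (n=%d)\n",
              x$group1$slope, x$group1$n, x$group2$slope, x$group2$n))
  if (x$degenerate) {
    cat("F undefined: both subgroup regressions are exact (S1 + S2 = 0)\n")
  } else {
    cat(sprintf("F(%d, %d) = %.4g, p = %.4g\n", x$dof["k"], x$dof["df2"],
                x$chow_F, x$chow_p))
  }
  invisible(x)
}

#' Cooperativity calls for a mutant panel
#'
#' Computes \eqn{\Delta\Delta\Delta G} per mutation and applies
#' [classify_cooperativity()]. Input mirrors the panel CSV layout
#' (`mutation, ddg_N, se_N, ddg_C, se_C, f_asa, environment`).
#'
#' @param panel data.frame with columns `mutation`, `ddg_N`, `ddg_C` and
#'   optionally `se_N`, `se_C`, `f_asa`.
#' @param context a [thermo_context()].
#' @param scheme cutoff scheme, see [classify_cooperativity()].
#' @param rt_cutoff optional explicit RT for the cutoffs.
#' @return data.frame of calls: `mutation`, `dddg`, `se`, `label`,
#'   `scheme`, and `burial` when `f_asa` is present.
#' @export
cooperativity_calls <- function(panel, context = thermo_context(),
                                scheme = c("standard", "narrow"),
                                rt_cutoff = NULL) {
  scheme <- match.arg(scheme)
  need <- c("mutation", "ddg_N", "ddg_C")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  se_n <- panel$se_N %||% rep(0, nrow(panel))
  se_c <- panel$se_C %||% rep(0, nrow(panel))
  dddg <- panel$ddg_N - panel$ddg_C
  out <- data.frame(
    mutation = panel$mutation,
    dddg = dddg,
    se = sqrt(se_n^2 + se_c^2),
    label = classify_cooperativity(dddg, context, scheme, rt_cutoff),
    scheme = scheme,
    stringsAsFactors = FALSE
  )
  if (!is.null(panel$f_asa)) out$burial <- burial_class(panel$f_asa)
  out
}
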