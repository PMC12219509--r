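# Independent oracles used across the suite. These deliberately avoid the
# closed forms in R/ so that agreement is evidence, not tautology.

# Brute-force single-site mass balance P + L <-> PL: solve for free ligand
# numerically, return the bound-protein fraction [PL]/P_T.
oracle_single_site_fraction <- function(msa_total, kd, protein_total) {
  vapply(msa_total, function(lt) {
    if (lt == 0) return(0)
    if (kd == 0) return(min(lt, protein_total) / protein_total)
    f <- function(lf) lf + protein_total * lf / (kd + lf) - lt
    lf <- stats::uniroot(f, c(0, lt), tol = 1e-15)$root
    (protein_total * lf / (kd + lf)) / protein_total
  }, numeric(1))
}

# Exhaustive grid search of the second-binding SSE surface.
oracle_grid_sse_min <- function(msa, y, kd_biotin, log_kd_grid, f0_grid, fi_grid) {
  best <- Inf; arg <- NULL
  for (lk in log_kd_grid) for (f0 in f0_grid) for (fi in fi_grid) {
    pred <- eval_second_binding(msa, exp(lk), kd_biotin, f0, fi)
    sse <- sum((y - pred)^2)
    if (sse < best) { best <- sse; arg <- c(lk, f0, fi) }
  }
  list(sse = best, par = arg)
}

# Direct evaluation of the two-regression F statistic from its printed
# definition, using nothing but residual sums of squares.
oracle_chow_f <- function(x1, y1, x2, y2) {
  sse <- function(x, y) sum(stats::residuals(stats::lm(y ~ x))^2)
  s1 <- sse(x1, y1); s2 <- sse(x2, y2); sc <- sse(c(x1, x2), c(y1, y2))
  k <- 2
  ((sc - (s1 + s2)) / k) / ((s1 + s2) / (length(x1) + length(x2) - 2 * k))
}

# Run-length contact-event scanner (no gap merging).
oracle_runs <- function(q) {
  inside <- FALSE; out <- NULL; s <- NA
  for (i in seq_along(q)) {
    if (q[i] > 0 && !inside) { inside <- TRUE; s <- i }
    if (q[i] == 0 && inside) { inside <- FALSE; out <- rbind(out, c(s, i - 1)) }
  }
  if (inside) out <- rbind(out, c(s, length(q)))
  out
}

# Bisection root of a multi-exponential decay at 1/e, independent of
# residence_time()'s uniroot machinery.
oracle_bisect_1e <- function(a, taus, lo = 0, hi = 1e6, tol = 1e-9) {
  f <- function(tt) sum(a * exp(-tt / taus)) - exp(-1)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Reference second-binding truth used by several fitting tests: a stable
# protein probed with a weak-affinity mSA variant so the half-transition
# falls inside the 0-60 uM design.
reference_second_truth <- function(ctx = thermo_context()) {
  list(k_denat = kd_from_dg(-7.1, ctx), kd_biotin = 2e-5,
       f0 = 1, f_inf = 0.1, protein_total = 1)
}
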