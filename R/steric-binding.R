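#' Binding titration container
#'
#' A titration of total monovalent streptavidin (mSA) against a
#' biotinylated protein at fixed total protein concentration, read out as
#' a fluorescence signal (quenching of the pyrene label).
#'
#' @param msa_total numeric vector of total mSA concentrations (uM).
#' @param signal numeric vector of fluorescence signal (arbitrary units).
#' @param protein_total total protein concentration P_T (uM), > 0.
#' @param label free-text construct/variant identifier.
#' @return An object of class `binding_titration`.
#' @export
binding_titration <- function(msa_total, signal, protein_total, label = "") {
  msa_total <- as.numeric(msa_total); signal <- as.numeric(signal)
  if (length(msa_total) != length(signal)) stop("msa_total and signal lengths differ")
  if (length(msa_total) < 4L) stop("need at least 4 titration points")
  if (any(!is.finite(msa_total)) || any(msa_total < 0)) stop("msa_total must be finite and >= 0")
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (!is.numeric(protein_total) || length(protein_total) != 1L || protein_total <= 0)
    stop("protein_total must be a single value > 0")
  structure(list(msa_total = msa_total, signal = signal,
                 protein_total = protein_total, label = as.character(label)),
            class = "binding_titration")
}

#' @export
print.binding_titration <- function(x, ...) {
  cat(sprintf("Binding titration '%s': %d points, [mSA] %.3g-%.3g uM, P_T = %.3g uM\n",
              x$label, length(x$msa_total), min(x$msa_total), max(x$msa_total),
              x$protein_total))
  invisible(x)
}

#' Competition titration container
#'
#' Titration of an unlabeled mSA competitor against a protein
#' pre-equilibrated with a dabcyl-labeled mSA; dequenching reports the
#' displacement of the labeled species.
#'
#' @param competitor_total numeric vector of total unlabeled-mSA
#'   concentrations (uM).
#' @param signal numeric vector of fluorescence signal.
#' @param labeled_total total labeled-mSA concentration C_T (uM).
#' @param protein_total total protein concentration P_T (uM).
#' @param label free-text identifier.
#' @return An object of class `competition_titration`.
#' @export
competition_titration <- function(competitor_total, signal, labeled_total,
                                  protein_total, label = "") {
  competitor_total <- as.numeric(competitor_total); signal <- as.numeric(signal)
  if (length(competitor_total) != length(signal)) stop("array lengths differ")
  if (length(competitor_total) < 4L) stop("need at least 4 titration points")
  if (any(!is.finite(competitor_total)) || any(competitor_total < 0))
    stop("competitor_total must be finite and >= 0")
  if (!is.numeric(protein_total) || length(protein_total) != 1L || protein_total <= 0)
    stop("protein_total must be a single value > 0")
  if (!is.numeric(labeled_total) || length(labeled_total) != 1L || labeled_total < protein_total)
    stop("labeled_total (C_T) must be a single value >= protein_total")
  structure(list(competitor_total = competitor_total, signal = signal,
                 labeled_total = labeled_total, protein_total = protein_total,
                 label = as.character(label)),
            class = "competition_titration")
}

#' First (unhindered) mSA binding isotherm
#'
#' Quadratic tight-binding expression for a single-site 1:1 equilibrium
#' at comparable protein and ligand concentrations:
#' \deqn{F = A_1 \frac{(P_T + [mSA] + K_d) - \sqrt{(P_T + [mSA] + K_d)^2
#'   - 4 P_T [mSA]}}{2 P_T} + A_2.}
#' The bracketed term is the bound-protein fraction, so the output is
#' bounded between `offset` and `offset + amplitude`.
#'
#' @param msa_total total mSA concentrations (uM), vector.
#' @param kd_biotin biotin dissociation constant of mSA (uM), >= 0.
#' @param amplitude total net signal change A1.
#' @param offset signal at zero mSA, A2.
#' @param protein_total total protein concentration P_T (uM), > 0.
#' @return Predicted signal vector.
#' @examples
#' # stoichiometric limit: Kd = 0, [mSA] = P_T/2 binds half the protein
#' eval_first_binding(0.05, kd_biotin = 0, amplitude = 1, offset = 0,
#'                    protein_total = 0.1)  # 0.5
#' @export
eval_first_binding <- function(msa_total, kd_biotin, amplitude, offset, protein_total) {
  if (!is.finite(kd_biotin) || kd_biotin < 0) stop("kd_biotin must be finite and >= 0")
  if (!is.finite(protein_total) || protein_total <= 0) stop("protein_total must be > 0")
  if (any(!is.finite(msa_total))) stop("msa_total must be finite")
  s <- protein_total + msa_total + kd_biotin
  disc <- pmax(s^2 - 4 * protein_total * msa_total, 0)
  frac <- (s - sqrt(disc)) / (2 * protein_total)
  amplitude * frac + offset
}

#' Competition binding isotherm (as-printed closed form)
#'
#' Closed-form expression for displacement of a labeled mSA (dissociation
#' constant K_label) by an unlabeled competitor (K_unlabel), implemented
#' exactly as used for the competition FRET assay: with
#' \eqn{x = P_T + [mSA] + (K_u/K_l)(C_T - P_T)},
#' \deqn{F = A_1 \frac{-x + \sqrt{x^2 + 4 P_T [mSA] K_u/K_l}}
#'   {2 P_T K_u/K_l} + A_2,}
#' where \eqn{[mSA]} is the total unlabeled competitor and C_T the total
#' labeled mSA. The formula is an approximation to the exact coupled
#' two-ligand equilibrium; [solve_competition_equilibrium()] is the exact
#' numeric solver, shipped as a diagnostic for quantifying the deviation.
#'
#' @param competitor_total total unlabeled competitor concentrations (uM).
#' @param k_ratio K_unlabel / K_label, dimensionless, > 0.
#' @param amplitude A1. @param offset A2.
#' @param protein_total P_T (uM), > 0.
#' @param labeled_total C_T (uM).
#' @return Predicted signal vector.
#' @export
eval_competition <- function(competitor_total, k_ratio, amplitude, offset,
                             protein_total, labeled_total) {
  if (!is.finite(k_ratio) || k_ratio <= 0) stop("k_ratio must be finite and > 0")
  if (!is.finite(protein_total) || protein_total == 0) stop("protein_total must be nonzero")
  if (protein_total < 0) stop("protein_total must be > 0")
  x <- protein_total + competitor_total + k_ratio * (labeled_total - protein_total)
  root <- -x + sqrt(x^2 + 4 * protein_total * competitor_total * k_ratio)
  amplitude * root / (2 * protein_total * k_ratio) + offset
}

#' Attenuated second mSA binding isotherm
#'
#' The second mSA binding is gated by spontaneous denaturation
#' (N.mSA <-> D.mSA, equilibrium constant K_D) followed by biotin capture
#' (D.mSA + mSA <-> D.2mSA, dissociation constant K_d,biotin):
#' \deqn{F = \frac{F_\infty - F_o}{1 + (K_d + K_d/K_D)/[mSA]} + F_o.}
#' The half-transition sits at \eqn{[mSA] = K_d (1 + 1/K_D)}, so an
#' unstable protein (large K_D) titrates at the raw biotin affinity while
#' a stable one requires proportionally more mSA.  `msa_total = 0`
#' evaluates the limit `f0` rather than dividing by zero.
#'
#' @param msa_total total mSA concentrations (uM).
#' @param k_denat denaturation equilibrium constant K_D, > 0.
#' @param kd_biotin unhindered biotin affinity of the mSA variant (uM), > 0.
#' @param f0 signal at zero mSA (F_o).
#' @param f_inf signal at saturating mSA (F_infinity).
#' @return Predicted signal vector.
#' @export
eval_second_binding <- function(msa_total, k_denat, kd_biotin, f0, f_inf) {
  if (!is.finite(k_denat) || k_denat <= 0) stop("k_denat (K_D) must be > 0")
  if (!is.finite(kd_biotin) || kd_biotin <= 0) stop("kd_biotin must be > 0")
  if (any(!is.finite(msa_total)) || any(msa_total < 0)) stop("msa_total must be >= 0")
  half <- kd_biotin * (1 + 1 / k_denat)
  out <- ifelse(msa_total == 0, f0, (f_inf - f0) / (1 + half / msa_total) + f0)
  out
}

#' Exact two-ligand competitive-equilibrium solver
#'
#' Numerically solves the coupled mass balances for one protein site and
#' two competing ligands (labeled, dissociation constant `kd_label`;
#' unlabeled, `kd_label * k_ratio`):
#' \deqn{P_T = P_f (1 + L_f/K_l + U_f/K_u),\quad
#'   C_T = L_f (1 + P_f/K_l),\quad U_T = U_f (1 + P_f/K_u).}
#' Used as the independent oracle against which the as-printed
#' [eval_competition()] closed form is compared.
#'
#' @param competitor_total total unlabeled-ligand concentrations (uM), vector.
#' @param kd_label dissociation constant of the labeled ligand (uM).
#' @param k_ratio K_unlabel/K_label.
#' @param protein_total P_T (uM). @param labeled_total C_T (uM).
#' @return data.frame with free species and the bound fractions
#'   `frac_labeled` = [P.L]/P_T and `frac_unlabeled` = [P.U]/P_T.
#' @export
solve_competition_equilibrium <- function(competitor_total, kd_label, k_ratio,
                                          protein_total, labeled_total) {
  stopifnot(kd_label > 0, k_ratio > 0, protein_total > 0, labeled_total >= 0)
  kd_unlabel <- kd_label * k_ratio
  one <- function(u_total) {
    # root in free protein; both ligand balances solved in closed form
    f <- function(p_free) {
      l_free <- labeled_total / (1 + p_free / kd_label)
      u_free <- u_total / (1 + p_free / kd_unlabel)
      p_free * (1 + l_free / kd_label + u_free / kd_unlabel) - protein_total
    }
    p_free <- stats::uniroot(f, c(0, protein_total), tol = 1e-14)$root
    l_free <- labeled_total / (1 + p_free / kd_label)
    u_free <- u_total / (1 + p_free / kd_unlabel)
    c(p_free = p_free, l_free = l_free, u_free = u_free,
      frac_labeled = (p_free * l_free / kd_label) / protein_total,
      frac_unlabeled = (p_free * u_free / kd_unlabel) / protein_total)
  }
  out <- t(vapply(competitor_total, one, numeric(5)))
  data.frame(competitor_total = competitor_total, out)
}
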