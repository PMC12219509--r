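#' Stability record
#'
#' A fitted folding free energy with its provenance: the subdomain probed
#' by the biotin pair (`"N"` for the 95/172 pair, `"C"` for 172/267),
#' the mutation (`"WT"` allowed), and the amphiphile environment.
#'
#' @param construct subdomain tag, typically `"N"` or `"C"`.
#' @param mutation mutation label; `"WT"` for the background.
#' @param environment environment label (e.g. `"micelle"`, `"bicelle"`).
#' @param dg_nd folding free energy (kcal/mol; negative = stable).
#' @param se standard error (kcal/mol), >= 0.
#' @return An object of class `stability_record`.
#' @export
stability_record <- function(construct, mutation = "WT", environment, dg_nd, se = 0) {
  stopifnot(is.numeric(dg_nd), length(dg_nd) == 1L, is.finite(dg_nd),
            is.numeric(se), length(se) == 1L, is.finite(se))
  if (se < 0) stop("se must be >= 0")
  structure(list(construct = as.character(construct),
                 mutation = as.character(mutation),
                 environment = as.character(environment),
                 dg_nd = dg_nd, se = se),
            class = "stability_record")
}

#' @export
print.stability_record <- function(x, ...) {
  cat(sprintf("Stability [%s, %s, %s]: dG_N-D = %.2f +/- %.2f kcal/mol\n",
              x$construct, x$mutation, x$environment, x$dg_nd, x$se))
  invisible(x)
}

#' Mutation-induced stability change
#'
#' \eqn{\Delta\Delta G^\circ_{N-D,WT-Mut} = \Delta G_{WT} - \Delta G_{Mut}}
#' for two records sharing construct and environment; standard errors add
#' in quadrature. Positive values mean the mutation destabilizes.
#'
#' @param wt,mut [stability_record()]s with matching construct and
#'   environment.
#' @return list with `ddg` and `se` (kcal/mol).
#' @export
ddg_wt_minus_mut <- function(wt, mut) {
  stopifnot(inherits(wt, "stability_record"), inherits(mut, "stability_record"))
  if (!identical(wt$construct, mut$construct))
    stop("construct mismatch: ", wt$construct, " vs ", mut$construct)
  if (!identical(wt$environment, mut$environment))
    stop("environment mismatch: ", wt$environment, " vs ", mut$environment)
  list(ddg = wt$dg_nd - mut$dg_nd, se = sqrt(wt$se^2 + mut$se^2))
}

#' Environment-induced stability change
#'
#' \eqn{\Delta\Delta G = \Delta G_{a} - \Delta G_{b}} for the same
#' construct and mutation measured in two environments (e.g. the
#' bicelle-minus-micelle subdomain stabilization); errors in quadrature.
#' Negative values mean environment `a` is the more stabilizing.
#'
#' @param a,b [stability_record()]s with matching construct and mutation.
#' @return list with `ddg` and `se` (kcal/mol).
#' @export
ddg_environment <- function(a, b) {
  stopifnot(inherits(a, "stability_record"), inherits(b, "stability_record"))
  if (!identical(a$construct, b$construct))
    stop("construct mismatch: ", a$construct, " vs ", b$construct)
  if (!identical(a$mutation, b$mutation))
    stop("mutation mismatch: ", a$mutation, " vs ", b$mutation)
  if (identical(a$environment, b$environment))
    stop("records are from the same environment; nothing to compare")
  list(ddg = a$dg_nd - b$dg_nd, se = sqrt(a$se^2 + b$se^2))
}
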