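#' Coordinate track container
#'
#' Heavy-atom coordinates of one molecule over trajectory frames, stored
#' as a frames x atoms x 3 array (angstrom).
#'
#' @param coords numeric array with dim (n_frames, n_atoms, 3), finite.
#' @param frame_interval frame spacing (ns), > 0.
#' @return An object of class `coordinate_track`.
#' @export
coordinate_track <- function(coords, frame_interval = 1) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x atoms x 3 array")
  if (dim(coords)[1] < 2L) stop("need at least 2 frames")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(coords = coords, frame_interval = frame_interval),
            class = "coordinate_track")
}

# frame f of a coords array as an atoms x 3 matrix (robust to 1-atom tracks)
frame_matrix <- function(co, f) matrix(co[f, , ], ncol = 3)

# Kabsch optimal superposition: rotate+translate `mobile` (n x 3) onto
# `fixed` (n x 3), minimizing RMSD. Returns the transformed coordinates.
kabsch_superpose <- function(mobile, fixed) {
  if (nrow(mobile) < 3L) stop("superposition needs at least 3 atoms")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  a <- sweep(mobile, 2, cm); b <- sweep(fixed, 2, cf)
  h <- t(a) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(a %*% t(rot), 2, cf, `+`)
}

rmsd_pair <- function(x, y, superpose = TRUE) {
  if (superpose) x <- kabsch_superpose(x, y)
  sqrt(mean(rowSums((x - y)^2)))
}

#' Time-lagged conformational RMSD of amphiphiles
#'
#' For each lag \eqn{\tau}, the heavy-atom RMSD between a molecule's
#' conformations at t and t + \eqn{\tau} after optimal rigid-body
#' superposition (Kabsch), averaged over all origins t and all
#' molecules:
#' \deqn{RMSD(\tau) = \frac{1}{N_L} \sum_{i=1}^{N_L}
#'   \langle RMSD_i(t, t+\tau) \rangle_t.}
#' The plateau lag of this curve is the amphiphile conformational
#' relaxation time, used as the default gap threshold for contact-event
#' merging.
#'
#' @param tracks a list of [coordinate_track()]s (one per molecule), or
#'   a single track.
#' @param lags lags in ns (rounded to whole frames); 0 allowed.
#' @return data.frame with `lag_ns` and `rmsd`.
#' @export
rmsd_lag <- function(tracks, lags) {
  if (inherits(tracks, "coordinate_track")) tracks <- list(tracks)
  stopifnot(all(vapply(tracks, inherits, TRUE, "coordinate_track")))
  dt <- tracks[[1]]$frame_interval
  if (any(!is.finite(lags)) || any(lags < 0)) stop("lags must be >= 0")
  lag_frames <- unique(round(lags / dt))
  out <- vapply(lag_frames, function(lf) {
    per_mol <- vapply(tracks, function(trk) {
      nf <- dim(trk$coords)[1]
      if (lf >= nf) return(NA_real_)
      origins <- seq_len(nf - lf)
      mean(vapply(origins, function(t0) {
        rmsd_pair(frame_matrix(trk$coords, t0 + lf),
                  frame_matrix(trk$coords, t0))
      }, numeric(1)))
    }, numeric(1))
    mean(per_mol, na.rm = TRUE)
  }, numeric(1))
  data.frame(lag_ns = lag_frames * dt, rmsd = out)
}

#' Root mean square fluctuation per atom
#'
#' Each frame is superposed onto the mean structure (iterated twice so
#' the reference is self-consistent), then
#' \deqn{RMSF_i = \sqrt{\langle |x_i(t) - \langle x_i \rangle|^2
#'   \rangle_t}.}
#'
#' @param track a [coordinate_track()] with >= 2 frames.
#' @param superpose superpose each frame onto the mean structure first
#'   (default); disable when the frames are already aligned, e.g. for
#'   closed-form checks on hand-built tracks.
#' @return numeric vector of per-atom RMSF (angstrom).
#' @export
rmsf <- function(track, superpose = TRUE) {
  stopifnot(inherits(track, "coordinate_track"))
  co <- track$coords
  nf <- dim(co)[1]
  ref <- frame_matrix(co, 1)
  if (superpose) {
    for (pass in 1:2) {
      fitted <- array(NA_real_, dim(co))
      for (f in seq_len(nf))
        fitted[f, , ] <- kabsch_superpose(frame_matrix(co, f), ref)
      ref <- apply(fitted, c(2, 3), mean)
    }
  } else {
    fitted <- co
    ref <- apply(co, c(2, 3), mean)
  }
  dev2 <- sweep(fitted, c(2, 3), ref)^2
  sqrt(apply(dev2, 2, function(m) mean(rowSums(matrix(m, nrow = nf)))))
}
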