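# Average deformation gradient from tracked fiducial markers, and the
# scalar functional metrics derived from it.
#
# Tracked sarcomere centers act as fiducial markers.  The vectors
# connecting every unordered marker pair in the reference frame (columns
# of L0, 2 x n) and in the current frame (L) define the over-determined
# system F L0 = L, solved in least squares by the normal equation
# F = L L0' (L0 L0')^-1.  Polar decomposition F = R U separates rotation
# from stretch; the eigenvalues of U are the principal stretches
# lambda1 <= lambda2 and J = det(F) is the area-change factor (< 1 under
# contraction).

#' Pairwise fiducial vectors for one frame
#'
#' @param markers m x 2 matrix of marker positions (pixels), m >= 3 and
#'   not all collinear.
#' @return 2 x n matrix, n = m(m-1)/2, columns in fixed lexicographic
#'   pair order (1-2, 1-3, ..., (m-1)-m).
#' @export
pair_vectors <- function(markers) {
  markers <- as.matrix(markers)
  m <- nrow(markers)
  if (m < 3) stopf("need >= 3 markers to estimate F (got %d)", m)
  idx <- utils::combn(m, 2)
  t(markers[idx[2, ], ] - markers[idx[1, ], ])
}

#' Least-squares average deformation gradient
#'
#' Solves `F L0 = L` by the normal equation
#' `F = L L0' (L0 L0')^-1`, the minimizer of
#' `sum_i || F v0_i - v_i ||^2`.  When `L = L0` the result is the
#' identity.
#'
#' @param L0 2 x n reference-frame pair vectors.
#' @param L 2 x n current-frame pair vectors (same pair order).
#' @return the 2 x 2 matrix `F`.
#' @export
estimate_F <- function(L0, L) {
  stopifnot(nrow(L0) == 2, nrow(L) == 2, ncol(L0) == ncol(L))
  A <- L0 %*% t(L0)
  if (!all(is.finite(A)) || kappa(A) > 1e8) {
    stopf("reference markers are (nearly) collinear: normal system is rank deficient")
  }
  t(solve(A, L0 %*% t(L)))
}

#' Polar decomposition and principal stretches
#'
#' Decomposes `F = R U` via the SVD (`F = W S V'`, `R = W V'`,
#' `U = V S V'`), robust near singular `F`.  Eigenvectors follow the sign
#' convention that their first nonzero component is positive.
#'
#' @param F 2 x 2 matrix with `det(F) > 0`.
#' @return list of class `deformation_state`: `F`, `R` (rotation), `U`
#'   (symmetric positive definite), `lambda1 <= lambda2`, unit
#'   eigenvectors `u1`, `u2`, and `J = det(F) = lambda1 * lambda2`.
#' @export
polar_and_stretches <- function(F) {
  F <- as.matrix(F)
  dF <- det(F)
  if (!(dF > 0)) stopf("det(F) = %.3g <= 0: non-physical frame flip", dF)
  sv <- svd(F)
  R <- sv$u %*% t(sv$v)
  U <- sv$v %*% diag(sv$d) %*% t(sv$v)
  e <- eigen((U + t(U)) / 2, symmetric = TRUE)
  fix_sign <- function(v) {
    nz <- which(abs(v) > 1e-12)[1]
    if (!is.na(nz) && v[nz] < 0) -v else v
  }
  # eigen() returns decreasing eigenvalues; report lambda1 <= lambda2
  structure(list(F = F, R = R, U = U,
                 lambda1 = e$values[2], lambda2 = e$values[1],
                 u1 = fix_sign(e$vectors[, 2]), u2 = fix_sign(e$vectors[, 1]),
                 J = dF),
            class = "deformation_state")
}

#' Average deformation gradient for every frame
#'
#' @param px,py K x T matrices of marker positions (tracked sarcomere
#'   centers), K >= 3.
#' @param reference_frame frame index used as the reference
#'   configuration; `F` there is the identity exactly.
#' @return list with `states` (per-frame `deformation_state`), `J`,
#'   `lambda1`, `lambda2` numeric vectors, and `reference_frame`.
#' @export
compute_F_series <- function(px, py, reference_frame = 1) {
  T_ <- ncol(px)
  L0 <- pair_vectors(cbind(px[, reference_frame], py[, reference_frame]))
  states <- vector("list", T_)
  for (t in seq_len(T_)) {
    F <- if (t == reference_frame) {
      diag(2)
    } else {
      estimate_F(L0, pair_vectors(cbind(px[, t], py[, t])))
    }
    states[[t]] <- polar_and_stretches(F)
  }
  list(states = states,
       J = vapply(states, function(s) s$J, numeric(1)),
       lambda1 = vapply(states, function(s) s$lambda1, numeric(1)),
       lambda2 = vapply(states, function(s) s$lambda2, numeric(1)),
       reference_frame = reference_frame)
}

#' Select the reference (most relaxed) and most contracted frames
#'
#' Two passes: `det(F)` is first computed with frame 1 as reference, and
#' the frame maximizing it (the most relaxed state) becomes the reference
#' frame; `det(F)` is then recomputed against that reference and the frame
#' minimizing it is the most contracted.  Ties break to the earliest
#' frame.
#'
#' @param px,py K x T marker position matrices.
#' @return named integer vector `c(reference, contracted)`.
#' @export
select_frames <- function(px, py) {
  stopifnot(ncol(px) >= 2)
  J1 <- compute_F_series(px, py, reference_frame = 1)$J
  ref <- which.max(J1)
  J2 <- compute_F_series(px, py, reference_frame = ref)$J
  c(reference = as.integer(ref), contracted = as.integer(which.min(J2)))
}

#' Sarcomere shortening from a normalized-length series
#'
#' `s = (y_max - y_min) / (y_max + 1)`, algebraically identical to
#' `(L_max - L_min) / L_max`.
#'
#' @param y normalized length series `(L - Lbar)/Lbar`.
#' @return the scalar `s`.
#' @export
shortening <- function(y) {
  (max(y) - min(y)) / (max(y) + 1)
}

#' Population shortening summaries
#'
#' `s_med` is the median of per-sarcomere `s` (median, not mean: less
#' outlier-prone); `s_avg` applies [shortening()] to the pointwise mean
#' series and therefore also reflects (lack of) synchrony — for identical
#' synchronous series the two coincide, for desynchronized ones
#' `s_avg < s_med`.
#'
#' @param Y K x T matrix of normalized-length series (rows = sarcomeres).
#' @return named numeric vector `c(s_med, s_avg)`.
#' @export
shortening_summary <- function(Y) {
  Y <- rbind(Y)
  c(s_med = stats::median(apply(Y, 1, shortening)),
    s_avg = shortening(colMeans(Y)))
}

#' Structural tensor and orientational order parameter
#'
#' `T = <2 r_i r_i' - I>` over unit orientation vectors; the OOP is its
#' largest eigenvalue (0 = random orientation, 1 = perfect alignment) and
#' `v_max` the dominant orientation.  Invariant under `r -> -r`.
#'
#' @param r K x 2 matrix of orientation vectors (normalized internally),
#'   or a numeric vector of axis angles in radians.
#' @return list with `T` (2 x 2, trace zero), `oop`, `v_max`, `a_min`,
#'   `v_min`.
#' @export
structural_tensor_oop <- function(r) {
  if (is.null(dim(r))) r <- cbind(cos(r), sin(r))
  r <- as.matrix(r)
  n <- sqrt(rowSums(r^2))
  r <- r / n
  Txx <- mean(2 * r[, 1]^2 - 1)
  Txy <- mean(2 * r[, 1] * r[, 2])
  Tm <- matrix(c(Txx, Txy, Txy, -Txx), 2, 2)
  e <- eigen(Tm, symmetric = TRUE)
  fix_sign <- function(v) {
    nz <- which(abs(v) > 1e-12)[1]
    if (!is.na(nz) && v[nz] < 0) -v else v
  }
  list(T = Tm, oop = e$values[1], v_max = fix_sign(e$vectors[, 1]),
       a_min = e$values[2], v_min = fix_sign(e$vectors[, 2]))
}

#' Equivalent isotropic contraction
#'
#' `C_iso = 1 - det(F)^(1/dim)`: the line shortening of an equivalent
#' isotropically contracting system (0 = no shortening; 0.10 = 10%
#' shortening in every direction).
#'
#' @param F average deformation gradient at the most contracted frame.
#' @param dim spatial dimension (2 for images).
#' @export
c_iso <- function(F, dim = 2) {
  dF <- det(as.matrix(F))
  if (!(dF > 0)) stopf("det(F) = %.3g <= 0", dF)
  1 - dF^(1 / dim)
}

#' Contraction along the dominant sarcomere orientation
#'
#' With `v0 = F^-1 v_max`, `C_par = (|v0| - |v_max|) / |v0|`: the
#' fractional shortening of a line that ends up along the dominant
#' orientation `v_max` in the contracted configuration.
#'
#' @param F average deformation gradient at the most contracted frame
#'   (invertible).
#' @param v_max unit dominant-orientation vector from
#'   [structural_tensor_oop()].
#' @export
c_parallel <- function(F, v_max) {
  F <- as.matrix(F)
  if (abs(det(F)) < 1e-12) stopf("F is singular")
  v0 <- solve(F, v_max / sqrt(sum(v_max^2)))
  n0 <- sqrt(sum(v0^2))
  (n0 - 1) / n0
}

#' Time constants of the J = det(F) series
#'
#' Applies the package's peak-detection conventions (see
#' [timeseries_parameters()]) to `J(t)`: contraction events are prominent
#' minima of `J`; reported are the event count, per-event contraction and
#' relaxation durations and the beat period, all in frames.
#'
#' @param J numeric series of `det(F)` per frame.
#' @param prominence_frac relative prominence threshold (default 0.25 of
#'   the series range).
#' @return the [timeseries_parameters()] summary for `J`.
#' @export
analyze_J <- function(J, prominence_frac = 0.25) {
  out <- timeseries_parameters(J, prominence_frac)
  if (out$n_events == 0) warning("no contraction events detected in J(t)")
  out
}

#' Full functional-metric bundle for a movie
#'
#' Selects the reference and contracted frames from the tracked marker
#' positions, computes the per-frame deformation gradient against the
#' selected reference, and reports the shortening summaries (from the
#' normalized-length series), the orientational order parameter (from the
#' reconstructed angles at the contracted frame), and the contraction
#' metrics `C_iso` and `C_par`.
#'
#' @param ts a `sarc_timeseries` from [build_timeseries()] with >= 3
#'   tracks.
#' @return list of class `functional_metrics`: `s`, `s_med`, `s_avg`,
#'   `oop`, `v_max`, `c_iso`, `c_parallel`, `reference_frame`,
#'   `contracted_frame`, `F_series`, and `J_summary` (from
#'   [analyze_J()]).
#' @export
functional_metrics <- function(ts) {
  if (length(ts$ids) < 3) {
    stopf("functional metrics need >= 3 tracked sarcomeres (got %d)",
          length(ts$ids))
  }
  fr <- select_frames(ts$px, ts$py)
  Fs <- compute_F_series(ts$px, ts$py, reference_frame = fr[["reference"]])
  Fc <- Fs$states[[fr[["contracted"]]]]$F
  oo <- structural_tensor_oop(ts$angle[, fr[["contracted"]]])
  ss <- shortening_summary(ts$ylen)
  js <- withCallingHandlers(analyze_J(Fs$J),
                            warning = function(w) invokeRestart("muffleWarning"))
  structure(list(
    s = apply(ts$ylen, 1, shortening),
    s_med = ss[["s_med"]], s_avg = ss[["s_avg"]],
    oop = oo$oop, v_max = oo$v_max,
    c_iso = c_iso(Fc), c_parallel = c_parallel(Fc, oo$v_max),
    reference_frame = fr[["reference"]], contracted_frame = fr[["contracted"]],
    F_series = Fs, J_summary = js
  ), class = "functional_metrics")
}

#' @export
print.functional_metrics <- function(x, ...) {
  cat("Functional metrics (", length(x$s), " tracked sarcomeres)\n",
      sep = "")
  cat(sprintf("  s_med = %.4g, s_avg = %.4g\n", x$s_med, x$s_avg))
  cat(sprintf("  OOP = %.4g (v_max = [%.3f, %.3f])\n",
              x$oop, x$v_max[1], x$v_max[2]))
  cat(sprintf("  C_iso = %.4g, C_par = %.4g\n", x$c_iso, x$c_parallel))
  cat(sprintf("  reference frame %d, contracted frame %d\n",
              x$reference_frame, x$contracted_frame))
  invisible(x)
}
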