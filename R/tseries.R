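# Gaussian-process reconstruction of tracked sarcomere time series.
#
# Each tracked quantity (length, width, angle, x, y) is observed only on
# the frames where the track was detected; a GP with an RBF plus white
# noise kernel, hyperparameters fitted by marginal-likelihood
# maximization, interpolates across lost frames and adaptively smooths
# without per-dataset tuning.  Only the posterior mean is consumed
# downstream.

#' Gaussian-process reconstruction of a sparse series
#'
#' Fits `k(t, t') = sf2 * exp(-(t - t')^2 / (2 l^2)) + sn2 * I` by
#' maximizing the log marginal likelihood over `(sf2, l, sn2)` (values are
#' standardized before fitting; the length scale is in frames, initialized
#' at 10 with bounds `[1, 100]`; the noise variance is initialized at 1e-2
#' with bounds `[1e-6, 1]`) and returns the posterior mean at every frame
#' `1..n_frames`.
#'
#' @param frames integer vector of observed frame indices (>= 3 values).
#' @param values observed values at those frames.
#' @param n_frames total number of frames to reconstruct.
#' @return list with `mean` (length `n_frames`), `hyper` (fitted
#'   `sf2`, `lengthscale`, `sn2`) and `observed` (logical mask).
#' @export
gp_reconstruct <- function(frames, values, n_frames) {
  ok <- is.finite(values) & is.finite(frames)
  frames <- frames[ok]
  values <- values[ok]
  if (length(frames) < 3) {
    stopf("gp_reconstruct needs >= 3 observations, got %d", length(frames))
  }
  mu <- mean(values)
  sdv <- stats::sd(values)
  grid <- seq_len(n_frames)
  obs <- grid %in% frames
  if (sdv == 0) {
    return(list(mean = rep(mu, n_frames),
                hyper = c(sf2 = 0, lengthscale = NA, sn2 = 0),
                observed = obs))
  }
  y <- (values - mu) / sdv
  d2 <- outer(frames, frames, "-")^2
  n <- length(y)
  nll <- function(p) {
    sf2 <- exp(p[1]); l <- exp(p[2]); sn2 <- exp(p[3])
    K <- sf2 * exp(-d2 / (2 * l^2)) + diag(sn2 + 1e-8, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), y))
    0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }
  # restarts from short/medium/long length scales guard against local
  # optima that oversmooth sharp beats
  fits <- lapply(c(3, 10, 30), function(l0) {
    stats::optim(c(log(1), log(l0), log(1e-2)), nll,
                 method = "L-BFGS-B",
                 lower = c(log(1e-3), log(1), log(1e-6)),
                 upper = c(log(1e3), log(100), log(1)))
  })
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  sf2 <- exp(fit$par[1]); l <- exp(fit$par[2]); sn2 <- exp(fit$par[3])
  K <- sf2 * exp(-d2 / (2 * l^2)) + diag(sn2 + 1e-8, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  ks <- sf2 * exp(-outer(grid, frames, "-")^2 / (2 * l^2))
  post <- as.numeric(ks %*% alpha)
  list(mean = post * sdv + mu,
       hyper = c(sf2 = sf2, lengthscale = l, sn2 = sn2),
       observed = obs)
}

# Unwrap a sequence of axis angles (defined modulo pi) so consecutive
# values never jump by more than pi/2.
.unwrap_axis_angle <- function(a) {
  out <- a
  for (i in seq_along(out)[-1]) {
    d <- out[i] - out[i - 1]
    out[i] <- out[i] - pi * round(d / pi)
  }
  out
}

#' Reconstruct time series for all well-tracked sarcomeres
#'
#' Sarcomere tracks present in at least `keep_thresh` of the movie frames
#' are reconstructed with [gp_reconstruct()] for each of length, width,
#' angle (unwrapped modulo pi before smoothing) and the x and y center
#' positions.  Normalized length is computed after reconstruction as
#' `y = (L - Lbar) / Lbar` with `Lbar` the mean of the dense reconstructed
#' length series, so every normalized series has zero mean by
#' construction.
#'
#' @param tracking a `tracking` from [track_movie()].
#' @param seg the `segmentation` the tracking was computed from.
#' @param keep_thresh minimum presence fraction (default 0.75; use
#'   values above `1/k`, with `k` the number of beats, only for
#'   visualization).
#' @return object of class `sarc_timeseries`: matrices `len`, `ylen`,
#'   `width`, `angle`, `px`, `py` (tracks x frames, rownames are global
#'   ids), logical `observed`, and `n_frames`.  Zero kept tracks yields an
#'   empty object with a warning.
#' @export
build_timeseries <- function(tracking, seg, keep_thresh = 0.75) {
  stopifnot(inherits(tracking, "tracking"), keep_thresh > 0,
            keep_thresh <= 1)
  T_ <- tracking$n_frames
  tr <- tracking$sarcomeres
  presence <- attr(tr, "presence")
  keep <- as.integer(names(presence)[presence >= keep_thresh])
  mk <- function() matrix(NA_real_, length(keep), T_,
                          dimnames = list(keep, NULL))
  out <- list(ids = keep, len = mk(), ylen = mk(), width = mk(),
              angle = mk(), px = mk(), py = mk(),
              observed = matrix(FALSE, length(keep), T_,
                                dimnames = list(keep, NULL)),
              n_frames = T_, keep_thresh = keep_thresh)
  class(out) <- "sarc_timeseries"
  if (length(keep) == 0) {
    warning("no sarcomere tracks meet keep_thresh = ", keep_thresh)
    return(out)
  }
  det <- seg$sarcomeres
  for (i in seq_along(keep)) {
    rows <- tr[tr$global_id == keep[i], ]
    d <- det[match(paste(rows$frame, rows$local_id),
                   paste(det$frame, det$local_id)), ]
    f <- rows$frame
    out$observed[i, f] <- TRUE
    out$len[i, ] <- gp_reconstruct(f, d$length, T_)$mean
    out$width[i, ] <- gp_reconstruct(f, d$width, T_)$mean
    out$angle[i, ] <- gp_reconstruct(f, .unwrap_axis_angle(d$angle), T_)$mean
    out$px[i, ] <- gp_reconstruct(f, d$x, T_)$mean
    out$py[i, ] <- gp_reconstruct(f, d$y, T_)$mean
  }
  lbar <- rowMeans(out$len)
  out$ylen <- (out$len - lbar) / lbar
  out
}

#' Compare tracked and untracked sarcomere populations
#'
#' The tracking step keeps only persistent detections; this summary checks
#' whether the kept population is biased by comparing the distributions of
#' length, width and angle between detections belonging to kept tracks and
#' a random sample of the remaining (untracked) detections, with a
#' two-sample Wilcoxon rank-sum statistic per property.
#'
#' @param seg a `segmentation`.
#' @param tracking a `tracking`.
#' @param ts a `sarc_timeseries` (defines the kept population).
#' @param n_sample untracked detections to sample (default 500).
#' @param seed sampling seed.
#' @return data.frame with one row per property: means, standard
#'   deviations and the Wilcoxon p-value.  With no untracked detections
#'   the statistic columns are `NA` (degenerate report).
#' @export
compare_tracked_untracked <- function(seg, tracking, ts, n_sample = 500,
                                      seed = 1) {
  if (length(ts$ids) == 0) stopf("no tracked sarcomere series to compare")
  tr <- tracking$sarcomeres
  tr <- tr[tr$global_id %in% ts$ids, ]
  det <- seg$sarcomeres
  key <- paste(det$frame, det$local_id)
  tracked <- det[key %in% paste(tr$frame, tr$local_id), , drop = FALSE]
  untracked <- det[!(key %in% paste(tr$frame, tr$local_id)), , drop = FALSE]
  if (nrow(untracked) > 0) {
    idx <- with_local_seed(seed, sample(nrow(untracked),
                                        min(n_sample, nrow(untracked))))
    untracked <- untracked[idx, , drop = FALSE]
  }
  prop <- c("length", "width", "angle")
  do.call(rbind, lapply(prop, function(p) {
    a <- tracked[[p]]
    b <- untracked[[p]]
    pv <- if (length(b) > 0 && stats::sd(c(a, b)) > 0) {
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    } else {
      NA_real_
    }
    data.frame(property = p, n_tracked = length(a), n_untracked = length(b),
               mean_tracked = mean(a),
               mean_untracked = if (length(b)) mean(b) else NA_real_,
               sd_tracked = stats::sd(a),
               sd_untracked = if (length(b) > 1) stats::sd(b) else NA_real_,
               wilcox_p = pv)
  }))
}

#' Export reconstructed time series as per-quantity CSV tables
#'
#' One file per quantity; each row is a tracked sarcomere, each column a
#' movie frame.  Lengths are in pixels, time in frames.
#'
#' @param ts a `sarc_timeseries`.
#' @param dir output directory.
#' @return the written paths, invisibly.
#' @export
write_timeseries <- function(ts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (q in c("len", "ylen", "width", "angle", "px", "py")) {
    p <- file.path(dir, sprintf("timeseries_%s.csv", q))
    utils::write.csv(data.frame(global_id = ts$ids, ts[[q]],
                                check.names = FALSE),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
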