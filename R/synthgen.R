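# Synthetic movie generator: ground-truthed movies of contracting sarcomere
# chains.  A chain is a smooth 3D path decorated with z-discs (oriented
# cylinders) every sarcomere rest length; per-frame disc positions follow a
# prescribed per-sarcomere fractional length-change program.  Frames are
# rendered by voxelizing the cylinders, slicing a focal slab, projecting by
# maximum intensity, blurring, and adding multi-octave Perlin noise.

#' Describe a sarcomere chain
#'
#' A chain is either a parametric sinusoid (the default) or an arbitrary
#' polyline given by `control_points`.  The parametric path is
#' `center + s*d + amplitude*sin(2*pi*s/period)*n` in the image plane with
#' `z = center_z + tilt_z*s`, where `d = (cos(angle), sin(angle))` and `n`
#' is its in-plane normal.  `n_sarcomeres + 1` z-discs are placed along the
#' path so that consecutive disc-to-disc 3D distances equal the prescribed
#' per-sarcomere lengths.
#'
#' @param n_sarcomeres number of sarcomeres (>= 1); the chain carries
#'   `n_sarcomeres + 1` z-discs.
#' @param rest_length sarcomere rest length in pixels (default 10, so one
#'   sarcomere spans about 10 px as in typical 100x acquisitions).
#' @param center 3D anchor point `(x, y, z)` of the chain in pixel units.
#' @param angle in-plane direction of the chain axis, radians.
#' @param amplitude,period amplitude and period (pixels) of the sinusoidal
#'   in-plane waviness; `amplitude = 0` gives a straight chain.
#' @param tilt_z dimensionless slope of the chain out of the focal plane.
#' @param disc_radius,disc_height z-disc cylinder radius and height in
#'   pixels.  The cylinder axis follows the local chain tangent, so the
#'   projected blob is elongated perpendicular to the chain.
#' @param anchor `"center"` fixes the middle z-disc at the anchor point
#'   (the chain contracts about its midpoint); `"start"` fixes the first
#'   z-disc there and the chain extends in the `+s` direction.
#' @param control_points optional k x 3 matrix of 3D points; when supplied
#'   the chain path is the polyline through them and the parametric fields
#'   are ignored.
#' @return an object of class `chain_spec`.
#' @export
chain_spec <- function(n_sarcomeres, rest_length = 10,
                       center = c(0, 0, 0), angle = 0,
                       amplitude = 0, period = 100, tilt_z = 0,
                       disc_radius = 3, disc_height = 1.5,
                       anchor = c("center", "start"),
                       control_points = NULL) {
  anchor <- match.arg(anchor)
  if (n_sarcomeres < 1) stopf("n_sarcomeres must be >= 1")
  if (rest_length <= 0) stopf("rest_length must be > 0")
  if (disc_radius <= 0) stopf("disc_radius must be > 0")
  if (!is.null(control_points)) {
    control_points <- as.matrix(control_points)
    if (ncol(control_points) != 3 || nrow(control_points) < 2) {
      stopf("control_points must be a k x 3 matrix with k >= 2")
    }
  }
  structure(list(
    n_sarcomeres = as.integer(n_sarcomeres), rest_length = rest_length,
    center = as.numeric(center), angle = angle,
    amplitude = amplitude, period = period, tilt_z = tilt_z,
    disc_radius = disc_radius, disc_height = disc_height,
    anchor = anchor, control_points = control_points
  ), class = "chain_spec")
}

#' Periodic beat contraction program
#'
#' Fractional length change `g_k(t)` for each sarcomere `k` and frame `t`
#' (0 at rest, negative while shortening).  Each beat is a Gaussian pulse of
#' depth `peak`; pulses repeat every `period` frames.  A per-sarcomere
#' `phase_lag` (frames per sarcomere index) desynchronizes the chain.
#'
#' @param n_frames,n_sarcomeres program dimensions.
#' @param peak peak fractional shortening (e.g. 0.15 for 15%).
#' @param period beat period in frames.
#' @param width Gaussian pulse standard deviation in frames.
#' @param first_peak frame of the first contraction peak.
#' @param phase_lag frames of delay per sarcomere index (0 = synchronous).
#' @return an `n_frames` x `n_sarcomeres` matrix of `g` values.
#' @export
beat_program <- function(n_frames, n_sarcomeres, peak = 0.15, period = 40,
                         width = period / 8, first_peak = ceiling(period / 2),
                         phase_lag = 0) {
  stopifnot(n_frames >= 1, n_sarcomeres >= 1, peak >= 0, peak < 1)
  t <- seq_len(n_frames)
  g <- matrix(0, n_frames, n_sarcomeres)
  n_beats <- ceiling(n_frames / period) + 1
  for (k in seq_len(n_sarcomeres)) {
    pulse <- numeric(n_frames)
    for (m in seq_len(n_beats) - 1) {
      tp <- first_peak + phase_lag * (k - 1) + m * period
      pulse <- pulse + exp(-(t - tp)^2 / (2 * width^2))
    }
    g[, k] <- -peak * pmin(pulse, 1)
  }
  g
}

#' Constant (static) contraction program
#' @param n_frames,n_sarcomeres program dimensions.
#' @param value fractional length change applied at every frame.
#' @export
constant_program <- function(n_frames, n_sarcomeres, value = 0) {
  matrix(value, n_frames, n_sarcomeres)
}

# Finely sampled polyline for a chain path, s in [-s_max, s_max] for
# parametric chains (anchor at s = 0) or the resampled control polyline.
# Returns list(pts = N x 3, s = arc length, s0 = arc position of anchor).
.chain_path <- function(spec, need_len, ds = 0.05) {
  if (!is.null(spec$control_points)) {
    cp <- spec$control_points
    seg <- sqrt(rowSums((cp[-1, , drop = FALSE] -
                         cp[-nrow(cp), , drop = FALSE])^2))
    pts <- cp[1, , drop = FALSE]
    for (i in seq_along(seg)) {
      n_i <- max(2, ceiling(seg[i] / ds))
      tt <- seq(0, 1, length.out = n_i)[-1]
      pts <- rbind(pts, cbind(
        cp[i, 1] + tt * (cp[i + 1, 1] - cp[i, 1]),
        cp[i, 2] + tt * (cp[i + 1, 2] - cp[i, 2]),
        cp[i, 3] + tt * (cp[i + 1, 3] - cp[i, 3])
      ))
    }
    s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    s0 <- if (spec$anchor == "center") max(s) / 2 else 0
    return(list(pts = pts, s = s, s0 = s0))
  }
  s_max <- need_len + 4 * spec$rest_length
  sv <- seq(-s_max, s_max, by = ds)
  d <- c(cos(spec$angle), sin(spec$angle))
  nv <- c(-sin(spec$angle), cos(spec$angle))
  wav <- if (spec$amplitude != 0) {
    spec$amplitude * sin(2 * pi * sv / spec$period)
  } else {
    0
  }
  pts <- cbind(
    spec$center[1] + sv * d[1] + wav * nv[1],
    spec$center[2] + sv * d[2] + wav * nv[2],
    spec$center[3] + spec$tilt_z * sv
  )
  s <- sv - sv[1]
  list(pts = pts, s = s, s0 = -sv[1])
}

# Point and unit tangent of a polyline path at arc position s.
.path_point <- function(path, s) {
  k <- findInterval(s, path$s, all.inside = TRUE)
  w <- (s - path$s[k]) / max(path$s[k + 1] - path$s[k], 1e-12)
  p <- path$pts[k, ] + w * (path$pts[k + 1, ] - path$pts[k, ])
  tg <- path$pts[k + 1, ] - path$pts[k, ]
  list(p = p, tangent = tg / sqrt(sum(tg^2)), s = s)
}

# Walk along the polyline from arc position s_from, placing points at exact
# 3D chord distances `lengths` (forward when dir = +1, backward when -1).
.chord_walk <- function(path, s_from, lengths, dir = 1) {
  pts <- path$pts
  s <- path$s
  if (dir < 0) {
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    s <- max(s) - rev(s)
    s_from <- max(path$s) - s_from
  }
  cur <- .path_point(list(pts = pts, s = s), s_from)
  out_p <- matrix(NA_real_, length(lengths), 3)
  out_s <- numeric(length(lengths))
  k <- findInterval(s_from, s, all.inside = TRUE)
  for (j in seq_along(lengths)) {
    L <- lengths[j]
    p <- cur$p
    # advance vertex index until the polyline leaves the sphere of radius L
    a <- p
    sa <- cur$s
    found <- FALSE
    while (k + 1 <= nrow(pts)) {
      b <- pts[k + 1, ]
      if (sum((b - p)^2) >= L^2) {
        u <- a - p
        w <- b - a
        ww <- sum(w^2)
        uw <- sum(u * w)
        disc <- uw^2 - ww * (sum(u^2) - L^2)
        tt <- (-uw + sqrt(max(disc, 0))) / ww
        newp <- a + tt * w
        news <- sa + tt * sqrt(ww)
        found <- TRUE
        break
      }
      k <- k + 1
      a <- b
      sa <- s[k]
    }
    if (!found) stopf("chain path too short for the prescribed lengths")
    out_p[j, ] <- newp
    out_s[j] <- news
    cur <- list(p = newp, s = news)
  }
  if (dir < 0) out_s <- max(path$s) - out_s
  list(pts = out_p, s = out_s)
}

#' Build per-frame 3D skeletons of z-discs and sarcomeres
#'
#' For every frame, z-discs are placed along each chain path so that the 3D
#' distance between consecutive discs equals
#' `rest_length * (1 + g_k(t))` exactly, where `g` is the contraction
#' program.  Disc cylinder axes follow the local chain tangent, so the disc
#' plane (and its projected elongation) is perpendicular to the chain.
#'
#' @param chains a `chain_spec` or list of them.
#' @param program matrix of fractional length changes, `n_frames` x
#'   total number of sarcomeres (chain sarcomeres concatenated in order).
#' @param n_frames number of frames to build (<= `nrow(program)`).
#' @return an object of class `sarc_skeleton`: per-frame z-disc and
#'   sarcomere tables (positions in pixels, 3D tangents and orientations).
#' @export
build_skeleton <- function(chains, program, n_frames = nrow(program)) {
  if (inherits(chains, "chain_spec")) chains <- list(chains)
  program <- as.matrix(program)
  k_tot <- sum(vapply(chains, function(ch) ch$n_sarcomeres, integer(1)))
  if (ncol(program) != k_tot) {
    stopf("program has %d columns but chains define %d sarcomeres",
          ncol(program), k_tot)
  }
  if (nrow(program) < n_frames) stopf("program does not cover n_frames")
  if (any(program <= -1)) {
    stopf("contraction program contains g <= -1 (non-physical collapse)")
  }
  disc_rows <- vector("list", n_frames * length(chains))
  sarc_rows <- vector("list", n_frames * length(chains))
  col0 <- 0
  ri <- 0
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    n <- ch$n_sarcomeres
    gmax <- max(program[, col0 + seq_len(n)])
    path <- .chain_path(ch, need_len = n * ch$rest_length * (1 + gmax))
    for (t in seq_len(n_frames)) {
      lens <- ch$rest_length * (1 + program[t, col0 + seq_len(n)])
      m <- if (ch$anchor == "center") floor(n / 2) + 1L else 1L
      anchor_pt <- .path_point(path, path$s0)
      p <- matrix(NA_real_, n + 1, 3)
      sarc_s <- numeric(n + 1)
      p[m, ] <- anchor_pt$p
      sarc_s[m] <- path$s0
      if (m <= n) {
        fw <- .chord_walk(path, path$s0, lens[m:n], dir = 1)
        p[(m + 1):(n + 1), ] <- fw$pts
        sarc_s[(m + 1):(n + 1)] <- fw$s
      }
      if (m > 1) {
        bw <- .chord_walk(path, path$s0, rev(lens[1:(m - 1)]), dir = -1)
        p[(m - 1):1, ] <- bw$pts
        sarc_s[(m - 1):1] <- bw$s
      }
      tang <- t(vapply(sarc_s, function(sv) .path_point(path, sv)$tangent,
                       numeric(3)))
      ri <- ri + 1
      disc_rows[[ri]] <- data.frame(
        frame = t, chain = ci, disc = seq_len(n + 1),
        x = p[, 1], y = p[, 2], z = p[, 3],
        tx = tang[, 1], ty = tang[, 2], tz = tang[, 3],
        radius = ch$disc_radius, height = ch$disc_height
      )
      seg <- p[-1, , drop = FALSE] - p[-(n + 1), , drop = FALSE]
      seg_len <- sqrt(rowSums(seg^2))
      r3 <- seg / seg_len
      r2n <- sqrt(r3[, 1]^2 + r3[, 2]^2)
      sarc_rows[[ri]] <- data.frame(
        frame = t, chain = ci, sarc = col0 + seq_len(n),
        length = seg_len,
        cx = (p[-1, 1] + p[-(n + 1), 1]) / 2,
        cy = (p[-1, 2] + p[-(n + 1), 2]) / 2,
        cz = (p[-1, 3] + p[-(n + 1), 3]) / 2,
        rx = ifelse(r2n > 0, r3[, 1] / r2n, 1),
        ry = ifelse(r2n > 0, r3[, 2] / r2n, 0)
      )
    }
    col0 <- col0 + n
  }
  discs <- do.call(rbind, disc_rows)
  sarcs <- do.call(rbind, sarc_rows)
  sarcs$angle <- axis_angle(sarcs$rx, sarcs$ry)
  structure(list(
    n_frames = n_frames, chains = chains, program = program[seq_len(n_frames), ,
                                                            drop = FALSE],
    discs = discs, sarcs = sarcs
  ), class = "sarc_skeleton")
}

#' Rendering parameters for synthetic frames
#'
#' @param shape image shape `c(rows, cols)` in pixels.
#' @param xy_res voxels per pixel in x and y (finer than z).
#' @param z_res voxels per pixel unit in z (coarser; z-resolution of typical
#'   epifluorescence stacks is well below the in-plane resolution).
#' @param focal_center z position (pixel units) of the focal plane.
#' @param slab_half half-width (pixel units) of the slab sliced around the
#'   focal plane before projection.
#' @param blur_sigma standard deviation in pixels of the Gaussian blur.
#' @param perlin_magnitude Perlin noise amplitude as a fraction of the peak
#'   image intensity (0 disables noise).
#' @param perlin_octaves number of noise octaves (persistence 0.5).
#' @param perlin_period lattice period in pixels of the first octave.
#' @param seed integer seed controlling the noise fields.
#' @export
render_params <- function(shape = c(128, 256), xy_res = 2, z_res = 1,
                          focal_center = 0, slab_half = 3, blur_sigma = 1,
                          perlin_magnitude = 0.1, perlin_octaves = 3,
                          perlin_period = 32, seed = 1) {
  stopifnot(length(shape) == 2, xy_res >= 1, z_res > 0,
            slab_half * z_res >= 1, perlin_magnitude >= 0)
  structure(list(
    shape = as.integer(shape), xy_res = as.integer(xy_res), z_res = z_res,
    focal_center = focal_center, slab_half = slab_half,
    blur_sigma = blur_sigma, perlin_magnitude = perlin_magnitude,
    perlin_octaves = as.integer(perlin_octaves),
    perlin_period = perlin_period, seed = as.integer(seed)
  ), class = "render_params")
}

#' Render one skeleton frame to a 2D image
#'
#' Each z-disc is voxelized as an oriented cylinder on a grid with `xy_res`
#' voxels per pixel in-plane and `1/z_res` pixel spacing between z layers;
#' layers within `focal_center +/- slab_half` are projected by maximum
#' intensity, block-averaged down to pixel resolution (anti-aliasing),
#' blurred, and normalized so the brightest pixel equals 1.  Noise is not
#' added here (see [add_perlin_noise()]).
#'
#' @param discs z-disc table for one frame (as produced by
#'   [build_skeleton()]).
#' @param params a [render_params()] object.
#' @return a `rows x cols` matrix in `[0, 1]`.  An empty slab yields an
#'   all-zero image flagged with `attr(, "empty")`.
#' @export
render_frame <- function(discs, params) {
  rows <- params$shape[1]
  cols <- params$shape[2]
  res <- params$xy_res
  hr <- matrix(0, rows * res, cols * res)
  zs <- seq(params$focal_center - params$slab_half,
            params$focal_center + params$slab_half, by = 1 / params$z_res)
  if (nrow(discs) > 0) {
    for (i in seq_len(nrow(discs))) {
      cx <- discs$x[i]; cy <- discs$y[i]; cz <- discs$z[i]
      ax <- discs$tx[i]; ay <- discs$ty[i]; az <- discs$tz[i]
      r <- discs$radius[i]; h <- discs$height[i]
      ext <- r + h
      # pixel c is centered at coordinate c (contour convention); hi-res
      # cell j therefore sits at (j - 0.5)/res + 0.5
      jr <- max(1, floor((cx - ext - 0.5) * res)):
        min(cols * res, ceiling((cx + ext + 0.5) * res))
      ir <- max(1, floor((cy - ext - 0.5) * res)):
        min(rows * res, ceiling((cy + ext + 0.5) * res))
      if (length(jr) < 1 || length(ir) < 1 || jr[1] > jr[length(jr)]) next
      dx <- (jr - 0.5) / res + 0.5 - cx
      dy <- (ir - 0.5) / res + 0.5 - cy
      reach2 <- r^2 + (h / 2)^2
      for (z in zs) {
        dz <- z - cz
        if (dz^2 > reach2) next
        axial <- outer(dy * ay, dx * ax, "+") + dz * az
        rad2 <- outer(dy^2, dx^2, "+") + dz^2 - axial^2
        inside <- (abs(axial) <= h / 2) & (rad2 <= r^2)
        if (any(inside)) {
          blk <- hr[ir, jr, drop = FALSE]
          blk[inside] <- 1
          hr[ir, jr] <- blk
        }
      }
    }
  }
  # block-mean downsample to pixel resolution
  img <- hr
  if (res > 1) {
    b <- colMeans(array(hr, dim = c(res, rows, res * cols)))
    bt <- t(matrix(b, rows, res * cols))
    img <- t(colMeans(array(bt, dim = c(res, cols, rows))))
  }
  if (params$blur_sigma > 0) {
    img <- EBImage::gblur(img, sigma = params$blur_sigma,
                          boundary = "replicate")
  }
  mx <- max(img)
  if (mx > 0) {
    img <- img / mx
  } else {
    attr(img, "empty") <- TRUE
    message("render_frame: empty focal slab, returning all-zero image")
  }
  img[img < 0] <- 0
  img
}

#' Multi-octave 2D Perlin gradient noise field
#'
#' Classic lattice gradient noise: octave `i` uses lattice period
#' `base_period / 2^i` and weight `persistence^i`, summed without
#' renormalization so that added octaves add high-frequency content.  The
#' field is deterministic given `seed`, zero at lattice points and
#' sign-symmetric (zero mean).
#'
#' @param shape `c(rows, cols)` of the field.
#' @param octaves number of octaves.
#' @param seed integer seed.
#' @param base_period lattice period in pixels of the first octave.
#' @param persistence octave weight decay (0.5 is standard).
#' @return a `rows x cols` matrix, approximately in `[-1, 1]`.
#' @export
perlin_field <- function(shape, octaves, seed, base_period = 32,
                         persistence = 0.5) {
  rows <- shape[1]
  cols <- shape[2]
  fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)
  field <- matrix(0, rows, cols)
  for (oct in seq_len(octaves) - 1) {
    per <- max(base_period / 2^oct, 2)
    w <- persistence^oct
    u <- (seq_len(cols) - 0.5) / per
    v <- (seq_len(rows) - 0.5) / per
    iu <- floor(u); iv <- floor(v)
    nlx <- max(iu) + 2L
    nly <- max(iv) + 2L
    ang <- with_local_seed(seed + 7919L * oct,
                           matrix(stats::runif(nlx * nly, 0, 2 * pi), nly, nlx))
    gx <- cos(ang); gy <- sin(ang)
    FU <- matrix(u - iu, rows, cols, byrow = TRUE)
    FV <- matrix(v - iv, rows, cols)
    IU <- matrix(iu, rows, cols, byrow = TRUE)
    IV <- matrix(iv, rows, cols)
    corner <- function(di, dj) {
      idx <- (IU + di) * nly + (IV + dj) + 1
      gx[idx] * (FU - di) + gy[idx] * (FV - dj)
    }
    fu <- fade(FU); fv <- fade(FV)
    n00 <- corner(0, 0); n10 <- corner(1, 0)
    n01 <- corner(0, 1); n11 <- corner(1, 1)
    nx0 <- n00 + fu * (n10 - n00)
    nx1 <- n01 + fu * (n11 - n01)
    field <- field + w * (nx0 + fv * (nx1 - nx0))
  }
  field
}

#' Add Perlin background noise to an image
#'
#' `clip(image + magnitude * field, 0, 1)` with a deterministic zero-mean
#' multi-octave gradient noise field (see [perlin_field()]).
#'
#' @param image matrix in `[0, 1]`.
#' @param magnitude noise amplitude as a fraction of peak intensity (>= 0).
#' @param octaves number of octaves.
#' @param seed integer seed (same seed, same field).
#' @param base_period first-octave lattice period in pixels.
#' @export
add_perlin_noise <- function(image, magnitude, octaves, seed,
                             base_period = 32) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(image)
  f <- perlin_field(dim(image), octaves, seed, base_period)
  out <- image + magnitude * f
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Bundle chains, program and rendering into a scene
#'
#' @param chains a `chain_spec` or list of them.
#' @param program contraction program matrix (frames x sarcomeres).
#' @param n_frames number of frames.
#' @param render a [render_params()] object.
#' @export
synth_scene <- function(chains, program, n_frames = nrow(program),
                        render = render_params()) {
  if (inherits(chains, "chain_spec")) chains <- list(chains)
  structure(list(chains = chains, program = as.matrix(program),
                 n_frames = n_frames, render = render),
            class = "synth_scene")
}

#' Baseline validation scene
#'
#' The reference condition used throughout the package's validation: a
#' single sinusoidal chain of 20 sarcomeres (rest length 10 px, amplitude
#' 10 px over a 200 px period, no out-of-plane tilt) beating homogeneously
#' with 15% peak shortening over 80 frames, rendered with low-magnitude
#' Perlin noise.
#'
#' @param n_sarcomeres,peak,amplitude,wave_period,tilt_z geometry and
#'   contraction overrides.
#' @param n_frames number of frames.
#' @param perlin_magnitude,perlin_octaves noise overrides.
#' @param phase_lag frames of contraction delay per sarcomere (0 =
#'   synchronous beating).
#' @param seed integer seed for the rendering noise.
#' @export
baseline_scene <- function(n_sarcomeres = 20, peak = 0.15, amplitude = 10,
                           wave_period = 200, tilt_z = 0, n_frames = 80,
                           perlin_magnitude = 0.1, perlin_octaves = 3,
                           phase_lag = 0, seed = 1) {
  ch <- chain_spec(n_sarcomeres, rest_length = 10,
                   center = c(128, 64, 0), angle = 0,
                   amplitude = amplitude, period = wave_period,
                   tilt_z = tilt_z)
  prog <- beat_program(n_frames, n_sarcomeres, peak = peak, period = 40,
                       phase_lag = phase_lag)
  synth_scene(ch, prog, n_frames,
              render_params(shape = c(128, 256),
                            perlin_magnitude = perlin_magnitude,
                            perlin_octaves = perlin_octaves, seed = seed))
}

#' Ground truth tables and metrics for a skeleton
#'
#' Projects the prescribed (not rendered) geometry to 2D and computes the
#' ground-truth functional metrics by running the package's own metric
#' definitions on the noiseless marker positions: normalized-length series
#' from the prescribed sarcomere lengths give `s`, the median `s_med` and
#' mean-series `s_avg`; the projected sarcomere centers act as fiducial
#' markers for the average deformation gradient, reference/contracted frame
#' selection, `c_iso` and `c_parallel`; projected orientations at the
#' contracted frame give the orientational order parameter.
#'
#' @param skel a `sarc_skeleton`.
#' @return an object of class `ground_truth` with elements `discs`,
#'   `sarcs` (per-frame tables) and `metrics`.
#' @export
ground_truth <- function(skel) {
  stopifnot(inherits(skel, "sarc_skeleton"))
  sarcs <- skel$sarcs
  ids <- sort(unique(sarcs$sarc))
  T_ <- skel$n_frames
  K <- length(ids)
  L <- matrix(NA_real_, K, T_)
  px <- matrix(NA_real_, K, T_)
  py <- matrix(NA_real_, K, T_)
  ang <- matrix(NA_real_, K, T_)
  for (i in seq_len(K)) {
    rows <- sarcs[sarcs$sarc == ids[i], ]
    rows <- rows[order(rows$frame), ]
    L[i, ] <- rows$length
    px[i, ] <- rows$cx
    py[i, ] <- rows$cy
    ang[i, ] <- rows$angle
  }
  Lbar <- rowMeans(L)
  Y <- (L - Lbar) / Lbar
  s <- apply(Y, 1, shortening)
  s_med <- stats::median(s)
  s_avg <- shortening(colMeans(Y))
  no_fmet <- list(reference = NA, contracted = NA, oop = NA_real_,
                  v_max = c(NA, NA), c_iso = NA_real_,
                  c_parallel = NA_real_)
  fmet <- if (T_ < 2) {
    # a single frame has no deformation history; frame-dependent metrics
    # are undefined
    no_fmet
  } else tryCatch({
    fr <- select_frames(px, py)
    Fs <- compute_F_series(px, py, reference_frame = fr[["reference"]])
    Fc <- Fs$states[[fr[["contracted"]]]]$F
    r <- cbind(cos(ang[, fr[["contracted"]]]), sin(ang[, fr[["contracted"]]]))
    oo <- structural_tensor_oop(r)
    list(reference = fr[["reference"]], contracted = fr[["contracted"]],
         oop = oo$oop, v_max = oo$v_max,
         c_iso = c_iso(Fc), c_parallel = c_parallel(Fc, oo$v_max))
  }, error = function(e) {
    warning("ground-truth deformation metrics unavailable: ",
            conditionMessage(e))
    list(reference = NA, contracted = NA, oop = NA_real_, v_max = c(NA, NA),
         c_iso = NA_real_, c_parallel = NA_real_)
  })
  structure(list(
    discs = skel$discs[, c("frame", "chain", "disc", "x", "y")],
    sarcs = sarcs[, c("frame", "chain", "sarc", "length",
                      "cx", "cy", "rx", "ry", "angle")],
    length = L, y = Y, px = px, py = py, angle = ang,
    metrics = list(s = s, s_med = s_med, s_avg = s_avg,
                   oop = fmet$oop, c_iso = fmet$c_iso,
                   c_parallel = fmet$c_parallel,
                   reference_frame = fmet$reference,
                   contracted_frame = fmet$contracted)
  ), class = "ground_truth")
}

#' Generate a complete synthetic movie with ground truth
#'
#' Builds the skeleton, computes the ground truth from the prescribed
#' geometry, renders every frame and adds per-frame Perlin noise (each
#' frame uses an independent field derived from the scene seed, emulating
#' fluctuating background rather than a fixed pattern).  The final stack is
#' rescaled to `[0, 1]` by its global min/max.
#'
#' @param scene a [synth_scene()].
#' @return list of class `synthetic_movie` with elements `stack`
#'   (a [frame_stack()]), `truth` (a [ground_truth()]) and `scene`.
#' @export
generate_movie <- function(scene) {
  stopifnot(inherits(scene, "synth_scene"))
  skel <- build_skeleton(scene$chains, scene$program, scene$n_frames)
  truth <- ground_truth(skel)
  rp <- scene$render
  frames <- vector("list", scene$n_frames)
  for (t in seq_len(scene$n_frames)) {
    img <- render_frame(skel$discs[skel$discs$frame == t, ], rp)
    if (rp$perlin_magnitude > 0) {
      img <- add_perlin_noise(img, rp$perlin_magnitude, rp$perlin_octaves,
                              seed = rp$seed + 7919L * t,
                              base_period = rp$perlin_period)
    }
    frames[[t]] <- img
  }
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  if (hi > lo) frames <- lapply(frames, function(f) (f - lo) / (hi - lo))
  structure(list(stack = frame_stack(frames, source = "synthetic"),
                 truth = truth, skeleton = skel, scene = scene),
            class = "synthetic_movie")
}

#' Write a synthetic movie plus its ground-truth sidecar files
#'
#' Writes `movie.tif` (multi-page float TIFF), `scene.json` (scene
#' parameters), `ground_truth_sarcomeres.csv` and
#' `ground_truth_zdiscs.csv` (per-frame tables) and
#' `ground_truth_metrics.json`.
#'
#' @param movie a `synthetic_movie`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(movie, dir) {
  stopifnot(inherits(movie, "synthetic_movie"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_movie(movie$stack, file.path(dir, "movie.tif"))
  sc <- movie$scene
  cfg <- list(
    n_frames = sc$n_frames,
    chains = lapply(sc$chains, function(ch) ch[!vapply(ch, is.null,
                                                       logical(1))]),
    render = unclass(sc$render)
  )
  jsonlite::write_json(cfg, file.path(dir, "scene.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(movie$truth$sarcs,
                   file.path(dir, "ground_truth_sarcomeres.csv"),
                   row.names = FALSE)
  utils::write.csv(movie$truth$discs,
                   file.path(dir, "ground_truth_zdiscs.csv"),
                   row.names = FALSE)
  m <- movie$truth$metrics
  jsonlite::write_json(m, file.path(dir, "ground_truth_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a declarative scene configuration
#'
#' JSON with fields `n_frames`, `chains` (array of [chain_spec()]
#' arguments), `program` (either `{"type": "beat", ...}` with
#' [beat_program()] arguments, `{"type": "constant", "value": v}`, or an
#' explicit frames x sarcomeres matrix under `"values"`), and `render`
#' ([render_params()] arguments).
#'
#' @param path JSON file.
#' @return a [synth_scene()].
#' @export
read_scene_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$n_frames)) stopf("scene config must set n_frames")
  cfg$n_frames <- as.integer(cfg$n_frames)
  mkchain <- function(a) {
    a <- lapply(a, function(x) if (is.list(x)) unlist(x) else x)
    if (!is.null(a$control_points)) {
      a$control_points <- matrix(a$control_points, ncol = 3, byrow = TRUE)
    }
    do.call(chain_spec, a)
  }
  chains <- lapply(cfg$chains, mkchain)
  k_tot <- sum(vapply(chains, function(ch) ch$n_sarcomeres, integer(1)))
  pr <- cfg$program
  program <- if (!is.null(pr$values)) {
    matrix(unlist(pr$values), nrow = cfg$n_frames, byrow = TRUE)
  } else if (identical(pr$type, "constant")) {
    constant_program(cfg$n_frames, k_tot,
                     value = if (is.null(pr$value)) 0 else pr$value)
  } else {
    args <- lapply(pr[setdiff(names(pr), "type")], unlist)
    do.call(beat_program, c(list(n_frames = cfg$n_frames,
                                 n_sarcomeres = k_tot), args))
  }
  render <- if (is.null(cfg$render)) render_params() else
    do.call(render_params,
            lapply(cfg$render, function(x) if (is.list(x)) unlist(x) else x))
  synth_scene(chains, program, cfg$n_frames, render)
}
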