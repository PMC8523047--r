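# Per-frame z-disc segmentation and procedural sarcomere linking.
#
# z-discs are bright compact blobs: the (negated) Laplacian of the frame is
# smoothed with a Gaussian and thresholded at the Otsu level; closed
# iso-contours of the response are the z-discs.  Sarcomeres are then found
# by the ghost-point rule: each disc casts two auxiliary points half the
# median nearest-neighbor distance away along its perpendicular, and a
# mutual nearest-neighbor match between ghost points of two discs links
# them into a sarcomere.

# 4-neighbor Laplacian, replicated boundary.
.laplacian <- function(img) {
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  EBImage::filter2(img, k, boundary = "replicate")
}

#' Segment z-discs in one frame
#'
#' Computes the Laplacian of the frame (negated so bright blob interiors
#' score positive), smooths it with a Gaussian of standard deviation
#' `gaussian_filter_size`, thresholds the response at the Otsu level, and
#' extracts closed iso-contours at that level.  Contours that touch the
#' image border without closing, or that have fewer than `min_points`
#' distinct vertices, are discarded.  Because thresholding acts on the
#' Laplacian, a constant intensity offset does not change the result and a
#' single global threshold suffices.
#'
#' @param frame matrix in `[0, 1]`.
#' @param gaussian_filter_size Gaussian standard deviation in pixels
#'   (default 1; use 2 for movies with strong fluctuating background).
#' @param min_points minimum number of distinct contour vertices (default
#'   4; exposed because no principled lower bound exists).
#' @return data.frame with one row per z-disc: `local_id`, center `x`,
#'   `y` (x = column, y = row, origin top-left, sub-pixel), `length`
#'   (maximum pairwise contour distance), endpoints `ex1, ey1, ex2, ey2`
#'   and `n_points`.  The contours themselves are attached as
#'   `attr(, "contours")` (list of n x 2 matrices, columns x, y).
#' @export
segment_zdiscs <- function(frame, gaussian_filter_size = 1, min_points = 4) {
  stopifnot(is.matrix(frame), gaussian_filter_size > 0)
  empty <- data.frame(local_id = integer(0), x = numeric(0), y = numeric(0),
                      length = numeric(0), ex1 = numeric(0), ey1 = numeric(0),
                      ex2 = numeric(0), ey2 = numeric(0),
                      n_points = integer(0))
  attr(empty, "contours") <- list()
  resp <- EBImage::gblur(-.laplacian(frame), sigma = gaussian_filter_size,
                         boundary = "replicate")
  rng <- range(resp)
  if (rng[2] <= rng[1]) return(empty)  # constant image: Otsu undefined
  scaled <- (resp - rng[1]) / (rng[2] - rng[1])
  th01 <- EBImage::otsu(scaled, range = c(0, 1))
  level <- rng[1] + th01 * (rng[2] - rng[1])
  cls <- grDevices::contourLines(seq_len(nrow(resp)), seq_len(ncol(resp)),
                                 resp, levels = level)
  contours <- list()
  rows <- list()
  id <- 0L
  for (cl in cls) {
    np <- length(cl$x)
    closed <- np > 1 && cl$x[1] == cl$x[np] && cl$y[1] == cl$y[np]
    if (!closed) next
    # drop the duplicated closing vertex; contourLines x-coordinate runs
    # along matrix rows (our y), its y along columns (our x)
    cx <- cl$y[-np]
    cy <- cl$x[-np]
    if (length(cx) < min_points) next
    # keep only contours enclosing above-threshold response (bright blobs,
    # not holes): test the response at the contour centroid
    mx <- mean(cx); my <- mean(cy)
    ri <- min(max(round(my), 1), nrow(resp))
    ci <- min(max(round(mx), 1), ncol(resp))
    if (resp[ri, ci] < level) next
    d2 <- pdist2(cbind(cx, cy), cbind(cx, cy))
    imax <- arrayInd(which.max(d2), dim(d2))
    id <- id + 1L
    contours[[id]] <- cbind(x = cx, y = cy)
    rows[[id]] <- data.frame(
      local_id = id, x = mx, y = my, length = sqrt(max(d2)),
      ex1 = cx[imax[1]], ey1 = cy[imax[1]],
      ex2 = cx[imax[2]], ey2 = cy[imax[2]], n_points = length(cx)
    )
  }
  if (id == 0L) return(empty)
  out <- do.call(rbind, rows)
  attr(out, "contours") <- contours
  out
}

#' Link z-discs into sarcomeres with the ghost-point rule
#'
#' Implements, in order: (1) nearest-neighbor center distance for every
#' disc; (2) `median_neigh`, the median of those distances; (3) two ghost
#' points per disc at `median_neigh / 2` along the unit vector
#' perpendicular to the disc's endpoint axis; (4) the nearest neighbor of
#' each ghost point among ghost points of other discs; (5) mutual
#' nearest-neighbor ghost pairs become sarcomeres.  Duplicate disc pairs
#' collapse to one sarcomere, so each disc joins at most two sarcomeres
#' (one per side).  Ties are broken by smaller distance, then lower disc
#' id, for determinism.
#'
#' @param zdiscs data.frame from [segment_zdiscs()].
#' @return data.frame with one row per sarcomere: `local_id`, `disc_a`,
#'   `disc_b` (disc local ids, `disc_a < disc_b`), center `x`, `y`,
#'   `length` (distance between disc centers), `width` (mean of the two
#'   disc lengths) and `angle` (radians in `[0, pi)`).
#' @export
link_sarcomeres <- function(zdiscs) {
  empty <- data.frame(local_id = integer(0), disc_a = integer(0),
                      disc_b = integer(0), x = numeric(0), y = numeric(0),
                      length = numeric(0), width = numeric(0),
                      angle = numeric(0))
  n <- nrow(zdiscs)
  if (is.null(n) || n < 2) return(empty)
  ctr <- cbind(zdiscs$x, zdiscs$y)
  d2 <- pdist2(ctr, ctr)
  diag(d2) <- Inf
  median_neigh <- stats::median(sqrt(apply(d2, 1, min)))
  ex <- zdiscs$ex2 - zdiscs$ex1
  ey <- zdiscs$ey2 - zdiscs$ey1
  nrm <- sqrt(ex^2 + ey^2)
  nrm[nrm == 0] <- 1
  perp <- cbind(-ey / nrm, ex / nrm)
  gx <- c(ctr[, 1] + perp[, 1] * median_neigh / 2,
          ctr[, 1] - perp[, 1] * median_neigh / 2)
  gy <- c(ctr[, 2] + perp[, 2] * median_neigh / 2,
          ctr[, 2] - perp[, 2] * median_neigh / 2)
  gdisc <- rep(zdiscs$local_id, 2)
  gp <- cbind(gx, gy)
  gd2 <- pdist2(gp, gp)
  same <- outer(gdisc, gdisc, "==")
  gd2[same] <- Inf
  # nearest ghost of another disc; ties by distance then lower disc id
  nn <- integer(2 * n)
  for (i in seq_len(2 * n)) {
    dmin <- min(gd2[i, ])
    cand <- which(gd2[i, ] <= dmin + 1e-12)
    cand <- cand[order(gdisc[cand], cand)]
    nn[i] <- cand[1]
  }
  pairs <- list()
  for (i in seq_len(2 * n)) {
    j <- nn[i]
    if (nn[j] == i && i < j) {
      a <- gdisc[i]; b <- gdisc[j]
      pairs[[length(pairs) + 1]] <- c(min(a, b), max(a, b))
    }
  }
  if (length(pairs) == 0) return(empty)
  pm <- unique(do.call(rbind, pairs))
  ia <- match(pm[, 1], zdiscs$local_id)
  ib <- match(pm[, 2], zdiscs$local_id)
  dx <- zdiscs$x[ib] - zdiscs$x[ia]
  dy <- zdiscs$y[ib] - zdiscs$y[ia]
  data.frame(
    local_id = seq_len(nrow(pm)),
    disc_a = pm[, 1], disc_b = pm[, 2],
    x = (zdiscs$x[ia] + zdiscs$x[ib]) / 2,
    y = (zdiscs$y[ia] + zdiscs$y[ib]) / 2,
    length = sqrt(dx^2 + dy^2),
    width = (zdiscs$length[ia] + zdiscs$length[ib]) / 2,
    angle = axis_angle(dx, dy)
  )
}

#' Segment an entire movie
#'
#' Runs [segment_zdiscs()] and [link_sarcomeres()] on every frame.
#'
#' @param stack a [frame_stack()].
#' @param gaussian_filter_size passed to [segment_zdiscs()].
#' @return list of class `segmentation` with `zdiscs` and `sarcomeres`
#'   data.frames (each with a `frame` column), `contours` (per-frame list)
#'   and `n_frames`.
#' @export
segment_movie <- function(stack, gaussian_filter_size = 1) {
  stopifnot(inherits(stack, "frame_stack"))
  zl <- vector("list", stack$n_frames)
  sl <- vector("list", stack$n_frames)
  ctl <- vector("list", stack$n_frames)
  for (t in seq_len(stack$n_frames)) {
    zd <- segment_zdiscs(stack$frames[[t]], gaussian_filter_size)
    sc <- link_sarcomeres(zd)
    ctl[[t]] <- attr(zd, "contours")
    if (nrow(zd) > 0) zd$frame <- t
    if (nrow(sc) > 0) sc$frame <- t
    zl[[t]] <- zd
    sl[[t]] <- sc
  }
  zd_all <- do.call(rbind, zl[vapply(zl, nrow, integer(1)) > 0])
  sc_all <- do.call(rbind, sl[vapply(sl, nrow, integer(1)) > 0])
  if (is.null(zd_all)) zd_all <- cbind(zl[[1]], frame = integer(0))
  if (is.null(sc_all)) sc_all <- cbind(sl[[1]], frame = integer(0))
  structure(list(zdiscs = zd_all, sarcomeres = sc_all, contours = ctl,
                 n_frames = stack$n_frames),
            class = "segmentation")
}

#' Overlay segmented z-discs and sarcomeres on a frame
#'
#' Purely presentational: returns an RGB array with z-disc contours in
#' green and sarcomere center-connecting segments in red.
#'
#' @param frame matrix in `[0, 1]`.
#' @param zdiscs data.frame from [segment_zdiscs()] (contours attached).
#' @param sarcomeres data.frame from [link_sarcomeres()].
#' @return a `rows x cols x 3` array in `[0, 1]`.
#' @export
visualize_segmentation <- function(frame, zdiscs, sarcomeres) {
  rows <- nrow(frame); cols <- ncol(frame)
  out <- array(rep(frame, 3), dim = c(rows, cols, 3))
  put <- function(x, y, ch) {
    r <- round(y); c <- round(x)
    ok <- r >= 1 & r <= rows & c >= 1 & c <= cols
    for (k in 1:3) {
      out[cbind(r[ok], c[ok], k)] <<- if (k == ch) 1 else 0
    }
  }
  contours <- attr(zdiscs, "contours")
  if (!is.null(contours)) {
    for (cc in contours) put(cc[, "x"], cc[, "y"], 2L)
  }
  if (!is.null(sarcomeres) && nrow(sarcomeres) > 0 &&
      !is.null(zdiscs) && nrow(zdiscs) > 0) {
    for (i in seq_len(nrow(sarcomeres))) {
      ia <- match(sarcomeres$disc_a[i], zdiscs$local_id)
      ib <- match(sarcomeres$disc_b[i], zdiscs$local_id)
      tt <- seq(0, 1, length.out = 50)
      put(zdiscs$x[ia] + tt * (zdiscs$x[ib] - zdiscs$x[ia]),
          zdiscs$y[ia] + tt * (zdiscs$y[ib] - zdiscs$y[ia]), 1L)
    }
  }
  out
}
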