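# Spatial-graph representation (z-discs as nodes, sarcomeres as edges)
# and spatiotemporal analyses: network distance between sarcomeres,
# correlation versus distance, hierarchical clustering of contraction
# series, and per-series timing parameters.

#' Build the z-disc / sarcomere spatial graph
#'
#' Nodes are globally tracked z-discs (mean tracked position as node
#' attributes); for every frame, each tracked sarcomere's two local z-disc
#' ids are mapped to global z-disc ids and the corresponding edge's weight
#' is incremented (created at weight 1 on first observation).  Frames
#' where an endpoint disc was never globally tracked are skipped.
#'
#' @param tracking a `tracking` from [track_movie()].
#' @param seg the `segmentation` the tracking came from.
#' @return an `igraph` graph; vertex attributes `name` (global z-disc
#'   id), `x`, `y`; edge attributes `weight` (frames observed),
#'   `sarc_ids` (comma-separated sarcomere global ids) and `mean_angle`.
#' @export
build_spatial_graph <- function(tracking, seg) {
  zt <- tracking$zdiscs
  st <- tracking$sarcomeres
  if (nrow(zt) == 0) stopf("no tracked z-discs: cannot build spatial graph")
  gkey <- paste(zt$frame, zt$local_id)
  g_of <- stats::setNames(zt$global_id, gkey)
  det <- seg$sarcomeres
  dkey <- paste(det$frame, det$local_id)
  edges <- new.env(parent = emptyenv())
  skipped <- 0L
  if (nrow(st) > 0) {
    for (i in seq_len(nrow(st))) {
      d <- det[match(paste(st$frame[i], st$local_id[i]), dkey), ]
      ga <- g_of[paste(st$frame[i], d$disc_a)]
      gb <- g_of[paste(st$frame[i], d$disc_b)]
      if (is.na(ga) || is.na(gb) || ga == gb) {
        skipped <- skipped + 1L
        next
      }
      k <- paste(min(ga, gb), max(ga, gb), sep = "-")
      e <- if (!is.null(edges[[k]])) edges[[k]] else
        list(weight = 0L, sarcs = integer(0), angles = numeric(0))
      e$weight <- e$weight + 1L
      e$sarcs <- union(e$sarcs, st$global_id[i])
      e$angles <- c(e$angles, d$angle)
      edges[[k]] <- e
    }
  }
  nodes <- do.call(rbind, lapply(split(zt, zt$global_id), function(d) {
    data.frame(global_id = d$global_id[1], x = mean(d$x), y = mean(d$y))
  }))
  keys <- ls(edges)
  edf <- NULL
  if (length(keys) > 0) {
    edf <- do.call(rbind, lapply(keys, function(k) {
      e <- edges[[k]]
      ab <- strsplit(k, "-", fixed = TRUE)[[1]]
      # axial circular mean (orientations live modulo pi)
      ma <- (atan2(mean(sin(2 * e$angles)), mean(cos(2 * e$angles))) / 2) %% pi
      data.frame(from = ab[1], to = ab[2], weight = e$weight,
                 sarc_ids = paste(sort(e$sarcs), collapse = ","),
                 mean_angle = ma)
    }))
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(edf)) data.frame(from = character(0), to = character(0))
    else edf,
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$global_id),
                          x = nodes$x, y = nodes$y))
  if (skipped > 0) {
    attr(g, "skipped_observations") <- skipped
    message("build_spatial_graph: skipped ", skipped,
            " sarcomere observations with untracked endpoint z-discs")
  }
  g
}

#' Network distance between two sarcomeres (edges)
#'
#' The number of connecting sarcomeres separating a pair: 0 for the same
#' edge, 1 for edges sharing a z-disc, and otherwise the minimum
#' shortest-path length between endpoint nodes plus one.  Disconnected
#' pairs return `Inf`.
#'
#' @param graph graph from [build_spatial_graph()].
#' @param edge_a,edge_b edge indices in `graph` (see
#'   [igraph::E()]).
#' @return integer hop count (or `Inf`).
#' @export
network_distance <- function(graph, edge_a, edge_b) {
  ne <- igraph::ecount(graph)
  if (edge_a < 1 || edge_a > ne || edge_b < 1 || edge_b > ne) {
    stopf("edge index out of range (graph has %d edges)", ne)
  }
  if (edge_a == edge_b) return(0L)
  va <- igraph::ends(graph, edge_a)[1, ]
  vb <- igraph::ends(graph, edge_b)[1, ]
  # weights = NA: hop counts, not the observation-count edge weights
  d <- igraph::distances(graph, v = va, to = vb, weights = NA)
  md <- min(d)
  if (!is.finite(md)) return(Inf)
  as.integer(md + 1)
}

#' Zero-lag correlation of contraction series versus distance
#'
#' For every pair of tracked sarcomere series: the zero-lag Pearson
#' correlation of the normalized-length series, the Euclidean distance
#' between mean centers, and the network distance along the spatial
#' graph.  Pairs with a constant series are excluded.  Per-integer
#' network-distance mean correlations are attached for plotting.
#'
#' @param ts a `sarc_timeseries`.
#' @param graph spatial graph from [build_spatial_graph()].
#' @return list with `records` (one row per pair: ids, `euclidean`,
#'   `network`, `correlation`) and `by_network` (mean correlation per
#'   integer network distance).
#' @export
correlation_vs_distance <- function(ts, graph) {
  K <- length(ts$ids)
  if (K < 2) stopf("need >= 2 series")
  # map sarcomere global id -> graph edge index
  eid <- rep(NA_integer_, K)
  if (igraph::ecount(graph) > 0) {
    sa <- igraph::edge_attr(graph, "sarc_ids")
    for (e in seq_along(sa)) {
      for (s in as.integer(strsplit(sa[e], ",")[[1]])) {
        i <- match(s, ts$ids)
        if (!is.na(i)) eid[i] <- e
      }
    }
  }
  mx <- rowMeans(ts$px)
  my <- rowMeans(ts$py)
  sds <- apply(ts$ylen, 1, stats::sd)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      if (sds[i] == 0 || sds[j] == 0) {
        dropped <- dropped + 1L
        next
      }
      net <- if (is.na(eid[i]) || is.na(eid[j])) NA_real_ else
        network_distance(graph, eid[i], eid[j])
      rows[[length(rows) + 1]] <- data.frame(
        id_a = ts$ids[i], id_b = ts$ids[j],
        euclidean = sqrt((mx[i] - mx[j])^2 + (my[i] - my[j])^2),
        network = net,
        correlation = stats::cor(ts$ylen[i, ], ts$ylen[j, ])
      )
    }
  }
  if (dropped > 0) {
    message("correlation_vs_distance: excluded ", dropped,
            " pairs with a constant series")
  }
  records <- do.call(rbind, rows)
  by_network <- NULL
  if (!is.null(records)) {
    ok <- is.finite(records$network)
    if (any(ok)) {
      agg <- stats::aggregate(correlation ~ network, data = records[ok, ],
                              FUN = mean)
      by_network <- agg[order(agg$network), ]
    }
  }
  list(records = records, by_network = by_network)
}

#' Dynamic time warping distance between two equal-length series
#'
#' Classic unconstrained dynamic-programming DTW with squared local cost
#' and unit steps; returns the square root of the optimal path cost, so
#' the DTW distance never exceeds the Euclidean distance between the
#' series.
#'
#' @param a,b numeric series of equal length.
#' @export
dtw_distance <- function(a, b) {
  n <- length(a)
  m <- length(b)
  if (n != m) stopf("dtw_distance expects equal-length series")
  prev <- c(0, rep(Inf, m))
  for (i in seq_len(n)) {
    cur <- rep(Inf, m + 1)
    costs <- (a[i] - b)^2
    for (j in seq_len(m)) {
      cur[j + 1] <- costs[j] + min(prev[j], prev[j + 1], cur[j])
    }
    prev <- cur
  }
  sqrt(prev[m + 1])
}

#' Hierarchical clustering of contraction time series
#'
#' Pairwise distances (DTW or Euclidean) between normalized-length series
#' feed average-linkage agglomerative clustering; results are
#' deterministic.
#'
#' @param Y K x T matrix of series (K >= 2, equal lengths by
#'   construction), or a `sarc_timeseries`.
#' @param metric `"dtw"` or `"euclidean"`.
#' @return list with `hclust` (the [stats::hclust()] tree), `order`
#'   (dendrogram leaf order) and `dist`.
#' @export
cluster_timeseries <- function(Y, metric = c("dtw", "euclidean")) {
  metric <- match.arg(metric)
  if (inherits(Y, "sarc_timeseries")) Y <- Y$ylen
  Y <- as.matrix(Y)
  K <- nrow(Y)
  if (K < 2) stopf("need >= 2 series to cluster")
  d <- if (metric == "euclidean") {
    stats::dist(Y)
  } else {
    dd <- matrix(0, K, K)
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        dd[i, j] <- dd[j, i] <- dtw_distance(Y[i, ], Y[j, ])
      }
    }
    stats::as.dist(dd)
  }
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = hc$order, dist = d)
}

# Prominence-filtered local minima of y plus surrounding descent/ascent
# landmarks.  Returns indices of accepted minima.
.find_minima <- function(y, prominence_frac) {
  n <- length(y)
  rng <- max(y) - min(y)
  if (rng == 0) return(integer(0))
  dy <- sign(diff(y))
  # candidate minima: position where the last nonzero slope was negative
  # and the next nonzero slope is positive
  nz <- which(dy != 0)
  cand <- integer(0)
  for (k in seq_along(nz)[-1]) {
    if (dy[nz[k - 1]] < 0 && dy[nz[k]] > 0) {
      lo <- nz[k - 1] + 1
      hi <- nz[k]
      cand <- c(cand, lo + which.min(y[lo:hi]) - 1)
    }
  }
  if (length(cand) == 0) return(integer(0))
  keep <- logical(length(cand))
  bounds <- c(0, cand, n + 1)
  for (i in seq_along(cand)) {
    left <- max(y[max(bounds[i] + 1, 1):cand[i]])
    right <- max(y[cand[i]:min(bounds[i + 2] - 1, n)])
    keep[i] <- (min(left, right) - y[cand[i]]) >= prominence_frac * rng
  }
  cand[keep]
}

#' Timing parameters of a contraction series
#'
#' Contraction events are prominence-filtered local minima of the series
#' (prominence at least `prominence_frac` of the series range).  For each
#' event, the contraction time is the number of frames from the preceding
#' local maximum (the last point attaining the running maximum before the
#' minimum) to the minimum; the relaxation time runs from the minimum to
#' the first point attaining the following maximum.  The period is the
#' median spacing between consecutive minima, the flat time is
#' `period - mean(contraction) - mean(relaxation)`, and the offset is the
#' frame of the first minimum.  These operational definitions are this
#' package's own; no standard algorithmic definition exists for them.
#'
#' @param y dense numeric series (normalized length, or `J`).
#' @param prominence_frac relative prominence threshold (default 0.25).
#' @return list with `n_events`, `events` (frame indices of minima),
#'   `contraction_time`, `relaxation_time`, `period`, `flat_time`,
#'   `offset` (all in frames; `NA`/empty when no events).
#' @export
timeseries_parameters <- function(y, prominence_frac = 0.25) {
  n <- length(y)
  mins <- .find_minima(y, prominence_frac)
  if (length(mins) == 0) {
    return(list(n_events = 0L, events = integer(0),
                contraction_time = numeric(0), relaxation_time = numeric(0),
                period = NA_real_, flat_time = NA_real_, offset = NA_real_))
  }
  bounds <- c(0, mins, n + 1)
  ct <- rt <- numeric(length(mins))
  for (i in seq_along(mins)) {
    m <- mins[i]
    wl <- max(bounds[i] + 1, 1):m
    runmax <- max(y[wl])
    p <- wl[max(which(y[wl] == runmax))]
    ct[i] <- m - p
    wr <- m:min(bounds[i + 2] - 1, n)
    q <- wr[min(which(y[wr] == max(y[wr])))]
    rt[i] <- q - m
  }
  period <- if (length(mins) >= 2) stats::median(diff(mins)) else NA_real_
  list(n_events = length(mins), events = mins,
       contraction_time = ct, relaxation_time = rt,
       period = period,
       flat_time = if (is.na(period)) NA_real_ else
         period - mean(ct) - mean(rt),
       offset = mins[1])
}

#' Export the spatial graph
#'
#' Writes GraphML plus an edge-list CSV.
#'
#' @param graph graph from [build_spatial_graph()].
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_spatial_graph <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "spatial_graph.graphml")
  igraph::write_graph(graph, p1, format = "graphml")
  el <- igraph::as_data_frame(graph, what = "edges")
  p2 <- file.path(dir, "spatial_graph_edges.csv")
  utils::write.csv(el, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
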