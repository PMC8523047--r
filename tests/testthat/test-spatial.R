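# Spatial graph, network distance, correlation vs distance, clustering,
# timing parameters.

# Fabricate a tracked movie of straight chains: `chains` is a list of
# x-offsets vectors; every disc persists for n_frames.
chain_tracking <- function(chains, n_frames = 5) {
  zdet <- list()
  sdet <- list()
  lid <- 0L
  for (ci in seq_along(chains)) {
    xs <- chains[[ci]]$x
    yy <- chains[[ci]]$y
    nd <- length(xs)
    for (t in seq_len(n_frames)) {
      zdet[[length(zdet) + 1]] <- data.frame(
        frame = t, local_id = lid + seq_len(nd), x = xs, y = yy)
      sdet[[length(sdet) + 1]] <- data.frame(
        frame = t, local_id = lid + seq_len(nd - 1),
        disc_a = lid + seq_len(nd - 1), disc_b = lid + 2:nd,
        x = (xs[-1] + xs[-nd]) / 2, y = yy,
        length = diff(xs), width = 4, angle = 0)
    }
    lid <- lid + nd
  }
  zdet <- do.call(rbind, zdet)
  sdet <- do.call(rbind, sdet)
  trk <- structure(list(
    zdiscs = filter_tracks(link_frames(zdet, n_frames = n_frames),
                           n_frames),
    sarcomeres = filter_tracks(link_frames(sdet, n_frames = n_frames),
                               n_frames),
    n_frames = n_frames), class = "tracking")
  seg <- list(zdiscs = zdet, sarcomeres = sdet, n_frames = n_frames)
  list(tracking = trk, seg = seg)
}

test_that("a single chain builds a weighted path graph", {
  cx <- chain_tracking(list(list(x = c(10, 20, 30, 40), y = 10)),
                       n_frames = 5)
  g <- build_spatial_graph(cx$tracking, cx$seg)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  expect_true(all(igraph::E(g)$weight == 5))
  expect_true(all(igraph::degree(g) <= 2))
  # two disjoint chains: two components
  c2 <- chain_tracking(list(list(x = c(10, 20, 30), y = 10),
                            list(x = c(10, 20, 30), y = 60)))
  g2 <- build_spatial_graph(c2$tracking, c2$seg)
  expect_equal(igraph::components(g2)$no, 2)
})

test_that("network distance follows the min-endpoint-path-plus-one rule
           and matches exhaustive path enumeration", {
  cx <- chain_tracking(list(list(x = 10 * (1:7), y = 10)))  # 6-edge path
  g <- build_spatial_graph(cx$tracking, cx$seg)
  # order edges along the chain for readability
  eo <- order(igraph::E(g)$sarc_ids)
  expect_equal(network_distance(g, eo[1], eo[1]), 0L)
  expect_equal(network_distance(g, eo[1], eo[2]), 1L)  # shared disc
  expect_equal(network_distance(g, eo[1], eo[6]), 5L)
  for (a in seq_along(eo)) {
    for (b in seq_along(eo)) {
      expect_equal(network_distance(g, eo[a], eo[b]),
                   brute_network_distance(g, eo[a], eo[b]))
    }
  }
  expect_error(network_distance(g, 1, 99), "out of range")
  # disconnected components are unreachable
  c2 <- chain_tracking(list(list(x = c(10, 20, 30), y = 10),
                            list(x = c(10, 20, 30), y = 60)))
  g2 <- build_spatial_graph(c2$tracking, c2$seg)
  comp <- igraph::components(g2)$membership
  ed <- igraph::ends(g2, igraph::E(g2))
  cross <- which(comp[ed[, 1]] != comp[ed[1, 1]])[1]
  expect_equal(network_distance(g2, 1, cross), Inf)
})

test_that("network distance is a metric on random connected graphs", {
  set.seed(14)
  for (rep in 1:3) {
    g <- igraph::sample_gnm(8, 12, directed = FALSE)
    while (igraph::components(g)$no > 1 ||
             any(igraph::which_loop(g))) {
      g <- igraph::sample_gnm(8, 12, directed = FALSE)
    }
    ne <- igraph::ecount(g)
    d <- outer(seq_len(ne), seq_len(ne),
               Vectorize(function(a, b) network_distance(g, a, b)))
    expect_true(all(d == t(d)))                      # symmetry
    expect_true(all(diag(d) == 0))
    for (a in 1:ne) {
      for (b in 1:ne) {
        for (cc in 1:ne) {
          expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-9)
        }
      }
    }
  }
})

test_that("correlation records behave at the exact symmetry points", {
  cx <- chain_tracking(list(list(x = c(10, 20, 30), y = 10)), n_frames = 40)
  g <- build_spatial_graph(cx$tracking, cx$seg)
  y <- 0.1 * sin(seq(0, 4 * pi, length.out = 40))
  mk_ts <- function(Y) {
    K <- nrow(Y)
    structure(list(ids = seq_len(K), ylen = Y,
                   px = matrix(rep(c(15, 25)[seq_len(K)], 40), K),
                   py = matrix(10, K, 40), n_frames = 40),
              class = "sarc_timeseries")
  }
  r1 <- correlation_vs_distance(mk_ts(rbind(y, y)), g)
  expect_equal(r1$records$correlation, 1)
  r2 <- correlation_vs_distance(mk_ts(rbind(y, -y)), g)
  expect_equal(r2$records$correlation, -1)
  expect_message(
    r3 <- correlation_vs_distance(mk_ts(rbind(y, y * 0)), g), "constant")
  expect_null(r3$records)
})

test_that("correlation decays with network distance under a phase-lagged
           program", {
  res <- desync_run()
  cvd <- correlation_vs_distance(res$timeseries, res$graph)
  bn <- cvd$by_network
  expect_gte(nrow(bn), 5)
  expect_lt(stats::cor(bn$network, bn$correlation, method = "spearman"),
            -0.8)
})

test_that("DTW distance is a self-distance zero, never exceeds Euclidean,
           and drives sensible clustering", {
  set.seed(6)
  a <- rnorm(30)
  expect_equal(dtw_distance(a, a), 0)
  for (i in 1:50) {
    x <- rnorm(25)
    y <- rnorm(25)
    expect_lte(dtw_distance(x, y), sqrt(sum((x - y)^2)) + 1e-12)
  }
  expect_error(dtw_distance(1:5, 1:6), "equal-length")
  y1 <- sin(seq(0, 4 * pi, length.out = 50))
  Y <- rbind(y1, y1, -y1)
  for (metric in c("dtw", "euclidean")) {
    cl <- cluster_timeseries(Y, metric)
    expect_identical(sort(cl$hclust$merge[1, ]), c(-2L, -1L))
  }
})

test_that("timing parameters are exact on an ideal sawtooth", {
  block <- c(rep(0, 12), seq(-0.2, -1, length.out = 5),
             seq(-2 / 3, 0, length.out = 3))
  y <- rep(block, 3)
  out <- timeseries_parameters(y)
  expect_equal(out$n_events, 3)
  expect_equal(out$contraction_time, rep(5, 3))
  expect_equal(out$relaxation_time, rep(3, 3))
  expect_equal(out$period, 20)
  expect_equal(out$flat_time, 12)
  expect_equal(out$offset, 17)
  # constant series: no events
  expect_equal(timeseries_parameters(rep(0.3, 40))$n_events, 0)
  # 3-beat smooth program: 3 events
  sc <- baseline_scene(n_frames = 120)
  yk <- sc$program[, 1]
  expect_equal(timeseries_parameters(yk)$n_events, 3)
})
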