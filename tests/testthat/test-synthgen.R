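# Synthetic generator: skeleton geometry, rendering, Perlin noise,
# ground-truth self-consistency.

test_that("skeleton places discs at exact prescribed segment lengths", {
  # straight static chain: collinear discs, constant lengths
  ch <- chain_spec(2, rest_length = 10, center = c(50, 50, 0))
  sk <- build_skeleton(ch, constant_program(5, 2))
  expect_equal(sum(sk$discs$frame == 1), 3)
  d1 <- sk$discs[sk$discs$frame == 1, ]
  v1 <- c(d1$x[2] - d1$x[1], d1$y[2] - d1$y[1])
  v2 <- c(d1$x[3] - d1$x[2], d1$y[3] - d1$y[2])
  expect_lt(abs(v1[1] * v2[2] - v1[2] * v2[1]), 1e-9)  # collinear
  expect_equal(sk$sarcs$length, rep(10, 10), tolerance = 1e-9)

  # curved chain, time-varying program: lengths follow rest * (1 + g)
  ch2 <- chain_spec(4, rest_length = 10, center = c(60, 60, 0),
                    amplitude = 8, period = 60)
  g <- matrix(rep(c(0, -0.05, -0.15, -0.10), each = 4), 4, 4, byrow = TRUE)
  sk2 <- build_skeleton(ch2, g)
  for (t in 1:4) {
    len <- sk2$sarcs$length[sk2$sarcs$frame == t]
    expect_equal(len, 10 * (1 + g[t, ]), tolerance = 1e-8)
  }
  # every segment's (Lmax - Lmin)/Lmax equals the prescribed 15% depth
  for (k in 1:4) {
    L <- sk2$sarcs$length[sk2$sarcs$sarc == k]
    expect_equal((max(L) - min(L)) / max(L), 0.15, tolerance = 1e-8)
  }
})

test_that("a 20-sarcomere sinusoidal chain yields 21 discs per frame", {
  sc <- baseline_scene(n_frames = 2)
  sk <- build_skeleton(sc$chains, sc$program, 2)
  expect_equal(as.vector(table(sk$discs$frame)), c(21L, 21L))
})

test_that("non-physical collapse (g <= -1) is rejected", {
  ch <- chain_spec(2, rest_length = 10)
  expect_error(build_skeleton(ch, constant_program(3, 2, value = -1)),
               "collapse")
})

test_that("rendered disc blob peaks at the projected center", {
  ch <- chain_spec(1, rest_length = 10, center = c(48.5, 32.5, 0))
  sk <- build_skeleton(ch, constant_program(1, 1))
  d1 <- sk$discs[sk$discs$frame == 1, ][1, ]  # the anchored disc
  rp <- render_params(shape = c(64, 96), perlin_magnitude = 0)
  img <- render_frame(d1, rp)
  pk <- arrayInd(which.max(img), dim(img))
  expect_lt(abs(pk[1, 2] - d1$x), 1)  # column vs x
  expect_lt(abs(pk[1, 1] - d1$y), 1)  # row vs y
})

test_that("rendering no discs gives an all-zero flagged frame", {
  rp <- render_params(shape = c(32, 32))
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      tx = numeric(0), ty = numeric(0), tz = numeric(0),
                      radius = numeric(0), height = numeric(0))
  expect_message(img <- render_frame(empty, rp), "empty")
  expect_true(all(img == 0))
  expect_true(isTRUE(attr(img, "empty")))
})

test_that("blob extent orders with prescribed disc radius", {
  discs <- data.frame(x = c(24, 72), y = c(32, 32), z = 0,
                      tx = 1, ty = 0, tz = 0,
                      radius = c(2, 4), height = 1.5)
  rp <- render_params(shape = c(64, 96), perlin_magnitude = 0)
  img <- render_frame(discs, rp)
  zd <- segment_zdiscs(img)
  expect_equal(nrow(zd), 2)
  zd <- zd[order(zd$x), ]
  expect_lt(zd$length[1], zd$length[2])
})

test_that("perlin noise is deterministic, zero-magnitude-safe, and gains
           gradient content with octaves", {
  img <- matrix(0.5, 64, 64)
  expect_identical(add_perlin_noise(img, 0, 3, seed = 9), img)
  f1 <- perlin_field(c(64, 64), octaves = 3, seed = 4)
  f2 <- perlin_field(c(64, 64), octaves = 3, seed = 4)
  expect_identical(f1, f2)
  # zero mean once the field spans many lattice cells
  fb <- perlin_field(c(256, 256), octaves = 3, seed = 4, base_period = 16)
  expect_lt(abs(mean(fb)), 0.02)
  grad <- vapply(1:4, function(o) {
    f <- perlin_field(c(64, 64), octaves = o, seed = 4)
    mean(abs(diff(f))) + mean(abs(t(diff(t(f)))))
  }, numeric(1))
  expect_true(all(diff(grad) > 0))
})

test_that("identical scene and seed render bit-identical movies", {
  m1 <- generate_movie(small_scene(seed = 3))
  m2 <- generate_movie(small_scene(seed = 3))
  expect_identical(m1$stack$frames, m2$stack$frames)
})

test_that("ground-truth metrics are self-consistent with the metric
           definitions on prescribed geometry", {
  # four radial chains anchored at a common center: homogeneous
  # contraction is an exact isotropic scaling of all markers
  chains <- lapply(c(0, 45, 90, 135) * pi / 180, function(a) {
    chain_spec(5, rest_length = 10, center = c(100, 100, 0), angle = a,
               anchor = "start")
  })
  # raised-sine beat attaining 0 and -0.15 exactly
  prog <- matrix(-0.15 * sin(pi * (0:39) / 40)^2, 40, 20)
  gt <- ground_truth(build_skeleton(chains, prog))
  expect_equal(gt$metrics$s_med, 0.15, tolerance = 1e-6)
  expect_equal(gt$metrics$s_avg, 0.15, tolerance = 1e-6)
  expect_equal(gt$metrics$c_iso, 0.15, tolerance = 1e-6)
  expect_equal(gt$metrics$oop, 0, tolerance = 1e-9)

  # parallel chains: perfect alignment
  par_chains <- list(
    chain_spec(5, rest_length = 10, center = c(100, 90, 0)),
    chain_spec(5, rest_length = 10, center = c(100, 110, 0)))
  gt2 <- ground_truth(build_skeleton(par_chains,
                                     beat_program(40, 10, peak = 0.1)))
  expect_equal(gt2$metrics$oop, 1, tolerance = 1e-9)

  # static program: no contraction anywhere
  gt3 <- ground_truth(build_skeleton(chains, constant_program(5, 20)))
  expect_equal(gt3$metrics$s_med, 0)
  expect_equal(gt3$metrics$s_avg, 0)
  expect_equal(gt3$metrics$c_iso, 0, tolerance = 1e-9)
})

test_that("ground-truth invariants: positive lengths, unit orientations", {
  sc <- baseline_scene(n_frames = 5)
  gt <- ground_truth(build_skeleton(sc$chains, sc$program, 5))
  expect_true(all(gt$sarcs$length > 0))
  expect_equal(sqrt(gt$sarcs$rx^2 + gt$sarcs$ry^2),
               rep(1, nrow(gt$sarcs)), tolerance = 1e-9)
})

test_that("scene configs round-trip through the declarative reader", {
  cfg <- list(
    n_frames = 6,
    chains = list(list(n_sarcomeres = 4, rest_length = 10,
                       center = c(48, 32, 0), amplitude = 5, period = 80)),
    program = list(type = "beat", peak = 0.1, period = 6, width = 1),
    render = list(shape = c(64, 96), perlin_magnitude = 0.05, seed = 2)
  )
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  sc <- read_scene_config(path)
  expect_s3_class(sc, "synth_scene")
  expect_equal(sc$n_frames, 6)
  expect_equal(sc$chains[[1]]$n_sarcomeres, 4L)
  expect_equal(dim(sc$program), c(6L, 4L))
  mov <- generate_movie(sc)
  expect_equal(mov$stack$n_frames, 6)
})
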