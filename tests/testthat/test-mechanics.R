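# Deformation-gradient estimation, polar decomposition, functional
# metrics.

test_that("pair vectors enumerate unordered pairs in stable order", {
  m3 <- cbind(c(0, 1, 0), c(0, 0, 1))
  expect_equal(ncol(pair_vectors(m3)), 3)
  m10 <- cbind(runif(10), runif(10))
  expect_equal(ncol(pair_vectors(m10)), 45)
  expect_identical(pair_vectors(m10), pair_vectors(m10))
  expect_error(pair_vectors(m3[1:2, ]), ">= 3")
})

test_that("estimate_F recovers affine motion exactly and degrades
           gracefully with noise", {
  set.seed(5)
  mk <- cbind(runif(8, 0, 50), runif(8, 0, 50))
  L0 <- pair_vectors(mk)
  expect_equal(estimate_F(L0, L0), diag(2), tolerance = 1e-12)

  Fstar <- matrix(c(0.9, 0, 0.05, 1.1), 2, 2)
  Ld <- pair_vectors(t(Fstar %*% t(mk)))
  expect_equal(estimate_F(L0, Ld), Fstar, tolerance = 1e-12)

  # estimation error shrinks as marker count grows (Monte Carlo)
  err <- vapply(c(5, 20, 80), function(m) {
    es <- vapply(1:20, function(r) {
      set.seed(1000 + 37 * m + r)
      mm <- cbind(runif(m, 0, 100), runif(m, 0, 100))
      def <- t(Fstar %*% t(mm)) + matrix(rnorm(2 * m, sd = 0.5), m, 2)
      norm(estimate_F(pair_vectors(mm), pair_vectors(def)) - Fstar, "F")
    }, numeric(1))
    mean(es)
  }, numeric(1))
  expect_true(all(diff(err) < 0))

  # collinear markers are rejected
  col <- cbind(1:5, 2 * (1:5))
  expect_error(estimate_F(pair_vectors(col), pair_vectors(col)), "collinear")
})

test_that("the normal-equation solution is least-squares optimal", {
  set.seed(8)
  mk <- cbind(runif(6, 0, 40), runif(6, 0, 40))
  L0 <- pair_vectors(mk)
  L <- L0 * 0.9 + matrix(rnorm(length(L0), sd = 0.3), 2)
  Fhat <- estimate_F(L0, L)
  r_hat <- norm(Fhat %*% L0 - L, "F")
  for (i in 1:1000) {
    cand <- Fhat + matrix(rnorm(4, sd = 0.05), 2, 2)
    expect_gte(norm(cand %*% L0 - L, "F"), r_hat)
  }
})

test_that("polar decomposition invariants hold, including on random
           rotation-stretch compositions", {
  st <- polar_and_stretches(diag(2))
  expect_equal(st$R, diag(2))
  expect_equal(c(st$lambda1, st$lambda2), c(1, 1))

  th <- pi / 6
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  st2 <- polar_and_stretches(Q)
  expect_equal(st2$U, diag(2), tolerance = 1e-12)

  st3 <- polar_and_stretches(diag(c(0.8, 1.1)))
  expect_equal(c(st3$lambda1, st3$lambda2), c(0.8, 1.1))
  expect_equal(st3$J, 0.88)

  set.seed(12)
  for (i in 1:1000) {
    a <- runif(1, 0, 2 * pi)
    Q <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    B <- matrix(rnorm(4), 2, 2)
    U <- crossprod(B) + diag(0.2, 2)   # SPD
    st <- polar_and_stretches(Q %*% U)
    expect_equal(crossprod(st$R), diag(2), tolerance = 1e-8)
    expect_equal(det(st$R), 1, tolerance = 1e-8)
    expect_equal(st$U, t(st$U), tolerance = 1e-8)
    expect_gt(st$lambda1, 0)
    expect_lte(st$lambda1, st$lambda2)
    expect_equal(st$R %*% st$U, Q %*% U, tolerance = 1e-8)
  }
  expect_error(polar_and_stretches(diag(c(-1, 1))), "flip")
})

test_that("F series track synthetic deformations and the reference frame
           is the identity", {
  set.seed(4)
  mk <- cbind(runif(6, 20, 80), runif(6, 20, 80))
  ctr <- colMeans(mk)
  cfun <- c(1, 0.95, 0.9, 0.95, 1)
  px <- vapply(cfun, function(c) ctr[1] + c * (mk[, 1] - ctr[1]), numeric(6))
  py <- vapply(cfun, function(c) ctr[2] + c * (mk[, 2] - ctr[2]), numeric(6))
  fs <- compute_F_series(px, py, reference_frame = 1)
  expect_identical(fs$states[[1]]$F, diag(2))
  for (t in seq_along(cfun)) {
    expect_equal(fs$lambda1[t], cfun[t], tolerance = 1e-6)
    expect_equal(fs$lambda2[t], cfun[t], tolerance = 1e-6)
  }
  # uniaxial stretch: lambda1 tracks, lambda2 stays 1
  ux <- vapply(cfun, function(c) ctr[1] + c * (mk[, 1] - ctr[1]), numeric(6))
  uy <- matrix(mk[, 2], 6, 5)
  fu <- compute_F_series(ux, uy, reference_frame = 1)
  expect_equal(fu$lambda1, cfun, tolerance = 1e-6)
  expect_equal(fu$lambda2, rep(1, 5), tolerance = 1e-6)
  # J multiplicativity under composed scalings
  expect_equal(fs$J[3], 0.9^2, tolerance = 1e-9)
  f23 <- estimate_F(pair_vectors(cbind(px[, 2], py[, 2])),
                    pair_vectors(cbind(px[, 3], py[, 3])))
  expect_equal(det(f23) * fs$J[2], fs$J[3], tolerance = 1e-9)
})

test_that("rotating the current frame rotates F accordingly", {
  set.seed(9)
  mk <- cbind(runif(5, 0, 30), runif(5, 0, 30))
  a <- 0.7
  Q <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  rot <- t(Q %*% t(mk))
  Fhat <- estimate_F(pair_vectors(mk), pair_vectors(rot))
  expect_equal(Fhat, Q, tolerance = 1e-10)
})

test_that("reference and contracted frames follow the two-pass det(F)
           rule", {
  set.seed(2)
  mk <- cbind(runif(5, 20, 80), runif(5, 20, 80))
  ctr <- colMeans(mk)
  scale_seq <- function(cf) list(
    px = vapply(cf, function(c) ctr[1] + c * (mk[, 1] - ctr[1]), numeric(5)),
    py = vapply(cf, function(c) ctr[2] + c * (mk[, 2] - ctr[2]), numeric(5)))
  # monotone relaxation: reference is the last frame
  rel <- scale_seq(seq(0.9, 1.1, length.out = 6))
  expect_equal(unname(select_frames(rel$px, rel$py)["reference"]), 6L)
  # static scene: tie broken to frame 1
  st <- scale_seq(rep(1, 4))
  expect_equal(unname(select_frames(st$px, st$py)["reference"]), 1L)
  # single beat: contracted frame at the minimum scale
  cf <- c(1, 0.97, 0.9, 0.85, 0.9, 1)
  bt <- scale_seq(cf)
  fr <- select_frames(bt$px, bt$py)
  expect_equal(unname(fr["contracted"]), which.min(cf))
})

test_that("shortening matches its closed forms and summaries respect
           synchrony", {
  expect_equal(shortening(rep(0, 10)), 0)
  expect_equal(shortening(c(0.05, -0.10)), 0.15 / 1.05)
  # equivalence with the (Lmax - Lmin)/Lmax form on random series
  set.seed(21)
  for (i in 1:100) {
    L <- runif(30, 5, 15)
    y <- (L - mean(L)) / mean(L)
    expect_equal(shortening(y), (max(L) - min(L)) / max(L),
                 tolerance = 1e-12)
  }
  # identical synchronous series: s_med == s_avg == s
  y1 <- 0.1 * sin(seq(0, 4 * pi, length.out = 60))
  ss <- shortening_summary(rbind(y1, y1, y1))
  expect_equal(unname(ss["s_med"]), unname(ss["s_avg"]))
  expect_equal(unname(ss["s_med"]), shortening(y1))
  # antiphase pair: the mean series flattens, s_avg < s_med
  ss2 <- shortening_summary(rbind(y1, -y1))
  expect_lt(ss2[["s_avg"]], ss2[["s_med"]])
  # single series: all three coincide
  ss3 <- shortening_summary(rbind(y1))
  expect_equal(unname(ss3["s_med"]), unname(ss3["s_avg"]))
})

test_that("structural tensor and OOP behave at the symmetry points", {
  o1 <- structural_tensor_oop(rep(pi / 7, 50))
  expect_equal(o1$oop, 1, tolerance = 1e-12)
  expect_equal(sum(diag(o1$T)), 0, tolerance = 1e-12)
  o2 <- structural_tensor_oop(c(0, 45, 90, 135) * pi / 180)
  expect_equal(o2$oop, 0, tolerance = 1e-12)
  # 3 at 0 degrees + 1 at 90: closed form mean of diag(+-1, -+1)
  o3 <- structural_tensor_oop(c(0, 0, 0, pi / 2))
  expect_equal(o3$oop, 0.5, tolerance = 1e-12)
  expect_equal(abs(o3$v_max), c(1, 0), tolerance = 1e-12)
  # invariance under r -> -r
  r <- cbind(cos(c(0.3, 1.2, 2.0)), sin(c(0.3, 1.2, 2.0)))
  expect_equal(structural_tensor_oop(r)$oop,
               structural_tensor_oop(-r)$oop, tolerance = 1e-12)
})

test_that("contraction metrics match their closed forms", {
  expect_equal(c_iso(diag(2)), 0)
  expect_equal(c_iso(0.9 * diag(2)), 0.1, tolerance = 1e-12)
  expect_equal(c_iso(diag(c(0.8, 1))), 1 - sqrt(0.8), tolerance = 1e-12)
  expect_error(c_iso(diag(c(-1, 1))), "<= 0")
  expect_equal(c_parallel(diag(2), c(1, 0)), 0)
  expect_equal(c_parallel(diag(c(0.8, 0.95)), c(1, 0)), 0.2,
               tolerance = 1e-12)
  expect_equal(c_parallel(0.9 * diag(2), c(1 / sqrt(2), 1 / sqrt(2))), 0.1,
               tolerance = 1e-12)
})

test_that("all contraction metrics increase with prescribed amplitude", {
  vals <- lapply(c(0.05, 0.15), function(p) {
    chains <- lapply(c(0, 45, 90, 135) * pi / 180, function(a) {
      chain_spec(5, rest_length = 10, center = c(100, 100, 0), angle = a,
                 anchor = "start")
    })
    ground_truth(build_skeleton(chains,
                                beat_program(40, 20, peak = p)))$metrics
  })
  for (m in c("s_med", "s_avg", "c_iso", "c_parallel")) {
    expect_lt(vals[[1]][[m]], vals[[2]][[m]])
  }
})

test_that("J-series analysis counts beats and recovers the period", {
  t <- 1:120
  J <- 1 - 0.2 * exp(-((t %% 40) - 20)^2 / 18)
  out <- analyze_J(J)
  expect_equal(out$n_events, 3)
  expect_lt(abs(out$period - 40), 1)
  expect_warning(analyze_J(rep(1, 50)), "no contraction")
})
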