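# Shared fixtures (computed once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Full pipeline on the baseline validation scene (20-sarcomere sinusoidal
# chain, 80 frames, homogeneous 15% beat, low Perlin noise).
baseline_run <- function() fixture("baseline_run", {
  run_all(run_config(scene = baseline_scene(), seed = 1))
})

baseline_truth <- function() fixture("baseline_truth", {
  sc <- baseline_scene()
  ground_truth(build_skeleton(sc$chains, sc$program, sc$n_frames))
})

# Desynchronized variant: 1 frame of contraction delay per sarcomere.
desync_run <- function() fixture("desync_run", {
  run_all(run_config(scene = baseline_scene(phase_lag = 1), seed = 1))
})

# Small scene for fast pipeline smoke tests (gently curved so tracked
# markers are never collinear).
small_scene <- function(seed = 1) {
  ch <- chain_spec(6, rest_length = 10, center = c(48, 32, 0),
                   amplitude = 4, period = 60)
  prog <- beat_program(24, 6, peak = 0.15, period = 16, width = 2,
                       first_peak = 8)
  synth_scene(ch, prog, 24,
              render_params(shape = c(64, 96), perlin_magnitude = 0.05,
                            seed = seed))
}

# --- independent oracles -------------------------------------------------

# Naive all-pairs mutual-nearest ghost-point search (plain double loops,
# no shared code with link_sarcomeres beyond the published definitions).
brute_link_sarcomeres <- function(zdiscs) {
  n <- nrow(zdiscs)
  if (n < 2) return(matrix(integer(0), 0, 2))
  nn_dist <- numeric(n)
  for (i in 1:n) {
    best <- Inf
    for (j in 1:n) {
      if (i == j) next
      d <- sqrt((zdiscs$x[i] - zdiscs$x[j])^2 + (zdiscs$y[i] - zdiscs$y[j])^2)
      if (d < best) best <- d
    }
    nn_dist[i] <- best
  }
  mn <- stats::median(nn_dist)
  ghosts <- list()
  for (i in 1:n) {
    ex <- zdiscs$ex2[i] - zdiscs$ex1[i]
    ey <- zdiscs$ey2[i] - zdiscs$ey1[i]
    nr <- sqrt(ex^2 + ey^2)
    if (nr == 0) nr <- 1
    px <- -ey / nr
    py <- ex / nr
    ghosts[[2 * i - 1]] <- c(zdiscs$x[i] + px * mn / 2,
                             zdiscs$y[i] + py * mn / 2, zdiscs$local_id[i])
    ghosts[[2 * i]] <- c(zdiscs$x[i] - px * mn / 2,
                         zdiscs$y[i] - py * mn / 2, zdiscs$local_id[i])
  }
  ng <- length(ghosts)
  nn <- integer(ng)
  for (a in 1:ng) {
    bestd <- Inf
    bestj <- NA_integer_
    for (b in 1:ng) {
      if (ghosts[[a]][3] == ghosts[[b]][3]) next
      d <- sqrt(sum((ghosts[[a]][1:2] - ghosts[[b]][1:2])^2))
      better <- d < bestd - 1e-12 ||
        (d <= bestd + 1e-12 && !is.na(bestj) &&
           (ghosts[[b]][3] < ghosts[[bestj]][3] ||
              (ghosts[[b]][3] == ghosts[[bestj]][3] && b < bestj)))
      if (is.na(bestj) || better) {
        bestd <- d
        bestj <- b
      }
    }
    nn[a] <- bestj
  }
  pairs <- matrix(integer(0), 0, 2)
  for (a in 1:ng) {
    b <- nn[a]
    if (nn[b] == a && a < b) {
      pr <- sort(c(ghosts[[a]][3], ghosts[[b]][3]))
      pairs <- rbind(pairs, pr)
    }
  }
  unique(pairs)
}

# Random z-disc configurations with separated centers and random axes.
random_disc_config <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    p <- runif(2, 10, 90)
    if (nrow(pts) == 0 || min(sqrt(rowSums((pts - matrix(p, nrow(pts), 2,
                                                         byrow = TRUE))^2))) > 6) {
      pts <- rbind(pts, p)
    }
  }
  th <- runif(n, 0, pi)
  len <- runif(n, 3, 6)
  data.frame(local_id = 1:n, x = pts[, 1], y = pts[, 2], length = len,
             ex1 = pts[, 1] - cos(th) * len / 2,
             ey1 = pts[, 2] - sin(th) * len / 2,
             ex2 = pts[, 1] + cos(th) * len / 2,
             ey2 = pts[, 2] + sin(th) * len / 2,
             n_points = 10L)
}

# Exhaustive-optimal one-to-one assignment (max links, then min squared
# cost) by enumerating all injections; for small frames only.
brute_assignment <- function(a, b, max_d) {
  na <- nrow(a)
  nb <- nrow(b)
  best <- list(links = -1L, cost = Inf, pairs = NULL)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  subsets <- function(v, k) if (k == 0) list(integer(0)) else
    utils::combn(v, k, simplify = FALSE)
  for (k in min(na, nb):0) {
    for (sa in subsets(seq_len(na), k)) {
      for (sb in subsets(seq_len(nb), k)) {
        for (p in perms(sb)) {
          d2 <- (a[sa, 1] - b[p, 1])^2 + (a[sa, 2] - b[p, 2])^2
          if (all(d2 <= max_d^2)) {
            cost <- sum(d2)
            if (k > best$links || (k == best$links && cost < best$cost)) {
              best <- list(links = k, cost = cost, pairs = cbind(sa, p))
            }
          }
        }
      }
    }
    if (best$links == k && k > 0) break
  }
  best
}

# Shortest sarcomere-pair network distance by exhaustive simple-path
# enumeration between all endpoint combinations.
brute_network_distance <- function(graph, edge_a, edge_b) {
  if (edge_a == edge_b) return(0L)
  va <- igraph::ends(graph, edge_a)[1, ]
  vb <- igraph::ends(graph, edge_b)[1, ]
  best <- Inf
  for (u in va) {
    for (w in vb) {
      if (u == w) {
        best <- min(best, 0)
        next
      }
      ps <- igraph::all_simple_paths(graph, from = u, to = w)
      for (p in ps) best <- min(best, length(p) - 1)
    }
  }
  if (!is.finite(best)) return(Inf)
  as.integer(best + 1)
}
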