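test_that("RDF matches brute-force pair counting bin by bin", {
  set.seed(31)
  n <- 50; L <- 8
  pts <- matrix(runif(3 * n, 0, L), ncol = 3)
  topo <- bare_topology(rep("CL", n), rep("CL", n), seq_len(n))
  tr <- traj_from_frames(list(pts), box = diag(L, 3))
  bw <- 0.2
  rdf <- radial_distribution(tr, topo, reference = "CL", target = "CL",
                             bin_width = bw, r_max = L / 2)
  # oracle: direct enumeration of all ordered pairs
  counts <- numeric(length(rdf$r))
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    d <- brute_min_image(pts[i, ], pts[j, ], diag(L, 3))
    if (d <= L / 2) {
      b <- min(length(counts), max(1, ceiling(d / bw)))
      counts[b] <- counts[b] + 1
    }
  }
  expect_equal(rdf$n_cum, cumsum(counts) / n, tolerance = 1e-12)
})

test_that("two fixed atoms produce a single occupied RDF bin", {
  pts <- rbind(c(1, 1, 1), c(1.5, 1, 1))
  topo <- bare_topology(c("CL", "CL"), c("CL", "CL"), 1:2)
  tr <- traj_from_frames(list(pts), box = diag(8, 3))
  rdf <- radial_distribution(tr, topo, reference = 1, target = 2,
                             bin_width = 0.1, r_max = 3)
  expect_equal(sum(rdf$g > 0), 1)
  expect_equal(rdf$r[rdf$g > 0], 0.45, tolerance = 0.051)  # bin holding 0.5
  expect_true(all(rdf$n_cum[rdf$r >= 0.5] == 1))
  expect_true(all(diff(rdf$n_cum) >= 0))
})

test_that("cumulative RDFs are exchange-consistent between selections", {
  set.seed(5)
  L <- 6
  A <- matrix(runif(12, 0, L), ncol = 3)
  B <- matrix(runif(21, 0, L), ncol = 3)
  nA <- nrow(A); nB <- nrow(B)
  topo <- bare_topology(c(rep("OW", nA), rep("CL", nB)),
                        c(rep("SOL", nA), rep("CL", nB)),
                        c(seq_len(nA), nA + seq_len(nB)))
  tr <- traj_from_frames(list(rbind(A, B)), box = diag(L, 3))
  r_ab <- radial_distribution(tr, topo, reference = seq_len(nA),
                              target = nA + seq_len(nB), bin_width = 0.25)
  r_ba <- radial_distribution(tr, topo, reference = nA + seq_len(nB),
                              target = seq_len(nA), bin_width = 0.25)
  expect_equal(r_ab$n_cum * nA, r_ba$n_cum * nB, tolerance = 1e-12)
})

test_that("shell counts recover density times volume and are additive", {
  n <- 800; L <- 10
  gas <- generate_uniform_gas(n, L, seed = 13)
  # one gold atom pinned at the centre defines the reference point
  topo <- bare_topology(c("AU", rep("CL", n)), c("AUC", rep("CL", n)),
                        c(1L, 1L + seq_len(n)))
  tr <- traj_from_frames(list(rbind(rep(L / 2, 3), gas)), box = diag(L, 3))
  shells <- cbind(c(0, 1, 2, 3), c(1, 2, 3, 4))
  sc <- shell_counts(tr, topo, target = "CL", shells = shells)
  rho <- n / L^3
  vol <- 4 / 3 * pi * (shells[, 2]^3 - shells[, 1]^3)
  expect_equal(sc$mean_count, rho * vol, tolerance = 0.15)
  total <- shell_counts(tr, topo, target = "CL", shells = cbind(0, 4))
  expect_equal(sum(sc$mean_count), total$mean_count)
  far <- shell_counts(tr, topo, target = "CL", shells = cbind(20, 30))
  expect_equal(far$mean_count, 0)
  expect_error(shell_counts(tr, topo, "CL", cbind(c(0, 1), c(2, 3))),
               class = "nanosite_config_error")
})

test_that("RMSF is zero for a static system and exact for planted motion", {
  np <- small_np()
  tr <- static_traj(np, n_frames = 4)
  r <- rmsf(tr, np$topology)
  expect_equal(max(r$rmsf), 0, tolerance = 1e-10)
  # one atom oscillating +/- d along x with equal occupancy -> RMSF = d
  d <- 0.3
  probe <- select_atoms(np$topology, roles = "ZN")[1]
  frames <- list(np$frame, np$frame, np$frame, np$frame)
  frames[[2]][probe, 1] <- frames[[2]][probe, 1] + d
  frames[[4]][probe, 1] <- frames[[4]][probe, 1] + d
  frames[[1]][probe, 1] <- frames[[1]][probe, 1] - d
  frames[[3]][probe, 1] <- frames[[3]][probe, 1] - d
  tr2 <- traj_from_frames(frames, box = diag(9, 3))
  r2 <- rmsf(tr2, np$topology)
  expect_equal(r2$rmsf[r2$index == probe], d, tolerance = 1e-9)
  expect_error(rmsf(static_traj(np, n_frames = 1), np$topology),
               class = "nanosite_insufficient_data_error")
})

test_that("RMSF is invariant under a global rotation of every frame", {
  np <- small_np()
  cfg <- small_config(n_frames = 5)
  tr <- generate_trajectory(np, NULL, cfg)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  rot <- tr
  for (f in seq_len(n_frames(tr)))
    rot$coords[f, , ] <- tr$coords[f, , ] %*% t(R)
  r1 <- rmsf(tr, np$topology)
  r2 <- rmsf(rot, np$topology)
  expect_equal(r2$rmsf, r1$rmsf, tolerance = 1e-8)
})

test_that("radius of gyration matches closed forms", {
  topo1 <- bare_topology("CL", "CL", 1L)
  tr1 <- traj_from_frames(list(matrix(c(1, 1, 1), ncol = 3)))
  expect_equal(radius_of_gyration(tr1, topo1, 1)$rg, 0)
  # two equal masses separated by d -> d/2
  topo2 <- bare_topology(c("CL", "CL"), c("CL", "CL"), 1:2)
  tr2 <- traj_from_frames(list(rbind(c(0, 0, 0), c(0.8, 0, 0))))
  expect_equal(radius_of_gyration(tr2, topo2, 1:2)$rg, 0.4)
  # dense thin shell of radius R -> Rg -> R
  R <- 1.7
  shell <- nanosite:::.fibonacci_sphere(2000) * R
  topo3 <- bare_topology(rep("CL", 2000), rep("CL", 2000), seq_len(2000))
  tr3 <- traj_from_frames(list(sweep(shell, 2, c(5, 5, 5), "+")))
  expect_equal(radius_of_gyration(tr3, topo3, seq_len(2000))$rg, R,
               tolerance = 1e-3)
})

test_that("eccentricity separates spheres from rods and needs 3D extent", {
  g <- as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0:3)) * 0.3
  topo <- bare_topology(rep("AU", nrow(g)), rep("AUC", nrow(g)),
                        rep(1L, nrow(g)))
  tr <- traj_from_frames(list(sweep(g, 2, c(4, 4, 4), "+")))
  e_cube <- eccentricity(tr, topo, seq_len(nrow(g)))$eccentricity
  expect_lt(e_cube, 0.02)
  # near-linear rod: I_min -> 0 so e -> 1
  rod <- cbind(seq(0, 5, length.out = 40), rnorm(40, sd = 1e-3),
               rnorm(40, sd = 1e-3))
  topo_r <- bare_topology(rep("AU", 40), rep("AUC", 40), rep(1L, 40))
  tr_r <- traj_from_frames(list(rod))
  expect_gt(eccentricity(tr_r, topo_r, 1:40)$eccentricity, 0.99)
  # rotation invariance
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  tr_rot <- traj_from_frames(list(sweep(g, 2, c(4, 4, 4), "+") %*% t(R)))
  expect_equal(eccentricity(tr_rot, topo, seq_len(nrow(g)))$eccentricity,
               e_cube, tolerance = 1e-9)
  # exactly collinear -> geometry error
  line <- cbind(1:5, 0, 0)
  topo_l <- bare_topology(rep("AU", 5), rep("AUC", 5), rep(1L, 5))
  expect_error(eccentricity(traj_from_frames(list(line)), topo_l, 1:5),
               class = "nanosite_geometry_error")
})

test_that("per-frame descriptors are invariant under global translation", {
  np <- small_np()
  cfg <- small_config(n_frames = 4)
  tr <- generate_trajectory(np, NULL, cfg)
  shifted <- tr
  for (f in seq_len(n_frames(tr)))
    shifted$coords[f, , ] <- sweep(tr$coords[f, , ], 2, c(1.3, -0.7, 2.2), "+")
  sel <- select_atoms(np$topology, roles = "GOLD")
  expect_equal(radius_of_gyration(shifted, np$topology, sel)$rg,
               radius_of_gyration(tr, np$topology, sel)$rg)
  expect_equal(eccentricity(shifted, np$topology, sel)$eccentricity,
               eccentricity(tr, np$topology, sel)$eccentricity)
  expect_equal(rmsf(shifted, np$topology)$rmsf, rmsf(tr, np$topology)$rmsf,
               tolerance = 1e-8)
})
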