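# small donor/hydrogen/acceptor system built by hand: two "ligand" residues
# each carrying N9-HN9 and O8 so interligand amide HBs can form
hb_fixture <- function(geometry) {
  # geometry: list of per-atom coordinates, names fixed below
  name <- c("N9", "HN9", "O8", "N9", "HN9", "O8")
  resname <- rep("LIG", 6)
  resid <- c(1L, 1L, 1L, 2L, 2L, 2L)
  topo <- bare_topology(name, resname, resid)
  tr <- traj_from_frames(list(do.call(rbind, geometry)))
  list(topo = topo, tr = tr)
}

test_that("a linear N-H...O arrangement inside both cutoffs is one bond", {
  fx <- hb_fixture(list(c(1, 1, 1), c(1.101, 1, 1), c(1.29, 1, 1),
                        c(5, 5, 5), c(5.101, 5, 5), c(3, 3, 3)))
  hb <- hydrogen_bonds(fx$tr, fx$topo, donors = "N9", hydrogens = 2,
                       acceptors = "O8")
  expect_equal(nrow(hb$bonds), 1)
  expect_equal(hb$bonds$donor, 1)
  expect_equal(hb$bonds$acceptor, 3)
  expect_equal(hb$bonds$tag, "intraligand")
})

test_that("donors beyond 0.35 nm or bent beyond 30 degrees do not bond", {
  far <- hb_fixture(list(c(1, 1, 1), c(1.101, 1, 1), c(1.40, 1, 1),
                         c(5, 5, 5), c(5.101, 5, 5), c(6, 6, 6)))
  expect_equal(nrow(hydrogen_bonds(far$tr, far$topo, "N9", c(2, 5),
                                   "O8")$bonds), 0)
  # acceptor at 0.3 nm but at 90 degrees from the N-H direction
  bent <- hb_fixture(list(c(1, 1, 1), c(1.101, 1, 1), c(1, 1.30, 1),
                          c(5, 5, 5), c(5.101, 5, 5), c(6, 6, 6)))
  expect_equal(nrow(hydrogen_bonds(bent$tr, bent$topo, "N9", c(2, 5),
                                   "O8")$bonds), 0)
})

test_that("a hydrogen without a covalently bonded donor is a labelling error", {
  fx <- hb_fixture(list(c(1, 1, 1), c(2.5, 1, 1), c(1.29, 1, 1),
                        c(5, 5, 5), c(5.101, 5, 5), c(6, 6, 6)))
  expect_error(hydrogen_bonds(fx$tr, fx$topo, "N9", 2, "O8"),
               class = "nanosite_labeling_error")
})

test_that("hydrogen bonds match brute-force triple enumeration", {
  # dense random cluster of ten N9/HN9/O8 residues in a 1.2 nm ball
  set.seed(17)
  nres <- 10
  nn <- matrix(runif(3 * nres, 2, 3.2), ncol = 3)
  hh <- nn + 0.101 * t(apply(matrix(rnorm(3 * nres), ncol = 3), 1,
                             function(u) u / sqrt(sum(u^2))))
  oo <- matrix(runif(3 * nres, 2, 3.2), ncol = 3)
  frame <- do.call(rbind, lapply(seq_len(nres), function(i)
    rbind(nn[i, ], hh[i, ], oo[i, ])))
  topo <- bare_topology(rep(c("N9", "HN9", "O8"), nres),
                        rep("LIG", 3 * nres),
                        rep(seq_len(nres), each = 3))
  tr <- traj_from_frames(list(frame), box = diag(9, 3))
  don <- select_atoms(topo, roles = "N9")
  hyd <- select_atoms(topo, names = "HN9")
  acc <- select_atoms(topo, roles = "O8")
  hb <- hydrogen_bonds(tr, topo, don, hyd, acc, d_cut = 0.6, angle_cut = 60)
  # oracle: enumerate every (D, H, A) triple directly (nearest-donor pairing)
  found <- list()
  box <- diag(9, 3)
  for (h in hyd) {
    dists <- vapply(don, function(dn)
      periodic_distance(frame[h, ], frame[dn, ], box), numeric(1))
    dn <- don[which.min(dists)]
    for (a in acc) {
      if (a == dn) next
      da <- periodic_distance(frame[dn, ], frame[a, ], box)
      if (da > 0.6) next
      vh <- frame[h, ] - frame[dn, ]; va <- frame[a, ] - frame[dn, ]
      ang <- acos(sum(vh * va) / sqrt(sum(vh^2) * sum(va^2))) * 180 / pi
      if (ang <= 60) found[[length(found) + 1]] <- c(dn, h, a)
    }
  }
  oracle <- do.call(rbind, found)
  got <- as.matrix(hb$bonds[, c("donor", "hydrogen", "acceptor")])
  expect_gt(nrow(oracle), 0)  # fixture is meaningful
  expect_equal(got[order(got[, 2], got[, 3]), , drop = FALSE],
               oracle[order(oracle[, 2], oracle[, 3]), , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("close contacts honour the inclusive cutoff boundary", {
  # Zn-Cl pairs at 0.24 and 0.26 nm with a 0.25 nm cutoff: exactly one contact
  name <- c("NT1", "ZN", "NT1", "ZN", "CL", "CL")
  resname <- c("LIG", "LIG", "LIG", "LIG", "CL", "CL")
  resid <- c(1L, 1L, 2L, 2L, 3L, 4L)
  topo <- bare_topology(name, resname, resid)
  frame <- rbind(c(1, 1, 1.2), c(1, 1, 1), c(5, 5, 5.2), c(5, 5, 5),
                 c(1.24, 1, 1), c(5.26, 5, 5))
  tr <- traj_from_frames(list(frame))
  cc <- close_contacts(tr, topo, "ZN", "CL", cutoff = 0.25)
  expect_equal(nrow(cc$contacts), 1)
  expect_equal(cc$contacts$distance, 0.24, tolerance = 1e-9)
  expect_equal(cc$summary$mean, 1)
  none <- close_contacts(tr, topo, "ZN", "CL", cutoff = 1e-6)
  expect_equal(nrow(none$contacts), 0)
})

test_that("contact detection equals a brute-force O(n^2) scan", {
  n <- 100; L <- 5
  gas <- generate_uniform_gas(n, L, seed = 29)
  topo <- bare_topology(c(rep("OW", 50), rep("CL", 50)),
                        c(rep("SOL", 50), rep("CL", 50)), seq_len(n))
  tr <- traj_from_frames(list(gas), box = diag(L, 3))
  cc <- close_contacts(tr, topo, "WATER_O", "CL", cutoff = 0.8)
  oracle <- 0
  for (i in 1:50) for (j in 51:100)
    if (brute_min_image(gas[i, ], gas[j, ], diag(L, 3)) <= 0.8)
      oracle <- oracle + 1
  expect_equal(nrow(cc$contacts), oracle)
})
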