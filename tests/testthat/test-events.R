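test_that("three mutually close Zn ions give three unique pairs", {
  np <- build_nanoparticle(synthetic_config(n_ligands = 4, n_substrates = 0,
                                            n_waters = 0, n_cl = 0,
                                            n_frames = 1, jitter_sigma = 0,
                                            seed = 2))
  frame <- np$frame
  zn <- select_atoms(np$topology, roles = "ZN")
  frame[zn[1], ] <- c(4.0, 4.0, 4.0)
  frame[zn[2], ] <- c(4.4, 4.0, 4.0)
  frame[zn[3], ] <- c(4.2, 4.3, 4.0)
  frame[zn[4], ] <- c(7.0, 7.0, 7.0)
  tr <- traj_from_frames(list(frame), box = diag(9, 3))
  det <- detect_zn_pair_series(tr, np$topology, cutoff = 0.50)
  expect_equal(det$n_unique_sites, 3)
  expect_setequal(paste(det$pairs$zn_i[det$pairs$ever],
                        det$pairs$zn_j[det$pairs$ever]),
                  c("1 2", "1 3", "2 3"))
})

test_that("distant Zn ions yield no sites and fewer than two Zn is an error", {
  np <- small_np()
  tr <- static_traj(np, n_frames = 3)
  det <- detect_zn_pair_series(tr, np$topology, cutoff = 0.50)
  expect_equal(det$n_unique_sites, 0)
  one <- build_nanoparticle(synthetic_config(n_ligands = 1, n_substrates = 0,
                                             n_waters = 0, n_cl = 0,
                                             n_frames = 1, seed = 2))
  expect_error(detect_zn_pair_series(static_traj(one, 2), one$topology),
               class = "nanosite_selection_error")
})

test_that("event segmentation splits boolean series into maximal runs", {
  seg <- segment_events(c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE), dt = 5)
  expect_equal(seg$start, c(2, 6))
  expect_equal(seg$existence_ps, c(15, 5))
  expect_equal(nrow(segment_events(rep(FALSE, 6), dt = 5)), 0)
  all_on <- segment_events(rep(TRUE, 7), dt = 5)
  expect_equal(all_on$existence_ps, 35)
  expect_equal(nrow(segment_events(logical(0), dt = 5)), 0)
  # gap tolerance bridges single false frames on request
  gapped <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(nrow(segment_events(gapped, 5)), 2)
  expect_equal(segment_events(gapped, 5, gap_tolerance = 1)$existence_ps, 25)
})

test_that("binding classification follows the mono/bi definitions", {
  # O4 on one Zn only -> monometallic
  d <- dist_matrix(o3 = c(0.6, 0.7), o4 = c(0.24, 0.8), o5 = c(0.6, 0.9))
  expect_equal(classify_binding_dists(d), list(state = "MONO_BINDING",
                                               zn = "zn1"))
  # O4 and O5 on two different Zn -> bimetallic
  d2 <- dist_matrix(o3 = c(0.6, 0.7), o4 = c(0.24, 0.8), o5 = c(0.9, 0.23))
  r2 <- classify_binding_dists(d2)
  expect_equal(r2$state, "BI_BINDING")
  expect_setequal(r2$zn, c("zn1", "zn2"))
  # everything far -> none
  d3 <- dist_matrix(o3 = c(0.6, 0.7), o4 = c(0.5, 0.8), o5 = c(0.9, 0.6))
  expect_equal(classify_binding_dists(d3)$state, "NONE")
  # a second Zn touching any substrate oxygen voids the mono assignment
  d4 <- dist_matrix(o3 = c(0.6, 0.22), o4 = c(0.24, 0.8), o5 = c(0.9, 0.6))
  expect_equal(classify_binding_dists(d4)$state, "NONE")
})

test_that("precatalytic types follow their definitions with 2 > 3 > 1 precedence", {
  # type 2: phosphoryl oxygens bridge two Zn, O3 on one of them
  d <- dist_matrix(o3 = c(0.24, 0.6), o4 = c(0.22, 0.7), o5 = c(0.8, 0.23))
  r <- classify_precatalytic_dists(d)
  expect_equal(r$state, "PRECAT_2")
  expect_equal(unname(r$geometry[c("d1", "d2", "d3")]), c(0.22, 0.23, 0.24))
  # type 3: one Zn on the phosphate, the second on the hydroxyl only
  d3m <- dist_matrix(o3 = c(0.6, 0.24), o4 = c(0.22, 0.7), o5 = c(0.8, 0.7))
  r3 <- classify_precatalytic_dists(d3m)
  expect_equal(r3$state, "PRECAT_3")
  expect_setequal(r3$zn, c("zn1", "zn2"))
  # type 1: a single Zn holds all three oxygens
  d1m <- dist_matrix(o3 = c(0.24, 0.6), o4 = c(0.22, 0.7), o5 = c(0.21, 0.8))
  r1 <- classify_precatalytic_dists(d1m)
  expect_equal(r1$state, "PRECAT_1")
  expect_equal(r1$zn, "zn1")
})


test_that("classifiers agree with the exhaustive truth-table oracle", {
  vals <- c(0.20, 0.30)
  grid <- expand.grid(o3a = vals, o3b = vals, o4a = vals, o4b = vals,
                      o5a = vals, o5b = vals)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    d <- dist_matrix(o3 = c(g$o3a, g$o3b), o4 = c(g$o4a, g$o4b),
                     o5 = c(g$o5a, g$o5b))
    expect_equal(classify_precatalytic_dists(d)$state, oracle_precat(d),
                 info = paste(unlist(g), collapse = ","))
    expect_equal(classify_binding_dists(d)$state, oracle_binding(d),
                 info = paste(unlist(g), collapse = ","))
    # subset relations between precatalytic and binding states
    ps <- classify_precatalytic_dists(d)$state
    bs <- classify_binding_dists(d)$state
    if (ps == "PRECAT_1") expect_equal(bs, "MONO_BINDING")
    if (ps == "PRECAT_2") expect_equal(bs, "BI_BINDING")
  }
})

test_that("solvation flags implement the d4/d5 activation criteria", {
  np <- small_np()
  frame <- np$frame
  zn1 <- select_atoms(np$topology, roles = "ZN", ligand = 1)
  o3 <- select_atoms(np$topology, roles = "SUB_O3", substrate = 1)
  wo <- select_atoms(np$topology, roles = "WATER_O")[1]
  # water 0.19 nm from Zn, O3 placed 0.24 nm from that water
  frame[wo, ] <- frame[zn1, ] + c(0.19, 0, 0)
  frame[o3, ] <- frame[wo, ] + c(0, 0.24, 0)
  tr <- traj_from_frames(list(frame), box = diag(9, 3))
  fl <- solvation_flags(tr, np$topology, 1, zn_ligand_ids = 1, substrate = 1)
  expect_true(fl[["solvated"]]); expect_true(fl[["nucleophile_ready"]])
  # nearest water beyond 0.20 nm: neither flag
  frame[wo, ] <- frame[zn1, ] + c(0.30, 0, 0)
  fl2 <- solvation_flags(traj_from_frames(list(frame), box = diag(9, 3)),
                         np$topology, 1, 1, 1)
  expect_false(fl2[["solvated"]]); expect_false(fl2[["nucleophile_ready"]])
  # bound water far from the hydroxyl oxygen: solvated only
  frame[wo, ] <- frame[zn1, ] + c(0.19, 0, 0)
  frame[o3, ] <- frame[wo, ] + c(0, 0.40, 0)
  fl3 <- solvation_flags(traj_from_frames(list(frame), box = diag(9, 3)),
                         np$topology, 1, 1, 1)
  expect_true(fl3[["solvated"]]); expect_false(fl3[["nucleophile_ready"]])
  # the d4 criterion is strict: exactly 0.20 nm does not count
  frame[wo, ] <- frame[zn1, ] + c(0.20, 0, 0)
  fl4 <- solvation_flags(traj_from_frames(list(frame), box = diag(9, 3)),
                         np$topology, 1, 1, 1)
  expect_false(fl4[["solvated"]])
})

test_that("planted complexes become events with exact identity and duration", {
  cfg <- small_config(n_frames = 40, jitter = 0)
  np <- build_nanoparticle(cfg)
  sch <- event_schedule(
    schedule_event("PRECAT_2", zn1 = 3, zn2 = 9, substrate = 1, start = 10,
                   duration = 6, d1 = 0.22, d2 = 0.23, d3 = 0.24),
    schedule_event("MONO_BINDING", zn1 = 5, substrate = 2, start = 4,
                   duration = 3, d1 = 0.24),
    # same identity active twice -> two separate events
    schedule_event("MONO_BINDING", zn1 = 5, substrate = 2, start = 20,
                   duration = 2, d1 = 0.24),
    n_frames = 40)
  tr <- generate_trajectory(np, sch, cfg)
  prec <- build_events(tr, np$topology, kind = "precat")
  expect_equal(nrow(prec), 1)
  expect_equal(prec$state, "PRECAT_2")
  expect_equal(prec$zn, "3,9")
  expect_equal(prec$start_ps, (10 - 1) * 5)
  expect_equal(prec$existence_ps, 30)
  bind <- build_events(tr, np$topology, kind = "binding")
  mono <- bind[bind$state == "MONO_BINDING", ]
  expect_equal(nrow(mono), 2)
  expect_equal(sort(mono$existence_ps), c(10, 15))
  expect_true(all(mono$zn == "5"))
  # the planted bimetallic complex is also a bimetallic binding event
  expect_true(any(bind$state == "BI_BINDING" & bind$zn == "3,9" &
                    bind$existence_ps == 30))
})

test_that("an empty trajectory of events yields an empty tibble", {
  cfg <- small_config(n_frames = 5)
  np <- build_nanoparticle(cfg)
  tr <- generate_trajectory(np, NULL, cfg)
  ev <- build_events(tr, np$topology, kind = "precat")
  expect_s3_class(ev, "nanosite_events")
  expect_equal(nrow(ev), 0)
})

test_that("transition counts tally consecutive distinct states", {
  tc <- transition_counts(c("MONO_BINDING", "PRECAT_1", "PRECAT_1",
                            "MONO_BINDING"))
  expect_equal(tc$count[tc$from == "MONO_BINDING" & tc$to == "PRECAT_1"], 1L)
  expect_equal(tc$count[tc$from == "PRECAT_1" & tc$to == "MONO_BINDING"], 1L)
  expect_equal(sum(tc$count), 2L)
  expect_equal(sum(transition_counts(rep("NONE", 10))$count), 0L)
  # aggregation over substrates
  tc2 <- transition_counts(list(c("NONE", "MONO_BINDING"),
                                c("NONE", "MONO_BINDING")))
  expect_equal(tc2$count[tc2$from == "NONE" & tc2$to == "MONO_BINDING"], 2L)
})

test_that("a planted mono-to-bimetallic path shows up in the transition matrix", {
  cfg <- small_config(n_frames = 12, jitter = 0)
  np <- build_nanoparticle(cfg)
  sch <- event_schedule(
    schedule_event("MONO_BINDING", zn1 = 2, substrate = 1, start = 3,
                   duration = 3, d1 = 0.24),
    schedule_event("PRECAT_2", zn1 = 2, zn2 = 8, substrate = 1, start = 6,
                   duration = 3, d1 = 0.22, d2 = 0.23, d3 = 0.24),
    n_frames = 12)
  tr <- generate_trajectory(np, sch, cfg)
  states <- vapply(seq_len(12), function(f)
    classify_precatalytic(tr, np$topology, f, 1)$state, character(1))
  bstates <- vapply(seq_len(12), function(f)
    classify_binding(tr, np$topology, f, 1)$state, character(1))
  merged <- ifelse(states == "NONE", bstates, states)
  tc <- transition_counts(merged)
  expect_equal(tc$count[tc$from == "MONO_BINDING" & tc$to == "PRECAT_2"], 1L)
})
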