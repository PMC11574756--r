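torsion_fixture <- function(angle, frame = 1) {
  # quadruple with the b-c axis along z; rotating d about that axis by
  # `angle` (clockwise looking from b to c) sets the signed torsion
  tibble::tibble(
    frame = frame, residue = "LIG1", atom = c("C5", "O5", "C1", "C2"),
    x = c(1, 0, 0, cos(angle * pi / 180)),
    y = c(0, 0, 0, -sin(angle * pi / 180)),
    z = c(-0.5, 0, 1, 1.5)
  )
}

test_that("torsions and distances are measured to machine precision", {
  for (a in c(-120, -60, 0, 11, 60, 179)) {
    fr <- torsion_fixture(a)
    m <- measure_frames(fr, dihedral = list(c("LIG1", "C5"), c("LIG1", "O5"),
                                            c("LIG1", "C1"), c("LIG1", "C2")))
    expect_equal(m$dihedral, a, tolerance = 1e-9)
  }
  # a perfectly planar fragment has zero torsion
  m0 <- measure_frames(torsion_fixture(0),
                       dihedral = list(c("LIG1", "C5"), c("LIG1", "O5"),
                                       c("LIG1", "C1"), c("LIG1", "C2")))
  expect_equal(m0$dihedral, 0, tolerance = 1e-12)
})

test_that("frame measurements match naive pairwise recomputation and survive rigid motion", {
  set.seed(31)
  traj <- gen_reaction_trajectory(n_recrossings = 1, frames_per_leg = 10,
                                  noise_sd = 0.01, seed = 5)
  sel <- list(
    d_c1_o1 = list(c("LIG1", "C1"), c("GAL1", "O1")),
    d_ow_c1 = list(c("WAT1", "OW"), c("LIG1", "C1")),
    d_c1_o5 = list(c("LIG1", "C1"), c("LIG1", "O5"))
  )
  dih <- list(c("LIG1", "C5"), c("LIG1", "O5"), c("LIG1", "C1"), c("LIG1", "C2"))
  m <- measure_frames(traj, distances = sel, dihedral = dih)
  fr3 <- traj[traj$frame == 3, ]
  for (nm in names(sel)) {
    a <- fr3[fr3$residue == sel[[nm]][[1]][1] & fr3$atom == sel[[nm]][[1]][2], ]
    b <- fr3[fr3$residue == sel[[nm]][[2]][1] & fr3$atom == sel[[nm]][[2]][2], ]
    expect_equal(m[[nm]][3],
                 sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2),
                 tolerance = 1e-12)
  }
  # rigid motion leaves every measured quantity unchanged
  traj2 <- apply_rigid_motion(traj, runif(3, 0, 2 * pi), rnorm(3, 0, 20))
  m2 <- measure_frames(traj2, distances = sel, dihedral = dih)
  for (col in c(names(sel), "dihedral")) {
    expect_lt(max(abs(m2[[col]] - m[[col]])), 1e-9)
  }
})

test_that("scripted TS frames carry the prescribed flattening dihedral", {
  traj <- gen_reaction_trajectory(n_recrossings = 1, frames_per_leg = 20,
                                  noise_sd = 0, seed = 2)
  presc <- attr(traj, "prescribed")
  m <- measure_frames(traj, dihedral = list(c("LIG1", "C5"), c("LIG1", "O5"),
                                            c("LIG1", "C1"), c("LIG1", "C2")))
  i_ts <- which.min(abs(presc$xi - 0.5))
  expect_equal(m$dihedral[i_ts], 11, tolerance = 1e-6)
  expect_equal(m$dihedral, presc$dihedral, tolerance = 1e-6)
})

test_that("dyad statistics recover the generating distribution and flag sharing", {
  traj <- gen_dyad_ensemble(1.32, 0.21, 2.54, 0.09, n = 5000, seed = 7)
  d <- measure_dyad(traj)
  rep_ <- dyad_analysis(d)
  expect_lt(abs(rep_$mean_dh - 1.32), 2 * 0.21 / sqrt(5000))
  expect_lt(abs(rep_$mean_da - 2.54), 2 * 0.09 / sqrt(5000))
  expect_true(rep_$lbhb_flag)
  expect_gt(rep_$fraction_shared, 0.25)
  expect_equal(generics::glance(rep_)$fraction_shared, rep_$fraction_shared)

  # an ordinary rigid H-bond never counts as shared
  rigid <- tibble::tibble(d_dh = rep(1.01, 50), d_da = rep(3.5, 50))
  rep2 <- dyad_analysis(rigid)
  expect_equal(rep2$fraction_shared, 0)
  expect_false(rep2$lbhb_flag)
  expect_equal(rep2$sd_dh, 0)
  expect_error(dyad_analysis(rigid[1:5, ]), "10 frames")
})

test_that("fraction_shared is monotone as the sharing threshold relaxes", {
  traj <- gen_dyad_ensemble(1.32, 0.21, 2.54, 0.09, n = 400, seed = 3)
  d <- measure_dyad(traj)
  fr <- vapply(seq(1.5, 0.8, by = -0.1),
               function(th) dyad_analysis(d, shared_dh_min = th)$fraction_shared,
               0)
  expect_true(all(diff(fr) >= 0))
})

test_that("itinerary compresses conformer runs and filters flicker", {
  # constant-conformer trajectory
  traj <- gen_ring_trajectory(c("1,4B" = 1), n_frames = 40, noise_sd = 0,
                              seed = 1)
  pk <- pucker_trajectory(traj)
  it <- itinerary(pk)
  expect_identical(it$string, "1,4B")
  expect_equal(sum(it$steps$dwell_fraction), 1)

  # scripted geodesic passage through the TS conformer: the forward
  # (R -> P) pass visits 1,4B, flattens to 4E at the TS, returns to 1,4B
  traj2 <- gen_reaction_trajectory(n_recrossings = 1, frames_per_leg = 40,
                                   noise_sd = 0, seed = 4)
  presc <- attr(traj2, "prescribed")
  fwd <- presc$frame[seq_len(which.max(presc$xi >= 1) + 12)]
  traj2 <- traj2[traj2$frame %in% fwd, ]
  pk2 <- pucker_trajectory(traj2[traj2$residue == "RNG1", ])
  it2 <- itinerary(pk2)
  expect_identical(it2$string, "1,4B -> 4E -> 1,4B")
  expect_true(all(it2$steps$conformer[-1] != head(it2$steps$conformer, -1)))
  expect_equal(sum(it2$steps$dwell_fraction), 1)

  # sub-threshold flicker collapses to a single label
  lab <- rep("1,4B", 200); lab[c(50, 120)] <- "4E"
  it3 <- itinerary(tibble::tibble(conformer = lab), min_dwell_fraction = 0.02)
  expect_identical(it3$string, "1,4B")
  # idempotent under re-compression
  it4 <- itinerary(tibble::tibble(conformer = rep(it3$steps$conformer,
                                                  times = 100)))
  expect_identical(it4$string, it3$string)
})

test_that("oxocarbenium descriptors track the scripted C1-O5 shortening", {
  traj <- gen_reaction_trajectory(n_recrossings = 1, frames_per_leg = 30,
                                  noise_sd = 0, seed = 6)
  presc <- attr(traj, "prescribed")
  m <- measure_frames(traj,
                      distances = list(d_c1_o5 = list(c("LIG1", "C1"),
                                                      c("LIG1", "O5"))),
                      dihedral = list(c("LIG1", "C5"), c("LIG1", "O5"),
                                      c("LIG1", "C1"), c("LIG1", "C2")))
  ox <- oxocarbenium_descriptors(m)
  expect_equal(ox$d_c1_o5, presc$d_c1_o5, tolerance = 1e-9)
  # bond shortest and ring flattest at the TS
  i_ts <- which.min(abs(presc$xi - 0.5))
  expect_equal(attr(ox, "min_d_c1_o5"), ox$frame[i_ts])
  expect_equal(ox$d_c1_o5[i_ts], 1.29, tolerance = 1e-9)
  expect_equal(attr(ox, "max_flattening"), ox$frame[i_ts])
  # a rigid fixture gives constant series
  mm <- tibble::tibble(frame = 1:12, d_c1_o5 = 1.41, dihedral = 35)
  oxr <- oxocarbenium_descriptors(mm)
  expect_equal(unique(oxr$d_c1_o5), 1.41)
})
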