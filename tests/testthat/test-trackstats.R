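test_that("Hungarian assignment matches brute-force enumeration", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(2:5, 1)
    m <- n + sample(0:2, 1)
    cost <- matrix(runif(n * m), n, m)
    a <- poretrack:::hungarian_assign(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), oracle_assignment_cost(cost),
                 tolerance = 1e-12)
    expect_equal(anyDuplicated(a), 0)
  }
})

test_that("linking conserves detections and resolves parallel emitters", {
  cfg <- acq_config(frame_count = 60, rng_seed = 12)
  locs <- sim_planar_trajectories(data.frame(D = 0.5, fraction = 1), n = 8,
                                  cfg = cfg)
  tr <- link_trajectories(dplyr::select(locs, -traj_id), max_disp = 1)
  expect_equal(nrow(tr), nrow(locs))                # every detection kept
  expect_false(any(duplicated(tr[c("frame", "x_um", "y_um")])))
  # strictly increasing frames within each trajectory
  by_tr <- split(tr$frame, tr$traj_id)
  expect_true(all(vapply(by_tr, function(f) all(diff(f) > 0), logical(1))))

  # two parallel emitters 10 px apart stay unbroken
  par2 <- tibble::tibble(
    frame = rep(0:49, 2),
    x_um = c(seq(1, 3, length.out = 50), seq(1, 3, length.out = 50)),
    y_um = rep(c(1, 1 + 10 * 0.107), each = 50)
  )
  tr2 <- link_trajectories(par2, max_disp = 0.5)
  expect_equal(dplyr::n_distinct(tr2$traj_id), 2)
  expect_true(all(table(tr2$traj_id) == 50))

  # single emitter over 100 frames: one full trajectory
  one <- tibble::tibble(frame = 0:99, x_um = 2, y_um = 2)
  tr3 <- link_trajectories(one, max_disp = 0.5)
  expect_equal(dplyr::n_distinct(tr3$traj_id), 1)
  expect_equal(nrow(tr3), 100)

  # a missing frame is bridged with max_gap = 1 but split with max_gap = 0
  gap <- one[one$frame != 50, ]
  expect_equal(dplyr::n_distinct(link_trajectories(gap, 0.5, max_gap = 1)$traj_id), 1)
  expect_equal(dplyr::n_distinct(link_trajectories(gap, 0.5, max_gap = 0)$traj_id), 2)
  expect_error(link_trajectories(one, max_disp = 0), "> 0")
})

test_that("grid DBSCAN agrees with the textbook implementation", {
  set.seed(13)
  for (i in 1:10) {
    n <- 120
    x <- c(rnorm(40, 1, 0.02), rnorm(40, 2, 0.02), runif(40, 0, 3))
    y <- c(rnorm(40, 1, 0.02), rnorm(40, 2, 0.02), runif(40, 0, 3))
    got <- poretrack:::dbscan_cluster(x, y, eps = 0.06, min_samples = 8)
    want <- oracle_dbscan(x, y, eps = 0.06, min_samples = 8)
    # same noise set and same partition (labels may be permuted)
    expect_equal(got == 0, want == 0)
    core <- got != 0
    expect_equal(length(unique(got[core])), length(unique(want[core])))
    tab <- table(got[core], want[core])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("immobile filtering separates stationary from fast emitters", {
  cfg <- acq_config(frame_count = 100, rng_seed = 14)
  mix <- sim_planar_trajectories(data.frame(D = 2.5, fraction = 1), n = 20,
                                 immobile_fraction = 0.5, cfg = cfg)
  truth <- sim_truth(mix)
  out <- filter_immobile(mix)
  agreement <- mean(out$mobility == truth$mobility_class[out$traj_id])
  expect_gt(agreement, 0.95)
  # empty table: empty result with the same columns
  empty <- filter_immobile(mix[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("mobility", "cluster_id") %in% names(empty)))
})

test_that("mobility classification reaches 95% accuracy at study conditions", {
  cfg <- acq_config(frame_count = 30, rng_seed = 15)
  mix <- sim_planar_trajectories(
    data.frame(D = c(2.5, 1.0), fraction = c(0.5, 0.5)),
    n = 400, immobile_fraction = 0.3, cfg = cfg
  )
  truth <- sim_truth(mix)
  cls <- classify_mobility(mix, cfg = cfg)
  acc <- mean(cls$mobility == truth$mobility_class[cls$traj_id])
  expect_gte(acc, 0.95)
  # short trajectories are unclassified
  short <- mix[mix$traj_id == 1 & mix$frame < 3, ]
  cls_short <- classify_mobility(short, cfg = cfg)
  expect_equal(cls_short$mobility, "unclassified")
})

test_that("rigid registration recovers exact and jittered transforms", {
  set.seed(16)
  beads <- tibble::tibble(x_um = runif(25, 0, 50), y_um = runif(25, 0, 50))
  # identity
  tf0 <- estimate_transform(beads, beads)
  expect_equal(tf0$angle, 0, tolerance = 1e-12)
  expect_equal(tf0$translation, c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tf0$rms_residual, 0, tolerance = 1e-12)
  # pure 1 um shift
  shifted <- dplyr::mutate(beads, x_um = x_um + 1)
  tf1 <- estimate_transform(beads, shifted)
  expect_equal(tf1$angle, 0, tolerance = 1e-12)
  expect_equal(tf1$translation, c(1, 0), tolerance = 1e-10, ignore_attr = TRUE)
  # random rigid motion + 10 nm jitter recovered to < 5 nm (Monte Carlo)
  for (i in 1:5) {
    ang <- runif(1, -0.3, 0.3); tx <- runif(2, -5, 5)
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    xy <- as.matrix(beads) %*% t(rot)
    moved <- tibble::tibble(x_um = xy[, 1] + tx[1] + rnorm(25, 0, 0.010),
                            y_um = xy[, 2] + tx[2] + rnorm(25, 0, 0.010))
    tf <- estimate_transform(beads, moved)
    back <- apply_transform(beads, tf)
    rms <- sqrt(mean((back$x_um - (xy[, 1] + tx[1]))^2 +
                       (back$y_um - (xy[, 2] + tx[2]))^2))
    expect_lt(rms, 0.005)
  }
  # estimate o apply is identity for noiseless rigid motion
  moved0 <- apply_transform(beads, structure(list(angle = 0.2,
                                                  translation = c(1, -2)),
                                             class = "rigid_transform2d"))
  tf2 <- estimate_transform(beads, moved0)
  round_trip <- apply_transform(beads, tf2)
  expect_equal(round_trip$x_um, moved0$x_um, tolerance = 1e-10)
  # degenerate geometry flagged
  two <- beads[1:2, ]
  expect_true(estimate_transform(two, two)$degenerate)
  expect_error(estimate_transform(beads[1, ], beads[1, ]), ">= 2")
})

test_that("co-localization applies the 107 nm radius inclusively and mutually", {
  # x = 0 keeps the offsets exactly representable: b - a == offset
  a <- tibble::tibble(frame = 0L, x_um = 0, y_um = c(0, 10, 20))
  # identical tables: all co-localized
  expect_equal(nrow(colocalize(a, a)), 3)
  # 200 nm offset: none at the default radius
  b200 <- dplyr::mutate(a, x_um = x_um + 0.200)
  expect_equal(nrow(colocalize(a, b200)), 0)
  # 100 nm offset: all
  b100 <- dplyr::mutate(a, x_um = x_um + 0.100)
  expect_equal(nrow(colocalize(a, b100)), 3)
  # exactly 107 nm: inside the threshold (<= semantics)
  b107 <- dplyr::mutate(a, x_um = x_um + 0.107)
  expect_equal(nrow(colocalize(a, b107)), 3)
  # mutual nearest neighbours: two A cannot claim one B twice
  a2 <- tibble::tibble(frame = 0L, x_um = c(1.00, 1.05), y_um = 1)
  b2 <- tibble::tibble(frame = 0L, x_um = 1.02, y_um = 1)
  expect_equal(nrow(colocalize(a2, b2)), 1)
})

test_that("kymographs show static, moving and bouncing signatures", {
  px <- 0.107
  cfg <- acq_config(field_size = 24, rng_seed = 17)
  line <- rbind(c(0.2, 12 * px), c(2.2, 12 * px))
  # static emitter: horizontal streak (same argmax every frame)
  still <- tibble::tibble(frame = 0:9, x_um = 1.2, y_um = 12 * px, photons = 1000)
  ks <- kymograph(sim_movie(still, cfg, shot_noise = FALSE, n_frames = 10), line)
  expect_equal(length(unique(apply(ks, 2, which.max))), 1)
  # constant velocity: argmax advances linearly
  mov <- tibble::tibble(frame = 0:9, x_um = seq(0.5, 1.9, length.out = 10),
                        y_um = 12 * px, photons = 1000)
  km <- kymograph(sim_movie(mov, cfg, shot_noise = FALSE, n_frames = 10), line)
  peaks <- apply(km, 2, which.max)
  expect_true(all(diff(peaks) > 0))
  fitv <- lm(peaks ~ seq_along(peaks))
  expect_gt(summary(fitv)$r.squared, 0.98)
  # two bouncing particles: approach then separation (V signature)
  xa <- c(seq(0.6, 1.2, length.out = 6), seq(1.1, 0.7, length.out = 5)[-1])
  xb <- c(seq(1.8, 1.2, length.out = 6), seq(1.3, 1.7, length.out = 5)[-1])
  boun <- tibble::tibble(frame = rep(0:9, 2), x_um = c(xa, xb),
                         y_um = 12 * px, photons = 1000)
  kb <- kymograph(boun, line, width_px = 3, cfg = cfg)
  pos <- apply(kb, 2, function(col) range(which(col > 0)))
  gap <- pos[2, ] - pos[1, ]
  expect_lt(min(gap[5:6]), gap[1])     # closest at the collision
  expect_gt(gap[10], min(gap))         # separating afterwards
  expect_error(kymograph(boun, rbind(c(1, 1), c(1, 1))), "zero length")
})
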