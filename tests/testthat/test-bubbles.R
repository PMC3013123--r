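test_that("opening_indicator requires every site in the window to be open", {
  expect_true(opening_indicator(c(2, 2, 2), 1, 3, 1.5))
  expect_false(opening_indicator(c(2, 1, 2), 1, 3, 1.5))
  expect_true(opening_indicator(c(0, 2, 0), 2, 1, 1.5))
  expect_error(opening_indicator(c(2, 2, 2), 2, 3, 1.5), "bounds")
})

test_that("detect_bubbles recovers a crafted plateau exactly", {
  # sites 6-8 open (y = 3) during frames 11-20 of 30; sample_dt = 1 ps
  ev <- data.frame(start = 6L, length = 3L, birth = 11L, death = 21L, amplitude = 3.0)
  traj <- make_planted_trajectory(12, 30, events = ev)
  hits <- detect_bubbles(traj, threshold = 1.5, length = 3, sample_dt = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 6L)
  expect_equal(hits$lifetime, 10)
  expect_equal(hits$birth_frame, 11L)
  expect_equal(hits$death_frame, 21L)
  expect_false(hits$censored)
  # all-zero trajectory -> no events
  expect_equal(nrow(detect_bubbles(matrix(0, 10, 5), 0.5, 2)), 0L)
})

test_that("events touching a trajectory boundary are flagged censored", {
  ev <- data.frame(start = c(2L, 5L), length = c(2L, 2L),
                   birth = c(1L, 15L), death = c(6L, 21L), amplitude = 3.0)
  traj <- make_planted_trajectory(8, 20, events = ev)
  hits <- detect_bubbles(traj, 1.5, 2)
  hits <- hits[order(hits$start), ]
  expect_equal(hits$censored, c(TRUE, TRUE))  # one at frame 1, one at last frame
  ev2 <- data.frame(start = 2L, length = 2L, birth = 5L, death = 10L, amplitude = 3.0)
  expect_false(any(detect_bubbles(make_planted_trajectory(8, 20, events = ev2),
                                  1.5, 2)$censored))
})

test_that("run-length detection matches brute-force per-cell scanning", {
  set.seed(99)
  for (rep in 1:10) {
    n_frames <- sample(5:50, 1); n_sites <- sample(3:20, 1)
    traj <- matrix(sample(c(0, 3), n_frames * n_sites, replace = TRUE,
                          prob = c(0.7, 0.3)), n_frames, n_sites)
    for (len in c(1L, 2L, min(3L, n_sites))) {
      fast <- detect_bubbles(traj, 1.5, len)
      slow <- brute_force_bubbles(traj, 1.5, len)
      o_f <- order(fast$start, fast$birth_frame)
      o_s <- order(slow$start, slow$birth_frame)
      expect_equal(fast[o_f, c("start", "birth_frame", "death_frame", "lifetime", "censored")],
                   slow[o_s, ], ignore_attr = TRUE)
    }
  }
})

test_that("lifetime_profile pools a replicated fixture with exact arithmetic", {
  ev <- data.frame(start = 6L, length = 3L, birth = 11L, death = 21L, amplitude = 3.0)
  traj <- make_planted_trajectory(12, 30, events = ev)
  s <- promoter_sequence(strrep("AT", 6), 6)
  ens <- manual_ensemble(replicate(4, traj, simplify = FALSE), s, sample_dt = 1)
  prof <- lifetime_profile(ens, thresholds = c(0.5, 1.5), L_max = 4, margin = 2)
  pos <- which(prof$starts == 6L)
  i15 <- which(prof$thresholds == 1.5)
  expect_equal(prof$mean_lifetime[i15, 3, pos], 10)
  expect_equal(prof$event_count[i15, 3, pos], 4L)
  expect_equal(prof$occupancy[i15, 3, pos], 10 / 30)
  # neighbouring start cannot host a 3-bp bubble (site 5 never opens)
  expect_equal(prof$event_count[i15, 3, which(prof$starts == 5L)], 0L)
  expect_true(is.na(prof$mean_lifetime[i15, 3, which(prof$starts == 5L)]))
  # positions are TSS-relative with no zero
  expect_false(any(prof$positions == 0L))
  expect_equal(prof$positions, tss_coordinate(s, prof$starts))
})

test_that("censoring policy: drop excludes boundary events from means, keep retains them", {
  ev <- data.frame(start = 3L, length = 2L, birth = 1L, death = 11L, amplitude = 3.0)
  traj <- make_planted_trajectory(10, 20, events = ev)
  s <- promoter_sequence(strrep("GC", 5), 5)
  ens <- manual_ensemble(list(traj), s, sample_dt = 1)
  drop <- lifetime_profile(ens, thresholds = 1.5, L_max = 2, margin = 1)
  keep <- lifetime_profile(ens, thresholds = 1.5, L_max = 2, margin = 1,
                           censoring = "keep")
  pos <- which(drop$starts == 3L)
  expect_equal(drop$event_count[1, 2, pos], 0L)
  expect_equal(drop$n_censored[1, 2, pos], 1L)
  expect_true(is.na(drop$mean_lifetime[1, 2, pos]))
  expect_equal(keep$event_count[1, 2, pos], 1L)
  expect_equal(keep$mean_lifetime[1, 2, pos], 10)
  # occupancy is identical under either policy
  expect_equal(drop$occupancy, keep$occupancy)
})

test_that("occupancy is monotone non-increasing in threshold and bubble length", {
  s <- make_sequence(focused_design(4))
  cfg <- test_scale_config(seed = 4, n_replicas = 4L)
  prof <- lifetime_profile(simulate_ensemble(s, default_params, cfg),
                           thresholds = c(0.5, 1.0, 1.5, 2.1), L_max = 10)
  occ <- prof$occupancy
  for (ti in seq_along(prof$thresholds)[-1]) {
    d <- occ[ti, , ] - occ[ti - 1L, , ]
    expect_lte(max(d, na.rm = TRUE), 0)
  }
  for (li in seq_along(prof$lengths)[-1]) {
    d <- occ[, li, ] - occ[, li - 1L, ]
    expect_lte(max(d, na.rm = TRUE), 0)
  }
  # lifetimes are at least one frame wherever events were counted
  has <- !is.na(prof$event_count) & prof$event_count > 0
  expect_true(all(prof$mean_lifetime[has] >= prof$sample_dt))
})

test_that("profile pooling is invariant under replica reordering", {
  s <- make_sequence(flat_design(8))
  cfg <- test_scale_config(seed = 8, n_replicas = 3L, n_prod_steps = 1000L,
                           n_equil_steps = 500L)
  ens <- simulate_ensemble(s, default_params, cfg)
  ens_rev <- ens
  ens_rev$replicas <- rev(ens$replicas)
  a <- lifetime_profile(ens, thresholds = c(0.5, 1.0), L_max = 5)
  b <- lifetime_profile(ens_rev, thresholds = c(0.5, 1.0), L_max = 5)
  expect_equal(a$occupancy, b$occupancy)
  expect_equal(a$mean_lifetime, b$mean_lifetime)
  expect_equal(a$event_count, b$event_count)
})

test_that("profile JSON round trip is lossless and the TSV export is complete", {
  s <- make_sequence(focused_design(6))
  cfg <- test_scale_config(seed = 6, n_replicas = 2L, n_prod_steps = 1000L,
                           n_equil_steps = 500L)
  prof <- lifetime_profile(simulate_ensemble(s, default_params, cfg),
                           thresholds = c(0.5, 1.0), L_max = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$occupancy, prof$occupancy)
  expect_equal(back$mean_lifetime, prof$mean_lifetime)
  expect_equal(back$event_count, prof$event_count)
  expect_equal(back$positions, prof$positions)
  expect_equal(back$thresholds, prof$thresholds)
  expect_equal(back$sample_dt, prof$sample_dt)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_profile_tsv(prof, tsv)
  tab <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), length(prof$thresholds) * length(prof$lengths) *
                 length(prof$positions))
  # masked cells carry empty lifetimes, occupancy written as 0
  masked <- is.na(as.vector(prof$mean_lifetime)) & is.na(as.vector(prof$occupancy))
  expect_true(all(tab$occupancy[masked] == 0))

  # version guard
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format":"other","format_version":"0"}', bad)
  expect_error(read_profile(bad), "version")
})
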