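test_that("layout presets realize the study block structures", {
  sch <- make_layout("schroeder_like", seed = 1)
  expect_equal(nrow(sch), 6L) # 3 sets x 2 conditions
  expect_true(all(sch$duration == 140))
  agg <- aggregate(duration ~ condition + set_id, sch, sum)
  expect_true(all(agg$duration == 140)) # 140 s per condition per set

  shin <- make_layout("shin_like", seed = 2)
  expect_equal(nrow(shin), 18L) # 3 sets x 3 x 2 interleaved runs
  expect_true(all(shin$duration == 40))
  agg <- aggregate(duration ~ condition + set_id, shin, sum)
  expect_true(all(agg$duration == 120)) # 120 s per condition per set
  # no condition twice in a row within a set
  for (s in 1:3) {
    cond <- shin$condition[shin$set_id == s][order(shin$chrono_index[shin$set_id == s])]
    expect_false(any(cond[-1] == cond[-length(cond)]))
  }

  hin <- make_layout("hinss_multiday_like", seed = 3)
  expect_equal(nrow(hin), 18L) # 3 days x 2 conditions x 3 runs
  agg <- aggregate(duration ~ condition + set_id, hin, sum)
  expect_true(all(agg$duration == 96)) # 96 s per condition per set
  # repetitions of one condition grouped in a single block within a day
  for (d in 1:3) {
    sub <- hin[hin$day_id == d, ]
    sub <- sub[order(sub$chrono_index), ]
    expect_equal(length(rle(sub$condition)$lengths), 2L)
  }

  hs <- make_layout("hinss_singleday_like", seed = 4)
  expect_equal(nrow(hs), 6L)
  expect_true(all(hs$day_id == 1L))
  # set membership cuts across the grouped condition blocks
  expect_equal(sort(unique(hs$set_id)), 1:3)
  expect_equal(length(unique(hs$block_id)), 2L)

  expect_error(make_layout("nope"), "arg")
})

test_that("pink noise has the requested aperiodic slope", {
  # oracle: log-log least squares on the averaged periodogram, 1-40 Hz
  fitted_slope <- function(slope, seed) {
    n <- 2^16
    fs <- 500
    x <- pink_noise(n, slope = slope, fs = fs, seed = seed)
    nseg <- 16
    seg <- matrix(x, n / nseg, nseg)
    P <- rowMeans(Mod(stats::mvfft(seg))^2)
    f <- (seq_len(n / nseg) - 1) * fs / (n / nseg)
    sel <- f >= 1.5 & f <= 40
    -coef(lm(log(P[sel]) ~ log(f[sel])))[2]
  }
  expect_lt(abs(fitted_slope(0, 11) - 0), 0.1)
  expect_lt(abs(fitted_slope(1, 12) - 1), 0.1)
  expect_identical(pink_noise(1000, 1, 500, seed = 5),
                   pink_noise(1000, 1, 500, seed = 5))
  expect_error(pink_noise(1000, slope = -1), "slope")
})

test_that("null class effect makes labels exchangeable", {
  # permutation oracle on mean theta-band power, 100 seeds
  n_seeds <- 100
  pvals <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    p <- small_params(layout = "schroeder_like", run_dur = 8,
                      class_effect = 0,
                      block_effect = c(channel_gain_sd = 0, drift_sd = 0,
                                       aperiodic_shift_sd = 0),
                      seed = 1000 + s)
    rec <- generate_subject(p)
    ws <- extract_windows(rec)
    bp <- bandpower_features(ws, bands = list(theta = c(4, 7)))
    stat <- abs(mean(rowMeans(bp$x)[ws$meta$condition == "high"]) -
                  mean(rowMeans(bp$x)[ws$meta$condition == "low"]))
    null <- neurocv:::with_seed(s, vapply(1:199, function(i) {
      lab <- sample(ws$meta$condition)
      abs(mean(rowMeans(bp$x)[lab == "high"]) -
            mean(rowMeans(bp$x)[lab == "low"]))
    }, numeric(1)))
    pvals[s] <- (1 + sum(null >= stat)) / 200
  }
  rejection <- mean(pvals <= 0.05)
  expect_gte(rejection, 0.02)
  expect_lte(rejection, 0.08)
})

test_that("positive class effect raises theta power in the high condition", {
  for (s in 1:20) {
    p <- small_params(layout = "schroeder_like", run_dur = 8,
                      class_effect = 0.5, seed = 2000 + s,
                      block_effect = c(channel_gain_sd = 0, drift_sd = 0,
                                       aperiodic_shift_sd = 0))
    rec <- generate_subject(p)
    ws <- extract_windows(rec)
    bp <- bandpower_features(ws, bands = list(theta = c(4, 7)))
    m <- tapply(rowMeans(bp$x), ws$meta$condition, mean)
    expect_gt(m[["high"]], m[["low"]])
  }
})

test_that("block confounds make set identity decodable from covariances", {
  # operational definition of the confound: the package's own MDM can
  # predict set_id above the adjusted chance level when class_effect = 0
  p <- small_params(layout = "shin_like", run_dur = 20, class_effect = 0,
                    block_effect = c(channel_gain_sd = 0.3, drift_sd = 0.3,
                                     aperiodic_shift_sd = 0.3), seed = 31)
  rec <- generate_subject(p)
  ws <- extract_windows(bandpass_fir(rec, 1, 25))
  covs <- neurocv:::lw_covariance_stack(ws$x)
  sets <- as.character(ws$meta$set_id)
  run <- ws$meta$run_id
  runs <- unique(run)
  test_runs <- neurocv:::with_seed(32, unlist(lapply(split(runs, ws$meta$set_id[match(runs, run)]),
                                           function(r) sample(r, 2))))
  test <- run %in% test_runs
  model <- mdm_fit(covs[, , !test], sets[!test], tol = 1e-4)
  pred <- mdm_predict(model, covs[, , test])
  acc <- mean(pred == sets[test])
  expect_gt(acc, adjusted_chance(sum(test), n_classes = 3))
})

test_that("within-set covariance distances are smaller than between-set", {
  # AIRM confound locality, >= 10 seeds; indistinguishable when
  # block_effect = 0
  gap <- function(block_sd, seed) {
    p <- small_params(layout = "schroeder_like", run_dur = 10,
                      class_effect = 0,
                      block_effect = c(channel_gain_sd = block_sd,
                                       drift_sd = block_sd,
                                       aperiodic_shift_sd = block_sd),
                      seed = seed)
    ws <- extract_windows(generate_subject(p))
    covs <- neurocv:::lw_covariance_stack(ws$x)
    n <- dim(covs)[3]
    pick <- neurocv:::with_seed(seed, sample(n, min(24, n)))
    D <- outer(pick, pick, Vectorize(function(i, j) {
      if (i >= j) NA_real_ else airm_distance(covs[, , i], covs[, , j])
    }))
    same <- outer(ws$meta$set_id[pick], ws$meta$set_id[pick], "==")
    mean(D[!same], na.rm = TRUE) - mean(D[same], na.rm = TRUE)
  }
  gaps_on <- vapply(1:10, function(s) gap(0.35, 40 + s), numeric(1))
  expect_true(all(gaps_on > 0))
  gaps_off <- vapply(1:10, function(s) gap(0, 60 + s), numeric(1))
  expect_lt(abs(mean(gaps_off)), mean(gaps_on) / 4)
})

test_that("cohort generation is deterministic and seed-derived", {
  p <- small_params(run_dur = 4, seed = 1)
  co1 <- generate_cohort(3, p, seed = 99)
  co2 <- generate_cohort(3, p, seed = 99)
  expect_identical(co1, co2)
  mixes <- lapply(co1, function(r) r$data[, 1:100])
  expect_false(identical(mixes[[1]], mixes[[2]]))
  seeds <- neurocv:::derive_seeds(99, 3)
  pk <- p
  pk$seed <- seeds[2]
  solo <- generate_subject(pk, subject_id = "S02")
  expect_identical(solo, co1[[2]])
})

test_that("generation is a pure function of the parameters", {
  p <- small_params(run_dur = 4, seed = 77)
  expect_identical(generate_subject(p), generate_subject(p))
})
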