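mk_window_set <- function(x, fs = 128, labels = NULL) {
  n_win <- dim(x)[3]
  meta <- data.frame(condition = labels %||% rep(c("low", "high"),
                                                 length.out = n_win),
                     run_id = 1L, set_id = 1L, day_id = 1L, block_id = 1L,
                     chrono_index = seq_len(n_win))
  structure(list(x = x, fs = fs,
                 channels = default_montage()[seq_len(dim(x)[1])],
                 meta = meta),
            class = "ncv_window_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("band powers concentrate, satisfy Parseval and count 4 x n", {
  fs <- 128
  tt <- seq_len(256) / fs
  x <- array(rnorm(28 * 256 * 3, sd = 0.001), c(28, 256, 3))
  x[1, , 1] <- sin(2 * pi * 10 * tt) # pure alpha on channel 1
  ws <- mk_window_set(x, fs)
  bp <- bandpower_features(ws)
  expect_equal(ncol(bp$x), 112) # 4 bands x 28 electrodes
  alpha_col <- which(bp$names == "alpha.Fp1")
  all_ch1 <- grep("\\.Fp1$", bp$names)
  expect_gt(bp$x[1, alpha_col] / sum(bp$x[1, all_ch1]), 0.99)
  # Parseval: the periodogram bins sum to the window variance (the band
  # [0, 64) covers every bin except Nyquist, whose power is accounted for)
  seg <- x[2, , 2] - mean(x[2, , 2])
  P <- Mod(fft(seg))^2 / 256^2
  v_pop <- mean(seg^2)
  full <- bandpower_features(ws, bands = list(all = c(0, 64)))
  got <- full$x[2, which(full$names == "all.Fp2")]
  expect_equal(got + P[129], v_pop, tolerance = 1e-10)
  expect_equal(sum(P[-1]), v_pop, tolerance = 1e-10)
  expect_error(bandpower_features(ws, bands = list(bad = c(10, 100))),
               "Nyquist")
})

test_that("CSP solves the two-class variance-ratio problem", {
  # analytic toy: trace-normalized class covariances diag(2,1)/3, diag(1,2)/3
  cube <- array(0, c(2, 2, 4))
  cube[, , 1] <- cube[, , 2] <- diag(c(2, 1))
  cube[, , 3] <- cube[, , 4] <- diag(c(1, 2))
  bank <- fit_csp(cube, c("a", "a", "b", "b"), n_filters = 2)
  expect_equal(max(bank$eigenvalues), 2 / 3, tolerance = 1e-8)
  expect_true(all(bank$eigenvalues > 0 & bank$eigenvalues < 1))
  # filters jointly diagonalize both class covariances
  set.seed(8)
  A <- matrix(rnorm(36), 6)
  n <- 40
  cube <- array(0, c(6, 6, n))
  lab <- rep(c("a", "b"), each = n / 2)
  for (i in seq_len(n)) {
    gains <- if (lab[i] == "a") c(3, 1, 1, 1, 1, 0.3) else rep(1, 6)
    x <- A %*% (matrix(rnorm(6 * 200), 6) * gains)
    cube[, , i] <- tcrossprod(x) / 199
  }
  bank <- fit_csp(cube, lab, n_filters = 6)
  avg <- function(cl) {
    M <- 0
    for (i in which(lab == cl)) M <- M + cube[, , i] / sum(diag(cube[, , i]))
    M / sum(lab == cl)
  }
  W <- bank$filters
  for (C in list(avg("a"), avg("b"))) {
    D <- t(W) %*% C %*% W
    expect_lt(max(abs(D - diag(diag(D)))), 1e-8)
  }
  expect_error(fit_csp(cube, rep("a", n)), "two classes")
})

test_that("z-normalization uses training statistics only", {
  set.seed(9)
  tr <- matrix(rnorm(100, mean = 5, sd = 2), 20)
  nrm <- zscore_fit(tr)
  z <- zscore_apply(tr, nrm)
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-12)
  te <- tr + 3
  expect_equal(zscore_apply(te, nrm), z + 3 / rep(nrm$sd, each = 20),
               tolerance = 1e-12)
  tr2 <- cbind(tr, 7) # constant feature
  nrm2 <- zscore_fit(tr2)
  expect_true(nrm2$constant[6])
  expect_true(all(zscore_apply(tr2, nrm2)[, 6] == 0))
})

test_that("mRMR follows the F-statistic/correlation difference criterion", {
  set.seed(10)
  n <- 60
  lab <- rep(c("a", "b"), each = n / 2)
  strong <- rnorm(n) + (lab == "a") * 0.9
  # f3: strong permuted within class -> identical F statistic, decorrelated
  weak <- c(sample(strong[lab == "a"]), sample(strong[lab == "b"]))
  X <- cbind(f1 = strong, f2 = strong, f3 = weak, f4 = rnorm(n))
  Fstat <- neurocv:::f_statistic(X, lab)
  expect_equal(mrmr_select(X, lab, 1), unname(which.max(Fstat)))
  # the duplicate of the best feature carries redundancy penalty 1 and
  # loses to the equally relevant but near-independent f3
  expect_lt(abs(cor(X[, 1], X[, 3])), 0.8)
  expect_equal(sort(mrmr_select(X, lab, 2)), c(1, 3))
  # greedy trace equals an independent step-wise oracle on random instances
  oracle <- function(X, y, k) {
    rel <- neurocv:::f_statistic(X, y)
    sel <- integer(0)
    for (s in seq_len(k)) {
      cand <- setdiff(seq_len(ncol(X)), sel)
      score <- vapply(cand, function(j) {
        red <- if (length(sel)) mean(abs(cor(X[, j], X[, sel]))) else 0
        rel[j] - red
      }, numeric(1))
      sel <- c(sel, cand[which.max(score)])
    }
    sel
  }
  for (i in 1:20) {
    Xr <- matrix(rnorm(40 * 8), 40)
    Xr[, 1:3] <- Xr[, 1:3] + (lab[1:40] == "a") * matrix(rep(c(2, 1, 1), each = 40), 40)
    expect_identical(mrmr_select(Xr, lab[1:40], 4), oracle(Xr, lab[1:40], 4))
  }
  expect_error(mrmr_select(X, lab, 9), "exceeds")
})

test_that("LDA separates classes and matches its analytic geometry", {
  set.seed(11)
  n <- 100
  lab <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 2), n) + (lab == "a") %o% c(10, 0)
  model <- lda_fit(X, lab)
  expect_identical(lda_predict(model, X), lab)
  # isotropic classes: boundary is the perpendicular bisector of the means
  m1 <- colMeans(X[lab == "a", ])
  m2 <- colMeans(X[lab == "b", ])
  grid <- as.matrix(expand.grid(seq(-3, 13, by = 1), seq(-3, 3, by = 1)))
  bisector <- ifelse(colSums((t(grid) - m1)^2) < colSums((t(grid) - m2)^2),
                     "a", "b")
  agree <- mean(lda_predict(model, grid) == bisector)
  expect_gt(agree, 0.9) # only cells adjacent to the boundary may differ
  # permuting features permutes weights, predictions unchanged
  perm <- c(2, 1)
  model_p <- lda_fit(X[, perm], lab)
  expect_equal(model_p$w, model$w[perm], tolerance = 1e-8)
  expect_identical(lda_predict(model_p, X[, perm]), lda_predict(model, X))
  # cross-check decisions against the reference implementation
  skip_if_not_installed("MASS")
  fit <- MASS::lda(X, grouping = lab, prior = c(0.5, 0.5))
  expect_identical(as.character(predict(fit, X)$class),
                   lda_predict(model, X))
})

test_that("pipelines expose the documented feature dimensions", {
  rec <- cached_small_subject()
  labels <- NULL
  # psd_lda: 18 features after selection
  pl <- build_pipeline("psd_lda")
  prep <- pl$prepare(rec)
  idx <- seq_len(nrow(prep$meta))
  model <- pl$fit(prep, idx)
  expect_length(model$sel, 18)
  expect_length(model$lda$w, 18)
  # fbcsp: 80 features before selection (10 bands x 8 filters)
  pl <- build_pipeline("fbcsp")
  prep <- pl$prepare(rec)
  model <- pl$fit(prep, idx)
  expect_length(model$banks, 10)
  expect_equal(sum(vapply(model$banks, function(b) ncol(b$filters), 1L)), 80)
  expect_length(model$sel, 18)
  # narrow_rmdm: 4 bands x 8 electrodes -> 32 x 32 materialized matrix
  pl <- build_pipeline("narrow_rmdm")
  prep <- pl$prepare(rec)
  model <- pl$fit(prep, idx)
  blocks <- lapply(model$per_band, function(b) b$mdm$means[[1]])
  M <- materialize_block_spd(assemble_block_spd(blocks))
  expect_equal(dim(M), c(32, 32))
  expect_error(build_pipeline("nope"))
})
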