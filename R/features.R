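#' Band-power features from windowed data
#'
#' Per window, channel and band: the sum of periodogram power over DFT
#' bins whose centre frequency falls in `[lo, hi)`. The periodogram is
#' normalized so that the total over all non-DC bins equals the
#' time-domain variance of the (mean-removed) window (Parseval), so band
#' powers are in squared microvolts.
#'
#' @param window_set an `ncv_window_set`.
#' @param bands named list of `c(lo, hi)` pairs (default
#'   [canonical_bands()]).
#' @return an `ncv_features` object: list with `x` (windows x features),
#'   `names`, and the window metadata.
#' @export
bandpower_features <- function(window_set, bands = canonical_bands()) {
  ws <- window_set
  n_ch <- dim(ws$x)[1]
  wlen <- dim(ws$x)[2]
  n_win <- dim(ws$x)[3]
  freqs <- (seq_len(wlen) - 1) * ws$fs / wlen
  if (any(vapply(bands, max, 1) > ws$fs / 2)) stop("band outside Nyquist")
  half <- 2:(floor(wlen / 2) + 1) # positive-frequency bins (DC excluded)
  dup <- if (wlen %% 2 == 0) c(rep(2, length(half) - 1), 1) else rep(2, length(half))
  bin_band <- lapply(bands, function(b) {
    which(freqs[half] >= b[1] & freqs[half] < b[2])
  })
  feat <- matrix(0, n_win, n_ch * length(bands))
  for (w in seq_len(n_win)) {
    seg <- ws$x[, , w, drop = FALSE][, , 1]
    seg <- seg - rowMeans(seg)
    P <- Mod(stats::mvfft(t(seg)))^2 / wlen^2 # bins x channels
    Ph <- P[half, , drop = FALSE] * dup
    for (b in seq_along(bands)) {
      feat[w, (b - 1) * n_ch + seq_len(n_ch)] <-
        colSums(Ph[bin_band[[b]], , drop = FALSE])
    }
  }
  nm <- as.vector(vapply(names(bands), function(b) paste0(b, ".", ws$channels),
                         character(n_ch)))
  structure(list(x = feat, names = nm, meta = ws$meta), class = "ncv_features")
}

#' Common spatial patterns for one frequency band
#'
#' Solves the generalized eigenproblem of `(C1, C1 + C2)` where `Ci` is
#' the average trace-normalized class covariance of the training windows;
#' keeps the eigenvectors of the 4 largest and 4 smallest eigenvalues
#' (8 spatial filters). Eigenvalues of this formulation lie in (0, 1).
#'
#' @param covs channels x channels x n array of per-window sample
#'   covariances (one band).
#' @param labels two-class training labels.
#' @param n_filters number of spatial filters (default 8: 4 + 4).
#' @return list with `filters` (channels x n_filters) and `eigenvalues`.
#' @export
fit_csp <- function(covs, labels, n_filters = 8) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("CSP requires exactly two classes")
  if (min(table(labels)) < 2) stop("need >= 2 windows per class")
  avg_norm <- function(cl) {
    idx <- which(labels == cl)
    M <- 0
    for (i in idx) M <- M + covs[, , i] / sum(diag(covs[, , i]))
    M / length(idx)
  }
  C1 <- avg_norm(classes[1])
  C2 <- avg_norm(classes[2])
  Ct <- C1 + C2
  Ct <- Ct + diag(1e-10 * sum(diag(Ct)) / nrow(Ct), nrow(Ct)) # ridge
  # whiten: eigenvectors of Ct^{-1/2} C1 Ct^{-1/2}
  e <- eigen(Ct, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
  M <- W %*% C1 %*% W
  g <- eigen((M + t(M)) / 2, symmetric = TRUE)
  half <- n_filters / 2
  pick <- c(seq_len(half), nrow(M) - half + seq_len(half))
  filters <- W %*% g$vectors[, pick, drop = FALSE]
  list(filters = filters, eigenvalues = g$values[pick])
}

#' Log-variance CSP features
#'
#' @param covs channels x channels x n array of per-window sample
#'   covariances for the band the bank was fitted on.
#' @param bank result of [fit_csp()].
#' @return windows x n_filters matrix of log-variances.
#' @export
apply_csp_logvar <- function(covs, bank) {
  n <- dim(covs)[3]
  d <- dim(covs)[1]
  W <- bank$filters
  # diag(W' S W)_j = <vec(S), vec(w_j w_j')>: one GEMM over all windows
  P <- vapply(seq_len(ncol(W)), function(j) as.vector(tcrossprod(W[, j])),
              numeric(d * d))
  log(t(crossprod(P, matrix(covs, d * d, n))))
}

#' Train-set z-normalization
#'
#' `zscore_fit` learns per-feature mean and standard deviation on the
#' training windows; `zscore_apply` standardizes any feature matrix with
#' those training statistics only. Features constant on the training set
#' are flagged; their SD is replaced by 1, so they map to 0.
#'
#' @param train_features windows x features matrix.
#' @return normalizer list with `mean`, `sd`, `constant`.
#' @export
zscore_fit <- function(train_features) {
  mu <- colMeans(train_features)
  sdv <- apply(train_features, 2, sd)
  constant <- sdv <= 0 | !is.finite(sdv)
  sdv[constant] <- 1
  list(mean = mu, sd = sdv, constant = constant)
}

#' @rdname zscore_fit
#' @param features matrix to transform.
#' @param normalizer result of `zscore_fit`.
#' @export
zscore_apply <- function(features, normalizer) {
  out <- sweep(sweep(features, 2, normalizer$mean), 2, normalizer$sd, "/")
  out[, normalizer$constant] <- 0
  out
}

#' Greedy minimum-redundancy maximum-relevance feature selection
#'
#' The continuous-feature F-test/correlation variant: relevance is the
#' one-way F statistic of feature vs class; redundancy is the mean
#' absolute Pearson correlation with the already selected features; each
#' step adds the feature maximizing `relevance - redundancy` (difference
#' criterion). The first pick is the most relevant feature; ties go to the
#' lowest feature index. Deterministic given its inputs.
#'
#' @param features windows x features matrix.
#' @param labels two-class labels.
#' @param k number of features to select.
#' @return integer vector of `k` selected column indices, in pick order.
#' @export
mrmr_select <- function(features, labels, k = 18) {
  p <- ncol(features)
  if (k > p) stop("k exceeds the number of features")
  rel <- f_statistic(features, labels)
  rel[!is.finite(rel)] <- 0
  selected <- integer(0)
  remaining <- seq_len(p)
  cor_sel <- NULL # |cor| of every feature with each selected feature
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0) rel[remaining]
    else rel[remaining] - rowMeans(cor_sel[remaining, , drop = FALSE])
    pick <- remaining[which.max(score)] # which.max: first index wins ties
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    cc <- abs(suppressWarnings(cor(features, features[, pick])))
    cc[!is.finite(cc)] <- 0
    cor_sel <- cbind(cor_sel, cc)
  }
  selected
}

# One-way (two-group) F statistic per feature column
f_statistic <- function(features, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("two classes required")
  n <- nrow(features)
  g1 <- labels == classes[1]
  n1 <- sum(g1)
  n2 <- n - n1
  m1 <- colMeans(features[g1, , drop = FALSE])
  m2 <- colMeans(features[!g1, , drop = FALSE])
  m <- colMeans(features)
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- colSums((features[g1, , drop = FALSE] -
                    matrix(m1, n1, ncol(features), byrow = TRUE))^2) +
    colSums((features[!g1, , drop = FALSE] -
               matrix(m2, n2, ncol(features), byrow = TRUE))^2)
  (ssb / 1) / (ssw / (n - 2))
}

#' Pooled-covariance linear discriminant analysis
#'
#' Two-class LDA with equal priors and a pooled within-class covariance
#' regularized by a ridge of `1e-9 tr(Sigma)/d` for invertibility; the
#' decision is the sign of the linear score relative to the class-mean
#' midpoint.
#'
#' @param features windows x features training matrix.
#' @param labels two-class labels.
#' @return an `ncv_lda` model.
#' @export
lda_fit <- function(features, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("LDA requires exactly two classes")
  if (min(table(labels)) < 2) stop("need >= 2 samples per class")
  g1 <- labels == classes[1]
  m1 <- colMeans(features[g1, , drop = FALSE])
  m2 <- colMeans(features[!g1, , drop = FALSE])
  X1 <- sweep(features[g1, , drop = FALSE], 2, m1)
  X2 <- sweep(features[!g1, , drop = FALSE], 2, m2)
  S <- (crossprod(X1) + crossprod(X2)) / (nrow(features) - 2)
  d <- ncol(features)
  S <- S + diag(1e-9 * sum(diag(S)) / d, d)
  w <- solve(S, m1 - m2)
  c0 <- sum(w * (m1 + m2)) / 2 # equal priors: midpoint threshold
  structure(list(classes = classes, w = w, c0 = c0), class = "ncv_lda")
}

#' @rdname lda_fit
#' @param model an `ncv_lda` model.
#' @export
lda_predict <- function(model, features) {
  score <- drop(features %*% model$w) - model$c0
  ifelse(score >= 0, model$classes[1], model$classes[2])
}
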