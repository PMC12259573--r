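sample_cov_stack <- function(x) {
  n <- dim(x)[3]
  out <- array(0, dim = c(dim(x)[1], dim(x)[1], n))
  for (i in seq_len(n)) {
    seg <- x[, , i]
    seg <- seg - rowMeans(seg)
    out[, , i] <- tcrossprod(seg) / (ncol(seg) - 1)
  }
  out
}

#' Build one of the four classification pipelines
#'
#' Each pipeline is a three-stage object:
#' * `prepare(rec)`: label-independent per-subject computation (classifier
#'   specific filtering, windowing, per-window covariances / features) done
#'   once per recording;
#' * `fit(prepared, train_idx)`: all data-dependent steps (class means,
#'   electrode selection, CSP, normalization, mRMR, LDA) fitted on the
#'   training windows only;
#' * `predict(model, prepared, test_idx)`: label-free prediction.
#'
#' Pipelines:
#' * `broad_rmdm`: 1-25 Hz FIR bandpass, Ledoit-Wolf covariance per 2-s
#'   window, Riemannian minimum-distance-to-mean.
#' * `narrow_rmdm`: Butterworth filter bank over the canonical bands,
#'   per-band Ledoit-Wolf covariances, per-band backward electrode
#'   selection to 8 channels, block-diagonal assembly, MDM (per-band
#'   squared distances summed, equivalent to MDM on the materialized
#'   block matrix).
#' * `psd_lda`: canonical band powers per electrode, train-set
#'   z-normalization, mRMR to 18 features, pooled-covariance LDA.
#' * `fbcsp`: 10-band Butterworth bank, 8 CSP filters per band (4 largest
#'   + 4 smallest eigenvalues), log-variance features (80 before
#'   selection), mRMR to 18, LDA.
#'
#' @param name pipeline name.
#' @param k_electrodes electrodes kept per band by `narrow_rmdm`.
#' @param k_features features kept by mRMR in the LDA pipelines.
#' @param n_csp CSP filters per band.
#' @return an `ncv_pipeline` object.
#' @export
build_pipeline <- function(name = c("broad_rmdm", "narrow_rmdm", "psd_lda",
                                    "fbcsp"),
                           k_electrodes = 8, k_features = 18, n_csp = 8) {
  name <- match.arg(name)
  pl <- switch(
    name,
    broad_rmdm = list(
      prepare = function(rec) {
        ws <- extract_windows(bandpass_fir(rec, 1, 25))
        list(meta = ws$meta, covs = lw_covariance_stack(ws$x))
      },
      fit = function(prep, idx) {
        # class prototypes: tolerance far below their statistical error
        mdm_fit(prep$covs[, , idx, drop = FALSE], prep$meta$condition[idx],
                tol = 1e-4)
      },
      predict = function(model, prep, idx) {
        mdm_predict(model, prep$covs[, , idx, drop = FALSE])
      }),
    narrow_rmdm = list(
      prepare = function(rec) {
        bank <- butter_filterbank(rec, canonical_bands())
        meta <- NULL
        covs <- lapply(bank, function(r) {
          ws <- extract_windows(r)
          meta <<- ws$meta
          lw_covariance_stack(ws$x)
        })
        list(meta = meta, covs = covs)
      },
      fit = function(prep, idx) {
        labels <- prep$meta$condition[idx]
        per_band <- lapply(prep$covs, function(cv) {
          sel <- select_electrodes(cv[, , idx, drop = FALSE], labels,
                                   k = k_electrodes)
          list(sel = sel,
               mdm = mdm_fit(cv[sel, sel, idx, drop = FALSE], labels,
                             tol = 1e-4))
        })
        list(per_band = per_band,
             classes = sort(unique(as.character(labels))))
      },
      predict = function(model, prep, idx) {
        D2 <- 0 # squared AIRM distances add across diagonal blocks
        for (b in seq_along(prep$covs)) {
          pb <- model$per_band[[b]]
          cube <- prep$covs[[b]][pb$sel, pb$sel, idx, drop = FALSE]
          means <- array(0, dim = c(length(pb$sel), length(pb$sel),
                                    length(pb$mdm$means)))
          for (j in seq_along(pb$mdm$means)) means[, , j] <- pb$mdm$means[[j]]
          D2 <- D2 + cpp_dist_to_means(cube, means)^2
        }
        model$classes[max.col(-D2, ties.method = "first")]
      }),
    psd_lda = list(
      prepare = function(rec) {
        feats <- bandpower_features(extract_windows(rec))
        list(meta = feats$meta, x = feats$x)
      },
      fit = function(prep, idx) {
        labels <- prep$meta$condition[idx]
        nrm <- zscore_fit(prep$x[idx, , drop = FALSE])
        z <- zscore_apply(prep$x[idx, , drop = FALSE], nrm)
        sel <- mrmr_select(z, labels, k = k_features)
        list(norm = nrm, sel = sel,
             lda = lda_fit(z[, sel, drop = FALSE], labels))
      },
      predict = function(model, prep, idx) {
        z <- zscore_apply(prep$x[idx, , drop = FALSE], model$norm)
        lda_predict(model$lda, z[, model$sel, drop = FALSE])
      }),
    fbcsp = list(
      prepare = function(rec) {
        bank <- butter_filterbank(rec, fbcsp_bands())
        meta <- NULL
        covs <- lapply(bank, function(r) {
          ws <- extract_windows(r)
          meta <<- ws$meta
          sample_cov_stack(ws$x)
        })
        list(meta = meta, covs = covs)
      },
      fit = function(prep, idx) {
        labels <- prep$meta$condition[idx]
        banks <- lapply(prep$covs, function(cv) {
          fit_csp(cv[, , idx, drop = FALSE], labels, n_filters = n_csp)
        })
        feat <- do.call(cbind, lapply(seq_along(banks), function(b) {
          apply_csp_logvar(prep$covs[[b]][, , idx, drop = FALSE], banks[[b]])
        }))
        sel <- mrmr_select(feat, labels, k = k_features)
        list(banks = banks, sel = sel,
             lda = lda_fit(feat[, sel, drop = FALSE], labels))
      },
      predict = function(model, prep, idx) {
        feat <- do.call(cbind, lapply(seq_along(model$banks), function(b) {
          apply_csp_logvar(prep$covs[[b]][, , idx, drop = FALSE],
                           model$banks[[b]])
        }))
        lda_predict(model$lda, feat[, model$sel, drop = FALSE])
      }))
  structure(c(list(name = name), pl), class = "ncv_pipeline")
}

#' @export
print.ncv_pipeline <- function(x, ...) {
  cat("<ncv_pipeline>", x$name, "\n")
  invisible(x)
}
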