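new_fold_plan <- function(scheme, folds, k = NA_integer_, seed = NULL,
                          meta = NULL) {
  plan <- structure(list(scheme = scheme, folds = folds, k = k, seed = seed),
                    class = "ncv_fold_plan")
  if (!is.null(meta)) validate_fold_plan(plan, meta)
  plan
}

plan_meta <- function(x) {
  if (inherits(x, "ncv_window_set")) x$meta
  else if (is.data.frame(x)) x
  else if (is.list(x) && is.data.frame(x$meta)) x$meta
  else stop("need a window set, prepared pipeline input, or metadata table")
}

#' Validate the structural invariants of a fold plan
#'
#' Checks train/test disjointness within folds; for the k-fold schemes,
#' that test sets partition all windows and per-fold class counts are
#' balanced (imbalance at most 1); for the block-respecting schemes, that
#' no set is split across train and test.
#'
#' @param plan an `ncv_fold_plan`.
#' @param meta window metadata (or window set / prepared object).
#' @return `TRUE` invisibly, or an error.
#' @export
validate_fold_plan <- function(plan, meta) {
  meta <- plan_meta(meta)
  n <- nrow(meta)
  for (f in plan$folds) {
    stopifnot(length(intersect(f$train, f$test)) == 0,
              all(c(f$train, f$test) %in% seq_len(n)))
  }
  if (plan$scheme %in% c("sequential_kfold", "randomized_kfold")) {
    tests <- unlist(lapply(plan$folds, `[[`, "test"))
    stopifnot(!anyDuplicated(tests), length(tests) == n)
    for (f in plan$folds) {
      counts <- table(meta$condition[f$test])
      stopifnot(max(counts) - min(counts) <= 1)
    }
  }
  if (plan$scheme %in% c("pseudo_online", "leave_one_block_out")) {
    for (f in plan$folds) {
      stopifnot(length(intersect(meta$set_id[f$train],
                                 meta$set_id[f$test])) == 0)
    }
  }
  invisible(TRUE)
}

#' Pseudo-online evaluation plan
#'
#' Trains only on the chronologically first set and tests on each of the
#' remaining sets separately: two folds with identical training indices,
#' mimicking a calibrate-then-use deployment. When the layout interleaves
#' sets in time (grouped single-day designs), strict chronology cannot
#' hold and a warning is issued.
#'
#' @param window_set window set, prepared pipeline input or metadata.
#' @return an `ncv_fold_plan` with 1-2 folds.
#' @export
plan_pseudo_online <- function(window_set) {
  meta <- plan_meta(window_set)
  sets <- sort(unique(meta$set_id))
  if (length(sets) < 2) stop("pseudo-online evaluation needs >= 2 sets")
  if (length(sets) == 2) {
    warning("only 2 sets available: single test fold")
  }
  train <- which(meta$set_id == sets[1])
  folds <- lapply(sets[-1], function(s) {
    list(train = train, test = which(meta$set_id == s))
  })
  for (f in folds) {
    if (max(meta$chrono_index[f$train]) > min(meta$chrono_index[f$test])) {
      warning("layout interleaves sets: pseudo-online folds are not strictly chronological")
      break
    }
  }
  new_fold_plan("pseudo_online", folds, meta = meta)
}

#' Leave-one-block-out plan
#'
#' One fold per set: that set is the test data, all other sets train.
#'
#' @param window_set window set, prepared pipeline input or metadata.
#' @return an `ncv_fold_plan`.
#' @export
plan_leave_one_block_out <- function(window_set) {
  meta <- plan_meta(window_set)
  sets <- sort(unique(meta$set_id))
  if (length(sets) < 2) stop("leave-one-block-out needs >= 2 sets")
  folds <- lapply(sets, function(s) {
    list(train = which(meta$set_id != s), test = which(meta$set_id == s))
  })
  new_fold_plan("leave_one_block_out", folds, meta = meta)
}

stratified_chunks <- function(meta, k, order_within_class) {
  classes <- sort(unique(meta$condition))
  assign <- integer(nrow(meta))
  for (cl in classes) {
    idx <- which(meta$condition == cl)
    if (length(idx) < k) stop("class '", cl, "' has fewer than k windows")
    idx <- order_within_class(idx)
    sizes <- rep(length(idx) %/% k, k)
    extra <- length(idx) %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    assign[idx] <- rep(seq_len(k), sizes)
  }
  lapply(seq_len(k), function(f) {
    list(train = which(assign != f), test = which(assign == f))
  })
}

#' Sequential stratified k-fold plan
#'
#' Within each class, windows ordered by chronological index are assigned
#' to folds in consecutive runs (no shuffling), so each test fold's
#' windows are contiguous in time within their class; per-fold class
#' counts differ by at most one.
#'
#' @param window_set window set, prepared pipeline input or metadata.
#' @param k number of folds (default 10).
#' @return an `ncv_fold_plan`.
#' @export
plan_sequential_kfold <- function(window_set, k = 10) {
  meta <- plan_meta(window_set)
  folds <- stratified_chunks(meta, k, function(idx) {
    idx[order(meta$chrono_index[idx])]
  })
  new_fold_plan("sequential_kfold", folds, k = k, meta = meta)
}

#' Randomized stratified k-fold plan
#'
#' As the sequential plan, but window order is shuffled (seeded) within
#' each class before fold assignment — the worst case for data with
#' temporal dependencies.
#'
#' @param window_set window set, prepared pipeline input or metadata.
#' @param k number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @return an `ncv_fold_plan`.
#' @export
plan_randomized_kfold <- function(window_set, k = 10, seed = 1L) {
  meta <- plan_meta(window_set)
  folds <- with_seed(seed, stratified_chunks(meta, k, function(idx) sample(idx)))
  new_fold_plan("randomized_kfold", folds, k = k, seed = seed, meta = meta)
}

#' Execute a fold plan with a pipeline
#'
#' For each fold, fits the pipeline on the training windows only, predicts
#' the held-out windows and records the fold accuracy; the pooled accuracy
#' is total correct over total tested. The adjusted chance level is
#' computed for the pooled test size.
#'
#' @param pipeline an `ncv_pipeline` (or any list with `fit`/`predict`).
#' @param prepared result of `pipeline$prepare(rec)`.
#' @param plan an `ncv_fold_plan`.
#' @param alpha significance level for the adjusted chance level.
#' @return an `ncv_accuracy` list: per-fold accuracies, `n_test`, pooled
#'   accuracy and adjusted chance level.
#' @export
run_cv <- function(pipeline, prepared, plan, alpha = 0.05) {
  meta <- plan_meta(prepared)
  validate_fold_plan(plan, meta)
  fold_acc <- numeric(length(plan$folds))
  n_test <- integer(length(plan$folds))
  correct <- 0
  prev_train <- NULL
  model <- NULL
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    if (identical(f$train, prev_train)) {
      # pseudo-online folds share one training set; reuse the fitted model
      pred <- pipeline$predict(model, prepared, f$test)
      hits <- sum(pred == meta$condition[f$test])
      fold_acc[i] <- hits / length(f$test)
      n_test[i] <- length(f$test)
      correct <- correct + hits
      next
    }
    prev_train <- f$train
    model <- tryCatch(pipeline$fit(prepared, f$train), error = function(e) {
      stop(sprintf("pipeline '%s' failed on fold %d of %s: %s",
                   pipeline$name %||% "<anonymous>", i, plan$scheme,
                   conditionMessage(e)))
    })
    pred <- pipeline$predict(model, prepared, f$test)
    hits <- sum(pred == meta$condition[f$test])
    fold_acc[i] <- hits / length(f$test)
    n_test[i] <- length(f$test)
    correct <- correct + hits
  }
  n_classes <- length(unique(meta$condition))
  structure(list(scheme = plan$scheme, fold_accuracy = fold_acc,
                 n_test = n_test, pooled_accuracy = correct / sum(n_test),
                 mean_accuracy = mean(fold_acc),
                 adjusted_chance = adjusted_chance(sum(n_test), n_classes,
                                                   alpha)),
            class = "ncv_accuracy")
}

#' Sample-size corrected chance level
#'
#' The binomial `1 - alpha` quantile of a guessing classifier
#' (`X ~ Binomial(n_test, 1/n_classes)`), as a proportion: the smallest
#' accuracy that a guesser exceeds with probability below `alpha`, i.e.
#' the upper binomial confidence bound on guessing accuracy. For 120
#' two-class test windows this is 69/120 = 0.575.
#'
#' @param n_test test-set size (>= 1).
#' @param n_classes number of classes (default 2).
#' @param alpha significance level (default 0.05).
#' @return chance-level accuracy as a proportion in (0, 1].
#' @export
adjusted_chance <- function(n_test, n_classes = 2, alpha = 0.05) {
  stopifnot(n_test >= 1)
  qbinom(1 - alpha, n_test, 1 / n_classes) / n_test
}
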