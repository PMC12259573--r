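layout_presets <- c("shin_like", "schroeder_like", "hinss_multiday_like",
                    "hinss_singleday_like")

#' Build block annotations for one of the study layouts
#'
#' Emulates the block structure of typical n-back pBCI recordings, split
#' into three equal-sized sets:
#' * `shin_like`: 3 sets, each a pseudo-random interleaving of 3 x
#'   n_conditions runs of 40 s, with no condition presented twice in a row.
#' * `schroeder_like`: 3 sets, each one 140-s run per condition in random
#'   order.
#' * `hinss_multiday_like`: 3 day-sets; within a day the repetitions of a
#'   condition are grouped into a single block of three 32-s runs (96 s per
#'   condition per set), condition block order randomized.
#' * `hinss_singleday_like`: the first day of the former only; the i-th run
#'   of every condition block forms set i, so set membership cuts across
#'   the grouped condition blocks.
#'
#' Runs are laid out back to back (inter-run pauses are not simulated), so
#' onsets tile the recording.
#'
#' @param preset one of `r paste(layout_presets, collapse = ", ")`.
#' @param run_duration_overrides optional single number replacing the
#'   preset's run duration (seconds); useful for scaled-down test fixtures.
#' @param n_conditions number of condition labels (default 2).
#' @param conditions optional character vector of condition labels.
#' @param seed integer seed for the randomized run orders.
#' @return a block-annotation data.frame (see [block_annotations()]).
#' @export
#' @examples
#' ann <- make_layout("schroeder_like", seed = 1)
#' nrow(ann) # 3 sets x 2 conditions = 6 runs of 140 s
make_layout <- function(preset, run_duration_overrides = NULL,
                        n_conditions = 2L, conditions = NULL, seed = NULL) {
  preset <- match.arg(preset, layout_presets)
  if (is.null(conditions)) {
    conditions <- if (n_conditions == 2L) c("low", "high")
    else paste0("cond", seq_len(n_conditions))
  }
  stopifnot(length(conditions) == n_conditions)
  dur <- run_duration_overrides %||%
    switch(preset, shin_like = 40, schroeder_like = 140,
           hinss_multiday_like = 32, hinss_singleday_like = 32)
  with_seed(seed, {
    rows <- switch(
      preset,
      shin_like = {
        out <- list()
        for (s in 1:3) {
          seq_cond <- interleave_no_repeat(conditions, 3L)
          out[[s]] <- data.frame(condition = seq_cond, set_id = s, day_id = 1L,
                                 duration = dur, stringsAsFactors = FALSE)
        }
        df <- do.call(rbind, out)
        df$block_id <- seq_len(nrow(df)) # confounds drawn per run
        df
      },
      schroeder_like = {
        out <- list()
        for (s in 1:3) {
          out[[s]] <- data.frame(condition = sample(conditions), set_id = s,
                                 day_id = 1L, duration = dur,
                                 stringsAsFactors = FALSE)
        }
        df <- do.call(rbind, out)
        df$block_id <- seq_len(nrow(df))
        df
      },
      hinss_multiday_like = {
        out <- list()
        blk <- 0L
        for (d in 1:3) {
          for (cond in sample(conditions)) {
            blk <- blk + 1L
            out[[length(out) + 1L]] <-
              data.frame(condition = cond, set_id = d, day_id = d,
                         duration = dur, block_id = blk,
                         stringsAsFactors = FALSE)[rep(1, 3), ]
          }
        }
        do.call(rbind, out)
      },
      hinss_singleday_like = {
        out <- list()
        blk <- 0L
        for (cond in sample(conditions)) {
          blk <- blk + 1L
          # the r-th repetition of each condition block belongs to set r
          out[[length(out) + 1L]] <-
            data.frame(condition = cond, set_id = 1:3, day_id = 1L,
                       duration = dur, block_id = blk,
                       stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
      })
    n <- nrow(rows)
    block_annotations(onset = cumsum(c(0, rows$duration[-n])),
                      duration = rows$duration, condition = rows$condition,
                      run_id = seq_len(n), set_id = rows$set_id,
                      day_id = rows$day_id, chrono_index = seq_len(n),
                      block_id = rows$block_id)
  })
}

# Random sequence with n_rep repetitions of each condition and no condition
# twice in a row (rejection sampling; feasible for the study layouts).
interleave_no_repeat <- function(conditions, n_rep) {
  pool <- rep(conditions, n_rep)
  for (attempt in 1:1000) {
    s <- sample(pool)
    if (!any(s[-1] == s[-length(s)])) return(s)
  }
  stop("could not interleave conditions without immediate repetition")
}
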