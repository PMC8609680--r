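#' Rate of change of the UPDRS-III score
#'
#' `(OFF - ON) / OFF`: the fractional motor improvement after the levodopa
#' challenge. Positive values mean improvement.
#'
#' @param off,on UPDRS-III scores in the OFF and ON states; `off` must be
#'   positive.
#' @return Dimensionless rate (vectorized).
#' @export
rate_of_change_updrs <- function(off, on) {
  assert_that(all(off > 0), "rate undefined: OFF score must be positive")
  (off - on) / off
}

#' Rate of change of somatomotor synchronization
#'
#' `(sync_OFF - sync_ON) / sync_OFF`. Synchronization typically rises after
#' levodopa, so responders have negative rates — the origin of the negative
#' correlations between this rate and LC contrast.
#'
#' @param off,on synchronization values in [0, 1]; `off` must be positive.
#' @return Dimensionless rate (vectorized).
#' @export
rate_of_change_sync <- function(off, on) {
  assert_that(all(off > 0), "rate undefined: OFF synchronization must be positive")
  (off - on) / off
}

#' Original (absolute) change of the UPDRS-III score
#'
#' @param off,on UPDRS-III scores.
#' @return `off - on` (vectorized).
#' @export
original_change_updrs <- function(off, on) off - on

#' Split a cohort into levodopa response and resistance groups
#'
#' Ranks subjects by the UPDRS-III rate of change in descending order and
#' labels the top `ceiling(n / 2)` as `response`, the remainder as
#' `resistance` (57 subjects split 29 / 28). Ties keep the stable input
#' order, and with odd n the extra subject goes to the response group.
#'
#' @param cohort data frame with columns `updrs3_off`, `updrs3_on`,
#'   `sync_off`, `sync_on` (and any others, carried through).
#' @return The cohort with appended columns `rate_updrs`, `rate_sync` and
#'   `group` (factor with levels `response`, `resistance`).
#' @export
split_by_response <- function(cohort) {
  need <- c("updrs3_off", "updrs3_on", "sync_off", "sync_on")
  miss <- setdiff(need, names(cohort))
  assert_that(length(miss) == 0,
              paste("missing cohort columns:", paste(miss, collapse = ", ")))
  n <- nrow(cohort)
  assert_that(n >= 2L, "at least 2 subjects required")
  cohort$rate_updrs <- rate_of_change_updrs(cohort$updrs3_off, cohort$updrs3_on)
  cohort$rate_sync <- rate_of_change_sync(cohort$sync_off, cohort$sync_on)
  rank_order <- order(-cohort$rate_updrs)  # stable: ties keep input order
  n_resp <- ceiling(n / 2)
  group <- character(n)
  group[rank_order[seq_len(n_resp)]] <- "response"
  group[rank_order[-seq_len(n_resp)]] <- "resistance"
  cohort$group <- factor(group, levels = c("response", "resistance"))
  cohort
}
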