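#' Default retrenchment schedule
#'
#' Builds the exclusion schedule of the extreme-response sweep: the
#' first step removes enough members of the larger group to reach a
#' 50:50 responder:non-responder ratio, and each subsequent step removes
#' `step` more participants from each group, stopping before fewer than
#' `min_n` participants would remain (or a group would empty). With
#' group sizes (113, 78) this yields the printed sweep
#' (35,0), (45,10), ... , (95,60), i.e. 156, 136, ..., 36 participants
#' included. If non-responders outnumber responders the schedule is
#' mirrored.
#'
#' @param n_responders,n_non_responders Group sizes.
#' @param step Additional exclusions per group per step.
#' @param min_n Minimum number of participants to retain.
#' @return Object of class `retrenchment_schedule`: data frame with
#'   cumulative `excl_responders`, `excl_non_responders`, `n_included`.
#'   The no-exclusion baseline is not part of the schedule;
#'   [retrench_and_refit()] prepends it.
#' @export
#' @examples
#' default_schedule(113, 78)
default_schedule <- function(n_responders, n_non_responders,
                             step = 10L, min_n = 30L) {
  if (n_responders < 0 || n_non_responders < 0 || step < 1)
    stop("invalid schedule parameters")
  n_total <- n_responders + n_non_responders
  mirrored <- n_non_responders > n_responders
  big <- max(n_responders, n_non_responders)
  small <- min(n_responders, n_non_responders)
  first <- big - small
  excl_big <- first
  excl_small <- 0L
  rows <- list()
  repeat {
    n_inc <- n_total - excl_big - excl_small
    if (n_inc < min_n || excl_big > big || excl_small > small ||
        big - excl_big < 1 || (small > 0 && small - excl_small < 1))
      break
    rows[[length(rows) + 1L]] <- c(excl_big, excl_small, n_inc)
    excl_big <- excl_big + step
    excl_small <- excl_small + step
  }
  if (length(rows) == 0)
    stop("no feasible retrenchment step with min_n = ", min_n)
  m <- do.call(rbind, rows)
  out <- if (mirrored) {
    data.frame(excl_responders = m[, 2], excl_non_responders = m[, 1],
               n_included = m[, 3])
  } else {
    data.frame(excl_responders = m[, 1], excl_non_responders = m[, 2],
               n_included = m[, 3])
  }
  class(out) <- c("retrenchment_schedule", "data.frame")
  out
}

#' Retrench towards extreme responses and refit the score model
#'
#' Reproduces the extreme-response sweep: at each schedule step the
#' scheduled number of responders with the least-negative triglyceride
#' change and of non-responders with the smallest change magnitude are
#' excluded — both groups lose their weakest members so the extremes are
#' retained — and the covariate-adjusted score model is refit on the
#' remainder with the score weights frozen from the full cohort. The
#' no-exclusion baseline is always emitted first and reproduces
#' [fit_grs_model()] on the full scored cohort exactly. Ties in the
#' triglyceride change are broken by participant id, so the output is
#' independent of input row order.
#'
#' The default `ranking = "magnitude"` removes non-responders with the
#' smallest positive change first (retaining the largest increases);
#' `ranking = "value"` removes those with the largest change first.
#'
#' @param phenotypes Output of [classify_responders()].
#' @param grs A `grs_vector` with frozen weights (see [compute_grs()]).
#' @param schedule A [default_schedule()] result, or `NULL` to derive
#'   one from the scored cohort's group sizes.
#' @param ranking Ordering of non-responder exclusions (see above).
#' @param step,min_n Passed to [default_schedule()] when `schedule` is
#'   `NULL`.
#' @return Data frame with one row per step (baseline first):
#'   `excl_responders`, `excl_non_responders`, `n_included`,
#'   `grs_percent_variance`, `grs_p`. Steps that would empty a group are
#'   dropped with a warning.
#' @export
retrench_and_refit <- function(phenotypes, grs, schedule = NULL,
                               ranking = c("magnitude", "value"),
                               step = 10L, min_n = 30L) {
  ranking <- match.arg(ranking)
  if (!inherits(grs, "grs_vector")) stop("expected a grs_vector")
  if (!all(c("responder", "delta_tg") %in% names(phenotypes)))
    stop("run classify_responders() first")
  scored_ids <- grs$participant_id[!is.na(grs$score)]
  ph <- phenotypes[phenotypes$participant_id %in% scored_ids, ,
                   drop = FALSE]
  resp <- ph[ph$responder, , drop = FALSE]
  nonr <- ph[!ph$responder, , drop = FALSE]
  if (is.null(schedule))
    schedule <- default_schedule(nrow(resp), nrow(nonr), step = step,
                                 min_n = min_n)
  # weakest-first exclusion orders (ties broken by participant id)
  resp_order <- resp$participant_id[order(-resp$delta_tg,
                                          resp$participant_id)]
  nonr_order <- switch(ranking,
    magnitude = nonr$participant_id[order(nonr$delta_tg,
                                          nonr$participant_id)],
    value = nonr$participant_id[order(-nonr$delta_tg,
                                      nonr$participant_id)])
  fit_subset <- function(ids) {
    sub <- ph[ph$participant_id %in% ids, , drop = FALSE]
    fit_grs_model(sub, grs)
  }
  baseline <- fit_subset(ph$participant_id)
  rows <- list(data.frame(excl_responders = 0L,
                          excl_non_responders = 0L,
                          n_included = baseline$n,
                          grs_percent_variance =
                            baseline$grs_percent_variance,
                          grs_p = baseline$grs_p))
  for (k in seq_len(nrow(schedule))) {
    er <- schedule$excl_responders[k]
    en <- schedule$excl_non_responders[k]
    if (er >= nrow(resp) || en >= nrow(nonr)) {
      warning("schedule step (", er, ", ", en,
              ") would empty a group; sweep truncated")
      break
    }
    keep <- c(setdiff(resp_order, resp_order[seq_len(er)]),
              setdiff(nonr_order, if (en > 0) nonr_order[seq_len(en)]
                                  else character(0)))
    fit <- fit_subset(keep)
    rows[[length(rows) + 1L]] <-
      data.frame(excl_responders = er, excl_non_responders = en,
                 n_included = fit$n,
                 grs_percent_variance = fit$grs_percent_variance,
                 grs_p = fit$grs_p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
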