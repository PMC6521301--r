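#' Classify responders to the supplementation
#'
#' Derives the triglyceride change `delta_tg = tg_post - tg_pre` (mg/dL)
#' and flags each participant: a decrease (`delta_tg < 0`) marks a
#' responder, no change or an increase (`delta_tg >= 0`) a non-responder.
#' Rows with a missing pre- or post-intervention value are rejected and
#' listed rather than silently dropped.
#'
#' @param phenotypes Data frame with at least `participant_id`, `tg_pre`,
#'   `tg_post`.
#' @return The phenotype table with added `delta_tg` and `responder`
#'   columns, restricted to classifiable rows. Attributes:
#'   `rejected_ids` (participant ids lacking a TG value) and `summary`, a
#'   list with `n_responders`, `n_non_responders`,
#'   `percent_non_responders` and `percent_responders` (percentages, one
#'   decimal).
#' @export
#' @examples
#' tab <- data.frame(participant_id = c("a", "b", "c"),
#'                   tg_pre = c(100, 90, 80), tg_post = c(80, 90, 95))
#' attr(classify_responders(tab), "summary")
classify_responders <- function(phenotypes) {
  phenotypes <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
  need <- c("participant_id", "tg_pre", "tg_post")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- is.na(phenotypes$tg_pre) | is.na(phenotypes$tg_post)
  rejected <- phenotypes$participant_id[bad]
  out <- phenotypes[!bad, , drop = FALSE]
  out$delta_tg <- out$tg_post - out$tg_pre
  out$responder <- out$delta_tg < 0
  n_resp <- sum(out$responder)
  n_non <- sum(!out$responder)
  n_tot <- n_resp + n_non
  summary <- list(
    n_responders = n_resp,
    n_non_responders = n_non,
    percent_non_responders = round(100 * n_non / n_tot, 1),
    percent_responders = round(100 * n_resp / n_tot, 1))
  attr(out, "rejected_ids") <- rejected
  attr(out, "summary") <- summary
  out
}

# paired or two-sample t-test that degrades gracefully on degenerate
# input; returns list(p, degenerate)
safe_t_test <- function(x, y, paired = FALSE, var.equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (paired) {
    d <- x - y
    if (length(d) < 2 || sd(d) == 0)
      return(list(p = 1, degenerate = TRUE))
    return(list(p = t.test(x, y, paired = TRUE)$p.value,
                degenerate = FALSE))
  }
  if (length(x) < 2 || length(y) < 2)
    return(list(p = NA_real_, degenerate = TRUE))
  if (sd(x) == 0 && sd(y) == 0)
    return(list(p = 1, degenerate = TRUE))
  list(p = t.test(x, y, var.equal = var.equal)$p.value,
       degenerate = FALSE)
}

#' Descriptive comparison of responders and non-responders
#'
#' Produces the standard baseline/post-intervention characteristics
#' table: mean +/- SD per subgroup, paired two-sided Student t-tests for
#' pre- vs post-intervention within each subgroup, and two-sample
#' two-sided t-tests between subgroups at baseline and post-intervention.
#' The between-group test uses the pooled-variance (Student) form by
#' default; set `welch = TRUE` for unequal variances. Variables without a
#' post-intervention measurement (age, sex) get within-group and post
#' cells left `NA`. Zero-variance contrasts are reported with p = 1 and
#' flagged degenerate rather than erroring.
#'
#' @param phenotypes Output of [classify_responders()] (must carry
#'   `responder` and `delta_tg`).
#' @param welch Use Welch's between-group test instead of pooled-variance
#'   Student.
#' @return Data frame with one row per (variable, timepoint):
#'   `variable`, `timepoint`, per-group mean and SD, within-group paired
#'   p-values and the between-group p-value, plus degenerate-input flags.
#' @export
descriptive_table <- function(phenotypes, welch = FALSE) {
  if (!all(c("responder", "delta_tg") %in% names(phenotypes)))
    stop("run classify_responders() first")
  r <- phenotypes[phenotypes$responder, , drop = FALSE]
  nr <- phenotypes[!phenotypes$responder, , drop = FALSE]
  row_for <- function(variable, timepoint, col_r, col_nr,
                      paired_cols = NULL) {
    between <- safe_t_test(col_r, col_nr, var.equal = !welch)
    within_r <- within_nr <- list(p = NA_real_, degenerate = NA)
    if (!is.null(paired_cols)) {
      within_r <- safe_t_test(r[[paired_cols[1]]], r[[paired_cols[2]]],
                              paired = TRUE)
      within_nr <- safe_t_test(nr[[paired_cols[1]]], nr[[paired_cols[2]]],
                               paired = TRUE)
    }
    data.frame(variable = variable, timepoint = timepoint,
               responder_mean = mean(col_r, na.rm = TRUE),
               responder_sd = sd(col_r, na.rm = TRUE),
               non_responder_mean = mean(col_nr, na.rm = TRUE),
               non_responder_sd = sd(col_nr, na.rm = TRUE),
               p_within_responders = within_r$p,
               p_within_non_responders = within_nr$p,
               p_between = between$p,
               degenerate = isTRUE(between$degenerate) ||
                 isTRUE(within_r$degenerate) ||
                 isTRUE(within_nr$degenerate),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row_for("age", "baseline", r$age, nr$age),
    row_for("bmi", "baseline", r$bmi, nr$bmi),
    row_for("tg", "baseline", r$tg_pre, nr$tg_pre,
            paired_cols = c("tg_post", "tg_pre")),
    row_for("tg", "post", r$tg_post, nr$tg_post),
    row_for("delta_tg", "change", r$delta_tg, nr$delta_tg))
  rownames(out) <- NULL
  out
}
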