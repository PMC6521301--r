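#' Covariate-adjusted variance explained by a risk score
#'
#' Fits the ANCOVA-style linear model `delta_tg ~ score + age + sex +
#' bmi` by ordinary least squares on complete cases and quantifies the
#' score's contribution as the incremental R-squared of adding the score
#' to the covariate-only model, reported as a percentage of the
#' triglyceride-response variance. Since the published analyses never
#' define "percent of variance explained" precisely, the partial
#' eta-squared reading is reported alongside
#' (`grs_partial_eta2 = (R2_full - R2_cov) / (1 - R2_cov)`). The score's
#' p-value is the two-sided t-test of its coefficient. Sex enters as a
#' single male indicator (female reference); the reference choice does
#' not affect the score statistics.
#'
#' @param phenotypes Output of [classify_responders()] (needs
#'   `delta_tg`, `age`, `sex`, `bmi`).
#' @param grs A `grs_vector` from [compute_grs()], matched by
#'   `participant_id`.
#' @return Object of class `grs_fit`: list with `n`, `coefficients`
#'   (term, estimate, se, t, p), `grs_percent_variance`, `grs_p`,
#'   `r2_full`, `r2_covariates_only`, `grs_partial_eta2`,
#'   `inestimable` flag, `panel_name`, `n_dropped`.
#' @export
fit_grs_model <- function(phenotypes, grs) {
  if (!inherits(grs, "grs_vector")) stop("expected a grs_vector")
  need <- c("participant_id", "delta_tg", "age", "sex", "bmi")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) stop("phenotypes missing columns: ",
                         paste(miss, collapse = ", "))
  d <- merge(phenotypes[need], as.data.frame(grs)[c("participant_id",
                                                    "score")],
             by = "participant_id")
  d$sex_male <- as.integer(d$sex == "male")
  keep <- complete.cases(d[c("delta_tg", "age", "sex_male", "bmi",
                             "score")])
  n_dropped <- nrow(d) - sum(keep)
  d <- d[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 6) stop("need at least 6 complete rows to fit the model")
  fit_cov <- lm(delta_tg ~ age + sex_male + bmi, data = d)
  inestimable <- length(unique(d$score)) < 2
  if (inestimable) {
    r2_cov <- summary(fit_cov)$r.squared
    out <- list(n = n, coefficients = NULL,
                grs_percent_variance = NA_real_, grs_p = NA_real_,
                r2_full = r2_cov, r2_covariates_only = r2_cov,
                grs_partial_eta2 = NA_real_, inestimable = TRUE,
                panel_name = attr(grs, "panel_name"),
                n_dropped = n_dropped)
    class(out) <- "grs_fit"
    return(out)
  }
  fit_full <- lm(delta_tg ~ score + age + sex_male + bmi, data = d)
  sm <- summary(fit_full)
  r2_full <- sm$r.squared
  r2_cov <- summary(fit_cov)$r.squared
  co <- sm$coefficients
  coefs <- data.frame(term = rownames(co), estimate = co[, 1],
                      se = co[, 2], t = co[, 3], p = co[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  inc <- max(r2_full - r2_cov, 0)  # nested models; guard rounding only
  out <- list(n = n, coefficients = coefs,
              grs_percent_variance = 100 * inc,
              grs_p = co["score", 4],
              r2_full = r2_full, r2_covariates_only = r2_cov,
              grs_partial_eta2 = if (r2_cov < 1) inc / (1 - r2_cov)
                                 else NA_real_,
              inestimable = FALSE,
              panel_name = attr(grs, "panel_name"),
              n_dropped = n_dropped)
  class(out) <- "grs_fit"
  out
}

#' @export
print.grs_fit <- function(x, ...) {
  cat("grs_fit (panel ", x$panel_name, "): n = ", x$n, "\n", sep = "")
  if (x$inestimable) {
    cat("  score term inestimable (constant or collinear)\n")
  } else {
    cat(sprintf("  score explains %.2f%% of delta-TG variance (p = %.3g)\n",
                x$grs_percent_variance, x$grs_p))
    cat(sprintf("  R2 full = %.4f, R2 covariates only = %.4f\n",
                x$r2_full, x$r2_covariates_only))
  }
  invisible(x)
}

#' Bidirectional stepwise SNP selection with forced covariates
#'
#' Classic bidirectional stepwise regression of the triglyceride
#' response on individual SNP dosages, with age, sex and BMI forced into
#' every model and never candidates for removal. At each iteration the
#' candidate with the smallest coefficient p-value below `entry_p` is
#' added, then any included SNP whose p-value (given the covariates and
#' the other included SNPs) exceeds `stay_p` is removed, worst first.
#' The procedure stops when no action is possible (or a previously
#' visited model recurs, which guards against entry/removal cycles).
#' Ties are broken by smaller p-value then lexicographic rsid, so the
#' result does not depend on candidate order. Thresholds default to
#' 0.15, the customary stepwise entry/stay significance levels.
#'
#' @param phenotypes Output of [classify_responders()].
#' @param gm A [genotype_matrix()].
#' @param candidates Character vector of candidate rsids (default: all
#'   SNPs of the matrix). Complete cases across phenotypes and all
#'   candidate dosages are used.
#' @param entry_p,stay_p Entry and stay significance thresholds in
#'   (0, 1).
#' @return Object of class `stepwise_result`: list with `selected`
#'   (rsids in entry order), `log` (data frame `step`, `action`, `rsid`,
#'   `p`), `entry_p`, `stay_p`, `n`.
#' @export
stepwise_select <- function(phenotypes, gm, candidates = NULL,
                            entry_p = 0.15, stay_p = 0.15) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (entry_p <= 0 || entry_p >= 1 || stay_p <= 0 || stay_p >= 1)
    stop("entry_p and stay_p must lie strictly between 0 and 1")
  if (is.null(candidates)) candidates <- gm$snps$rsid
  absent <- setdiff(candidates, gm$snps$rsid)
  if (length(absent))
    stop("candidate rsids absent from matrix: ",
         paste(absent, collapse = ", "))
  if (length(candidates) < 1) stop("at least one candidate required")
  need <- c("participant_id", "delta_tg", "age", "sex", "bmi")
  idx <- match(gm$participant_ids, phenotypes$participant_id)
  d <- phenotypes[idx, need]
  d$sex_male <- as.integer(d$sex == "male")
  geno <- as.data.frame(gm$dosage[, candidates, drop = FALSE])
  d <- cbind(d, geno)
  keep <- complete.cases(d[c("delta_tg", "age", "sex_male", "bmi",
                             candidates)])
  d <- d[keep, , drop = FALSE]
  forced <- c("age", "sex_male", "bmi")

  term_p <- function(terms, of) {
    f <- stats::reformulate(c(forced, terms), response = "delta_tg")
    co <- summary(lm(f, data = d))$coefficients
    if (!of %in% rownames(co)) return(NA_real_)  # collinear: inestimable
    co[of, 4]
  }

  selected <- character(0)
  log <- list()
  visited <- character(0)
  step <- 0L
  repeat {
    state <- paste(sort(selected), collapse = ",")
    if (state %in% visited) break
    visited <- c(visited, state)
    acted <- FALSE
    # forward step
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      pvals <- vapply(pool, function(s) term_p(c(selected, s), s),
                      numeric(1))
      ok <- !is.na(pvals)
      if (any(ok)) {
        pool <- pool[ok]; pvals <- pvals[ok]
        ord <- order(pvals, pool)
        if (pvals[ord[1]] < entry_p) {
          add <- pool[ord[1]]
          selected <- c(selected, add)
          step <- step + 1L
          log[[length(log) + 1L]] <-
            data.frame(step = step, action = "add", rsid = add,
                       p = pvals[ord[1]], stringsAsFactors = FALSE)
          acted <- TRUE
        }
      }
    }
    # backward steps
    repeat {
      if (length(selected) == 0) break
      pvals <- vapply(selected, function(s) term_p(selected, s),
                      numeric(1))
      pvals[is.na(pvals)] <- Inf  # collinear terms are dropped first
      ord <- order(-pvals, selected)
      worst <- selected[ord[1]]
      worst_p <- pvals[ord[1]]
      if (worst_p > stay_p) {
        selected <- setdiff(selected, worst)
        step <- step + 1L
        log[[length(log) + 1L]] <-
          data.frame(step = step, action = "remove", rsid = worst,
                     p = if (is.finite(worst_p)) worst_p else NA_real_,
                     stringsAsFactors = FALSE)
        acted <- TRUE
      } else break
    }
    if (!acted) break
  }
  out <- list(selected = selected,
              log = if (length(log)) do.call(rbind, log) else
                data.frame(step = integer(0), action = character(0),
                           rsid = character(0), p = numeric(0)),
              entry_p = entry_p, stay_p = stay_p, n = nrow(d))
  class(out) <- "stepwise_result"
  out
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("stepwise_result: ", length(x$selected), " SNPs selected (entry_p = ",
      x$entry_p, ", stay_p = ", x$stay_p, ", n = ", x$n, ")\n", sep = "")
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "),
                              "\n", sep = "")
  invisible(x)
}

#' Refit the variance-explained model on a refined SNP panel
#'
#' Builds the panel's risk score with [compute_grs()] (frozen weights,
#' signed dosages) and delegates to [fit_grs_model()].
#'
#' @param gm A [genotype_matrix()].
#' @param phenotypes Output of [classify_responders()].
#' @param selected Non-empty character vector of rsids (typically
#'   `stepwise_select()$selected`).
#' @param weights Weight table from [compute_weights()].
#' @return A `grs_fit` (see [fit_grs_model()]).
#' @export
refit_refined_grs <- function(gm, phenotypes, selected, weights) {
  if (length(selected) == 0) stop("selected panel must be non-empty")
  grs <- compute_grs(gm, weights, panel = selected,
                     panel_name = paste0("refined_", length(selected)))
  fit_grs_model(phenotypes, grs)
}
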