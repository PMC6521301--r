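# Independent oracles and small fixture builders shared across tests.

# Brute-force Hardy-Weinberg chi-square: expected counts spelt out from
# the estimated allele frequency, summed cell by cell.
oracle_hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  q <- (n_Aa + 2 * n_aa) / (2 * n)
  p <- 1 - q
  e <- c(n * p * p, n * 2 * p * q, n * q * q)
  o <- c(n_AA, n_Aa, n_aa)
  sum((o - e)^2 / e)
}

# Exhaustive-refit stepwise oracle: at every step refits every candidate
# model from scratch; mirrors the published protocol (forward add of the
# smallest-p candidate under the entry threshold, then repeated removal
# of the worst included term over the stay threshold), ties by smaller p
# then lexicographic rsid.
oracle_stepwise <- function(d, candidates, entry_p, stay_p) {
  p_of <- function(terms, target) {
    rhs <- paste(c("age", "sex_male", "bmi", terms), collapse = " + ")
    sm <- summary(lm(stats::as.formula(paste("delta_tg ~", rhs)),
                     data = d))$coefficients
    if (!target %in% rownames(sm)) return(NA_real_)
    sm[target, 4]
  }
  sel <- character(0)
  log <- list()
  step <- 0L
  repeat {
    acted <- FALSE
    pool <- setdiff(candidates, sel)
    if (length(pool)) {
      ps <- vapply(pool, function(s) p_of(c(sel, s), s), numeric(1))
      ok <- !is.na(ps)
      if (any(ok)) {
        pool <- pool[ok]; ps <- ps[ok]
        o <- order(ps, pool)
        if (ps[o[1]] < entry_p) {
          sel <- c(sel, pool[o[1]])
          step <- step + 1L
          log[[length(log) + 1L]] <- data.frame(
            step = step, action = "add", rsid = pool[o[1]], p = ps[o[1]],
            stringsAsFactors = FALSE)
          acted <- TRUE
        }
      }
    }
    repeat {
      if (!length(sel)) break
      ps <- vapply(sel, function(s) p_of(sel, s), numeric(1))
      ps[is.na(ps)] <- Inf
      o <- order(-ps, sel)
      if (ps[o[1]] > stay_p) {
        worst <- sel[o[1]]
        sel <- setdiff(sel, worst)
        step <- step + 1L
        log[[length(log) + 1L]] <- data.frame(
          step = step, action = "remove", rsid = worst,
          p = if (is.finite(ps[o[1]])) ps[o[1]] else NA_real_,
          stringsAsFactors = FALSE)
        acted <- TRUE
      } else break
    }
    if (!acted) break
  }
  list(selected = sel,
       log = if (length(log)) do.call(rbind, log) else NULL)
}

# Tiny phenotype table with prescribed delta TG values.
make_phenotypes <- function(delta, seed = 1) {
  set.seed(seed)
  n <- length(delta)
  tg_pre <- 100 + abs(rnorm(n, 0, 20))
  data.frame(participant_id = sprintf("P%04d", seq_len(n)),
             age = runif(n, 18, 40),
             sex = sample(c("male", "female"), n, replace = TRUE),
             bmi = runif(n, 18.5, 30),
             tg_pre = tg_pre, tg_post = tg_pre + delta,
             stringsAsFactors = FALSE)
}

# Genotype matrix from an explicit dosage matrix.
make_gm <- function(dosage, rsids = sprintf("rs%d", seq_len(ncol(dosage)))) {
  m <- length(rsids)
  genotype_matrix(dosage,
                  data.frame(rsid = rsids,
                             minor_allele = rep("A", m),
                             major_allele = rep("G", m),
                             stringsAsFactors = FALSE),
                  participant_ids = sprintf("P%04d", seq_len(nrow(dosage))))
}

# Monte-Carlo expectation of the covariate-adjusted incremental R^2 (in
# percent) of one pure-noise regressor at sample size n: plain rnorm
# data and stats::lm only, no package code.
oracle_null_increment_pct <- function(n, reps = 200, seed = 99) {
  set.seed(seed)
  mean(vapply(seq_len(reps), function(i) {
    y <- rnorm(n); x <- rnorm(n)
    a <- rnorm(n); s <- rbinom(n, 1, 0.4); b <- rnorm(n)
    r2c <- summary(lm(y ~ a + s + b))$r.squared
    r2f <- summary(lm(y ~ x + a + s + b))$r.squared
    100 * (r2f - r2c)
  }, numeric(1)))
}
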