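#' Hardy-Weinberg equilibrium chi-squared test
#'
#' One-degree-of-freedom Pearson chi-squared test of observed genotype
#' counts against the Hardy-Weinberg expectations `n * (p^2, 2pq, q^2)`,
#' with allele frequencies estimated from the sample. No continuity
#' correction. A monomorphic SNP (minor allele frequency 0) is returned
#' with statistic 0 and flagged rather than erroring.
#'
#' @param counts Integer vector `c(n_major_hom, n_het, n_minor_hom)`.
#' @return List with `chi2`, `p`, `in_hwe` (TRUE when `p >= 0.05`),
#'   `maf`, and `monomorphic`.
#' @export
#' @examples
#' hwe_test(c(30, 40, 30))  # chi2 = 4, p ~ 0.0455
hwe_test <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be three non-negative integers ",
         "(n_major_hom, n_het, n_minor_hom)")
  n <- sum(counts)
  if (n < 1) stop("at least one called genotype required")
  q <- (counts[2] + 2 * counts[3]) / (2 * n)  # minor allele frequency
  if (q == 0 || q == 1) {
    return(list(chi2 = 0, p = 1, in_hwe = TRUE, maf = min(q, 1 - q),
                monomorphic = TRUE))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, in_hwe = p >= 0.05, maf = min(q, 1 - q),
       monomorphic = FALSE)
}

# normalize a cohort spec to c(minor, major) allele counts;
# accepts c(minor, major) counts or list(maf=, n=) with n participants
allele_counts <- function(x) {
  if (is.list(x) && all(c("maf", "n") %in% names(x))) {
    if (x$n < 1) stop("cohort size must be positive")
    if (x$maf < 0 || x$maf > 1) stop("maf must be in [0, 1]")
    total <- 2 * x$n
    minor <- round(x$maf * total)
    c(minor = minor, major = total - minor, reconstructed = 1)
  } else {
    x <- as.numeric(x)
    if (length(x) != 2 || any(x < 0)) stop("expected c(minor, major) counts")
    c(minor = x[1], major = x[2], reconstructed = 0)
  }
}

#' Compare allele frequencies between two cohorts
#'
#' Pearson chi-squared test (1 df, no continuity correction) on the 2x2
#' table of minor/major allele counts by cohort. A cohort may be given as
#' raw allele counts `c(minor, major)` or, when only a published
#' frequency is available, as `list(maf = , n = )` with `n` participants;
#' counts are then reconstructed by rounding `maf * 2n` and the result is
#' flagged approximate.
#'
#' @param counts_a,counts_b Cohort allele counts or `list(maf, n)`.
#' @param rsid Optional SNP identifier carried into the result.
#' @return List with `rsid`, `maf_a`, `maf_b`, `chi2`, `p`, and
#'   `reconstructed` (TRUE when either cohort's counts were rebuilt from
#'   a printed frequency).
#' @export
#' @examples
#' compare_maf(c(133, 283), c(103, 279))
compare_maf <- function(counts_a, counts_b, rsid = NA_character_) {
  a <- allele_counts(counts_a)
  b <- allele_counts(counts_b)
  if (a[["minor"]] + a[["major"]] == 0 || b[["minor"]] + b[["major"]] == 0)
    stop("zero total alleles in a cohort")
  tab <- rbind(a[c("minor", "major")], b[c("minor", "major")])
  row_tot <- rowSums(tab); col_tot <- colSums(tab); total <- sum(tab)
  expected <- outer(row_tot, col_tot) / total
  if (any(col_tot == 0)) {
    chi2 <- 0  # an allele absent from both cohorts: no difference testable
  } else {
    chi2 <- sum((tab - expected)^2 / expected)
  }
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(rsid = rsid,
       maf_a = a[["minor"]] / (a[["minor"]] + a[["major"]]),
       maf_b = b[["minor"]] / (b[["minor"]] + b[["major"]]),
       chi2 = chi2, p = p,
       reconstructed = (a[["reconstructed"]] + b[["reconstructed"]]) > 0)
}

#' Per-SNP quality-control report
#'
#' Computes, for every SNP of a genotype matrix, the minor allele
#' frequency (folded to at most 0.5, with any relabelling recorded),
#' genotype counts on complete calls, and the Hardy-Weinberg
#' equilibrium chi-squared test. SNPs failing HWE at alpha = 0.05 are
#' flagged but never removed: downstream analyses retain the full panel.
#'
#' @param gm A [genotype_matrix()].
#' @return Data frame with one row per SNP: `rsid`, `locus`, `maf`,
#'   `n_called`, `n_major_hom`, `n_het`, `n_minor_hom`, `hwe_chi2`,
#'   `hwe_p`, `in_hwe`, `monomorphic`, `folded`.
#' @export
qc_report <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$snps) == 0) stop("genotype matrix has no SNPs")
  rows <- lapply(seq_len(nrow(gm$snps)), function(j) {
    d <- gm$dosage[, j]
    d <- d[!is.na(d)]
    n_called <- length(d)
    counts <- c(sum(d == 0), sum(d == 1), sum(d == 2))
    folded <- FALSE
    maf_raw <- if (n_called > 0) sum(d) / (2 * n_called) else NA_real_
    if (!is.na(maf_raw) && maf_raw > 0.5) {
      counts <- rev(counts)  # counted allele was actually the major one
      folded <- TRUE
    }
    h <- if (n_called > 0) hwe_test(counts) else
      list(chi2 = NA_real_, p = NA_real_, in_hwe = NA, maf = NA_real_,
           monomorphic = NA)
    data.frame(rsid = gm$snps$rsid[j], locus = gm$snps$locus[j],
               maf = h$maf, n_called = n_called,
               n_major_hom = counts[1], n_het = counts[2],
               n_minor_hom = counts[3],
               hwe_chi2 = h$chi2, hwe_p = h$p, in_hwe = h$in_hwe,
               monomorphic = h$monomorphic, folded = folded,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare a cohort's allele frequencies with a published reference
#'
#' Mirrors the published two-cohort allele frequency table: for each SNP
#' shared between the genotype matrix and the reference table, the
#' cohort's observed allele counts are tested against counts
#' reconstructed from the reference frequency via [compare_maf()].
#'
#' @param gm A [genotype_matrix()].
#' @param reference Data frame with columns `rsid`, `maf`, and optionally
#'   `n`; rows absent from the matrix are skipped.
#' @param reference_n Default reference cohort size (participants) used
#'   when the reference table has no `n` column.
#' @return Data frame with `rsid`, `maf_cohort`, `maf_reference`, `chi2`,
#'   `p`, `reconstructed`.
#' @export
maf_comparison <- function(gm, reference, reference_n = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  reference <- as.data.frame(reference, stringsAsFactors = FALSE)
  if (!all(c("rsid", "maf") %in% names(reference)))
    stop("reference needs `rsid` and `maf` columns")
  if (!"n" %in% names(reference)) {
    if (is.null(reference_n))
      stop("supply reference_n or an `n` column in the reference table")
    reference$n <- reference_n
  }
  qc <- qc_report(gm)
  shared <- intersect(reference$rsid, qc$rsid)
  rows <- lapply(shared, function(id) {
    q <- qc[qc$rsid == id, ]
    r <- reference[reference$rsid == id, ][1, ]
    minor <- q$n_het + 2 * q$n_minor_hom
    cmp <- compare_maf(c(minor, 2 * q$n_called - minor),
                       list(maf = r$maf, n = r$n), rsid = id)
    data.frame(rsid = id, maf_cohort = cmp$maf_a,
               maf_reference = cmp$maf_b, chi2 = cmp$chi2, p = cmp$p,
               reconstructed = cmp$reconstructed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
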