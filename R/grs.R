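#' Allelic odds ratio and risk direction for one SNP
#'
#' Builds the allele-level 2x2 table (minor/major allele counts by
#' non-responder/responder, allele counts summed over dosages on called
#' genotypes) and computes the odds ratio of carrying the minor allele
#' among non-responders versus responders. The risk direction follows the
#' coding rule of the score: `+1` when OR > 1 (minor allele enriched in
#' non-responders, i.e. at-risk), `-1` when OR < 1, `0` when OR equals 1
#' exactly or is undefined. Any zero cell triggers the Haldane-Anscombe
#' correction (+0.5 to all four cells), flagged in the result.
#'
#' @param dosages Integer vector of minor-allele dosages (0/1/2, `NA`
#'   allowed) for one SNP.
#' @param responder Logical vector, same length: `TRUE` for responders.
#' @return List with `odds_ratio`, `direction`, `table` (named counts:
#'   `minor_nr`, `major_nr`, `minor_r`, `major_r`), `haldane` and
#'   `uninformative` flags.
#' @export
#' @examples
#' # minor allele enriched among non-responders
#' allele_odds_ratio(c(2, 2, 1, 0, 0), c(FALSE, FALSE, FALSE, TRUE, TRUE))
allele_odds_ratio <- function(dosages, responder) {
  if (length(dosages) != length(responder))
    stop("dosages and responder must have equal length")
  responder <- as.logical(responder)
  if (!any(responder) || !any(!responder))
    stop("both responder groups must be non-empty")
  ok <- !is.na(dosages)
  cell <- function(group) {
    d <- dosages[ok & group]
    c(minor = sum(d), major = 2 * length(d) - sum(d), n_called = length(d))
  }
  nr <- cell(!responder)
  r <- cell(responder)
  tab <- c(minor_nr = nr[["minor"]], major_nr = nr[["major"]],
           minor_r = r[["minor"]], major_r = r[["major"]])
  if (nr[["n_called"]] == 0 || r[["n_called"]] == 0) {
    return(list(odds_ratio = NA_real_, direction = 0L, table = tab,
                haldane = FALSE, uninformative = TRUE))
  }
  haldane <- any(tab == 0)
  t2 <- if (haldane) tab + 0.5 else tab
  or <- (t2[["minor_nr"]] / t2[["major_nr"]]) /
    (t2[["minor_r"]] / t2[["major_r"]])
  direction <- if (or > 1) 1L else if (or < 1) -1L else 0L
  list(odds_ratio = unname(or), direction = direction, table = tab,
       haldane = haldane, uninformative = FALSE)
}

#' Risk directions for every SNP of a cohort
#'
#' Applies [allele_odds_ratio()] to each SNP of a genotype matrix
#' against the cohort's responder flags, yielding the weight set used to
#' build risk scores.
#'
#' @param gm A [genotype_matrix()].
#' @param phenotypes Output of [classify_responders()] covering the
#'   matrix's participants (matched by `participant_id`).
#' @return Data frame with one row per SNP: `rsid`, `odds_ratio`,
#'   `direction`, the four allele counts, `haldane`, `uninformative`.
#' @export
compute_weights <- function(gm, phenotypes) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!"responder" %in% names(phenotypes))
    stop("run classify_responders() first")
  idx <- match(gm$participant_ids, phenotypes$participant_id)
  if (anyNA(idx))
    stop("phenotypes missing for participants: ",
         paste(gm$participant_ids[is.na(idx)][1:5], collapse = ", "))
  resp <- phenotypes$responder[idx]
  rows <- lapply(seq_len(nrow(gm$snps)), function(j) {
    w <- allele_odds_ratio(gm$dosage[, j], resp)
    data.frame(rsid = gm$snps$rsid[j], odds_ratio = w$odds_ratio,
               direction = w$direction,
               minor_nr = w$table[["minor_nr"]],
               major_nr = w$table[["major_nr"]],
               minor_r = w$table[["minor_r"]],
               major_r = w$table[["major_r"]],
               haldane = w$haldane, uninformative = w$uninformative,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compute a genetic risk score over a SNP panel
#'
#' The score of a participant is the sum of signed minor-allele dosages
#' over the panel: each SNP contributes `direction * dosage`, so a
#' heterozygote adds -1/0/+1 and a minor-allele homozygote -2/0/+2. A
#' positive score means the participant carries more at-risk than
#' beneficial alleles. Participants missing any panel genotype are not
#' scored (score `NA`) and their missing-call counts reported; no
#' imputation is performed. A carrier mode (`+/-1` per carrier regardless
#' of dosage) is available behind `mode = "carrier"`.
#'
#' @param gm A [genotype_matrix()].
#' @param weights Weight table from [compute_weights()] (needs `rsid`
#'   and `direction`).
#' @param panel Character vector of rsids, or `"all"` for every SNP of
#'   the matrix.
#' @param panel_name Label attached to the result.
#' @param mode `"dosage"` (default) or `"carrier"`.
#' @return Object of class `grs_vector`: data frame `participant_id`,
#'   `score` (integer, `NA` when unscored), `n_missing` (missing panel
#'   genotypes), with attributes `panel_name`, `rsids`, `n_scored`.
#' @export
compute_grs <- function(gm, weights, panel = "all",
                        panel_name = NULL, mode = c("dosage", "carrier")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mode <- match.arg(mode)
  if (identical(panel, "all")) {
    panel <- gm$snps$rsid
    if (is.null(panel_name)) panel_name <- "all"
  }
  if (length(panel) == 0) stop("panel must contain at least one rsid")
  if (is.null(panel_name)) panel_name <- paste0(length(panel), "-SNP")
  absent <- setdiff(panel, gm$snps$rsid)
  if (length(absent))
    stop("panel rsids absent from genotype matrix: ",
         paste(absent, collapse = ", "))
  unweighted <- setdiff(panel, weights$rsid)
  if (length(unweighted))
    stop("panel rsids absent from weights: ",
         paste(unweighted, collapse = ", "))
  dir <- weights$direction[match(panel, weights$rsid)]
  dos <- gm$dosage[, panel, drop = FALSE]
  if (mode == "carrier") dos <- pmin(dos, 1L)
  n_missing <- rowSums(is.na(dos))
  dos0 <- dos; dos0[is.na(dos0)] <- 0L
  score <- as.integer(drop(dos0 %*% dir))
  score[n_missing > 0] <- NA_integer_
  out <- data.frame(participant_id = gm$participant_ids, score = score,
                    n_missing = n_missing, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, panel_name = panel_name, rsids = panel,
            n_scored = sum(!is.na(score)), class = c("grs_vector",
                                                     "data.frame"))
}

#' Genetic risk score of the seven-SNP replication panel
#'
#' Convenience wrapper: [compute_grs()] restricted to the fixed
#' seven-SNP panel of [replication_panel()], with directions computed
#' in-cohort (pass externally derived weights to transfer directions
#' from another cohort instead).
#'
#' @param gm A [genotype_matrix()]; must contain all seven panel rsids.
#' @param weights Weight table from [compute_weights()].
#' @return A `grs_vector` (see [compute_grs()]).
#' @export
replication_panel_grs <- function(gm, weights) {
  compute_grs(gm, weights, panel = replication_panel(),
              panel_name = "replication_7")
}

#' Integer histogram of a risk score vector
#'
#' @param grs A `grs_vector` from [compute_grs()].
#' @return Data frame `score`, `count` over scored participants, with
#'   attribute `n` (total scored participants).
#' @export
grs_distribution <- function(grs) {
  if (!inherits(grs, "grs_vector")) stop("expected a grs_vector")
  s <- grs$score[!is.na(grs$score)]
  if (length(s) == 0) stop("no scored participants")
  tab <- table(factor(s, levels = seq(min(s), max(s))))
  out <- data.frame(score = as.integer(names(tab)),
                    count = as.integer(tab))
  structure(out, n = length(s))
}
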