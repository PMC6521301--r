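#' Reference SNP panel with published minor allele frequencies
#'
#' Returns the 91-SNP panel for which minor allele frequencies were
#' published in both the French Canadian (Caucasian) discovery cohort and
#' the Mexican replication cohort, together with the locus label of each
#' SNP and a flag marking the seven SNPs of the replication risk score.
#' These frequencies drive the default settings of the synthetic cohort
#' generator and serve as the reference table for cross-cohort allele
#' frequency comparisons.
#'
#' @return A data frame with columns `locus`, `rsid`, `maf_caucasian`,
#'   `maf_mexican` and `replication_panel` (logical).
#' @export
#' @examples
#' head(snp_panel())
snp_panel <- function() {
  path <- system.file("extdata", "cohort_maf_panel.csv",
                      package = "grspipe", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' SNP identifiers of the seven-SNP replication risk score
#'
#' The seven genotyped SNPs retained (after linkage-disequilibrium pruning
#' and assay-design constraints) to replicate the discovery cohort's
#' 10-SNP risk score.
#'
#' @return Character vector of seven rsids.
#' @export
replication_panel <- function() {
  c("rs1449009", "rs61332355", "rs1216352", "rs1216365",
    "rs6920829", "rs6463808", "rs752088")
}

#' SNP identifiers of the refined five-SNP risk score
#'
#' The five lead SNPs retained by bidirectional stepwise selection
#' (adjusted for age, sex and BMI) in the replication cohort. Provided as
#' a convenience panel; stepwise selection on new data is performed with
#' [stepwise_select()].
#'
#' @return Character vector of five rsids.
#' @export
refined_panel <- function() {
  c("rs10265408", "rs10486228", "rs17150341", "rs6974252", "rs2595241")
}
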