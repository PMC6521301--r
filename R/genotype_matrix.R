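#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds minor-allele dosages (0, 1, 2 or `NA`) for a
#' set of participants at a set of biallelic SNPs, together with per-SNP
#' metadata. Dosages always count copies of the minor allele as recorded
#' in the metadata.
#'
#' @param dosage Integer matrix, participants in rows and SNPs in
#'   columns; entries in `{0, 1, 2}` or `NA` for missing calls.
#' @param snps Data frame with one row per SNP column, containing at
#'   least `rsid`; optional `locus`, `minor_allele`, `major_allele`.
#' @param participant_ids Character vector of unique participant ids; by
#'   default taken from `rownames(dosage)`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `snps`, `participant_ids`.
#' @export
genotype_matrix <- function(dosage, snps, participant_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(participant_ids))
    participant_ids <- sprintf("S%04d", seq_len(nrow(dosage)))
  participant_ids <- as.character(participant_ids)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!"rsid" %in% names(snps)) stop("`snps` must contain an `rsid` column")
  for (col in c("locus", "minor_allele", "major_allele"))
    if (!col %in% names(snps))
      snps[[col]] <- rep(NA_character_, nrow(snps))
  if (nrow(dosage) != length(participant_ids))
    stop("dosage rows (", nrow(dosage), ") != participant ids (",
         length(participant_ids), ")")
  if (ncol(dosage) != nrow(snps))
    stop("dosage columns (", ncol(dosage), ") != SNP metadata rows (",
         nrow(snps), ")")
  if (anyDuplicated(snps$rsid))
    stop("duplicate rsid: ",
         paste(unique(snps$rsid[duplicated(snps$rsid)]), collapse = ", "))
  if (anyDuplicated(participant_ids))
    stop("duplicate participant ids")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("dosage entries must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(participant_ids, snps$rsid)
  structure(list(dosage = dosage, snps = snps,
                 participant_ids = participant_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$participant_ids), " participants x ",
      nrow(x$snps), " SNPs; ",
      sum(is.na(x$dosage)), " missing calls\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read a genotype matrix from VCF or PLINK-style text
#'
#' Dosages are counted on the minor allele as determined from the file's
#' own allele frequencies: after parsing, any SNP whose counted allele has
#' frequency above 0.5 is folded (dosage mapped to `2 - dosage`, allele
#' labels swapped). Multiallelic VCF records are rejected. Genomic
#' coordinates are carried along but not used: the file is treated purely
#' as a genotype container.
#'
#' @param path Path to a VCF file (`format = "vcf"`) or to a PLINK `.ped`
#'   file / prefix with an accompanying `.map` (`format = "plink_text"`).
#' @param format Input format.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  switch(format,
         vcf = read_genotypes_vcf(path),
         plink_text = read_genotypes_plink(path))
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  rsid <- fix$ID
  no_id <- is.na(rsid) | rsid == "."
  rsid[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    stop("multiallelic records not supported: ",
         paste(rsid[multi], collapse = ", "))
  if (anyDuplicated(rsid))
    stop("duplicate rsid in VCF: ",
         paste(unique(rsid[duplicated(rsid)]), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")  # SNPs x samples
  samples <- colnames(gt)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- (a1 == "1") + (a2 == "1")
  dos[a1 == "." | a2 == "." | is.na(gt)] <- NA
  bad <- !is.na(a1) & !(a1 %in% c("0", "1", ".")) |
         !is.na(a2) & !(a2 %in% c("0", "1", "."))
  if (any(bad)) stop("non-biallelic genotype codes in GT field")
  dos <- t(dos)  # participants x SNPs
  minor <- fix$ALT
  major <- fix$REF
  # fold so that the counted allele is the minor one
  alt_freq <- colMeans(dos, na.rm = TRUE) / 2
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  if (any(flip)) {
    dos[, flip] <- 2L - dos[, flip]
    tmp <- minor[flip]; minor[flip] <- major[flip]; major[flip] <- tmp
  }
  genotype_matrix(dos,
                  data.frame(rsid = rsid, locus = NA_character_,
                             minor_allele = minor, major_allele = major,
                             stringsAsFactors = FALSE),
                  participant_ids = samples)
}

read_genotypes_plink <- function(path) {
  prefix <- sub("\\.ped$", "", path)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path)) stop("file not found: ", ped_path)
  if (!file.exists(map_path)) stop("file not found: ", map_path)
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop("malformed .map: expected 4 columns")
  rsid <- as.character(map[[2]])
  if (anyDuplicated(rsid))
    stop("duplicate rsid in .map: ",
         paste(unique(rsid[duplicated(rsid)]), collapse = ", "))
  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  n_snps <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snps)
    stop("malformed .ped: expected ", 6 + 2 * n_snps,
         " columns, found ", ncol(ped))
  ids <- ped[[2]]
  n <- nrow(ped)
  dos <- matrix(NA_integer_, n, n_snps)
  minor <- major <- character(n_snps)
  for (j in seq_len(n_snps)) {
    al1 <- ped[[6 + 2 * j - 1]]
    al2 <- ped[[6 + 2 * j]]
    al1[al1 == "0"] <- NA; al2[al2 == "0"] <- NA
    alleles <- sort(table(c(al1, al2)), decreasing = TRUE)
    if (length(alleles) > 2)
      stop("SNP ", rsid[j], " has more than two alleles in .ped")
    if (length(alleles) == 0) { minor[j] <- major[j] <- NA; next }
    major[j] <- names(alleles)[1]
    minor[j] <- if (length(alleles) == 2) names(alleles)[2] else names(alleles)[1]
    d <- (al1 == minor[j]) + (al2 == minor[j])
    d[is.na(al1) | is.na(al2)] <- NA
    if (length(alleles) == 1) d[!is.na(al1) & !is.na(al2)] <- 0L
    dos[, j] <- d
  }
  genotype_matrix(dos,
                  data.frame(rsid = rsid, locus = NA_character_,
                             minor_allele = minor, major_allele = major,
                             stringsAsFactors = FALSE),
                  participant_ids = ids)
}

#' Write a genotype matrix as a minimal VCF
#'
#' One sample column per participant, GT field only; REF is the major and
#' ALT the minor allele, so the ALT dosage equals the stored minor-allele
#' dosage. Positions are synthetic ordinals (no positional meaning).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  minor <- ifelse(is.na(gm$snps$minor_allele), "A", gm$snps$minor_allele)
  major <- ifelse(is.na(gm$snps$major_allele), "G", gm$snps$major_allele)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grspipe",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$participant_ids), collapse = "\t"))
  gt_map <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(gm$snps)), function(j) {
    d <- gm$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_map[d + 1L])
    paste(c("1", j, gm$snps$rsid[j], major[j], minor[j],
            ".", ".", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype matrix as PLINK-style .ped/.map text
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map`
#'   are written.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  minor <- ifelse(is.na(gm$snps$minor_allele), "A", gm$snps$minor_allele)
  major <- ifelse(is.na(gm$snps$major_allele), "G", gm$snps$major_allele)
  map <- data.frame(chrom = 1, rsid = gm$snps$rsid, cm = 0,
                    pos = seq_len(nrow(gm$snps)))
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- length(gm$participant_ids)
  allele_cols <- matrix("0", n, 2 * nrow(gm$snps))
  for (j in seq_len(nrow(gm$snps))) {
    d <- gm$dosage[, j]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, minor[j], major[j]))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, minor[j], major[j]))
    allele_cols[, 2 * j - 1] <- a1
    allele_cols[, 2 * j] <- a2
  }
  ped <- cbind(gm$participant_ids, gm$participant_ids, "0", "0", "0", "-9",
               allele_cols)
  write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
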