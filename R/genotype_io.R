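#' Load genotypes from VCF, PLINK binary, or a dosage table
#'
#' Builds a [genotype_matrix()] from one of three dialects. Allele A (the
#' counted allele of the dosage codes) is fixed per dialect: the VCF ALT
#' allele, the PLINK counted allele (`.bim` column 5, A1), or whatever
#' allele the dosage table's author counted. Multi-allelic records are
#' rejected explicitly.
#'
#' @param path file path: a `.vcf` file, a PLINK `.bed` file (or fileset
#'   prefix; `.bim`/`.fam` must sit alongside), or a tab-separated dosage
#'   table whose first column is the sample id and remaining columns are
#'   markers with cells in `{0, 1, 2, NA}`.
#' @param format one of `"dosage_tsv"`, `"vcf"`, `"plink_bed"`.
#' @return A `genotype_matrix`.
#' @export
load_genotypes <- function(path, format = c("dosage_tsv", "vcf", "plink_bed")) {
  format <- match.arg(format)
  switch(format,
         dosage_tsv = .load_dosage_tsv(path),
         vcf = .load_vcf(path),
         plink_bed = .load_plink_bed(path))
}

.load_dosage_tsv <- function(path) {
  if (!file.exists(path)) stop_gs("file not found: ", path)
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop_gs("dosage TSV parse error in '", path, "': ",
                                conditionMessage(e)))
  if (ncol(tab) < 2) stop_gs("dosage TSV '", path,
                             "' needs a sample-id column plus >= 1 marker column")
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(d)) {
    bad <- colnames(d)[!vapply(seq_len(ncol(d)), function(j)
      is.numeric(tab[[j + 1]]), logical(1))][1]
    stop_gs("dosage TSV '", path, "': non-numeric entries in marker column '", bad, "'")
  }
  genotype_matrix(d, sample_ids = ids, marker_ids = colnames(tab)[-1])
}

#' Write a genotype matrix as a dosage TSV
#'
#' Inverse of `load_genotypes(format = "dosage_tsv")`: header row of marker
#' ids, first column `sample_id`, cells in `{0, 1, 2, NA}`. Round-trips
#' exactly.
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(sample_id = sample_ids(g), g$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.load_vcf <- function(path) {
  if (!file.exists(path)) stop_gs("file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_gs("VCF parse error in '", path, "': ",
                                            conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  mids <- fix[, "ID"]
  noid <- is.na(mids) | mids == "."
  mids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  if (any(multi))
    stop_gs("multi-allelic VCF records are not supported: ",
            paste(mids[multi], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop_gs("VCF '", path, "' has no GT field")
  # dosage of the ALT allele from the GT string; any missing allele -> NA
  s <- as.vector(gt)
  al <- strsplit(ifelse(is.na(s), ".", s), "[/|]")
  bad <- vapply(al, function(a) any(!a %in% c("0", "1", ".")), logical(1))
  if (any(bad))
    stop_gs("unsupported GT allele codes (multi-allelic?): ",
            paste(unique(s[bad]), collapse = ", "))
  dv <- vapply(al, function(a) {
    if (any(a == ".")) NA_real_ else sum(a == "1")
  }, numeric(1))
  d <- matrix(dv, nrow = nrow(gt), ncol = ncol(gt))  # markers x samples
  genotype_matrix(t(d), sample_ids = colnames(gt), marker_ids = mids)
}

# PLINK .bed is SNP-major: per marker, ceil(n/4) bytes, 2 bits per sample:
# 00 = hom A1 (dosage 2), 10 = het (1), 11 = hom A2 (0), 01 = missing.
.load_plink_bed <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop_gs("file not found: ", f)
  bimtab <- read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  famtab <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(bimtab); n <- nrow(famtab)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop_gs("'", bed, "' is not a PLINK .bed file (bad magic number)")
  if (raw[3] != as.raw(0x01))
    stop_gs("'", bed, "' is not in SNP-major order")
  bpm <- ceiling(n / 4)
  if (length(raw) - 3 != bpm * m)
    stop_gs("'", bed, "' has unexpected length for ", n, " samples x ", m, " markers")
  body <- raw[-(1:3)]
  # decode all two-bit fields at once
  ints <- as.integer(body)
  codes <- cbind(ints %% 4L, (ints %/% 4L) %% 4L, (ints %/% 16L) %% 4L, ints %/% 64L)
  lookup <- c(2, NA, 1, 0)  # 00, 01, 10, 11
  d <- matrix(NA_real_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    block <- codes[((j - 1) * bpm + 1):(j * bpm), , drop = FALSE]
    vals <- lookup[t(block) + 1L]
    d[, j] <- vals[seq_len(n)]
  }
  genotype_matrix(d,
                  sample_ids = as.character(famtab[[2]]),
                  marker_ids = as.character(bimtab[[2]]))
}

# writer used for round-trip testing of the .bed reader
.write_plink_bed <- function(g, prefix) {
  d <- g$dosages
  n <- nrow(d); m <- ncol(d)
  code <- matrix(1L, n, m)           # 01 = missing
  code[!is.na(d) & d == 2] <- 0L     # 00 = hom A1
  code[!is.na(d) & d == 1] <- 2L     # 10 = het
  code[!is.na(d) & d == 0] <- 3L     # 11 = hom A2
  bpm <- ceiling(n / 4)
  bytes <- raw(3 + bpm * m)
  bytes[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  pos <- 4L
  for (j in seq_len(m)) {
    v <- c(code[, j], rep(0L, bpm * 4 - n))
    quads <- matrix(v, nrow = 4)
    b <- quads[1, ] + 4L * quads[2, ] + 16L * quads[3, ] + 64L * quads[4, ]
    bytes[pos:(pos + bpm - 1)] <- as.raw(b)
    pos <- pos + bpm
  }
  writeBin(bytes, paste0(prefix, ".bed"))
  write.table(data.frame(1, marker_ids(g), 0, seq_len(m), "A", "B"),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(sample_ids(g), sample_ids(g), 0, 0, 0, -9),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a phenotype table
#'
#' Tab-separated with header; must contain `sample_id` and `value` columns
#' (a `trait` column and covariate columns may follow).
#'
#' @param path file path.
#' @param trait optional trait name to select when the table holds several.
#' @return Named numeric vector of phenotype values (names = sample ids);
#'   additional columns are attached as the `"covariates"` attribute.
#' @export
read_phenotypes <- function(path, trait = NULL) {
  if (!file.exists(path)) stop_gs("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "value") %in% names(tab)))
    stop_gs("phenotype table must have 'sample_id' and 'value' columns")
  if (!is.null(trait) && "trait" %in% names(tab))
    tab <- tab[tab$trait == trait, , drop = FALSE]
  if (anyDuplicated(tab$sample_id))
    stop_gs("duplicated sample ids in phenotype table")
  y <- setNames(as.numeric(tab$value), as.character(tab$sample_id))
  extra <- setdiff(names(tab), c("sample_id", "trait", "value"))
  if (length(extra)) attr(y, "covariates") <- tab[, extra, drop = FALSE]
  y
}

#' Write a phenotype table
#'
#' @param y named numeric vector (names = sample ids).
#' @param path output path.
#' @param trait trait label written to the `trait` column.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(y, path, trait = "trait") {
  stopifnot(!is.null(names(y)))
  write.table(data.frame(sample_id = names(y), trait = trait, value = as.numeric(y)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
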