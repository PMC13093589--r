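#' @useDynLib reciprocross, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median model.matrix pchisq pnorm reformulate rnorm rbinom
#'   rnbinom kmeans var quantile binom.test sd cor
#' @importFrom utils read.delim write.table
NULL

CROSS_LEVELS <- c("HH", "HN", "NH", "NN")

# Family letter coding within a crossing block: A = HH, B = NH, C = NN, D = HN
CROSS_LETTER <- c(HH = "A", NH = "B", NN = "C", HN = "D")

rc_log <- function(...) {
  message("[reciprocross] ", sprintf(...))
}

#' Pipeline thresholds
#'
#' Returns the analysis thresholds used throughout the pipeline, optionally
#' overridden from a YAML file.  Defaults: FDR 0.05 for calling a gene
#' differentially expressed, minor-allele-frequency floor 0.01, genotype
#' missingness caps 0.20 (per locus and per individual), and 1000 replicates
#' for randomization procedures.
#'
#' @param path optional YAML file whose top-level keys override the defaults.
#' @return named list of thresholds.
#' @export
pipeline_thresholds <- function(path = NULL) {
  defaults <- list(
    fdr = 0.05,
    maf_min = 0.01,
    locus_missing_max = 0.20,
    indiv_missing_max = 0.20,
    replicates = 1000L
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) defaults[[k]] <- user[[k]]
  }
  defaults
}

## ---- validation -----------------------------------------------------------

#' Validate a count matrix
#'
#' A count matrix is a genes x samples integer matrix with unique gene ids as
#' row names and unique sample ids as column names; all entries must be
#' non-negative integers.
#'
#' @param counts matrix to validate.
#' @return the matrix, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count (negative, missing or non-integer) at gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  invisible(counts)
}

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `matrix_id`, `cross` (one of HH/HN/NH/NN,
#' mother's origin listed first), `family_code`, `sex` (F/M), `cross_date`.
#'
#' @param meta data.frame to validate.
#' @return the data.frame, invisibly, if valid.
#' @export
validate_metadata <- function(meta) {
  required <- c("sample_id", "matrix_id", "cross", "family_code", "sex", "cross_date")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  bad_cross <- setdiff(unique(as.character(meta$cross)), CROSS_LEVELS)
  if (length(bad_cross) > 0)
    stop("unknown cross code(s): ", paste(bad_cross, collapse = ", "),
         " (expected HH, HN, NH or NN, mother first)")
  bad_sex <- setdiff(unique(as.character(meta$sex)), c("F", "M"))
  if (length(bad_sex) > 0)
    stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "))
  invisible(meta)
}

#' Validate a genotype matrix
#'
#' Samples x loci matrix of alternate-allele dosages coded 0/1/2 with `NA`
#' for missing calls.
#'
#' @param geno matrix to validate.
#' @return the matrix, invisibly, if valid.
#' @export
validate_genotypes <- function(geno) {
  if (!is.matrix(geno)) stop("genotypes must be a matrix")
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("genotypes must have sample ids as rownames and locus ids as colnames")
  vals <- unique(as.vector(geno))
  vals <- vals[!is.na(vals)]
  if (length(setdiff(vals, c(0, 1, 2))) > 0)
    stop("genotype values must be 0, 1, 2 or NA")
  invisible(geno)
}

#' Validate a GO-term table
#'
#' Required columns: `go_id`, `name`, `count` (number of distinct DEGs
#' carrying the term, positive integer), and 2-D semantic coordinates
#' `pc1`, `pc2`.
#'
#' @param terms data.frame to validate.
#' @return the data.frame, invisibly, if valid.
#' @export
validate_terms <- function(terms) {
  required <- c("go_id", "name", "count", "pc1", "pc2")
  missing_cols <- setdiff(required, names(terms))
  if (length(missing_cols) > 0)
    stop("term table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(terms$count < 1)) stop("term counts must be >= 1")
  if (any(!is.finite(terms$pc1)) || any(!is.finite(terms$pc2)))
    stop("term coordinates must be finite")
  invisible(terms)
}

## ---- readers / writers ----------------------------------------------------

#' Read a gene x sample count matrix from TSV
#'
#' First column holds gene ids, header row holds sample ids, cells are
#' non-negative integers.  Row and column order are preserved.
#'
#' @param path TSV file path.
#' @return validated integer matrix (genes x samples).
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count file must have a gene-id column plus >= 1 sample")
  sample_ids <- colnames(df)[-1]   # before subsetting, which repairs duplicates
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  colnames(m) <- sample_ids
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix to TSV
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Cross codes are mother-first: `HN` is a hatchery mother crossed to a
#' natural-origin father.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if ("matrix_id" %in% names(meta))
    meta$matrix_id <- as.integer(meta$matrix_id)
  validate_metadata(meta)
  meta$cross <- factor(meta$cross, levels = CROSS_LEVELS)
  meta$sex <- factor(meta$sex, levels = c("F", "M"))
  meta$cross_date <- factor(meta$cross_date)
  meta
}

#' Write a sample metadata table to TSV
#'
#' @param meta validated metadata.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses GT fields into alternate-allele dosages (0/1/2; `./.` becomes
#' `NA`).  Multiallelic records are skipped with a logged count, since the
#' kinship estimator is defined for biallelic sites.  Locus ids are
#' `chrom:pos`.
#'
#' @param path VCF (v4.x) file path.
#' @return samples x loci genotype matrix.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    rc_log("skipping %d multiallelic record(s)", sum(multi))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  locus_ids <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  code_one <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    out
  }
  coded <- apply(gt, 2, code_one)
  if (is.null(dim(coded))) coded <- matrix(coded, ncol = ncol(gt), dimnames = dimnames(gt))
  geno <- t(coded)
  colnames(geno) <- locus_ids
  rownames(geno) <- colnames(gt)
  validate_genotypes(geno)
  geno
}

#' Write a genotype matrix as a minimal uncompressed VCF
#'
#' Emits one biallelic record per locus (REF `A`, ALT `G` placeholders when
#' the locus id carries no allele information) with unphased GT calls;
#' missing dosages become `./.`.  Locus ids of the form `chrom:pos` supply
#' CHROM and POS.
#'
#' @param geno samples x loci genotype matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  validate_genotypes(geno)
  loci <- colnames(geno)
  parts <- strsplit(loci, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1)
  pos <- vapply(parts, function(p) if (length(p) > 1) p[2] else "1", "")
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=reciprocross",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t")
  )
  body <- vapply(seq_along(loci), function(l) {
    g <- geno[, l]
    calls <- ifelse(is.na(g), "./.", gt_codes[as.character(g)])
    paste(c(chrom[l], pos[l], loci[l], "A", "G", ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GO-term table from TSV
#'
#' Expects the tabular export of a semantic-similarity reduction: columns
#' `go_id`, `name`, `count` and the 2-D coordinates `pc1`, `pc2`.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_terms <- function(path) {
  terms <- read.delim(path, stringsAsFactors = FALSE)
  validate_terms(terms)
  terms
}
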