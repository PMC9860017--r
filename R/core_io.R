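# Readers/writers for the on-disk formats the pipeline touches, plus
# configuration and classed error conditions. Coordinate conventions:
# BED intervals are 0-based half-open; variants and annotations are 1-based
# (VCF convention). All conversions between the two happen here and nowhere
# else downstream.

#' Classed error constructors
#'
#' All parser and pipeline failures are signalled as classed conditions so
#' callers (and tests) can distinguish malformed input (`finewas_format_error`),
#' inconsistent but well-formed input (`finewas_integrity_error`), bad
#' arguments (`finewas_argument_error`), numeric failures
#' (`finewas_numeric_error`) and enumeration-cap violations
#' (`finewas_size_error`).
#'
#' @param class condition subclass suffix, e.g. "format"
#' @param msg message text
#' @keywords internal
fw_stop <- function(class, msg) {
  stop(structure(
    class = c(paste0("finewas_", class, "_error"), "finewas_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# full double precision on write (round trips to >= 12 significant digits)
fw_num <- function(x) formatC(x, digits = 17, format = "g")

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file in the LDSC dialect with
#' header columns SNP, CHR, BP, A1, A2, Z and N (case-insensitive, any
#' order). Rows whose Z or N field is non-numeric are dropped and counted in
#' the `n_dropped` attribute; duplicate variant keys (CHR, BP, A1, A2) are an
#' integrity error.
#'
#' @param path path to a tab-delimited sumstats file
#' @return data.frame with columns `snp`, `chr`, `bp`, `a1`, `a2`, `z`, `n`
#'   and `chi2` (`= z^2`), attribute `n_dropped` giving the dropped-row count.
#' @export
read_sumstats <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  nm <- toupper(names(raw))
  need <- c("SNP", "CHR", "BP", "A1", "A2", "Z", "N")
  miss <- setdiff(need, nm)
  if (length(miss) > 0L)
    fw_stop("format", paste0("sumstats file ", path,
                             " is missing mandatory column(s): ",
                             paste(miss, collapse = ", ")))
  idx <- match(need, nm)
  out <- data.frame(
    snp = raw[[idx[1]]], chr = raw[[idx[2]]],
    bp  = suppressWarnings(as.integer(raw[[idx[3]]])),
    a1  = raw[[idx[4]]], a2 = raw[[idx[5]]],
    z   = suppressWarnings(as.numeric(raw[[idx[6]]])),
    n   = suppressWarnings(as.numeric(raw[[idx[7]]])),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(out$z) | !is.finite(out$n)
  n_dropped <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  if (any(out$n <= 0))
    fw_stop("format", "sumstats column N must be > 0")
  key <- paste(out$chr, out$bp, out$a1, out$a2, sep = ":")
  if (anyDuplicated(key)) {
    first <- key[duplicated(key)][1L]
    fw_stop("integrity", paste0("duplicate variant key in sumstats: ", first))
  }
  out$chi2 <- out$z^2
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_sumstats()]: writes the LDSC-dialect TSV with numeric
#' fields at 17 significant digits so that read/write is a lossless round
#' trip.
#'
#' @param x sumstats data.frame from [read_sumstats()] or [simulate_gwas()]
#' @param path output path
#' @export
write_sumstats <- function(x, path) {
  out <- data.frame(SNP = x$snp, CHR = x$chr, BP = x$bp, A1 = x$a1,
                    A2 = x$a2, Z = fw_num(x$z), N = fw_num(x$n))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-SNP annotation table (.annot dialect)
#'
#' Tab-delimited with columns SNP, CHR, BP followed by one numeric column per
#' annotation. Continuous annotation values must lie in [0, 1].
#'
#' @param path path to the annotation TSV
#' @return data.frame with `snp`, `chr`, `bp` then one numeric column per
#'   annotation.
#' @export
read_annot <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- toupper(names(raw))
  if (!all(c("SNP", "CHR", "BP") %in% nm))
    fw_stop("format", paste0("annotation file ", path,
                             " must start with SNP, CHR, BP columns"))
  ann_cols <- which(!nm %in% c("SNP", "CHR", "BP"))
  if (anyDuplicated(names(raw)[ann_cols]))
    fw_stop("integrity", "duplicate annotation column names")
  out <- data.frame(snp = raw[[which(nm == "SNP")]],
                    chr = raw[[which(nm == "CHR")]],
                    bp  = as.integer(raw[[which(nm == "BP")]]),
                    stringsAsFactors = FALSE)
  for (j in ann_cols) {
    v <- as.numeric(raw[[j]])
    if (anyNA(v))
      fw_stop("format", paste0("non-numeric value in annotation column ",
                               names(raw)[j]))
    out[[names(raw)[j]]] <- v
  }
  out
}

#' @rdname read_annot
#' @param x annotation data.frame
#' @export
write_annot <- function(x, path) {
  out <- x
  names(out)[1:3] <- c("SNP", "CHR", "BP")
  for (j in seq_along(out)[-(1:3)]) out[[j]] <- fw_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic intervals from a BED3+ file
#'
#' BED coordinates are 0-based half-open; the returned `GRanges` uses the
#' usual 1-based closed convention (a BED line `chr1 100 200` becomes
#' positions 101..200). Intervals are sorted by (chrom, start); zero-length
#' intervals are a format error.
#'
#' @param path BED file path
#' @return a [GenomicRanges::GRanges] sorted by (seqnames, start)
#' @export
read_intervals <- function(path) {
  # pre-scan for zero/negative-length records so the error carries a line number
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(raw) < 3L)
    fw_stop("format", paste0(path, " is not BED3+: fewer than 3 columns"))
  bad <- which(raw[[2]] >= raw[[3]])
  if (length(bad) > 0L)
    fw_stop("format", paste0("zero-length or inverted interval at line ",
                             bad[1L], " of ", path))
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname read_intervals
#' @param gr a `GRanges` object (1-based closed)
#' @export
write_intervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a labelled LD correlation matrix
#'
#' Plain-text square matrix with header labels (and matching row labels).
#' The matrix is symmetrized to (M + t(M))/2, the diagonal is forced to 1 and
#' off-diagonal entries are clipped to [-1, 1] — text-rounding artifacts such
#' as 1.0000001 are tolerated rather than propagated.
#'
#' @param path path to the matrix file
#' @param snps optional character vector of expected SNP labels; a mismatch
#'   is an integrity error
#' @return numeric matrix with dimnames
#' @export
read_ld_matrix <- function(path, snps = NULL) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1L,
                                   check.names = FALSE))
  if (nrow(m) != ncol(m))
    fw_stop("format", paste0("LD matrix in ", path, " is not square: ",
                             nrow(m), " x ", ncol(m)))
  if (!is.null(snps) && !identical(colnames(m), snps))
    fw_stop("integrity", "LD matrix labels do not match the SNP list")
  m <- (m + t(m)) / 2
  off <- row(m) != col(m)
  m[off] <- pmin(pmax(m[off], -1), 1)
  diag(m) <- 1
  m
}

#' @rdname read_ld_matrix
#' @param m symmetric correlation matrix with dimnames
#' @export
write_ld_matrix <- function(m, path) {
  out <- apply(m, 2L, fw_num)
  dimnames(out) <- dimnames(m)
  df <- data.frame(SNP = rownames(m), out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' TSV keyed on sample ID (first column or a column named IID/ID/SAMPLE,
#' case-insensitive). Duplicate sample IDs are an integrity error.
#'
#' @param path TSV path
#' @return data.frame with first column `iid`, remaining columns as-is
#' @export
read_phenotypes <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- toupper(names(raw))
  idc <- which(nm %in% c("IID", "ID", "SAMPLE"))[1]
  if (is.na(idc)) idc <- 1L
  ids <- as.character(raw[[idc]])
  if (anyDuplicated(ids))
    fw_stop("integrity", paste0("duplicate sample ID: ",
                                ids[duplicated(ids)][1L]))
  out <- cbind(data.frame(iid = ids, stringsAsFactors = FALSE),
               raw[, -idc, drop = FALSE])
  out
}

#' Write rare-variant cohort genotypes as VCF
#'
#' Emits a minimal VCF 4.2 with GT-only genotype fields (plain text,
#' uncompressed). Sites are written in (chrom, pos) order as given.
#'
#' @param variants data.frame with columns `chr`, `pos`, `ref`, `alt`, `id`
#' @param geno integer matrix individuals x variants with allele dosages
#'   0/1/2; rownames are sample IDs
#' @param path output .vcf path
#' @export
write_vcf <- function(variants, geno, path) {
  stopifnot(nrow(variants) == ncol(geno))
  gt <- c("0/0", "0/1", "1/1")[geno + 1L]
  dim(gt) <- dim(geno)
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chr[i], variants$pos[i], variants$id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
            gt[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read rare-variant cohort genotypes from VCF
#'
#' Thin wrapper over `vcfR`: returns the variant table and an
#' individuals x variants dosage matrix (count of alternate alleles).
#'
#' @param path VCF path (plain text or bgzipped)
#' @return list with `variants` (data.frame chr, pos, id, ref, alt) and
#'   `geno` (integer matrix, individuals x variants)
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  variants <- data.frame(chr = fix$CHROM, pos = as.integer(fix$POS),
                         id = fix$ID, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  list(variants = variants, geno = t(dos))
}

#' Pipeline configuration
#'
#' A pipeline configuration is a named list of stage parameters and per-stage
#' seeds, serialized as YAML. Round trips are lossless for numeric, logical
#' and character scalars and vectors.
#'
#' @param path YAML path
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config named list
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17L)
  invisible(path)
}
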