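#' @importFrom stats complete.cases cor cor.test median pt qnorm rbinom rnorm
#'   runif sd setNames t.test var p.adjust
#' @importFrom utils read.delim write.table head modifyList
NULL

DATA_TYPES <- c("genotype", "cnv", "expression", "methylation")

#' Profile matrix for one omics data type
#'
#' Container for a feature x profile numeric matrix together with feature
#' genomic positions.  Genotypes are coded as minor-allele dosages in
#' \{0, 1, 2\} with `NA` for missing calls; expression, methylation and
#' copy-number values are real-valued.  Positions are held 1-based inclusive;
#' features without a position are flagged unplaced and are skipped by the
#' cis scans (they still participate in gender inference, e.g. a Y marker
#' identified by chromosome name).
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   profiles in columns (colnames = profile ids).
#' @param data_type one of `"genotype"`, `"cnv"`, `"expression"`,
#'   `"methylation"`.
#' @param positions data frame with columns `feature_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).  Features absent from it are unplaced.
#' @return An object of class `ProfileMatrix`.
#' @export
profile_matrix <- function(values, data_type, positions = NULL) {
  data_type <- match.arg(data_type, DATA_TYPES)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature ids as rownames and profile ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate profile ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (data_type == "genotype") {
    bad <- !(values %in% c(0, 1, 2) | is.na(values))
    if (any(bad)) {
      idx <- which(matrix(bad, nrow(values)), arr.ind = TRUE)[1, ]
      stop(sprintf("genotype values must be 0/1/2/NA; offending cell [%s, %s] = %s",
                   rownames(values)[idx[1]], colnames(values)[idx[2]],
                   values[idx[1], idx[2]]))
    }
  }
  pos <- empty_positions()
  if (!is.null(positions) && nrow(positions) > 0) {
    req <- c("feature_id", "chrom", "start", "end")
    if (!all(req %in% names(positions)))
      stop("`positions` needs columns: ", paste(req, collapse = ", "))
    positions <- positions[positions$feature_id %in% rownames(values), req, drop = FALSE]
    if (anyDuplicated(positions$feature_id))
      stop("duplicate positions for feature(s): ",
           paste(unique(positions$feature_id[duplicated(positions$feature_id)]),
                 collapse = ", "))
    if (any(positions$start > positions$end))
      stop("feature position with start > end")
    pos <- positions
  }
  unplaced <- setdiff(rownames(values), pos$feature_id)
  if (length(unplaced) > 0)
    msg("%d/%d %s feature(s) lack positions; excluded from cis scans",
        length(unplaced), nrow(values), data_type)
  structure(
    list(data_type = data_type, values = values, positions = pos,
         unplaced = unplaced),
    class = "ProfileMatrix")
}

empty_positions <- function() {
  data.frame(feature_id = character(), chrom = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

#' @export
print.ProfileMatrix <- function(x, ...) {
  cat(sprintf("ProfileMatrix <%s>: %d features x %d profiles (%d unplaced)\n",
              x$data_type, nrow(x$values), ncol(x$values), length(x$unplaced)))
  invisible(x)
}

#' @export
dim.ProfileMatrix <- function(x) dim(x$values)

profile_ids <- function(pm) colnames(pm$values)
feature_ids <- function(pm) rownames(pm$values)

#' Positions of placed features as a GRanges
#'
#' @param pm a `ProfileMatrix`.
#' @return `GRanges` named by feature id.
#' @export
feature_ranges <- function(pm) {
  p <- pm$positions
  gr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start, p$end))
  names(gr) <- p$feature_id
  gr
}

# ---- readers / writers -----------------------------------------------------

#' Read a profile matrix from TSV (or VCF for genotypes)
#'
#' The matrix file is tab-separated with a header row of profile ids and the
#' first column holding feature ids.  Genotype input may instead be a VCF
#' (v4.x); only the GT field is used, mapped 0/0 -> 0, 0/1 -> 1, 1/1 -> 2,
#' ./. -> NA (phased separators accepted).  The position file is BED-like
#' (chrom, start, end, feature_id); BED 0-based half-open coordinates are
#' converted to 1-based inclusive on read.
#'
#' @param path matrix TSV or VCF file.
#' @param data_type one of the four data types.
#' @param pos_path optional BED file of feature positions (ignored for VCF,
#'   which carries its own positions).
#' @return A validated [profile_matrix()].
#' @export
read_profile_matrix <- function(path, data_type, pos_path = NULL) {
  data_type <- match.arg(data_type, DATA_TYPES)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (data_type != "genotype")
      stop("VCF input is only supported for genotype data")
    return(read_genotype_vcf(path))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fid <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!matrix(grepl("^\\s*(NA|[-+0-9.eE]*)\\s*$", m), nrow(m)),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric cell at feature '%s', profile '%s'",
                   fid[bad[1, 1]], colnames(m)[bad[1, 2]]))
    m <- matrix(as.numeric(m), nrow(m), dimnames = dimnames(m))
  }
  storage.mode(m) <- "double"
  rownames(m) <- fid
  pos <- if (!is.null(pos_path)) read_positions_bed(pos_path) else NULL
  profile_matrix(m, data_type, pos)
}

#' Read feature positions from a BED-like file
#'
#' Columns: chrom, start, end, feature_id (no header).  BED 0-based
#' half-open intervals become 1-based inclusive.
#'
#' @param path BED file.
#' @return data frame with `feature_id`, `chrom`, `start`, `end`.
#' @export
read_positions_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED position file needs >= 4 columns")
  data.frame(feature_id = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
             start = as.integer(bed[[2]]) + 1L, end = as.integer(bed[[3]]),
             stringsAsFactors = FALSE)
}

#' Read genotypes from a VCF file
#'
#' @param path VCF v4.x file; GT is the only field used.
#' @return A genotype [profile_matrix()].
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g %in% "0/0"] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% "1/1"] <- 2
    out
  }
  m <- matrix(code(gt), nrow(gt), dimnames = dimnames(gt))
  ids <- vcfR::getID(v)
  if (anyNA(ids) || anyDuplicated(ids))
    ids <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
  rownames(m) <- ids
  pos <- data.frame(feature_id = ids, chrom = vcfR::getCHROM(v),
                    start = vcfR::getPOS(v), end = vcfR::getPOS(v),
                    stringsAsFactors = FALSE)
  profile_matrix(m, "genotype", pos)
}

#' Write a profile matrix (and optionally its positions) to disk
#'
#' Values are written at full precision (15 significant digits) so a
#' write/read round trip reproduces reals to printed precision and genotypes
#' bit-exactly.
#'
#' @param pm a `ProfileMatrix`.
#' @param path output TSV path.
#' @param pos_path optional output BED path (1-based inclusive converted
#'   back to BED convention).
#' @export
write_profile_matrix <- function(pm, path, pos_path = NULL) {
  df <- data.frame(feature_id = rownames(pm$values),
                   format(pm$values, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(pm$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pos_path)) {
    p <- pm$positions
    write.table(data.frame(p$chrom, p$start - 1L, p$end, p$feature_id),
                pos_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

msg <- function(fmt, ...) message(sprintf(fmt, ...))
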