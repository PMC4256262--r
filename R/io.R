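## Table readers/writers for the pipeline's on-disk formats.
## All coordinates are 1-based inclusive internally; BED export converts
## to 0-based half-open.

.table_schemas <- list(
  pileup     = c("chrom", "pos", "strand", "sample_id",
                 "c_count", "t_count", "other_count"),
  variant    = c("chrom", "pos", "bn_allele", "shr_allele", "kind"),
  genotype   = NULL,  # strain x marker matrix; validated separately
  phenotype  = c("strain", "trait", "replicate", "value"),
  marker_map = c("marker", "chrom", "pos"),
  truth      = c("chrom", "pos", "strand", "theta_bn", "theta_shr",
                 "is_dm", "is_imprinted", "controlling_marker")
)

#' Read a typed pipeline table
#'
#' Reads one of the tab-separated formats used throughout the pipeline
#' and validates it against its schema.  Malformed rows raise an error
#' (they are never silently dropped) and positions are interpreted as
#' 1-based.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param kind One of `"pileup"`, `"variant"`, `"genotype"`,
#'   `"phenotype"`, `"marker_map"`, `"truth"`.  The genotype matrix has
#'   recombinant inbred strains as rows (first column `strain`) and
#'   markers as columns, with entries in `B`, `S` or `NA`.
#' @return A `data.frame` of validated records; for `kind = "genotype"`
#'   a character matrix with strain row names and marker column names.
#' @export
read_tables <- function(path, kind = c("pileup", "variant", "genotype",
                                       "phenotype", "marker_map", "truth")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA", colClasses = "character")
  if (kind == "genotype") {
    if (ncol(df) < 2L || names(df)[1] != "strain")
      stop("genotype matrix must have a leading 'strain' column")
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$strain
    bad <- which(!(mat %in% c("B", "S") | is.na(mat)))
    if (length(bad)) {
      ij <- arrayInd(bad[1], dim(mat))
      stop(sprintf(
        "invalid genotype '%s' for strain '%s', marker '%s' (alphabet B/S/NA)",
        mat[bad[1]], rownames(mat)[ij[1]], colnames(mat)[ij[2]]))
    }
    return(mat)
  }
  schema <- .table_schemas[[kind]]
  if (!identical(names(df), schema))
    stop(sprintf("schema mismatch for kind '%s': expected columns %s, got %s",
                 kind, paste(schema, collapse = ","),
                 paste(names(df), collapse = ",")))
  df <- switch(kind,
    pileup     = .validate_pileup(df),
    variant    = .validate_variant(df),
    phenotype  = .validate_phenotype(df),
    marker_map = .validate_marker_map(df),
    truth      = .validate_truth(df))
  df
}

.as_int <- function(x, what) {
  suppressWarnings(v <- as.numeric(x))
  if (anyNA(v) || any(v != floor(v)))
    stop("non-integer value in column '", what, "'")
  as.integer(v)
}

.as_num <- function(x, what) {
  suppressWarnings(v <- as.numeric(x))
  if (anyNA(v) && !all(is.na(x) == is.na(v)))
    stop("non-numeric value in column '", what, "'")
  v
}

.validate_pileup <- function(df) {
  df$pos <- .as_int(df$pos, "pos")
  for (cc in c("c_count", "t_count", "other_count"))
    df[[cc]] <- .as_int(df[[cc]], cc)
  if (any(df$pos < 1L)) stop("pileup positions must be >= 1")
  if (any(df$c_count < 0L | df$t_count < 0L | df$other_count < 0L))
    stop("pileup counts must be non-negative")
  if (!all(df$strand %in% c("+", "-")))
    stop("pileup strand must be '+' or '-'")
  key <- paste(df$chrom, df$pos, df$strand, df$sample_id)
  if (anyDuplicated(key))
    stop("duplicate (site, sample) key in pileup: ", key[duplicated(key)][1])
  df
}

.validate_variant <- function(df) {
  df$pos <- .as_int(df$pos, "pos")
  if (any(df$pos < 1L)) stop("variant positions must be >= 1")
  if (!all(df$kind %in% c("snp", "indel")))
    stop("variant kind must be 'snp' or 'indel'")
  same <- df$bn_allele == df$shr_allele
  if (any(same))
    stop("variant with identical BN and SHR alleles at ",
         df$chrom[same][1], ":", df$pos[same][1])
  snp <- df$kind == "snp"
  if (any(nchar(df$bn_allele[snp]) != 1L | nchar(df$shr_allele[snp]) != 1L))
    stop("snp alleles must be single bases")
  df
}

.validate_phenotype <- function(df) {
  df$replicate <- .as_int(df$replicate, "replicate")
  df$value <- .as_num(df$value, "value")
  df
}

.validate_marker_map <- function(df) {
  df$pos <- .as_int(df$pos, "pos")
  if (anyDuplicated(df$marker)) stop("duplicate marker name in map")
  df
}

.validate_truth <- function(df) {
  df$pos <- .as_int(df$pos, "pos")
  df$theta_bn <- .as_num(df$theta_bn, "theta_bn")
  df$theta_shr <- .as_num(df$theta_shr, "theta_shr")
  df$is_dm <- as.logical(df$is_dm)
  df$is_imprinted <- as.logical(df$is_imprinted)
  df
}

#' Write a typed pipeline table
#'
#' Inverse of [read_tables()]: `read_tables(write_tables(x, p, k), k)`
#' reproduces `x` bit-exactly for integer columns and at fixed decimal
#' precision for floating-point columns.
#'
#' @param records A validated table (or genotype matrix).
#' @param path Output path.
#' @param kind Table kind, as in [read_tables()].
#' @return `path`, invisibly.
#' @export
write_tables <- function(records, path,
                         kind = c("pileup", "variant", "genotype",
                                  "phenotype", "marker_map", "truth")) {
  kind <- match.arg(kind)
  if (kind == "genotype") {
    df <- data.frame(strain = rownames(records), records,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(path))
  }
  schema <- .table_schemas[[kind]]
  if (!identical(names(records), schema))
    stop("records do not match schema for kind '", kind, "'")
  out <- records
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 6,
                                                   format = "f"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write regions as BED with extra columns
#'
#' Converts 1-based inclusive region coordinates to BED's 0-based
#' half-open convention (`start - 1`, `end`).
#'
#' @param regions Data frame with at least `chrom`, `start`, `end`
#'   (1-based inclusive); any further columns are appended after the
#'   name field.
#' @param path Output path.
#' @param names Optional character vector of region names (column 4).
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path, names = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (is.null(names)) names <- rep(".", nrow(regions))
  extra <- setdiff(names(regions), c("chrom", "start", "end"))
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = names,
                    stringsAsFactors = FALSE)
  if (length(extra)) bed <- cbind(bed, regions[, extra, drop = FALSE])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
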