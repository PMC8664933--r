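#' Segment tables: ROH and IBD intervals
#'
#' The lingua franca between the caller, footprint and score modules.
#' Each row is one segment: an ROH (one carrier, `carrier_b` empty) or an
#' IBD segment (two distinct carriers). Physical coordinates are half-open
#' `[start_bp, end_bp)`; genetic length is `end_cM - start_cM`.
#'
#' @param carrier_a,carrier_b sample identifiers; `carrier_b` is `NA` or
#'   `""` for ROH rows.
#' @param chrom chromosome labels.
#' @param start_bp,end_bp physical coordinates (bp, half-open).
#' @param start_cM,end_cM genetic coordinates (cM).
#' @return a data.frame of class `segment_table` with a `length_cM` column.
#' @export
segment_table <- function(carrier_a = character(), carrier_b = NA_character_,
                          chrom = character(), start_bp = integer(),
                          end_bp = integer(), start_cM = numeric(),
                          end_cM = numeric()) {
  n <- length(carrier_a)
  d <- data.frame(
    carrier_a = as.character(carrier_a),
    carrier_b = if (n) as.character(rep_len(carrier_b, n)) else character(),
    chrom = if (n) as.character(rep_len(chrom, n)) else character(),
    start_bp = as.numeric(start_bp), end_bp = as.numeric(end_bp),
    start_cM = as.numeric(start_cM), end_cM = as.numeric(end_cM),
    stringsAsFactors = FALSE
  )
  d$carrier_b[!is.na(d$carrier_b) & d$carrier_b == ""] <- NA_character_
  d$length_cM <- d$end_cM - d$start_cM
  validate_segment_table(d)
  class(d) <- c("segment_table", "data.frame")
  d
}

#' Validate segment-table invariants
#'
#' Checks that end > start in both coordinate systems, that ROH rows have
#' exactly one carrier and IBD rows two distinct carriers, and that
#' `length_cM` is consistent. Errors name the first offending row.
#'
#' @param d a segment table (data.frame).
#' @return `d`, invisibly.
#' @export
validate_segment_table <- function(d) {
  req <- c("carrier_a", "carrier_b", "chrom", "start_bp", "end_bp",
           "start_cM", "end_cM")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("segment table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(d$end_bp <= d$start_bp)
  if (length(bad)) stop("end_bp <= start_bp at row ", bad[1])
  bad <- which(d$end_cM < d$start_cM)
  if (length(bad)) stop("end_cM < start_cM at row ", bad[1])
  bad <- which(!is.na(d$carrier_b) & d$carrier_b == d$carrier_a)
  if (length(bad)) stop("IBD row with identical carriers at row ", bad[1])
  if (!is.null(d$length_cM)) {
    bad <- which(abs(d$length_cM - (d$end_cM - d$start_cM)) > 1e-6)
    if (length(bad)) stop("length_cM inconsistent at row ", bad[1])
  }
  invisible(d)
}

#' Is a row an ROH (single-carrier) segment?
#' @param d a segment table.
#' @return logical vector.
#' @export
is_roh <- function(d) is.na(d$carrier_b)

#' Read/write tab-delimited segment tables
#'
#' Tab-delimited with header; bp written as integers, cM with six decimals.
#' Reading validates every invariant and reports offending row numbers.
#'
#' @param path file path.
#' @return [read_segment_table()]: a `segment_table`.
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(carrier_a = "character",
                                        carrier_b = "character",
                                        chrom = "character"))
  segment_table(d$carrier_a, d$carrier_b, d$chrom, d$start_bp, d$end_bp,
                d$start_cM, d$end_cM)
}

#' @rdname read_segment_table
#' @param d a `segment_table`.
#' @export
write_segment_table <- function(d, path) {
  validate_segment_table(d)
  out <- data.frame(
    carrier_a = d$carrier_a,
    carrier_b = ifelse(is.na(d$carrier_b), "", d$carrier_b),
    chrom = d$chrom,
    start_bp = sprintf("%d", as.integer(round(d$start_bp))),
    end_bp = sprintf("%d", as.integer(round(d$end_bp))),
    start_cM = sprintf("%.6f", d$start_cM),
    end_cM = sprintf("%.6f", d$end_cM),
    length_cM = sprintf("%.6f", d$end_cM - d$start_cM),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
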