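#' Read a per-sample window coverage table
#'
#' The coverage table is the entry point of the phasing pipeline: one row per
#' window per sample with total nucleotide coverage and the nucleotide
#' coverage of reads containing CAST or S129 SNPs. Columns: `chrom`, `start`,
#' `stop`, `sample`, `total_cov`, `cast_cov`, `s129_cov`.
#'
#' @param path TSV file path.
#' @return a validated `data.table`.
#' @export
read_coverage_table <- function(path) {
  ct <- fread(path, sep = "\t")
  validate_coverage_table(ct)
}

#' @rdname read_coverage_table
#' @param ct coverage table.
#' @export
write_coverage_table <- function(ct, path) {
  fwrite(ct, path, sep = "\t")
  invisible(path)
}

validate_coverage_table <- function(ct) {
  need <- c("chrom", "start", "stop", "sample", "total_cov", "cast_cov",
            "s129_cov")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop_config("coverage table is missing columns: %s",
                paste(miss, collapse = ", "))
  if (nrow(ct) == 0L) stop_config("coverage table is empty")
  if (any(ct$total_cov < 0 | ct$cast_cov < 0 | ct$s129_cov < 0))
    stop_config("coverage values must be non-negative")
  if (any(ct$cast_cov + ct$s129_cov > ct$total_cov))
    stop_config("phased coverage exceeds total coverage (data integrity)")
  as.data.table(ct)
}

#' Write a segregation table as TSV
#'
#' Format: `chrom`, `start`, `stop`, then one 0/1 column per sample.
#'
#' @param seg a `gam_segregation` object (see [build_segregation_tables()]).
#' @param path output file.
#' @export
write_segregation_table <- function(seg, path) {
  stopifnot(inherits(seg, "gam_segregation"))
  out <- cbind(as.data.table(seg$windows),
               as.data.table(seg$mat * 1L))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_segregation_table
#' @param phase phase label to attach (`"unphased"`, `"cast"`, `"s129"`).
#' @export
read_segregation_table <- function(path, phase = "unphased") {
  dt <- fread(path, sep = "\t")
  windows <- dt[, .(chrom, start, stop)]
  mat <- as.matrix(dt[, -(1:3)]) > 0
  new_segregation(windows, mat, phase)
}

#' Write a per-window scalar track as bedGraph
#'
#' @param track data.frame with `chrom`, `start`, `stop`, `value`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  fwrite(track[, c("chrom", "start", "stop", "value")], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file
#' @param path BED file.
#' @export
read_bed <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE)
  setnames(dt, seq_len(min(6L, ncol(dt))),
           c("chrom", "start", "stop", "name", "score", "strand")[
             seq_len(min(6L, ncol(dt)))])
  dt[]
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numbers where possible, otherwise kept as strings. Comma-separated
#' values become vectors.
#'
#' @param path config file.
#' @return named list.
#' @export
read_keyvalue_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop_config("cannot parse config line: '%s'", ln)
    vals <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[m[2]]] <- if (!anyNA(num)) num else vals
  }
  out
}
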