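#' Build a fixed-size genomic window grid
#'
#' Partitions each chromosome into consecutive windows of `window_size` bp
#' using 0-based, half-open (BED) coordinates. The terminal window of a
#' chromosome is truncated to the chromosome end.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param window_size window size in bp (> 0).
#' @return a `data.table` with columns `chrom`, `start`, `stop`.
#' @export
gam_windows <- function(chrom_sizes, window_size) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop_config("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0) || window_size <= 0)
    stop_config("chromosome lengths and window size must be positive")
  out <- rbindlist(lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = window_size)
    data.table(chrom = ch, start = starts,
               stop = pmin(starts + window_size, len))
  }))
  out[]
}

# Check two window grids are identical (chrom/start/stop).
same_grid <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
    all(a$start == b$start) && all(a$stop == b$stop)
}

assert_same_grid <- function(a, b, what = "window grids") {
  if (!same_grid(a, b)) stop_config("%s do not match", what)
}

# For a logical/numeric vector ordered along the grid, TRUE where the window
# has at least one positive neighbour at index +/- 1 on the same chromosome.
has_positive_neighbor <- function(positive, chrom) {
  n <- length(positive)
  left <- c(FALSE, positive[-n]) & c(FALSE, chrom[-n] == chrom[-1])
  right <- c(positive[-1], FALSE) & c(chrom[-n] == chrom[-1], FALSE)
  left | right
}
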