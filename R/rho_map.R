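#' Construct a piecewise-constant scaled recombination map
#'
#' A `rho_map` stores the population-scaled recombination rate
#' \eqn{\rho = 4 N_e r} per base pair between adjacent SNPs of one
#' chromosome, as produced by LD-based estimators. Positions are physical
#' coordinates (bp, 1-based) and rate `i` applies on the half-open physical
#' interval `[positions[i], positions[i+1])`.
#'
#' @param chrom Chromosome label (length-1 character).
#' @param positions Strictly increasing integer-valued physical positions
#'   (bp, 1-based); at least two.
#' @param rates Non-negative rates (\eqn{\rho}/bp), one per interval between
#'   adjacent positions, so `length(rates) == length(positions) - 1`.
#' @param provenance Optional named list of metadata (estimator, block
#'   penalty, window scheme, gap repairs...). Stored verbatim.
#'
#' @return An object of class `rho_map`: a list with elements `chrom`,
#'   `positions`, `rates`, `provenance`.
#' @examples
#' m <- rho_map("chr1", c(100, 200, 500), c(0.01, 0.002))
#' weighted_mean_rho(m)
#' @export
rho_map <- function(chrom, positions, rates, provenance = list()) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  positions <- as.numeric(positions)
  rates <- as.numeric(rates)
  if (length(positions) < 2L)
    stop("a rho_map needs at least 2 positions", call. = FALSE)
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  if (length(rates) != length(positions) - 1L)
    stop("length(rates) must equal length(positions) - 1", call. = FALSE)
  if (anyNA(rates) || any(rates < 0))
    stop("rates must be non-negative and non-missing", call. = FALSE)
  structure(
    list(chrom = chrom, positions = positions, rates = rates,
         provenance = provenance),
    class = "rho_map"
  )
}

#' @export
print.rho_map <- function(x, ...) {
  cat(sprintf(
    "<rho_map> %s: %d SNP positions spanning %s-%s bp\n",
    x$chrom, length(x$positions),
    format(x$positions[1], big.mark = ","),
    format(x$positions[length(x$positions)], big.mark = ",")))
  cat(sprintf("  mean rate (bp-weighted): %.4g rho/bp\n", weighted_mean_rho(x)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

map_span <- function(map) c(map$positions[1], map$positions[length(map$positions)])

#' Read a per-SNP recombination rate table
#'
#' Parses the whitespace-delimited text emitted by LDhat/LDhelmet-style
#' estimators: one row per adjacent-SNP pair with columns
#' `left_pos right_pos rate` (any further columns, e.g. posterior
#' quantiles, are ignored). Lines starting with `#` or `%` are comments.
#' Rows must be contiguous: the right position of one row is the left
#' position of the next.
#'
#' @param source Path to a file, or a connection.
#' @param chrom Chromosome label to attach; default `"chr"`.
#' @param rate_unit `"per_bp"` (LDhelmet convention) or `"per_kbp"`
#'   (LDhat convention; rates are divided by 1000 on read). Never guessed
#'   from the data: silent unit errors are the dominant failure mode for
#'   these files.
#' @param gap_tolerant If `TRUE`, a gap between consecutive rows is bridged
#'   with a zero-rate interval and recorded under
#'   `provenance$gap_bridges`; if `FALSE` (default) a gap is an error.
#'
#' @return A [rho_map].
#' @export
read_rho_map <- function(source, chrom = "chr",
                         rate_unit = c("per_bp", "per_kbp"),
                         gap_tolerant = FALSE) {
  rate_unit <- match.arg(rate_unit)
  lines <- readLines(source)
  lines <- lines[!grepl("^\\s*($|#|%)", lines)]
  if (!length(lines)) stop("no data rows in rate table", call. = FALSE)
  tab <- utils::read.table(text = lines, header = FALSE,
                           colClasses = "numeric")
  if (ncol(tab) < 3L)
    stop("rate table needs at least 3 columns (left, right, rate)",
         call. = FALSE)
  left <- tab[[1]]; right <- tab[[2]]; rate <- tab[[3]]
  if (any(right <= left)) {
    bad <- which(right <= left)[1]
    stop(sprintf("non-monotone positions at data row %d", bad), call. = FALSE)
  }
  if (any(rate < 0)) {
    bad <- which(rate < 0)[1]
    stop(sprintf("negative rate at data row %d", bad), call. = FALSE)
  }
  if (rate_unit == "per_kbp") rate <- rate / 1000
  positions <- left[1]
  rates <- numeric(0)
  bridges <- numeric(0)
  n <- length(left)
  if (n > 1L) {
    step <- left[-1] - right[-n]
    if (any(step < 0)) {
      bad <- which(step < 0)[1] + 1L
      stop(sprintf("overlapping/non-monotone rows at data row %d", bad),
           call. = FALSE)
    }
    if (any(step > 0) && !gap_tolerant) {
      bad <- which(step > 0)[1] + 1L
      stop(sprintf(
        "gap before data row %d (right=%s, next left=%s); set gap_tolerant = TRUE to bridge with rate 0",
        bad, format(right[bad - 1L]), format(left[bad])), call. = FALSE)
    }
  }
  for (i in seq_len(n)) {
    if (i > 1L && left[i] > right[i - 1L]) {
      # bridge the gap with a zero-rate interval, flagged in provenance
      positions <- c(positions, left[i])
      rates <- c(rates, 0)
      bridges <- c(bridges, right[i - 1L])
    }
    positions <- c(positions, right[i])
    rates <- c(rates, rate[i])
  }
  prov <- list(rate_unit = rate_unit)
  if (length(bridges)) prov$gap_bridges <- bridges
  rho_map(chrom, positions, rates, provenance = prov)
}

#' Write a recombination map as a per-SNP rate table
#'
#' Emits `left_pos right_pos rate` rows (tab-separated, rate per bp, full
#' double precision) with a single `#` header line, the format read back by
#' [read_rho_map()]. Round-trips exactly on positions and rates.
#'
#' @param map A [rho_map].
#' @param sink Path or connection to write to.
#' @return Invisibly, the number of data rows written.
#' @export
write_rho_map <- function(map, sink) {
  stopifnot(inherits(map, "rho_map"))
  n <- length(map$rates)
  rows <- sprintf("%s\t%s\t%s",
                  format(map$positions[-(n + 1L)], scientific = FALSE, trim = TRUE),
                  format(map$positions[-1L], scientific = FALSE, trim = TRUE),
                  formatC(map$rates, format = "g", digits = 17))
  writeLines(c("# left_pos\tright_pos\trate_per_bp", rows), sink)
  invisible(n)
}

#' Stitch overlapping estimation windows into one chromosome map
#'
#' LD-based estimators are typically run on windows of a few thousand SNPs
#' that overlap by a fixed SNP count (e.g. 4400-SNP windows overlapping by
#' 200 SNPs); the overlapping copies must be removed before the windows are
#' concatenated into a chromosome-scale map. Within each overlap the region
#' is split at its midpoint: the earlier window supplies the rates for the
#' left half of the shared intervals and the later window the right half —
#' a symmetric, deterministic tie-break.
#'
#' @param window_maps List of [rho_map]s in chromosomal order, consecutive
#'   maps sharing exactly `overlap_snps` positions (the trailing positions
#'   of one are the leading positions of the next, and identical).
#' @param overlap_snps Number of shared SNP positions between consecutive
#'   windows (>= 1).
#' @return A single [rho_map] with `sum(window SNPs) - overlaps` positions.
#' @export
stitch_windows <- function(window_maps, overlap_snps) {
  stopifnot(is.list(window_maps), length(window_maps) >= 1L,
            overlap_snps >= 1L)
  for (m in window_maps) stopifnot(inherits(m, "rho_map"))
  if (length(window_maps) == 1L) return(window_maps[[1]])
  k <- as.integer(overlap_snps)
  out_pos <- window_maps[[1]]$positions
  out_rate <- window_maps[[1]]$rates
  for (w in 2:length(window_maps)) {
    nxt <- window_maps[[w]]
    np <- length(out_pos)
    if (length(nxt$positions) < k || np < k)
      stop("window shorter than the stated overlap", call. = FALSE)
    shared_prev <- out_pos[(np - k + 1L):np]
    shared_next <- nxt$positions[1:k]
    if (!isTRUE(all.equal(shared_prev, shared_next))) {
      bad <- which(shared_prev != shared_next)[1]
      stop(sprintf("overlap position mismatch between windows %d and %d at shared position %d (%s vs %s)",
                   w - 1L, w, bad, format(shared_prev[bad]),
                   format(shared_next[bad])), call. = FALSE)
    }
    # k shared positions bound k-1 shared intervals; earlier window keeps
    # the left ceil((k-1)/2) of them
    n_shared_int <- k - 1L
    keep_prev <- as.integer(ceiling(n_shared_int / 2))
    nr <- length(out_rate)
    if (n_shared_int > keep_prev)
      out_rate[(nr - n_shared_int + keep_prev + 1L):nr] <-
        nxt$rates[(keep_prev + 1L):n_shared_int]
    out_pos <- c(out_pos, nxt$positions[-(1:k)])
    out_rate <- c(out_rate, nxt$rates[-seq_len(n_shared_int)])
  }
  prov <- window_maps[[1]]$provenance
  prov$stitched_windows <- length(window_maps)
  prov$overlap_snps <- k
  rho_map(window_maps[[1]]$chrom, out_pos, out_rate, provenance = prov)
}
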