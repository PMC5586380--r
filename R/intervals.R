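#' Construct a genomic interval set
#'
#' Intervals use BED semantics: 0-based, half-open `[start, end)`. Records
#' are stored sorted by `(chrom, start, end)`; any extra columns in `x` are
#' carried through untouched.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` (and
#'   optionally more).
#' @param chrom_lengths Optional named numeric vector of chromosome lengths
#'   (bp); when supplied, intervals must fit inside their chromosome.
#' @return A tibble of class `interval_set`, sorted, with the lengths (if
#'   any) in `attr(, "chrom_lengths")`.
#' @export
interval_set <- function(x, chrom_lengths = NULL) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start < 0) || any(x$start >= x$end))
    stop("intervals must satisfy 0 <= start < end", call. = FALSE)
  if (!is.null(chrom_lengths)) {
    stopifnot(!is.null(names(chrom_lengths)))
    unknown <- setdiff(unique(x$chrom), names(chrom_lengths))
    if (length(unknown))
      stop("no length given for chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(x$end > chrom_lengths[x$chrom]))
      stop("interval end exceeds chromosome length", call. = FALSE)
  }
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  structure(x, class = c("interval_set", class(x)),
            chrom_lengths = chrom_lengths)
}

#' Read a BED3+ file
#'
#' Minimum three columns (chrom, start, end; 0-based half-open); any extra
#' columns are preserved opaquely as `V4`, `V5`, ... Track/browser/comment
#' lines are skipped. Records are returned sorted.
#'
#' @param source Path or connection.
#' @inheritParams interval_set
#' @return An [interval_set].
#' @export
read_bed <- function(source, chrom_lengths = NULL) {
  lines <- readLines(source)
  lines <- lines[!grepl("^\\s*($|#|track\\b|browser\\b)", lines)]
  if (!length(lines)) stop("no records in BED input", call. = FALSE)
  tab <- utils::read.table(text = lines, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED needs >= 3 columns", call. = FALSE)
  names(tab)[1:3] <- c("chrom", "start", "end")
  bad <- which(tab$start >= tab$end)
  if (length(bad))
    stop(sprintf("empty or inverted interval at line %d", bad[1]),
         call. = FALSE)
  interval_set(tab, chrom_lengths = chrom_lengths)
}

#' Write an interval set as BED
#'
#' @param x An [interval_set] (or data frame with chrom/start/end).
#' @param sink Path or connection.
#' @return Invisibly, the number of records written.
#' @export
write_bed <- function(x, sink) {
  df <- as.data.frame(x)
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, sink, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}

# IRanges view of one chromosome's records (1-based closed, so start+1)
.iranges_of <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Count intervals of one set overlapped by another
#'
#' Returns the number of intervals in `b` that overlap (share at least one
#' base with) any interval in `a`. Coordinates are half-open, so abutting
#' intervals do not overlap. This "b-side" count answers questions of the
#' form "how many DSB hotspots are hit by at least one putative hotspot";
#' `symmetric = TRUE` additionally returns the a-side count.
#'
#' @param a,b [interval_set]s on a shared chromosome namespace.
#' @param symmetric If `TRUE`, return `c(b_in_a =, a_in_b =)`.
#' @return Integer count (or named length-2 vector).
#' @export
count_overlaps <- function(a, b, symmetric = FALSE) {
  one_side <- function(a, b) {
    tot <- 0L
    for (ch in unique(b$chrom)) {
      bi <- b[b$chrom == ch, , drop = FALSE]
      ai <- a[a$chrom == ch, , drop = FALSE]
      if (!nrow(ai)) next
      tot <- tot + sum(IRanges::countOverlaps(.iranges_of(bi),
                                              .iranges_of(ai)) > 0L)
    }
    tot
  }
  if (symmetric)
    c(b_in_a = one_side(a, b), a_in_b = one_side(b, a))
  else
    one_side(a, b)
}

#' Randomization test of interval overlap
#'
#' Null distribution for the number of `target` intervals overlapped by the
#' `query` set. In each replicate every query interval is re-placed
#' uniformly at random on its own chromosome (start drawn from
#' `0 ... L - length`, length preserved, placements independent; overlaps
#' among placed intervals are permitted), and the overlap count against the
#' fixed `target` set is recorded. The maximum count across replicates is
#' returned as an approximate `1/replicates` significance threshold, the
#' convention used when 1000 replicates stand in for a 0.1% test.
#'
#' @param query,target [interval_set]s.
#' @param chrom_lengths Named numeric vector of chromosome lengths covering
#'   every chromosome carrying query intervals (falls back to
#'   `attr(query, "chrom_lengths")`).
#' @param replicates Number of randomizations (default 1000).
#' @param seed Optional integer seed; when given the run is reproducible
#'   and the global RNG state is left untouched.
#' @param permute_chrom If `TRUE`, query intervals are also reassigned to a
#'   random chromosome (probability proportional to chromosome length)
#'   before placement. Default `FALSE`: randomization is within-chromosome.
#' @return A list with `observed`, `null_counts` (length `replicates`),
#'   `threshold` (= max null count), `p_value` (fraction of null counts
#'   >= observed, with the +1 continuity correction), and `seed`.
#' @export
randomized_overlap_null <- function(query, target, chrom_lengths = NULL,
                                    replicates = 1000, seed = NULL,
                                    permute_chrom = FALSE) {
  if (is.null(chrom_lengths)) chrom_lengths <- attr(query, "chrom_lengths")
  if (is.null(chrom_lengths))
    stop("chromosome lengths are required for randomization", call. = FALSE)
  missing_len <- setdiff(unique(query$chrom), names(chrom_lengths))
  if (length(missing_len))
    stop("no length for chromosome(s): ",
         paste(missing_len, collapse = ", "), call. = FALSE)
  len <- query$end - query$start
  if (any(len > chrom_lengths[query$chrom]))
    stop("query interval longer than its chromosome", call. = FALSE)
  observed <- count_overlaps(query, target)
  run <- function() {
    null_counts <- integer(replicates)
    for (r in seq_len(replicates)) {
      ch <- query$chrom
      if (permute_chrom) {
        ch <- sample(names(chrom_lengths), length(len), replace = TRUE,
                     prob = chrom_lengths)
        # keep drawing for intervals that do not fit their chromosome
        while (any(bad <- len > chrom_lengths[ch]))
          ch[bad] <- sample(names(chrom_lengths), sum(bad), replace = TRUE,
                            prob = chrom_lengths)
      }
      lmax <- chrom_lengths[ch] - len
      start <- floor(stats::runif(length(len)) * (lmax + 1))
      start <- pmin(start, lmax)  # guard the runif(1)==1 edge
      placed <- interval_set(
        tibble::tibble(chrom = ch, start = start, end = start + len))
      null_counts[r] <- count_overlaps(placed, target)
    }
    null_counts
  }
  null_counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(observed = observed,
       null_counts = null_counts,
       threshold = max(null_counts),
       p_value = (sum(null_counts >= observed) + 1) / (replicates + 1),
       seed = seed)
}
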