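#' Call recombination hotspots from a fine-scale map
#'
#' Operational hotspot definition: tile the chromosome into nonoverlapping
#' analysis windows of `window` bp (anchored at coordinate 0); flag every
#' window whose frequency-weighted mean rate is at least `ratio` times the
#' rate in the surrounding `flank_total` bp (half on each side, the focal
#' window itself excluded, truncated at the ends of the map or chromosome);
#' then merge runs of adjacent flagged windows into single intervals, since
#' real hotspots can exceed one analysis window. The threshold is
#' inclusive: a window at exactly `ratio` times its background is called.
#'
#' Windows whose flanking background has zero rate but positive focal rate
#' are flagged and annotated `"zero-background"`; windows with zero focal
#' and zero background are not called. Windows with less than
#' `min_flank_coverage` of their flank spanned by map intervals are skipped
#' (background unmeasurable), as are windows with no map coverage.
#'
#' @param map A [rho_map], typically from a low-smoothing-penalty
#'   (fine-scale) estimator run.
#' @param window Analysis window size in bp (default 2000).
#' @param flank_total Total flanking background span in bp (default 80000,
#'   i.e. 40 kb each side).
#' @param ratio Focal/background threshold multiplier (default 5).
#' @param min_flank_coverage Minimum fraction of the (truncated) flank that
#'   must be covered by map intervals (default 0.5).
#' @param chrom_length Optional chromosome length (bp) used to truncate
#'   flanks; defaults to the map span.
#' @return An [interval_set] of merged hotspot intervals with columns
#'   `score` (maximum focal/background ratio among merged windows;
#'   `Inf` for zero-background calls) and `note` (`""` or
#'   `"zero-background"`).
#' @export
call_hotspots <- function(map, window = 2000, flank_total = 80000,
                          ratio = 5, min_flank_coverage = 0.5,
                          chrom_length = NULL) {
  stopifnot(inherits(map, "rho_map"), window > 0, flank_total > window,
            ratio > 1)
  span <- map_span(map)
  if (diff(span) < flank_total)
    stop("map span is shorter than the flanking background span",
         call. = FALSE)
  lo <- if (is.null(chrom_length)) span[1] else 0
  hi <- if (is.null(chrom_length)) span[2] else chrom_length
  left <- map$positions[-length(map$positions)]
  right <- map$positions[-1]
  wmean <- function(a, b) {
    # weighted mean over [a,b); NA when uncovered; second element = coverage bp
    ca <- pmax(left, a); cb <- pmin(right, b)
    d <- pmax(cb - ca, 0)
    s <- sum(d)
    c(if (s > 0) sum(map$rates * d) / s else NA_real_, s)
  }
  half <- flank_total / 2
  starts <- seq(floor(span[1] / window) * window, span[2] - 1, by = window)
  flagged <- logical(length(starts))
  score <- rep(NA_real_, length(starts))
  zerobg <- logical(length(starts))
  for (i in seq_along(starts)) {
    ws <- starts[i]; we <- ws + window
    foc <- wmean(ws, we)
    if (is.na(foc[1])) next
    fl_lo <- max(ws - half, lo); fl_hi <- min(we + half, hi)
    l <- wmean(fl_lo, ws); r <- wmean(we, fl_hi)
    flank_bp <- (ws - fl_lo) + (fl_hi - we)
    covered <- l[2] + r[2]
    if (flank_bp <= 0 || covered / flank_bp < min_flank_coverage) next
    bg <- sum(c(l[1] * l[2], r[1] * r[2]), na.rm = TRUE) / covered
    if (bg == 0) {
      if (foc[1] > 0) { flagged[i] <- TRUE; zerobg[i] <- TRUE; score[i] <- Inf }
    } else if (foc[1] >= ratio * bg) {
      flagged[i] <- TRUE
      score[i] <- foc[1] / bg
    }
  }
  idx <- which(flagged)
  if (!length(idx))
    return(interval_set(tibble::tibble(chrom = character(), start = numeric(),
                                       end = numeric(), score = numeric(),
                                       note = character())))
  run <- cumsum(c(1L, diff(idx) != 1L))
  recs <- lapply(split(idx, run), function(ii) {
    tibble::tibble(chrom = map$chrom,
                   start = starts[ii[1]],
                   end = starts[ii[length(ii)]] + window,
                   score = max(score[ii]),
                   note = if (any(zerobg[ii])) "zero-background" else "")
  })
  interval_set(do.call(rbind, recs))
}
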