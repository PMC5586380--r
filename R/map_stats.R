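#' Frequency-weighted mean recombination rate
#'
#' Mean of the per-interval rates weighted by the physical distance (bp)
#' separating the adjacent SNPs bounding each interval:
#' \eqn{\bar\rho = \sum_i \rho_i d_i / \sum_i d_i}, with intervals clipped
#' to `region` when one is given. Weighting by inter-SNP distance is the
#' standard way to summarize per-SNP-pair estimator output over a region,
#' since SNP spacing is irregular.
#'
#' @param map A [rho_map].
#' @param region Optional length-2 numeric `c(start, end)` physical range
#'   (half-open, same coordinates as the map positions) to clip to.
#' @return The weighted mean rate (\eqn{\rho}/bp).
#' @export
weighted_mean_rho <- function(map, region = NULL) {
  stopifnot(inherits(map, "rho_map"))
  left <- map$positions[-length(map$positions)]
  right <- map$positions[-1]
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] < region[2])
    left <- pmax(left, region[1])
    right <- pmin(right, region[2])
  }
  d <- pmax(right - left, 0)
  if (sum(d) == 0)
    stop("region does not intersect the map span", call. = FALSE)
  sum(map$rates * d) / sum(d)
}

#' Anchor a scaled map to a known genetic map length
#'
#' Converts cumulative scaled recombination (\eqn{\rho}) into centimorgans
#' by fixing the total genetic length of the chromosome to an external
#' (e.g. pedigree-based) estimate: cumulative \eqn{\rho} at each SNP,
#' weighted by inter-SNP distance, is rescaled so the chromosome end lands
#' exactly on `total_cM`. This is how LD-based maps, which only measure
#' \eqn{4 N_e r}, are put on the cM scale of a linkage map.
#'
#' @param map A [rho_map] with positive total cumulative \eqn{\rho}.
#' @param total_cM Genetic length of the chromosome (centimorgans, > 0).
#' @return An object of class `genetic_map`: list with `chrom`,
#'   `positions`, `cM` (cumulative, `cM[1] == 0`,
#'   `cM[n] == total_cM` exactly), and `total_cM`.
#' @export
anchor_to_centimorgans <- function(map, total_cM) {
  stopifnot(inherits(map, "rho_map"), is.numeric(total_cM),
            length(total_cM) == 1L, total_cM > 0)
  d <- diff(map$positions)
  cum_rho <- c(0, cumsum(map$rates * d))
  total <- cum_rho[length(cum_rho)]
  if (total <= 0)
    stop("total cumulative rho is zero; map cannot be anchored",
         call. = FALSE)
  cM <- total_cM * cum_rho / total
  cM[length(cM)] <- total_cM  # exact by construction, guard rounding
  structure(list(chrom = map$chrom, positions = map$positions, cM = cM,
                 total_cM = total_cM),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %s: %d positions, %.3g cM over %s bp\n",
              x$chrom, length(x$positions), x$total_cM,
              format(diff(range(x$positions)), big.mark = ",")))
  invisible(x)
}

#' Express an anchored genetic map as local rates in cM/Mb
#'
#' @param gm A `genetic_map` from [anchor_to_centimorgans()].
#' @return A [rho_map] whose "rates" are local recombination rates in
#'   centimorgans per megabase.
#' @export
cm_per_mb_map <- function(gm) {
  stopifnot(inherits(gm, "genetic_map"))
  d <- diff(gm$positions)
  rho_map(gm$chrom, gm$positions, diff(gm$cM) / d * 1e6,
          provenance = list(unit = "cM/Mb", total_cM = gm$total_cM))
}

#' Windowed map summary
#'
#' Frequency-weighted mean rate in genomic windows. Windows are half-open
#' `[start, start + size)` anchored at coordinate 0 of the chromosome; the
#' final partial window is kept, flagged by its coverage. Windows whose
#' fraction of bases covered by map intervals falls below `min_coverage`
#' get `NA` values ("missing", never zero).
#'
#' @param map A [rho_map] (\eqn{\rho}/bp) or the output of
#'   [cm_per_mb_map()] (cM/Mb).
#' @param size Window size in bp (> 0).
#' @param mode `"nonoverlapping"` (step = size) or `"sliding"`
#'   (step = `offset`).
#' @param offset Step between sliding-window starts (bp); required when
#'   `mode = "sliding"`.
#' @param min_coverage Minimum fraction of a window that must be spanned by
#'   map intervals for its value to be reported (default 0.5).
#' @return A tibble (`chrom`, `window_start`, `window_end`, `value`,
#'   `coverage`), class `window_series`.
#' @export
window_series <- function(map, size, mode = c("nonoverlapping", "sliding"),
                          offset = NULL, min_coverage = 0.5) {
  stopifnot(inherits(map, "rho_map"), size > 0)
  mode <- match.arg(mode)
  step <- if (mode == "sliding") {
    if (is.null(offset) || offset <= 0)
      stop("sliding mode needs a positive offset", call. = FALSE)
    offset
  } else size
  span <- map_span(map)
  # windows anchored at 0; keep every window intersecting the map span
  first <- floor(span[1] / step) * step
  starts <- seq(first, span[2] - 1, by = step)
  starts <- starts[starts + size > span[1]]
  if (mode == "sliding")  # sliding series report fully-contained windows only
    starts <- starts[starts + size <= span[2]]
  if (!length(starts))
    stop("no window fits the map span", call. = FALSE)
  left <- map$positions[-length(map$positions)]
  right <- map$positions[-1]
  val <- cov <- numeric(length(starts))
  for (i in seq_along(starts)) {
    a <- pmax(left, starts[i]); b <- pmin(right, starts[i] + size)
    d <- pmax(b - a, 0)
    covered <- sum(d)
    cov[i] <- covered / size
    val[i] <- if (covered > 0) sum(map$rates * d) / covered else NA_real_
  }
  val[cov < min_coverage] <- NA_real_
  out <- tibble::tibble(chrom = map$chrom, window_start = starts,
                        window_end = starts + size, value = val,
                        coverage = cov)
  class(out) <- c("window_series", class(out))
  out
}

#' Correlate two aligned window series
#'
#' Series must be computed on identical window grids; windows missing
#' (`NA`) in either series are dropped pairwise.
#'
#' @param a,b `window_series` tibbles over the same windows.
#' @param method Correlation method.
#' @return List with `estimate`, `n_windows`, `method`.
#' @export
correlate_windows <- function(a, b,
                              method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  if (nrow(a) != nrow(b) ||
      !all(a$chrom == b$chrom & a$window_start == b$window_start))
    stop("window series are not aligned on identical windows", call. = FALSE)
  keep <- stats::complete.cases(a$value, b$value)
  if (sum(keep) < 3L)
    stop("fewer than 3 shared windows with data", call. = FALSE)
  list(estimate = stats::cor(a$value[keep], b$value[keep], method = method),
       n_windows = sum(keep), method = method)
}

#' Effective population size from a scaled recombination rate
#'
#' With \eqn{\rho = 4 N_e r} per bp and an independent estimate of the
#' per-generation recombination fraction \eqn{r} (from a cM/Mb rate:
#' \eqn{r = \mathrm{cM/Mb} \times 10^{-8}} per bp),
#' \eqn{N_e = \bar\rho / (4 r)}.
#'
#' @param rho_bar Frequency-weighted mean \eqn{\rho}/bp (> 0).
#' @param cm_per_mb Recombination rate in centimorgans per megabase (> 0).
#' @return List with `rho_bar`, `r_per_bp`, `ne`, and `ne_rounded`
#'   (nearest 1,000, the usual table formatting).
#' @examples
#' estimate_ne(0.0079, 0.50)$ne  # 395,000
#' @export
estimate_ne <- function(rho_bar, cm_per_mb) {
  stopifnot(is.numeric(rho_bar), is.numeric(cm_per_mb))
  if (rho_bar <= 0 || cm_per_mb <= 0)
    stop("rho_bar and cm_per_mb must be positive", call. = FALSE)
  r <- cm_per_mb * 1e-8
  ne <- rho_bar / (4 * r)
  list(rho_bar = rho_bar, r_per_bp = r, ne = ne,
       ne_rounded = round(ne / 1000) * 1000)
}
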