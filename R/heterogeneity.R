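#' Lorenz curve and Gini coefficient of a recombination map
#'
#' Quantifies how concentrated recombination is along the chromosome.
#' Map intervals are sorted by rate (ascending; ties broken by position for
#' determinism — the result is invariant to tie order). Each interval then
#' contributes its share of physical distance to the x axis and its share
#' of genetic distance (\eqn{\rho_i d_i}) to the y axis, giving a polyline
#' from (0,0) to (1,1) lying on or below the diagonal. The Gini coefficient
#' is one minus twice the trapezoidal area under that curve: 0 for a
#' uniform map, approaching 1 when all recombination sits in a tiny
#' fraction of the sequence.
#'
#' @param map A [rho_map] with positive total \eqn{\rho}.
#' @return A list of class `lorenz_result`: `points` (tibble
#'   `cum_physical`, `cum_genetic`, including the origin) and `gini`.
#' @examples
#' m <- rho_map("chr", c(0, 1, 2, 3, 4) * 1000, c(0, 0, 0, 1))
#' lorenz_gini(m)$gini  # 0.75: all recombination in 1 of 4 equal bins
#' @export
lorenz_gini <- function(map) {
  stopifnot(inherits(map, "rho_map"))
  d <- diff(map$positions)
  mass <- map$rates * d
  if (sum(mass) <= 0)
    stop("total map rho is zero; Lorenz curve undefined", call. = FALSE)
  ord <- order(map$rates, map$positions[-length(map$positions)])
  x <- cumsum(d[ord]) / sum(d)
  y <- cumsum(mass[ord]) / sum(mass)
  x <- c(0, x); y <- c(0, y)
  area <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  structure(list(points = tibble::tibble(cum_physical = x, cum_genetic = y),
                 gini = 1 - 2 * area),
            class = "lorenz_result")
}

#' @export
print.lorenz_result <- function(x, ...) {
  cat(sprintf("<lorenz_result> %d curve points, Gini = %.4f\n",
              nrow(x$points) - 1L, x$gini))
  invisible(x)
}
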