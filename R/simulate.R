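#' Uniform recombination map
#'
#' Convenience constructor for a constant-rate [rho_map] over `[0, length)`.
#'
#' @param rho Rate (\eqn{\rho}/bp).
#' @param length Span in bp.
#' @param chrom Chromosome label.
#' @return A [rho_map] with a single interval.
#' @export
uniform_rho_map <- function(rho, length, chrom = "sim") {
  rho_map(chrom, c(0, length), rho)
}

#' Simulate a recombination landscape with planted hotspots
#'
#' Ground-truth generator for the hotspot caller. The background is
#' piecewise constant on intervals of `bg_interval` bp with rates drawn
#' from a gamma distribution of mean `background_mean` (shape `bg_shape`;
#' shape 5 gives the moderate interval-to-interval heterogeneity typical
#' of fine-scale LD maps outside hotspots). Hotspot intervals of `width`
#' bp are placed uniformly at random, non-overlapping and at least
#' `min_gap` bp apart; each is assigned `intensity` times the
#' frequency-weighted mean *background* rate of the `flank_total` bp
#' surrounding it (so the planted focal/flank ratio is the intensity
#' itself, not a single noisy draw).
#'
#' @param background_mean Mean background rate (\eqn{\rho}/bp).
#' @param hotspot_density Hotspots per Mb (15/Mb is a genome-scale figure
#'   for house mice; use less for isolated-hotspot tests).
#' @param intensity Hotspot/background multiplier (> 1).
#' @param width Hotspot width in bp (default 2000).
#' @param length Chromosome length in bp.
#' @param seed Optional integer seed.
#' @param bg_interval Background interval size in bp (default 2000).
#' @param bg_shape Gamma shape of background rates (default 5).
#' @param grid_align If `TRUE` (default) hotspot starts snap to multiples
#'   of `width`, aligning them with a `width`-bp analysis window grid.
#' @param min_gap Minimum bp between hotspots (default `width`).
#' @param flank_total Span (bp) of the surrounding background used to set
#'   each hotspot's rate (default 80000).
#' @return List with `map` (a [rho_map]) and `hotspots` (an
#'   [interval_set] of the true planted intervals, with their rates in
#'   column `rate`).
#' @export
simulate_landscape <- function(background_mean, hotspot_density, intensity,
                               width = 2000, length = 1e6, seed = NULL,
                               bg_interval = 2000, bg_shape = 5,
                               grid_align = TRUE, min_gap = width,
                               flank_total = 80000) {
  stopifnot(background_mean > 0, hotspot_density >= 0, intensity > 1,
            width > 0, length > 2 * width)
  run <- function() {
    bg_breaks <- unique(c(seq(0, length, by = bg_interval), length))
    bg_rates <- stats::rgamma(length(bg_breaks) - 1L, shape = bg_shape,
                              rate = bg_shape / background_mean)
    n_hot <- round(hotspot_density * length / 1e6)
    starts <- numeric(0)
    if (n_hot > 0) {
      cand_max <- length - width
      for (attempt in seq_len(1000L * n_hot)) {
        if (length(starts) == n_hot) break
        s <- if (grid_align)
          sample.int(floor(cand_max / width) + 1L, 1L) * width - width
        else floor(stats::runif(1) * (cand_max + 1))
        if (all(abs(s - starts) >= width + min_gap)) starts <- c(starts, s)
      }
      if (length(starts) < n_hot)
        stop("could not place ", n_hot,
             " non-overlapping hotspots at this density", call. = FALSE)
      starts <- sort(starts)
    }
    bg_map <- rho_map("sim", bg_breaks, bg_rates)
    half <- flank_total / 2
    hot_rate <- vapply(starts, function(s) {
      lo <- max(s - half, 0); hi <- min(s + width + half, length)
      fl <- 0
      if (s > lo) fl <- fl + weighted_mean_rho(bg_map, c(lo, s)) * (s - lo)
      if (hi > s + width)
        fl <- fl + weighted_mean_rho(bg_map, c(s + width, hi)) *
          (hi - s - width)
      intensity * fl / ((s - lo) + (hi - s - width))
    }, numeric(1))
    breaks <- sort(unique(c(bg_breaks, starts, starts + width)))
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    rates <- bg_rates[findInterval(mids, bg_breaks,
                                   rightmost.closed = TRUE)]
    if (length(starts)) {
      hit <- findInterval(mids, as.vector(rbind(starts, starts + width)))
      in_hot <- hit %% 2L == 1L
      rates[in_hot] <- hot_rate[(hit[in_hot] + 1L) %/% 2L]
    }
    hotspots <- if (length(starts))
      interval_set(tibble::tibble(chrom = "sim", start = starts,
                                  end = starts + width, rate = hot_rate),
                   chrom_lengths = c(sim = length))
    else
      interval_set(tibble::tibble(chrom = character(), start = numeric(),
                                  end = numeric(), rate = numeric()),
                   chrom_lengths = c(sim = length))
    list(map = rho_map("sim", breaks, rates,
                       provenance = list(generator = "simulate_landscape",
                                         seed = seed)),
         hotspots = hotspots)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate outgroup quartet sites from a known mutation model
#'
#' Ground truth for ancestral-allele inference: ancestral bases are drawn
#' from the model's stationary distribution, derived bases from the
#' corresponding row of the conditional mutation spectrum, and each
#' outgroup copies the ancestral base but is independently perturbed to a
#' uniformly chosen different base with probability `error_rate`
#' (homoplasy / alignment error in one lineage).
#'
#' @param model A [mutation_model].
#' @param n Number of sites.
#' @param error_rate Per-outgroup perturbation probability.
#' @param seed Optional integer seed.
#' @return Tibble: `ancestral`, `derived` (truth), `outgroup1`,
#'   `outgroup2`.
#' @export
simulate_polarization_sites <- function(model, n, error_rate = 0,
                                        seed = NULL) {
  stopifnot(inherits(model, "mutation_model"), n >= 1,
            error_rate >= 0, error_rate <= 1)
  cond <- model$matrix
  diag(cond) <- 0
  cond <- cond / rowSums(cond)
  run <- function() {
    anc <- sample(BASES, n, replace = TRUE, prob = model$stationary)
    der <- vapply(anc, function(a)
      sample(BASES, 1L, prob = cond[a, ]), character(1))
    perturb <- function(b) {
      hit <- stats::runif(n) < error_rate
      b[hit] <- vapply(b[hit], function(x)
        sample(setdiff(BASES, x), 1L), character(1))
      b
    }
    tibble::tibble(ancestral = anc, derived = unname(der),
                   outgroup1 = perturb(anc), outgroup2 = perturb(anc))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a gene table with a known rank correlation
#'
#' Draws per-gene (\eqn{\bar\rho}, \eqn{\pi}) pairs from a Gaussian copula
#' whose correlation is chosen so the population Kendall tau equals
#' `tau_target` (\eqn{r = \sin(\pi \tau / 2)}), with gamma marginals on
#' scales typical of a murid dataset (mean \eqn{\bar\rho} 0.009/bp, mean
#' \eqn{\pi} 0.01). Divergence `d_rat` is drawn independently. Because the
#' marginals are continuous, the measured tau of the sample is an unbiased
#' estimate of `tau_target`.
#'
#' @param n Number of genes.
#' @param tau_target Target Kendall tau between `rho_bar` and `pi`
#'   (`|tau| < 1`).
#' @param seed Optional integer seed.
#' @return Tibble: `gene_id`, `rho_bar`, `pi`, `d_rat`, `pi_over_d`.
#' @export
simulate_gene_table <- function(n, tau_target, seed = NULL) {
  stopifnot(n >= 3, abs(tau_target) <= 1)
  r <- sin(pi * tau_target / 2)
  run <- function() {
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    rho_bar <- stats::qgamma(stats::pnorm(z1), shape = 4,
                             rate = 4 / 0.009)
    pi_ <- stats::qgamma(stats::pnorm(z2), shape = 2, rate = 2 / 0.01)
    d_rat <- stats::rgamma(n, shape = 10, rate = 10 / 0.15)
    tibble::tibble(gene_id = sprintf("g%05d", seq_len(n)),
                   rho_bar = rho_bar, pi = pi_, d_rat = d_rat,
                   pi_over_d = pi_ / d_rat)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Count four-gamete-test violations in a haplotype matrix
#'
#' A pair of biallelic sites violates the four-gamete test when all four
#' combinations of alleles are present in the sample — impossible under a
#' single non-recombining genealogy with at most one mutation per site, so
#' the count grows with the recombination rate.
#'
#' @param haps 0/1 matrix, haplotypes in rows, sites in columns.
#' @return Number of violating site pairs.
#' @export
count_four_gamete_violations <- function(haps) {
  haps <- as.matrix(haps)
  s <- ncol(haps)
  if (s < 2L) return(0L)
  n11 <- crossprod(haps)
  n10 <- crossprod(haps, 1 - haps)
  n01 <- t(n10)
  n00 <- crossprod(1 - haps)
  viol <- n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0
  sum(viol[upper.tri(viol)])
}
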