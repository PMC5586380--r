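#' Published per-chromosome recombination rate summary for house mice
#'
#' Per-chromosome summary of three house-mouse genetic maps, as printed in
#' published map comparisons: the pedigree-based laboratory linkage map of
#' Cox and colleagues (cM/Mb), the frequency-weighted mean scaled rates
#' (\eqn{\rho}/bp) of an LD-based map from wild *M. m. castaneus* with the
#' corresponding \eqn{N_e} estimates, and the same quantities for the
#' LD-based Brunschwig laboratory-strain map. The \eqn{N_e} columns assume
#' the per-generation rates of the Cox map (see [estimate_ne()]);
#' Brunschwig values are absent for the X.
#'
#' @return A tibble with one row per chromosome (1-19 and X) and columns
#'   `chrom`, `cox_cm_per_mb`, `castaneus_rho`, `castaneus_ne`,
#'   `brunschwig_rho`, `brunschwig_ne`.
#' @examples
#' tab <- mouse_chromosome_rates()
#' signif(mean(tab$castaneus_rho[tab$chrom != "X"]), 2)
#' @export
mouse_chromosome_rates <- function() {
  tibble::tibble(
    chrom = c(as.character(1:19), "X"),
    cox_cm_per_mb = c(0.50, 0.57, 0.52, 0.56, 0.59, 0.53, 0.58, 0.58, 0.61,
                      0.61, 0.70, 0.53, 0.56, 0.53, 0.56, 0.59, 0.65, 0.66,
                      0.94, 0.48),
    castaneus_rho = c(0.0079, 0.0088, 0.0083, 0.0091, 0.0090, 0.0089,
                      0.0100, 0.0094, 0.0096, 0.0096, 0.0102, 0.0089,
                      0.0095, 0.0084, 0.0083, 0.0091, 0.0087, 0.0098,
                      0.0122, 0.0026),
    castaneus_ne = c(395000, 386000, 400000, 408000, 382000, 421000, 429000,
                     404000, 394000, 392000, 365000, 420000, 426000, 395000,
                     371000, 386000, 335000, 371000, 323000, 137000),
    brunschwig_rho = c(0.000015, 0.000015, 0.000014, 0.000020, 0.000015,
                       0.000015, 0.000019, 0.000014, 0.000018, 0.000023,
                       0.000019, 0.000019, 0.000014, 0.000013, 0.000024,
                       0.000017, 0.000052, 0.000021, 0.000026, NA),
    brunschwig_ne = c(745, 653, 693, 889, 646, 728, 801, 610, 749, 928, 689,
                      897, 629, 632, 1080, 721, 2020, 785, 681, NA)
  )
}
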