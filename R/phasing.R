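#' Construct a phased haplotype pair
#'
#' Two allele vectors over ordered heterozygous sites. Every site must be
#' heterozygous (`hapA != hapB`); the pair is the unit on which relative
#' phase, and hence switch error, is defined.
#'
#' @param positions Strictly increasing site coordinates (bp).
#' @param hapA,hapB Character vectors of single-base alleles, one per site.
#' @return Object of class `phased_pair`.
#' @export
phased_pair <- function(positions, hapA, hapB) {
  positions <- as.numeric(positions)
  hapA <- as.character(hapA); hapB <- as.character(hapB)
  stopifnot(length(positions) == length(hapA),
            length(hapA) == length(hapB))
  if (length(positions) > 1L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  if (any(hapA == hapB))
    stop("all sites of a phased_pair must be heterozygous", call. = FALSE)
  structure(list(positions = positions, hapA = hapA, hapB = hapB),
            class = "phased_pair")
}

#' @export
print.phased_pair <- function(x, ...) {
  cat(sprintf("<phased_pair> %d heterozygous sites\n", length(x$positions)))
  invisible(x)
}

#' Build a pseudofemale from two known haploid sequences
#'
#' Merging two haploid (e.g. male X-chromosome) sequences yields a synthetic
#' diploid whose genotypes can be re-phased while the true haplotypes are
#' known — the trick that lets phasing error be measured on real data.
#' Genotypes are returned for every site; the truth [phased_pair] is
#' restricted to sites where the haplotypes differ and neither base is
#' missing.
#'
#' @param hap1,hap2 Equal-length character vectors of bases over shared
#'   positions; missing bases as `"N"`, `"-"` or `NA`.
#' @param positions Site coordinates; defaults to `1:length(hap1)`.
#' @return List with `genotypes` (tibble `position`, `allele1`, `allele2`)
#'   and `truth` (a [phased_pair] over the usable heterozygous sites).
#' @export
make_pseudofemale <- function(hap1, hap2, positions = seq_along(hap1)) {
  hap1 <- toupper(as.character(hap1)); hap2 <- toupper(as.character(hap2))
  if (length(hap1) != length(hap2))
    stop("haploid sequences differ in length", call. = FALSE)
  stopifnot(length(positions) == length(hap1))
  miss <- function(x) is.na(x) | x %in% c("N", "-", ".")
  usable <- !miss(hap1) & !miss(hap2)
  het <- usable & hap1 != hap2
  list(
    genotypes = tibble::tibble(position = positions, allele1 = hap1,
                               allele2 = hap2),
    truth = phased_pair(positions[het], hap1[het], hap2[het])
  )
}

#' Switch error rate between a true and an inferred phasing
#'
#' At each heterozygous site the inferred pair is oriented against the
#' truth (does inferred hapA carry truth hapA's allele, or truth hapB's?);
#' a switch is a flip of that orientation between consecutive sites. The
#' primary rate divides the number of switches by the total number of
#' heterozygous sites; the conventional rate (denominator `n_het - 1`,
#' the number of consecutive pairs) is reported alongside. The measure is
#' invariant to a global hapA/hapB relabeling.
#'
#' @param truth,inferred [phased_pair]s over identical positions with
#'   identical unordered allele pairs at every site.
#' @return List of class `switch_error_report`: `n_het`, `n_switches`,
#'   `rate` (= n_switches / n_het), `rate_conventional`
#'   (= n_switches / (n_het - 1)).
#' @export
switch_error_rate <- function(truth, inferred) {
  stopifnot(inherits(truth, "phased_pair"), inherits(inferred, "phased_pair"))
  if (length(truth$positions) != length(inferred$positions) ||
      any(truth$positions != inferred$positions))
    stop("truth and inferred cover different sites", call. = FALSE)
  n <- length(truth$positions)
  match_A <- inferred$hapA == truth$hapA & inferred$hapB == truth$hapB
  match_B <- inferred$hapA == truth$hapB & inferred$hapB == truth$hapA
  if (any(!match_A & !match_B)) {
    bad <- which(!match_A & !match_B)[1]
    stop(sprintf("allele pair mismatch at position %s: genotypes disagree, not a phase switch",
                 format(truth$positions[bad])), call. = FALSE)
  }
  orient <- ifelse(match_A, 1L, 2L)
  n_sw <- if (n > 1L) sum(diff(orient) != 0L) else 0L
  structure(list(n_het = n, n_switches = n_sw,
                 rate = n_sw / n,
                 rate_conventional = if (n > 1L) n_sw / (n - 1L) else NA_real_),
            class = "switch_error_report")
}

#' @export
print.switch_error_report <- function(x, ...) {
  cat(sprintf("<switch_error_report> %d switches over %d het sites: rate %.4g (conventional %.4g)\n",
              x$n_switches, x$n_het, x$rate, x$rate_conventional))
  invisible(x)
}

#' Inject switch errors into a phased pair
#'
#' Each heterozygous site independently triggers a switch event with
#' probability `e` (in position order); each event toggles a running swap
#' state, and alleles are emitted swapped while the state is active. One
#' event therefore produces exactly one orientation flip — mimicking the
#' spurious crossover that a phasing switch error creates in downstream
#' LD-based rate estimation.
#'
#' @param pair A [phased_pair].
#' @param e Per-site switch probability in `[0, 1]`.
#' @param seed Optional integer seed (global RNG state untouched).
#' @return A [phased_pair] of the same sites with errors incorporated.
#' @export
inject_switch_errors <- function(pair, e, seed = NULL) {
  stopifnot(inherits(pair, "phased_pair"), e >= 0, e <= 1)
  n <- length(pair$positions)
  draw <- function() stats::runif(n) < e
  events <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  swapped <- cumsum(events) %% 2L == 1L
  hapA <- ifelse(swapped, pair$hapB, pair$hapA)
  hapB <- ifelse(swapped, pair$hapA, pair$hapB)
  phased_pair(pair$positions, hapA, hapB)
}
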