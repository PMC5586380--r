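#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the
#' probability of each possible heterozygote count `h` follows the
#' hypergeometric-type distribution
#' \deqn{P(h) = \frac{N!\,/\,(n_{AA}!\,h!\,n_{aa}!)\;2^h}{\binom{2N}{n_a}},}
#' and the two-sided p-value sums `P(h)` over all `h` (same parity as the
#' minor-allele count) with `P(h)` no larger than that of the observed
#' configuration — the probability-ordering convention. Computed in log
#' space via the ratio recurrence, so it is stable for large samples.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return The p-value; 1 for monomorphic sites.
#' @examples
#' hwe_exact_test(2, 0, 2)  # 6/70
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) ||
      any(c(n_AA, n_Aa, n_aa) != round(c(n_AA, n_Aa, n_aa))))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  N <- n_AA + n_Aa + n_aa
  if (N < 1) stop("at least one genotype is required", call. = FALSE)
  n_a <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)  # minor allele count
  if (n_a == 0L) return(1)
  hs <- seq(n_a %% 2L, n_a, by = 2L)
  hs <- hs[(n_a - hs) / 2L + hs <= N]  # minor homs + hets cannot exceed N
  # unnormalized log-probabilities by recurrence:
  # P(h+2)/P(h) = (n_minor_hom * n_major_hom * 4) / ((h+1)(h+2))
  logp <- numeric(length(hs))
  for (i in seq_along(hs)[-1]) {
    h <- hs[i - 1L]
    hom_minor <- (n_a - h) / 2
    hom_major <- N - h - hom_minor
    logp[i] <- logp[i - 1L] +
      log(4 * hom_minor * hom_major) - log((h + 1) * (h + 2))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_Aa, hs)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Filter variant sites for map estimation
#'
#' Applies the site-selection rules used before LD-based map inference:
#' only biallelic SNPs are kept (indels and multiallelic sites dropped);
#' sites must reach the variant quality threshold; for per-individual
#' statistics (genotype quality and, optionally, depth) a single failing
#' individual removes the whole site; and sites failing an exact
#' Hardy-Weinberg test at `hwe_alpha` are dropped. Rules are applied in
#' that order and each site is charged to the first rule it fails.
#'
#' @param sites A data frame with one row per site and columns:
#'   `id` (site identifier), `is_indel` (logical), `n_alleles` (integer),
#'   `qual` (variant quality), `gq` (list column: per-individual genotype
#'   qualities), optionally `dp` (list column: per-individual depths), and
#'   `n_AA`, `n_Aa`, `n_aa` (genotype counts for the HWE test). See
#'   [read_sites_vcf()] for building this from a VCF.
#' @param min_qual Minimum variant quality (default 30).
#' @param min_gq Minimum per-individual genotype quality (default 15).
#' @param dp_bounds Optional `c(min, max)` per-individual depth range;
#'   `NULL` (default) disables the depth rule.
#' @param hwe_alpha Exclusion p-value for the HWE test (default 0.002).
#' @return List with `kept` (the passing rows), `report` (tibble of counts
#'   removed per rule) and `fraction_removed`.
#' @export
filter_sites <- function(sites, min_qual = 30, min_gq = 15,
                         dp_bounds = NULL, hwe_alpha = 0.002) {
  sites <- tibble::as_tibble(sites)
  need <- c("id", "is_indel", "n_alleles", "qual", "gq",
            "n_AA", "n_Aa", "n_aa")
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols))
    stop("site table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  stopifnot(hwe_alpha > 0, hwe_alpha < 1)
  n <- nrow(sites)
  reason <- rep(NA_character_, n)
  fails <- function(f) is.na(reason) & f
  reason[fails(sites$is_indel)] <- "indel"
  reason[fails(sites$n_alleles != 2L)] <- "multiallelic"
  reason[fails(sites$qual < min_qual)] <- "qual"
  gq_fail <- vapply(sites$gq, function(g) any(g < min_gq, na.rm = FALSE),
                    logical(1))
  reason[fails(gq_fail)] <- "gq"
  if (!is.null(dp_bounds)) {
    stopifnot(length(dp_bounds) == 2L, dp_bounds[1] <= dp_bounds[2])
    if (!"dp" %in% names(sites))
      stop("dp_bounds set but site table has no dp column", call. = FALSE)
    dp_fail <- vapply(sites$dp, function(d)
      any(d < dp_bounds[1] | d > dp_bounds[2]), logical(1))
    reason[fails(dp_fail)] <- "dp"
  }
  todo <- which(is.na(reason))
  hwe_p <- vapply(todo, function(i)
    hwe_exact_test(sites$n_AA[i], sites$n_Aa[i], sites$n_aa[i]), numeric(1))
  reason[todo[hwe_p < hwe_alpha]] <- "hwe"
  rules <- c("indel", "multiallelic", "qual", "gq", "dp", "hwe")
  report <- tibble::tibble(
    rule = rules,
    removed = unname(vapply(rules, function(r)
      sum(reason == r, na.rm = TRUE), integer(1))))
  list(kept = sites[is.na(reason), , drop = FALSE],
       report = report,
       fraction_removed = sum(!is.na(reason)) / n)
}

#' Build a site table from a VCF file
#'
#' Thin wrapper over \pkg{vcfR} that extracts what [filter_sites()] needs:
#' allele structure, QUAL, per-individual GQ and DP, and genotype counts.
#' Genotype counts treat any genotype carrying two identical ALT (or REF)
#' alleles as homozygous and anything mixed as heterozygous.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @return A tibble suitable for [filter_sites()].
#' @export
read_sites_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_sites_vcf() needs the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  alt_alleles <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  n_alt <- lengths(alt_alleles)
  is_indel <- nchar(ref) != 1L |
    vapply(alt_alleles, function(a) any(nchar(a) != 1L), logical(1))
  gt <- vcfR::extract.gt(v, element = "GT")
  gq <- suppressWarnings(
    vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  split_gt <- function(g) strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
  counts <- t(apply(gt, 1, function(row) {
    al <- split_gt(row)
    hom_ref <- sum(vapply(al, function(x) length(x) == 2 && all(x == "0"),
                          logical(1)), na.rm = TRUE)
    het <- sum(vapply(al, function(x)
      length(x) == 2 && !anyNA(suppressWarnings(as.integer(x))) &&
        x[1] != x[2], logical(1)), na.rm = TRUE)
    hom_alt <- sum(vapply(al, function(x)
      length(x) == 2 && all(x != "0") && x[1] == x[2] &&
        !anyNA(suppressWarnings(as.integer(x))), logical(1)), na.rm = TRUE)
    c(hom_ref, het, hom_alt)
  }))
  tibble::tibble(
    id = paste0(fix[, "CHROM"], ":", fix[, "POS"]),
    is_indel = is_indel,
    n_alleles = 1L + n_alt,
    qual = as.numeric(fix[, "QUAL"]),
    gq = lapply(seq_len(nrow(gq)), function(i) unname(gq[i, ])),
    dp = lapply(seq_len(nrow(dp)), function(i) unname(dp[i, ])),
    n_AA = unname(counts[, 1]), n_Aa = unname(counts[, 2]),
    n_aa = unname(counts[, 3]))
}
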