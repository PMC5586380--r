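FOURFOLD_PREFIXES <- local({
  # codon prefixes whose four completions encode the same amino acid
  gc <- Biostrings::GENETIC_CODE
  pre <- unique(substr(names(gc), 1, 2))
  pre[vapply(pre, function(p)
    length(unique(gc[paste0(p, BASES)])) == 1L, logical(1))]
})

#' Locate fourfold degenerate sites of a protein-coding gene
#'
#' Finds third codon positions that are fourfold degenerate (any base
#' yields the same amino acid, standard genetic code) in the focal species
#' *and* in both outgroup alignments — the all-three-species rule that
#' guards against annotation differences. Minus-strand genes are evaluated
#' on the reverse complement of the concatenated exons. Each retained site
#' is also tagged as CpG-prone or not from its genomic context in the
#' three species (see [classify_cpg_prone()]).
#'
#' @param exons Data frame with columns `start`, `end` (1-based inclusive
#'   genomic coordinates of the coding exons, in genomic order).
#' @param strand `"+"` or `"-"`.
#' @param seqs Named character vector of length 3 (`focal`, `outgroup1`,
#'   `outgroup2`): chromosome-scale sequences aligned to the focal
#'   coordinates, gaps as `"-"`.
#' @return A tibble with one row per fourfold site: `position` (genomic,
#'   1-based), `codon_index`, `focal_base`, `outgroup1_base`,
#'   `outgroup2_base`, `cpg_prone`. Genes whose concatenated CDS length is
#'   not a multiple of 3 are flagged: an empty tibble is returned with
#'   `attr(, "flag") == "cds_not_multiple_of_3"`.
#' @export
annotate_fourfold_sites <- function(exons, strand, seqs) {
  stopifnot(all(c("start", "end") %in% names(exons)),
            strand %in% c("+", "-"),
            length(seqs) == 3L)
  seqs <- toupper(seqs)
  empty <- function(flag = NULL) {
    out <- tibble::tibble(position = numeric(), codon_index = integer(),
                          focal_base = character(),
                          outgroup1_base = character(),
                          outgroup2_base = character(),
                          cpg_prone = logical())
    if (!is.null(flag)) attr(out, "flag") <- flag
    out
  }
  cds_pos <- unlist(Map(seq, exons$start, exons$end))
  if (length(cds_pos) %% 3L != 0L) return(empty("cds_not_multiple_of_3"))
  if (strand == "-") cds_pos <- rev(cds_pos)
  base_at <- function(s, i) substring(s, i, i)
  cds_base <- function(s) {
    b <- base_at(s, cds_pos)
    if (strand == "-") chartr("ACGT", "TGCA", b) else b
  }
  cb <- lapply(seqs, cds_base)
  n_codon <- length(cds_pos) %/% 3L
  i3 <- 3L * seq_len(n_codon)  # CDS index of each third position
  fourfold_all <- rep(TRUE, n_codon)
  for (b in cb) {
    prefix <- paste0(b[i3 - 2L], b[i3 - 1L])
    fourfold_all <- fourfold_all & prefix %in% FOURFOLD_PREFIXES &
      b[i3] %in% BASES
  }
  keep <- which(fourfold_all)
  if (!length(keep)) return(empty())
  gpos <- cds_pos[i3[keep]]
  ctx <- function(off) vapply(seqs, base_at, character(length(gpos)),
                              i = gpos + off)
  lc <- ctx(-1L); rc <- ctx(1L)
  if (length(gpos) == 1L) { lc <- matrix(lc, 1); rc <- matrix(rc, 1) }
  out <- tibble::tibble(
    position = gpos,
    codon_index = keep,
    focal_base = base_at(seqs[[1]], gpos),
    outgroup1_base = base_at(seqs[[2]], gpos),
    outgroup2_base = base_at(seqs[[3]], gpos),
    cpg_prone = classify_cpg_prone(lc, rc))
  out[order(out$position), ]
}

#' GC fraction of a sequence
#'
#' @param seq A character string; non-ACGT characters are ignored.
#' @return Fraction of G+C among A/C/G/T characters.
#' @export
gc_fraction <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  b <- b[b %in% BASES]
  if (!length(b)) return(NA_real_)
  mean(b %in% c("G", "C"))
}

.site_pi <- function(counts) {
  # counts: matrix sites x 4; pi = fraction of pairwise differences
  n <- rowSums(counts)
  same <- rowSums(choose(counts, 2))
  ifelse(n >= 2, 1 - same / choose(n, 2), NA_real_)
}

#' Per-gene diversity and divergence at fourfold sites
#'
#' Computes, for one gene, pairwise nucleotide diversity \eqn{\pi} (mean
#' over fourfold sites of the fraction of allele pairs that differ),
#' divergence from the rat outgroup \eqn{d_{rat}} (fraction of comparable
#' sites whose focal consensus base mismatches the rat base), and their
#' ratio \eqn{\pi / d_{rat}} — a mutation-rate-corrected diversity. All
#' three are reported both over all fourfold sites and over non-CpG-prone
#' sites only.
#'
#' Quality rules: a gene is excluded when more than `max_missing` of its
#' fourfold sites are missing (no usable rat base or fewer than 2 sampled
#' alleles), or when *every* comparable non-CpG-prone site mismatches the
#' rat (and at least one exists) — the signature of a misalignment rather
#' than genuine divergence.
#'
#' @param sites Tibble with one row per fourfold site: allele counts
#'   `count_A`, `count_C`, `count_G`, `count_T` over the sampled focal
#'   chromosomes, `rat_base` (single base; gap/`N`/`NA` = missing) and
#'   `cpg_prone` (logical).
#' @param gene_id Identifier copied into the output.
#' @param rho_bar Optional frequency-weighted mean \eqn{\rho}/bp over the
#'   gene span (from [weighted_mean_rho()]); copied into the output.
#' @param gc Optional GC fraction of the gene span (see [gc_fraction()]).
#' @param max_missing Missing-site fraction above which the gene is
#'   excluded (default 0.8).
#' @return One-row tibble: `gene_id`, `rho_bar`, `n_fourfold`, `n_used`,
#'   `pi_all`, `d_rat_all`, `pi_over_d_all`, `pi_noncpg`, `d_rat_noncpg`,
#'   `pi_over_d_noncpg`, `gc`, `excluded`, `exclude_reason`.
#' @export
gene_diversity_divergence <- function(sites, gene_id = NA_character_,
                                      rho_bar = NA_real_, gc = NA_real_,
                                      max_missing = 0.8) {
  sites <- tibble::as_tibble(sites)
  need <- c("count_A", "count_C", "count_G", "count_T", "rat_base",
            "cpg_prone")
  stopifnot(all(need %in% names(sites)))
  counts <- as.matrix(sites[, paste0("count_", BASES)])
  n_alleles <- rowSums(counts)
  rat <- toupper(as.character(sites$rat_base))
  usable <- .is_base(rat) & n_alleles >= 2
  n_sites <- nrow(sites)
  rec <- function(excluded, reason, pi_a = NA, d_a = NA, pi_n = NA,
                  d_n = NA) {
    ratio <- function(p, d) if (!is.na(d) && d > 0) p / d else NA_real_
    tibble::tibble(gene_id = gene_id, rho_bar = rho_bar,
                   n_fourfold = n_sites, n_used = sum(usable),
                   pi_all = pi_a, d_rat_all = d_a,
                   pi_over_d_all = ratio(pi_a, d_a),
                   pi_noncpg = pi_n, d_rat_noncpg = d_n,
                   pi_over_d_noncpg = ratio(pi_n, d_n),
                   gc = gc, excluded = excluded,
                   exclude_reason = reason)
  }
  if (n_sites == 0L || sum(usable) == 0L)
    return(rec(TRUE, "no_usable_sites"))
  if (1 - sum(usable) / n_sites > max_missing)
    return(rec(TRUE, "too_many_missing"))
  consensus <- BASES[max.col(counts, ties.method = "first")]
  mismatch <- consensus != rat
  pi_site <- .site_pi(counts)
  noncpg <- usable & !sites$cpg_prone
  if (sum(noncpg) > 0 && all(mismatch[noncpg]))
    return(rec(TRUE, "all_noncpg_sites_mismatch_rat"))
  mean_or_na <- function(x, w) if (sum(w) > 0) mean(x[w]) else NA_real_
  rec(FALSE, NA_character_,
      pi_a = mean_or_na(pi_site, usable),
      d_a = mean_or_na(mismatch, usable),
      pi_n = mean_or_na(pi_site, noncpg),
      d_n = mean_or_na(mismatch, noncpg))
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall coefficient, the nonparametric correlation used
#' for gene-level comparisons where neither margin is close to normal.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The tau-b coefficient in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("kendall_tau needs at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("kendall_tau undefined when a vector is entirely tied",
         call. = FALSE)
  stats::cor(x, y, method = "kendall")
}
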