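# build a chromosome triple in which gene structure is fully controlled:
# seqs is list(focal, outgroup1, outgroup2) as single strings
make_seqs <- function(focal, out1 = focal, out2 = focal) {
  c(focal = focal, outgroup1 = out1, outgroup2 = out2)
}

test_that("fourfold sites require degeneracy in all three species", {
  # gene: codons GCA (Ala, fourfold) + AAA (Lys, not fourfold)
  focal <- paste0("TT", "GCA", "AAA", "TT")
  sites <- annotate_fourfold_sites(
    data.frame(start = 3, end = 8), "+", make_seqs(focal))
  expect_equal(sites$position, 5)  # third base of GCA only
  expect_equal(sites$focal_base, "A")

  # same codon family in all species still counts (GCA / GCC / GCG = Ala)
  s2 <- annotate_fourfold_sites(
    data.frame(start = 3, end = 8), "+",
    make_seqs(focal, paste0("TT", "GCC", "AAA", "TT"),
              paste0("TT", "GCG", "AAA", "TT")))
  expect_equal(s2$position, 5)

  # rat codon TCA (Ser, fourfold family) does not rescue focal AAA, and a
  # non-fourfold outgroup codon vetoes a fourfold focal codon
  s3 <- annotate_fourfold_sites(
    data.frame(start = 3, end = 8), "+",
    make_seqs(focal, paste0("TT", "AAA", "AAA", "TT"), focal))
  expect_equal(nrow(s3), 0)
})

test_that("minus-strand genes give the same sites as their revcomp CDS", {
  # plus-strand gene GGT GCA at 3..8 -> fourfold third positions 5 and 8
  plus <- paste0("NN", "GGTGCA", "NN")
  sp <- annotate_fourfold_sites(data.frame(start = 3, end = 8), "+",
                                make_seqs(plus))
  expect_equal(sp$position, c(5, 8))
  # the same gene on the minus strand: genomic sequence is the revcomp,
  # CDS read 8->3; third codon positions land at genomic 6 and 3
  minus <- paste0("NN", "TGCACC", "NN")
  sm <- annotate_fourfold_sites(data.frame(start = 3, end = 8), "-",
                                make_seqs(minus))
  expect_equal(sm$position, c(3, 6))
  expect_equal(length(sm$position), length(sp$position))
})

test_that("CDS length not divisible by three flags the gene", {
  out <- annotate_fourfold_sites(data.frame(start = 1, end = 4), "+",
                                 make_seqs("GCAT"))
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "flag"), "cds_not_multiple_of_3")
})

test_that("fourfold sites are tagged CpG-prone from any species' context", {
  # GCA then GGA: third position of GCA is followed by G in the focal
  focal <- paste0("T", "GCAGGA", "T")
  s <- annotate_fourfold_sites(data.frame(start = 2, end = 7), "+",
                               make_seqs(focal))
  expect_equal(s$cpg_prone[s$position == 4], TRUE)   # followed by G
  expect_equal(s$cpg_prone[s$position == 7], FALSE)  # G_T context
})

test_that("site diversity matches the pairwise enumeration", {
  sites <- tibble::tibble(count_A = 10, count_C = 0, count_G = 0,
                          count_T = 10, rat_base = "A", cpg_prone = FALSE)
  g <- gene_diversity_divergence(sites)
  expect_equal(g$pi_all, 100 / 190)
  # unbiased-estimator identity: pi = 2 p (1-p) n / (n-1) for biallelic counts
  for (na in c(1, 5, 9)) {  # minor allele A; consensus stays T, matching rat
    n <- 20; p <- na / n
    s2 <- tibble::tibble(count_A = na, count_C = 0, count_G = 0,
                         count_T = n - na, rat_base = "T",
                         cpg_prone = FALSE)
    expect_equal(gene_diversity_divergence(s2)$pi_all,
                 2 * p * (1 - p) * n / (n - 1), tolerance = 1e-12)
  }
})

test_that("monomorphic genes matching rat give zero pi and d, undefined ratio", {
  sites <- tibble::tibble(count_A = c(20, 20), count_C = 0, count_G = 0,
                          count_T = 0, rat_base = "A",
                          cpg_prone = c(FALSE, TRUE))
  g <- gene_diversity_divergence(sites)
  expect_equal(g$pi_all, 0)
  expect_equal(g$d_rat_all, 0)
  expect_true(is.na(g$pi_over_d_all))
  expect_false(g$excluded)
})

test_that("quality rules exclude mostly-missing and all-mismatch genes", {
  # 10 sites, 9 with no usable rat base: > 80% missing
  sites <- tibble::tibble(count_A = 20, count_C = 0, count_G = 0,
                          count_T = 0,
                          rat_base = c("A", rep("-", 9)),
                          cpg_prone = FALSE)
  g <- gene_diversity_divergence(sites)
  expect_true(g$excluded)
  expect_equal(g$exclude_reason, "too_many_missing")

  # every comparable non-CpG site mismatches rat: misalignment signature
  s2 <- tibble::tibble(count_A = 20, count_C = 0, count_G = 0, count_T = 0,
                       rat_base = c("G", "G", "A"),
                       cpg_prone = c(FALSE, FALSE, TRUE))
  g2 <- gene_diversity_divergence(s2)
  expect_true(g2$excluded)
  expect_equal(g2$exclude_reason, "all_noncpg_sites_mismatch_rat")

  # same pattern but one matching non-CpG site: retained
  s3 <- s2; s3$rat_base <- c("G", "A", "A")
  expect_false(gene_diversity_divergence(s3)$excluded)
})

test_that("CpG and non-CpG columns are computed on their own site sets", {
  sites <- tibble::tibble(
    count_A = c(10, 20), count_C = 0, count_G = 0, count_T = c(10, 0),
    rat_base = c("A", "G"), cpg_prone = c(FALSE, TRUE))
  g <- gene_diversity_divergence(sites)
  expect_equal(g$pi_noncpg, 100 / 190)
  expect_equal(g$d_rat_noncpg, 0)
  expect_equal(g$pi_all, (100 / 190) / 2)
  expect_equal(g$d_rat_all, 0.5)
})

test_that("kendall tau reproduces hand counts and the O(n^2) oracle", {
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  expect_equal(kendall_tau(1:10, 1:10), 1)
  expect_error(kendall_tau(c(1, 1, 1), c(1, 2, 3)), "tied")
  expect_error(kendall_tau(1:2, 1:2), "at least 3")
  set.seed(81)
  for (k in 1:10) {
    n <- sample(5:25, 1)
    x <- sample(1:8, n, TRUE)  # ties on purpose
    y <- x + sample(-2:2, n, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y), kendall_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("gc_fraction ignores non-ACGT characters", {
  expect_equal(gc_fraction("GGCCAATT"), 0.5)
  expect_equal(gc_fraction("GC-N"), 1)
})
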