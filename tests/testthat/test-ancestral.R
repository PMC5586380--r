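# a deliberately asymmetric but valid mutation model for reuse
toy_model <- function() {
  m <- matrix(0.02, 4, 4)
  m[1, 3] <- 0.10; m[3, 1] <- 0.08  # transition-heavy A<->G
  m[2, 4] <- 0.06; m[4, 2] <- 0.06
  diag(m) <- 0
  diag(m) <- 1 - rowSums(m)
  mutation_model(m)
}

test_that("CpG-prone classification applies the any-species rule", {
  # focal T_A, outgroup1 T_A, outgroup2 T_G: followed by G in one species
  expect_true(classify_cpg_prone(c("T", "T", "T"), c("A", "A", "G")))
  expect_false(classify_cpg_prone(c("T", "T", "T"), c("A", "A", "A")))
  # preceded by C in the focal species alone suffices
  expect_true(classify_cpg_prone(c("C", "T", "T"), c("A", "A", "A")))
  # missing context contributes nothing
  expect_false(classify_cpg_prone(c(NA, "-", "N"), c("A", NA, "A")))
  # vectorized over sites
  lc <- rbind(c("T", "T", "T"), c("C", "A", "A"))
  rc <- rbind(c("A", "A", "A"), c("T", "T", "T"))
  expect_equal(classify_cpg_prone(lc, rc), c(FALSE, TRUE))
})

test_that("ancestral priors follow the resolved/unresolved scheme", {
  mod <- toy_model()
  res <- assign_ancestral_prior("A", "A", mod)
  expect_equal(res$status, "resolved")
  expect_equal(unname(res$prior["A"]), 0.91)
  expect_equal(unname(res$prior["C"]), 0.03)
  expect_equal(sum(res$prior), 1)

  dis <- assign_ancestral_prior("A", "G", mod)
  expect_equal(dis$status, "unresolved")
  expect_equal(unname(dis$prior), unname(mod$stationary))

  gap <- assign_ancestral_prior("A", "-", mod)
  expect_equal(gap$status, "unresolved")

  # every emitted prior sums to 1, vectorized
  many <- assign_ancestral_prior(c("A", "C", "N", "T"),
                                 c("A", "G", "C", "T"), mod)
  expect_equal(unname(rowSums(many$prior)), rep(1, 4))
  expect_equal(many$status, c("resolved", "unresolved", "unresolved",
                              "resolved"))
})

test_that("the stationary distribution is a verified fixed point", {
  mod <- toy_model()
  expect_equal(sum(mod$stationary), 1, tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(mod$stationary %*% mod$matrix) -
                      mod$stationary)), 1e-10)
  expect_equal(abs(rowSums(mod$matrix)), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("symmetric mutation counts give a uniform stationary distribution", {
  anc <- rep(BASES_FIXTURE <- c("A", "C", "G", "T"), each = 3)
  der <- unlist(lapply(BASES_FIXTURE, function(a)
    setdiff(BASES_FIXTURE, a)))
  mod <- build_mutation_model(rep(anc, 5), rep(der, 5))
  expect_equal(unname(mod$stationary), rep(0.25, 4), tolerance = 1e-10)
})

test_that("A<->G dominated counts concentrate stationary mass on A and G", {
  anc <- c(rep("A", 500), rep("G", 500), "C", "T", "C", "T")
  der <- c(rep("G", 500), rep("A", 500), "A", "A", "G", "G")
  # every row needs observations; give C and T a few
  mod <- build_mutation_model(anc, der)
  expect_gt(sum(mod$stationary[c("A", "G")]), 0.9)
  # two-state chain closed form: pi_A/pi_G = rate(G->A)/rate(A->G) = 1
  expect_equal(unname(mod$stationary["A"]), unname(mod$stationary["G"]),
               tolerance = 0.01)
})

test_that("the stationary distribution is invariant to the diagonal convention", {
  set.seed(72)
  anc <- sample(c("A", "C", "G", "T"), 300, TRUE)
  der <- vapply(anc, function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1), character(1))
  m1 <- build_mutation_model(anc, der, off_mass = 0.05)
  m2 <- build_mutation_model(anc, der, off_mass = 0.6)
  expect_equal(m1$stationary, m2$stationary, tolerance = 1e-10)
})

test_that("unobserved ancestral bases are an explicit error", {
  expect_error(build_mutation_model(c("A", "A"), c("C", "G")),
               "pseudocounts")
  expect_error(build_mutation_model(c("A", "A"), c("A", "G")), "distinct")
})

test_that("polarization recovers a known matrix within sampling error", {
  mod <- toy_model()
  sites <- simulate_polarization_sites(mod, 2e4, error_rate = 0, seed = 71)
  # perfect outgroups: every site resolves to the true ancestor
  pri <- assign_ancestral_prior(sites$outgroup1, sites$outgroup2, mod)
  expect_true(all(pri$status == "resolved"))
  top <- colnames(pri$prior)[max.col(pri$prior)]
  expect_equal(top, sites$ancestral)

  fit <- build_mutation_model(sites$ancestral, sites$derived)
  cond_true <- mod$matrix; diag(cond_true) <- 0
  cond_true <- cond_true / rowSums(cond_true)
  cond_fit <- fit$matrix; diag(cond_fit) <- 0
  cond_fit <- cond_fit / rowSums(cond_fit)
  n_row <- table(factor(sites$ancestral, c("A", "C", "G", "T")))
  for (a in c("A", "C", "G", "T")) {
    se <- sqrt(cond_true[a, ] * (1 - cond_true[a, ]) / n_row[[a]])
    off <- setdiff(c("A", "C", "G", "T"), a)
    expect_true(all(abs(cond_fit[a, off] - cond_true[a, off]) <=
                      3 * se[off] + 1e-12),
                label = paste("row", a))
  }
})
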