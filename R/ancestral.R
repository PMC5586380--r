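BASES <- c("A", "C", "G", "T")

.is_base <- function(x) !is.na(x) & x %in% BASES

#' Classify sites as CpG-prone
#'
#' A site is CpG-prone if it is preceded by a C or followed by a G in the
#' focal species *or in either outgroup* — the conservative any-species
#' rule that captures sites that may have spent time in a hypermutable CpG
#' context in any lineage. Missing context (gap, `N`, `NA`) in a species
#' contributes nothing for that species.
#'
#' @param left_context Character matrix or data frame, one column per
#'   species (focal, outgroup1, outgroup2), of the base immediately 5' of
#'   each site; or a vector for a single site.
#' @param right_context Same shape, base immediately 3' of each site.
#' @return Logical vector, one per site.
#' @examples
#' classify_cpg_prone(c("T", "T", "T"), c("A", "A", "G"))  # TRUE
#' @export
classify_cpg_prone <- function(left_context, right_context) {
  if (is.atomic(left_context) && is.null(dim(left_context))) {
    left_context <- matrix(left_context, nrow = 1L)
    right_context <- matrix(right_context, nrow = 1L)
  }
  lc <- toupper(as.matrix(left_context))
  rc <- toupper(as.matrix(right_context))
  stopifnot(all(dim(lc) == dim(rc)))
  rowSums(lc == "C" & !is.na(lc)) > 0 | rowSums(rc == "G" & !is.na(rc)) > 0
}

#' Construct a mutation model
#'
#' A 4x4 row-stochastic single-base mutation matrix over A, C, G, T, its
#' stationary distribution, and the prior mass placed on the inferred
#' ancestral base at resolved sites (the remainder split equally over the
#' other three bases).
#'
#' @param matrix 4x4 row-stochastic matrix, rows/cols named A,C,G,T.
#' @param resolved_prior Prior mass on the inferred ancestral base at
#'   resolved sites (default 0.91, leaving 0.03 for each other base).
#' @return Object of class `mutation_model` with elements `matrix`,
#'   `stationary`, `resolved_prior`.
#' @export
mutation_model <- function(matrix, resolved_prior = 0.91) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(4L, 4L)))
  dimnames(matrix) <- list(BASES, BASES)
  if (any(matrix < 0) || any(abs(rowSums(matrix) - 1) > 1e-12))
    stop("mutation matrix must be row-stochastic", call. = FALSE)
  stopifnot(resolved_prior > 0, resolved_prior < 1)
  structure(list(matrix = matrix,
                 stationary = stationary_distribution(matrix),
                 resolved_prior = resolved_prior),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("<mutation_model>\n")
  print(round(x$matrix, 4))
  cat("stationary:", paste(sprintf("%s=%.4f", BASES, x$stationary),
                           collapse = " "), "\n")
  cat(sprintf("resolved-site prior: %.2f on the ancestral base\n",
              x$resolved_prior))
  invisible(x)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of eigenvalue 1, normalized to sum to 1, cross-checked
#' against power iteration.
#'
#' @param m Row-stochastic square matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(m) {
  e <- eigen(t(m))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10))
    stop("stationary distribution has negative mass; matrix not stochastic?",
         call. = FALSE)
  v <- pmax(v, 0); v <- v / sum(v)
  # verify by iteration: a fixed point must reproduce itself
  it <- v
  for (k in 1:200) it <- as.numeric(it %*% m)
  if (max(abs(it - v)) > 1e-8)
    stop("eigen and iterative stationary distributions disagree",
         call. = FALSE)
  stats::setNames(v, rownames(m) %||% BASES)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign an ancestral-allele prior from two outgroups
#'
#' Parsimony with explicit uncertainty: when both outgroups carry the same
#' (non-gap) base, the site is resolved and that base receives the model's
#' resolved prior (default 0.91; 0.03 on each other base, allowing for
#' homoplasy and back mutation). When the outgroups disagree, or either
#' shows a gap/missing base, the site is unresolved and the prior is the
#' stationary distribution of the mutation matrix.
#'
#' @param outgroup1,outgroup2 Single bases (gap `"-"`, `"N"` or `NA` for
#'   missing); vectorized.
#' @param model A [mutation_model].
#' @return For scalar input, list with `status` (`"resolved"`/
#'   `"unresolved"`) and `prior` (named 4-vector summing to 1). For vector
#'   input, list with `status` vector and `prior` matrix (sites x 4).
#' @export
assign_ancestral_prior <- function(outgroup1, outgroup2, model) {
  stopifnot(inherits(model, "mutation_model"))
  o1 <- toupper(as.character(outgroup1))
  o2 <- toupper(as.character(outgroup2))
  stopifnot(length(o1) == length(o2))
  resolved <- .is_base(o1) & .is_base(o2) & o1 == o2
  n <- length(o1)
  prior <- matrix(rep(model$stationary, each = n), nrow = n,
                  dimnames = list(NULL, BASES))
  off <- (1 - model$resolved_prior) / 3
  if (any(resolved)) {
    pr <- matrix(off, sum(resolved), 4, dimnames = list(NULL, BASES))
    pr[cbind(seq_len(sum(resolved)), match(o1[resolved], BASES))] <-
      model$resolved_prior
    prior[resolved, ] <- pr
  }
  status <- ifelse(resolved, "resolved", "unresolved")
  if (n == 1L) list(status = status, prior = prior[1, ])
  else list(status = status, prior = prior)
}

#' Estimate a mutation model from polarized sites
#'
#' Builds the single-base mutation matrix from resolved, biallelic,
#' non-CpG-prone SNPs whose ancestral and derived bases are known. The
#' off-diagonal entries of each row are the observed conditional spectrum
#' of derived bases given the ancestral base, scaled so that each row's
#' total off-diagonal mass equals `off_mass`; the diagonal takes the
#' remainder. The stationary distribution is invariant to `off_mass`
#' (uniform row-wise damping does not move the fixed point), so the choice
#' only matters to estimator-specific matrix conventions, which differ
#' between tools and are therefore left configurable.
#'
#' @param ancestral,derived Character vectors of single bases, one pair per
#'   polarized site.
#' @param off_mass Total off-diagonal probability per row (default 0.1).
#' @param resolved_prior Passed to [mutation_model()].
#' @return A [mutation_model]; the raw off-diagonal counts are attached as
#'   `attr(, "counts")`.
#' @export
build_mutation_model <- function(ancestral, derived, off_mass = 0.1,
                                 resolved_prior = 0.91) {
  a <- toupper(as.character(ancestral)); d <- toupper(as.character(derived))
  stopifnot(length(a) == length(d), off_mass > 0, off_mass < 1)
  ok <- .is_base(a) & .is_base(d) & a != d
  if (!all(ok))
    stop("ancestral/derived pairs must be distinct A/C/G/T bases",
         call. = FALSE)
  counts <- table(factor(a, BASES), factor(d, BASES))
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(BASES, BASES))
  if (any(rowSums(counts) == 0))
    stop("no observations for ancestral base(s): ",
         paste(BASES[rowSums(counts) == 0], collapse = ", "),
         "; add pseudocounts or more sites", call. = FALSE)
  m <- counts / rowSums(counts) * off_mass
  diag(m) <- 0
  diag(m) <- 1 - rowSums(m)
  mod <- mutation_model(m, resolved_prior = resolved_prior)
  attr(mod, "counts") <- counts
  mod
}
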