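#' Simulation configuration for haplotype generation
#'
#' Bundles the neutral-equilibrium parameters of a haplotype simulation:
#' the scaled mutation rate \eqn{\theta = 4 N_e \mu} per bp (0.01 is the
#' approximate genome-wide neutral diversity of wild house mice, the
#' regime these tools target), sequence length, sample size and seed.
#'
#' @param theta Scaled mutation rate per bp (default 0.01).
#' @param length Sequence length in bp (default 5e5).
#' @param n_haplotypes Sampled haplotypes (default 20, i.e. 10 diploids).
#' @param seed Optional integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(theta = 0.01, length = 5e5, n_haplotypes = 20,
                       seed = NULL) {
  stopifnot(theta > 0, length > 0, n_haplotypes >= 2)
  structure(list(theta = theta, length = length,
                 n_haplotypes = as.integer(n_haplotypes), seed = seed),
            class = "sim_config")
}

# --- internal tree machinery (times in units of 2N generations, so the
# --- pairwise coalescence rate is 1 and E[pairwise branch length] = 2) ---

.kingman_tree <- function(n) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  lineages <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  for (k in n:2) {
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
    pick <- sample(length(lineages), 2L)
    time[nxt] <- t
    parent[lineages[pick]] <- nxt
    lineages <- c(lineages[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, time = time, root = lineages, n = n)
}

.branch_lengths <- function(tr) {
  bl <- numeric(length(tr$parent))
  has_p <- tr$parent != 0L
  bl[has_p] <- tr$time[tr$parent[has_p]] - tr$time[has_p]
  bl
}

.leaves_under <- function(tr, v) {
  out <- logical(tr$n)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (x <= tr$n) out[x] <- TRUE
    else stack <- c(stack, which(tr$parent == x))
  }
  out
}

# one SMC step: cut the tree at a uniform point and re-coalesce the
# detached lineage with the remaining tree
.smc_recombine <- function(tr) {
  bl <- .branch_lengths(tr)
  b <- sample.int(length(bl), 1L, prob = bl)
  u <- tr$time[b] + stats::runif(1) * bl[b]
  p <- tr$parent[b]
  sib <- setdiff(which(tr$parent == p), b)
  gp <- tr$parent[p]
  # splice out p
  tr$parent[sib] <- gp
  tr$parent[b] <- 0L
  root <- if (p == tr$root) sib else tr$root
  # re-coalesce the floating lineage (node b, active from time u)
  node_times <- sort(unique(c(u, tr$time[tr$time > u &
                                           seq_along(tr$time) != p])))
  crossing <- function(t) {
    active <- seq_along(tr$parent)[-c(b, p)]
    has_p <- tr$parent[active] != 0L
    k <- sum(tr$time[active[has_p]] <= t &
               tr$time[tr$parent[active[has_p]]] > t)
    k + as.integer(t >= tr$time[root])
  }
  t <- u
  repeat {
    k <- crossing(t)
    nxt_bound <- node_times[node_times > t]
    nxt_bound <- if (length(nxt_bound)) nxt_bound[1] else Inf
    if (k == 0L) { t <- nxt_bound; next }
    w <- stats::rexp(1, rate = k)
    if (t + w < nxt_bound) { t <- t + w; break }
    t <- nxt_bound
  }
  # choose the partner lineage crossing time t
  active <- seq_along(tr$parent)[-c(b, p)]
  has_p <- tr$parent[active] != 0L
  cand <- active[has_p][tr$time[active[has_p]] <= t &
                          tr$time[tr$parent[active[has_p]]] > t]
  if (t >= tr$time[root]) cand <- c(cand, root)
  partner <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  # reuse node id p as the new coalescence node
  tr$time[p] <- t
  tr$parent[p] <- if (partner == root && t >= tr$time[root]) 0L
                  else tr$parent[partner]
  tr$parent[partner] <- p
  tr$parent[b] <- p
  tr$root <- if (tr$parent[p] == 0L) p else root
  tr
}

#' Simulate haplotypes under the coalescent with recombination
#'
#' Sequentially Markovian coalescent along the sequence: the genealogy at
#' the left end is a standard Kingman tree; moving rightwards, breakpoints
#' arrive at rate \eqn{\rho(x) L_T / 2} per bp (where \eqn{L_T} is the
#' total branch length of the current tree, times in units of
#' \eqn{2 N_e}), and at each breakpoint a uniformly chosen point of the
#' tree is detached and re-coalesced with the remainder. The marginal
#' genealogy at every position is exactly the Kingman coalescent, so
#' expected pairwise diversity equals \eqn{\theta} per bp. Mutations fall
#' on each constant-genealogy segment as a Poisson process of rate
#' \eqn{\theta L_T / 2} per bp, each placed uniformly on the tree; sites
#' are strictly biallelic (infinite-sites, positions rounded to unique
#' integers). Ancestral and derived bases may be assigned from a
#' [mutation_model].
#'
#' @param config A [sim_config].
#' @param map Optional [rho_map] giving \eqn{\rho(x)}; defaults to
#'   \eqn{\rho = 0} everywhere (a single genealogy). Its span is clipped
#'   to `[0, config$length]`.
#' @param model Optional [mutation_model] used to draw an ancestral base
#'   (stationary distribution) and derived base (conditional spectrum) per
#'   site; without it alleles are coded 0 (ancestral) / 1 (derived).
#' @return A list of class `sim_haplotypes`: `haplotypes` (0/1 matrix,
#'   `n_haplotypes` rows, one column per segregating site), `positions`
#'   (integer bp, strictly increasing), `bases` (tibble `ancestral`,
#'   `derived`, or `NULL`), `n_breakpoints`, `config`.
#' @export
simulate_haplotypes <- function(config, map = NULL, model = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(map)) stopifnot(inherits(map, "rho_map"))
  if (!is.null(model)) stopifnot(inherits(model, "mutation_model"))
  run <- function() .simulate_haplotypes_impl(config, map, model)
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

.simulate_haplotypes_impl <- function(config, map, model) {
  n <- config$n_haplotypes
  L <- config$length
  # cumulative-rho coordinate over [0, L]
  if (is.null(map)) {
    cum_pos <- c(0, L); cum_rho <- c(0, 0)
  } else {
    pos <- pmin(pmax(map$positions, 0), L)
    cum_pos <- pos
    cum_rho <- c(0, cumsum(map$rates * diff(pos)))
    if (cum_pos[1] > 0) {  # rho = 0 before the map starts
      cum_pos <- c(0, cum_pos); cum_rho <- c(0, cum_rho)
    }
    if (cum_pos[length(cum_pos)] < L) {
      cum_pos <- c(cum_pos, L)
      cum_rho <- c(cum_rho, cum_rho[length(cum_rho)])
    }
  }
  C_tot <- cum_rho[length(cum_rho)]
  phys_of <- function(c_val) {
    # invert the piecewise-linear cumulative map
    i <- findInterval(c_val, cum_rho, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(cum_pos) - 1L)
    dr <- cum_rho[i + 1L] - cum_rho[i]
    if (dr <= 0) return(cum_pos[i])
    cum_pos[i] + (c_val - cum_rho[i]) / dr * (cum_pos[i + 1L] - cum_pos[i])
  }
  tr <- .kingman_tree(n)
  mut_pos <- numeric(0)
  mut_carriers <- list()
  drop_mutations <- function(tr, x0, x1) {
    bl <- .branch_lengths(tr)
    lt <- sum(bl)
    n_mut <- stats::rpois(1, config$theta / 2 * lt * (x1 - x0))
    if (n_mut == 0) return()
    br <- sample.int(length(bl), n_mut, replace = TRUE, prob = bl)
    xs <- stats::runif(n_mut, x0, x1)
    for (j in seq_len(n_mut)) {
      mut_pos[[length(mut_pos) + 1L]] <<- xs[j]
      mut_carriers[[length(mut_carriers) + 1L]] <<- .leaves_under(tr, br[j])
    }
  }
  c_cur <- 0
  x_cur <- 0
  n_bp <- 0L
  repeat {
    lt <- sum(.branch_lengths(tr))
    c_next <- if (C_tot > 0) c_cur + stats::rexp(1, rate = lt / 2) else Inf
    if (c_next >= C_tot) {
      drop_mutations(tr, x_cur, L)
      break
    }
    x_next <- phys_of(c_next)
    drop_mutations(tr, x_cur, x_next)
    tr <- .smc_recombine(tr)
    n_bp <- n_bp + 1L
    c_cur <- c_next
    x_cur <- x_next
  }
  if (!length(mut_pos)) {
    return(structure(list(haplotypes = matrix(0L, n, 0L),
                          positions = integer(0), bases = NULL,
                          n_breakpoints = n_bp, config = config),
                     class = "sim_haplotypes"))
  }
  ord <- order(mut_pos)
  pos_int <- round(unlist(mut_pos[ord]))
  keep <- !duplicated(pos_int)  # infinite-sites: drop rare integer clashes
  pos_int <- pos_int[keep]
  carriers <- mut_carriers[ord][keep]
  # drop sites fixed in the sample (mutation above the whole sample)
  seg <- vapply(carriers, function(cc) any(cc) && !all(cc), logical(1))
  pos_int <- pos_int[seg]; carriers <- carriers[seg]
  haps <- matrix(0L, n, length(pos_int))
  for (j in seq_along(carriers)) haps[carriers[[j]], j] <- 1L
  bases <- NULL
  if (!is.null(model) && length(pos_int)) {
    cond <- model$matrix; diag(cond) <- 0; cond <- cond / rowSums(cond)
    anc <- sample(BASES, length(pos_int), replace = TRUE,
                  prob = model$stationary)
    der <- vapply(anc, function(a) sample(BASES, 1L, prob = cond[a, ]),
                  character(1))
    bases <- tibble::tibble(ancestral = anc, derived = unname(der))
  }
  structure(list(haplotypes = haps, positions = as.integer(pos_int),
                 bases = bases, n_breakpoints = n_bp, config = config),
            class = "sim_haplotypes")
}

#' @export
print.sim_haplotypes <- function(x, ...) {
  cat(sprintf("<sim_haplotypes> %d haplotypes x %d segregating sites, %d breakpoints\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$n_breakpoints))
  invisible(x)
}

#' Mean pairwise diversity of simulated haplotypes
#'
#' \eqn{\pi} per bp: average fraction of differing haplotype pairs per
#' site, summed over sites and divided by the sequence length. Under
#' neutral equilibrium its expectation is \eqn{\theta}.
#'
#' @param sim A `sim_haplotypes` object.
#' @return Mean pairwise diversity per bp.
#' @export
pairwise_diversity <- function(sim) {
  stopifnot(inherits(sim, "sim_haplotypes"))
  h <- sim$haplotypes
  n <- nrow(h)
  if (!ncol(h)) return(0)
  freq <- colSums(h)
  sum(freq * (n - freq)) / choose(n, 2) / sim$config$length
}

#' Write simulated haplotypes as estimator-ready text
#'
#' Emits the two plain-text files consumed by LDhat/LDhelmet-style
#' estimators: a "sites" FASTA of haplotype sequences over the segregating
#' sites and a "locs" file of their positions, plus nothing else. Requires
#' base-labelled sites (simulate with a [mutation_model]).
#'
#' @param sim A `sim_haplotypes` object with `bases`.
#' @param sites_path,locs_path Output paths.
#' @return Invisibly, the number of sites written.
#' @export
write_estimator_input <- function(sim, sites_path, locs_path) {
  stopifnot(inherits(sim, "sim_haplotypes"))
  if (is.null(sim$bases))
    stop("simulate with a mutation_model to get base-labelled sites",
         call. = FALSE)
  h <- sim$haplotypes
  seqs <- apply(h, 1, function(row)
    paste0(ifelse(row == 1L, sim$bases$derived, sim$bases$ancestral),
           collapse = ""))
  fasta <- as.vector(rbind(sprintf(">hap%d", seq_len(nrow(h))), seqs))
  writeLines(fasta, sites_path)
  writeLines(c(sprintf("%d %d L", ncol(h), sim$config$length),
               paste(sim$positions, collapse = " ")), locs_path)
  invisible(ncol(h))
}
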