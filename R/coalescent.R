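## Kingman-coalescent Monte-Carlo engine.
##
## Time unit: Ne generations with pairwise coalescence rate 1 (the haploid
## / organelle convention), so that theta = 2 Ne mu and the between- to
## within-population divergence ratio K/theta estimates the split time
## tau = t/Ne directly.

#' Configuration for the two-population coalescent
#'
#' @param tau Divergence time between the two populations, in Ne
#'   generations (dimensionless; `tau >= 0`).
#' @param n1,n2 Focal sample sizes per population (`>= 1`).
#' @param background Lineages per population standing in for "the whole
#'   population" when assessing population-level reciprocal monophyly;
#'   must be `>= max(n1, n2)`. Default 100.
#' @param theta 2*Ne*mu per site (used by the sequence simulator).
#' @param L Number of sites.
#' @param replicates Number of Monte-Carlo replicates.
#' @param seed Optional integer seed.
#' @return A validated list of class `coalescent_config`.
#' @export
coalescent_config <- function(tau, n1, n2, background = 100, theta = 0.01,
                              L = 500, replicates = 1, seed = NULL) {
  if (tau < 0) stop("tau must be >= 0")
  if (n1 < 1 || n2 < 1) stop("sample sizes must be >= 1")
  if (background < max(n1, n2))
    stop("background must be >= max(n1, n2)")
  if (replicates < 1) stop("replicates must be >= 1")
  if (theta < 0) stop("theta must be >= 0")
  if (L < 1) stop("L must be >= 1")
  structure(list(tau = tau, n1 = n1, n2 = n2, background = background,
                 theta = theta, L = L, replicates = replicates, seed = seed),
            class = "coalescent_config")
}

#' Simulate times to the most recent common ancestor
#'
#' Each replicate draws the single-population coalescent TMRCA for a
#' sample of `n` lineages as the sum of exponential epochs
#' `T_k ~ Exp(k (k - 1) / 2)`, `k = n..2`, in Ne-generation units. The
#' exact expectation is `2 (1 - 1/n)`.
#'
#' @param n Sample size (`>= 2`).
#' @param replicates Number of replicates.
#' @param seed Optional integer seed.
#' @return Numeric vector of TMRCA values (Ne generations).
#' @export
sample_tmrca <- function(n, replicates, seed = NULL) {
  if (n < 2) stop("TMRCA requires n >= 2")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  k <- n:2
  rates <- k * (k - 1) / 2
  colSums(matrix(stats::rexp((n - 1) * replicates, rates), nrow = n - 1))
}

## uniform pair index m in [0, k(k-1)/2) -> (i, j), 1 <= i < j <= k;
## identical to the C++ engine's mapping
pair_from_index <- function(m, k) {
  off <- 0L
  for (i in seq_len(k - 1L)) {
    block <- k - i
    if (m < off + block) return(c(i, i + 1L + (m - off)))
    off <- off + block
  }
  c(k - 1L, k)
}

## one coalescent phase on a set of lineages represented by an arbitrary
## state list; `merge_fun(state, i, j, t)` must merge j into i and return
## the state. Mirrors the C++ engine's RNG draw order exactly
## (one exponential, then one uniform per merge).
coalesce_phase <- function(state, k, tmax, merge_fun, t0 = 0) {
  t <- t0
  while (k > 1L) {
    rate <- k * (k - 1) / 2
    t <- t + stats::rexp(1L, rate)
    if (t > tmax) break
    npairs <- k * (k - 1) / 2
    m <- floor(stats::runif(1L) * npairs)
    if (m >= npairs) m <- npairs - 1
    ij <- pair_from_index(m, k)
    state <- merge_fun(state, ij[1L], ij[2L], t)
    k <- k - 1L
  }
  list(state = state, k = k, t = t)
}

#' Simulate a two-population genealogy
#'
#' Each population starts with `background` lineages; lineages coalesce
#' within their population until time `tau` (Ne generations), after which
#' the survivors coalesce in the merged ancestral population. Tips of
#' population 1 are labelled `A1, A2, ...`, population 2 `B1, B2, ...`;
#' the first `n1` / `n2` of each are the focal samples.
#'
#' @param config A [coalescent_config()].
#' @return A rooted, ultrametric `phylo` tree with branch lengths in Ne
#'   generations and attributes `populations` (named tip-to-population
#'   vector), `focal` (focal tip labels) and `tmrca` (root time).
#' @export
two_population_genealogy <- function(config) {
  stopifnot(inherits(config, "coalescent_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  B <- config$background
  fmt <- function(x) sprintf("%.12g", x)
  make_state <- function(labels) list(frag = labels, time = rep(0, length(labels)))
  merge_frag <- function(st, i, j, t) {
    st$frag[i] <- paste0("(", st$frag[i], ":", fmt(t - st$time[i]), ",",
                         st$frag[j], ":", fmt(t - st$time[j]), ")")
    st$time[i] <- t
    keep <- seq_along(st$frag) != j
    st$frag <- st$frag[keep]; st$time <- st$time[keep]
    st
  }
  p1 <- coalesce_phase(make_state(paste0("A", seq_len(B))), B, config$tau, merge_frag)
  p2 <- coalesce_phase(make_state(paste0("B", seq_len(B))), B, config$tau, merge_frag)
  st <- list(frag = c(p1$state$frag, p2$state$frag),
             time = c(p1$state$time, p2$state$time))
  anc <- coalesce_phase(st, p1$k + p2$k, Inf, merge_frag, t0 = config$tau)
  phy <- ape::read.tree(text = paste0(anc$state$frag[1L], ";"))
  attr(phy, "populations") <- stats::setNames(
    rep(c("pop1", "pop2"), each = B), c(paste0("A", seq_len(B)), paste0("B", seq_len(B))))
  attr(phy, "focal") <- c(paste0("A", seq_len(config$n1)),
                          paste0("B", seq_len(config$n2)))
  attr(phy, "tmrca") <- if (p1$k + p2$k > 1L) anc$state$time[1L] else
    max(p1$state$time, p2$state$time)
  phy
}

#' Reciprocal monophyly of two tip sets
#'
#' TRUE iff, in the tree restricted to the union of the two sets, each
#' set's MRCA subtree contains no tip of the other. A singleton set is
#' monophyletic by convention.
#'
#' @param genealogy A rooted `phylo` tree.
#' @param tips_a,tips_b Disjoint, non-empty character vectors of tip
#'   labels.
#' @return Logical scalar.
#' @export
reciprocal_monophyly <- function(genealogy, tips_a, tips_b) {
  if (length(tips_a) == 0L || length(tips_b) == 0L)
    stop("tip subsets must be non-empty")
  if (length(intersect(tips_a, tips_b)) > 0L)
    stop("tip subsets must be disjoint")
  sub <- ape::keep.tip(genealogy, c(tips_a, tips_b))
  mono <- function(tp) length(tp) == 1L || ape::is.monophyletic(sub, tp)
  mono(tips_a) && mono(tips_b)
}

## pure-R reference for the C++ engine: same model, same RNG draw order.
## Returns a logical matrix (replicates x 2): sample RM, population RM.
r_two_pop_rm <- function(n1, n2, B, tau, reps) {
  one <- function() {
    mono <- new.env(parent = emptyenv())
    mono$A <- n1 <= 1; mono$B <- n2 <= 1
    mono$P1 <- B <= 1; mono$P2 <- B <= 1
    mono$dA <- mono$A; mono$dB <- mono$B; mono$dP1 <- mono$P1; mono$dP2 <- mono$P2
    observe <- function(row) {
      if (!mono$dA && row[3L] == n1) { mono$A <- row[4L] == 0; mono$dA <- TRUE }
      if (!mono$dB && row[4L] == n2) { mono$B <- row[3L] == 0; mono$dB <- TRUE }
      if (!mono$dP1 && row[1L] == B) { mono$P1 <- row[2L] == 0; mono$dP1 <- TRUE }
      if (!mono$dP2 && row[2L] == B) { mono$P2 <- row[1L] == 0; mono$dP2 <- TRUE }
    }
    merge_counts <- function(st, i, j, t) {
      st[i, ] <- st[i, ] + st[j, ]
      observe(st[i, ])
      st[-j, , drop = FALSE]
    }
    s1 <- cbind(1, 0, as.integer(seq_len(B) <= n1), 0)
    p1 <- coalesce_phase(s1, B, tau, merge_counts)
    s2 <- cbind(0, 1, 0, as.integer(seq_len(B) <= n2))
    p2 <- coalesce_phase(s2, B, tau, merge_counts)
    st <- rbind(p1$state, p2$state)
    coalesce_phase(st, p1$k + p2$k, Inf, merge_counts)
    c(mono$A && mono$B, mono$P1 && mono$P2)
  }
  t(vapply(seq_len(reps), function(i) one(), logical(2L)))
}

#' Conditional probability of population-level reciprocal monophyly
#'
#' Monte-Carlo estimate of the probability that two whole populations
#' (approximated by `background` lineages each) are reciprocally
#' monophyletic, given that the focal samples of sizes `n1` and `n2` are.
#' This is the quantity that justifies calling samples that pass the
#' 4x test distinct species with ~95% confidence.
#'
#' @param tau Divergence time in Ne generations.
#' @param n1,n2 Focal sample sizes.
#' @param background Background lineages per population (default 100).
#'   Finite background can only overestimate the population-level
#'   probability; check sensitivity by doubling it.
#' @param replicates Monte-Carlo replicates (default 1e5).
#' @param seed Optional integer seed.
#' @param conf.level Confidence level of the Clopper-Pearson interval.
#' @return A list with `p_sample_rm` (probability that the samples are
#'   reciprocally monophyletic), `p_pop_rm_given_sample_rm`, `ci`
#'   (Clopper-Pearson interval for the conditional probability),
#'   `n_conditioned` and `replicates`.
#' @export
conditional_rm_probability <- function(tau, n1, n2, background = 100,
                                       replicates = 1e5, seed = NULL,
                                       conf.level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_two_pop_rm(n1, n2, background, tau, as.integer(replicates))
  sample_rm <- res[, 1L]
  n_cond <- sum(sample_rm)
  if (n_cond == 0L)
    stop("no replicate satisfied the conditioning event; ",
         "increase replicates or tau")
  if (n_cond < 100L)
    warning("only ", n_cond, " replicates satisfied the conditioning event; ",
            "the conditional estimate is imprecise")
  x <- sum(res[sample_rm, 2L])
  ci <- as.numeric(stats::binom.test(x, n_cond,
                                     conf.level = conf.level)$conf.int)
  list(p_sample_rm = mean(sample_rm),
       p_pop_rm_given_sample_rm = x / n_cond,
       ci = ci, n_conditioned = n_cond,
       replicates = as.integer(replicates))
}

#' Evolve sequences along a genealogy
#'
#' Places mutations on branches as a Poisson process with per-site rate
#' `theta / 2` per Ne generation and applies Jukes-Cantor site evolution
#' over A, C, G, T, so the expected within-population pairwise difference
#' is approximately `theta` (before saturation).
#'
#' @param genealogy A rooted `phylo` tree with branch lengths in Ne
#'   generations.
#' @param theta 2*Ne*mu per site (`>= 0`).
#' @param L Number of sites (`>= 1`).
#' @param seed Optional integer seed.
#' @return An [aligned_seqs] object with one sequence per tip.
#' @export
simulate_sequences <- function(genealogy, theta, L, seed = NULL) {
  if (theta < 0) stop("theta must be >= 0")
  if (L < 1) stop("L must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  phy <- stats::reorder(genealogy, "cladewise")
  n <- length(phy$tip.label)
  nnode <- phy$Nnode
  seqs <- matrix(NA_integer_, n + nnode, L)
  root <- n + 1L
  seqs[root, ] <- sample.int(4L, L, replace = TRUE)
  rate <- theta / 2
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    s <- seqs[p, ]
    nmut <- stats::rpois(1L, rate * L * phy$edge.length[e])
    if (nmut > 0L) {
      sites <- sample.int(L, nmut, replace = TRUE)
      steps <- sample.int(3L, nmut, replace = TRUE)
      for (mi in seq_len(nmut)) {
        s[sites[mi]] <- (s[sites[mi]] - 1L + steps[mi]) %% 4L + 1L
      }
    }
    seqs[ch, ] <- s
  }
  m <- matrix(c("A", "C", "G", "T")[seqs[seq_len(n), , drop = FALSE]], n, L)
  rownames(m) <- phy$tip.label
  aligned_seqs(m)
}

#' Simulate a two-population alignment fixture
#'
#' Convenience wrapper: draws a two-population genealogy, evolves
#' sequences along it, and returns the alignment restricted to the focal
#' samples together with the true species partition.
#'
#' @param n1,n2 Focal sample sizes.
#' @param tau Divergence time in Ne generations.
#' @param theta 2*Ne*mu per site.
#' @param L Number of sites.
#' @param seed Optional integer seed.
#' @param background Lineages per population (default `max(n1, n2)`,
#'   i.e. the populations are fully sampled).
#' @return A list with `aln` ([aligned_seqs] of the focal tips), `truth`
#'   (data frame mapping tip id to population), and `genealogy`.
#' @export
simulate_two_population_alignment <- function(n1, n2, tau, theta, L,
                                              seed = NULL,
                                              background = max(n1, n2)) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- coalescent_config(tau = tau, n1 = n1, n2 = n2,
                           background = background, theta = theta, L = L)
  phy <- two_population_genealogy(cfg)
  aln_full <- simulate_sequences(phy, theta, L)
  focal <- attr(phy, "focal")
  aln <- aligned_seqs(aln_full$seqs[focal, , drop = FALSE])
  truth <- data.frame(id = focal,
                      population = ifelse(grepl("^A", focal), "pop1", "pop2"),
                      stringsAsFactors = FALSE)
  list(aln = aln, truth = truth, genealogy = phy)
}
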