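# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except files the tests write themselves.

# a kdist object from a plain D matrix (K = model-corrected D)
make_kd <- function(D, L = 591, model = "JC") {
  ids <- rownames(D)
  if (is.null(ids)) {
    ids <- paste0("t", seq_len(nrow(D)))
    dimnames(D) <- list(ids, ids)
  }
  K <- apply(D, c(1, 2), function(x) correct_distance(x, model))
  dimnames(K) <- dimnames(D)
  ktheta:::kdist_from_matrices(D = D, K = K, L = L, model = model)
}

# symmetric matrix from the upper triangle given row-wise
sym_matrix <- function(n, upper, ids = paste0("t", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- upper
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# alignment of two blocks: identical within, differing at `ndiff` of L
# sites between blocks
block_alignment <- function(n1 = 3, n2 = 3, L = 100, ndiff = 20) {
  s1 <- rep("A", L)
  s2 <- s1
  s2[seq_len(ndiff)] <- "G"
  m <- rbind(matrix(rep(s1, n1), nrow = n1, byrow = TRUE),
             matrix(rep(s2, n2), nrow = n2, byrow = TRUE))
  rownames(m) <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
  aligned_seqs(m)
}

# random alignment via the coalescent simulator (single population)
random_alignment <- function(n = 6, theta = 0.01, L = 300, seed = 1) {
  sim <- simulate_two_population_alignment(
    n1 = ceiling(n / 2), n2 = floor(n / 2), tau = 0,
    theta = theta, L = L, seed = seed)
  sim$aln
}

expect_setequal_partition <- function(partition, expected_sets) {
  got <- unname(lapply(partition$species, sort))
  exp <- lapply(expected_sets, sort)
  expect_true(length(got) == length(exp) &&
                all(vapply(exp, function(s)
                  any(vapply(got, identical, logical(1), s)), logical(1))))
}
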