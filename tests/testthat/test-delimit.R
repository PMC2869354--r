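test_that("the multiplier table follows the sample-size rules", {
  expect_equal(multiplier_for(3, 2), 4.0)
  expect_equal(multiplier_for(2, 3), 4.0)   # order-normalized
  expect_equal(multiplier_for(10, 7), 4.0)
  expect_equal(multiplier_for(5, 1), 4.0)
  expect_equal(multiplier_for(2, 2), 4.1)
  expect_equal(multiplier_for(4, 1), 4.3)
  expect_equal(multiplier_for(2, 1), 4.3)
  expect_warning(m <- multiplier_for(1, 1), "low power")
  expect_equal(m, 4.3)
  expect_error(multiplier_for(0, 1))
})

test_that("the Lumbriculus worked example gives ratio ~13.4, distinct", {
  # two clades of 23 and 7; printed within-clade diversities 0.6% and
  # 1.3%, uncorrected between-clade difference 17.7%
  n1 <- 23; n2 <- 7
  ids <- c(paste0("I", seq_len(n1)), paste0("II", seq_len(n2)))
  D <- matrix(0.177, n1 + n2, n1 + n2, dimnames = list(ids, ids))
  a <- seq_len(n1); b <- n1 + seq_len(n2)
  # within-clade distances chosen so pi comes out at the printed values
  D[a, a] <- 0.006 * (n1 - 1) / n1
  D[b, b] <- 0.013 * (n2 - 1) / n2
  diag(D) <- 0
  kd <- ktheta:::kdist_from_matrices(D = D, K = D, L = 591, model = "none")
  dec <- ktheta_test(clade_diversity(kd, ids[a]), clade_diversity(kd, ids[b]), kd)
  expect_equal(dec$theta_used, 0.0132293, tolerance = 1e-5)
  expect_equal(dec$ratio, 0.177 / 0.0132293, tolerance = 1e-4)
  expect_equal(dec$ratio, 13.379, tolerance = 1e-3)
  expect_equal(dec$multiplier, 4.0)
  expect_equal(dec$verdict, "distinct")
})

test_that("verdicts use strict inequality against the multiplier", {
  mk <- function(n1, n2, K, theta) {
    ids <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
    D <- matrix(K, n1 + n2, n1 + n2, dimnames = list(ids, ids))
    a <- seq_len(n1); b <- n1 + seq_len(n2)
    pi <- theta / (1 + 4 * theta / 3)     # invert theta_from_pi
    D[a, a] <- pi * (n1 - 1) / n1
    if (n2 > 1) D[b, b] <- pi * (n2 - 1) / n2
    diag(D) <- 0
    kd <- ktheta:::kdist_from_matrices(D = D, K = D, L = 591, model = "none")
    ktheta_test(clade_diversity(kd, ids[a]), clade_diversity(kd, ids[b]), kd)
  }
  # ratio 3.9 <= 4.0 at (3, 2) -> merged
  d1 <- mk(3, 2, K = 0.039, theta = 0.01)
  expect_equal(d1$ratio, 3.9, tolerance = 1e-9)
  expect_equal(d1$verdict, "merged")
  # ratio 4.05 <= 4.1 at (2, 2) -> merged
  d2 <- mk(2, 2, K = 0.0405, theta = 0.01)
  expect_equal(d2$multiplier, 4.1)
  expect_equal(d2$verdict, "merged")
  # just above the threshold -> distinct
  d3 <- mk(3, 2, K = 0.0401, theta = 0.01)
  expect_equal(d3$verdict, "distinct")
})

test_that("singleton pairs are undecidable unless the floor fallback is on", {
  D <- sym_matrix(2, 0.2, ids = c("a", "b"))
  kd <- make_kd(D, L = 591)
  da <- clade_diversity(kd, "a"); db <- clade_diversity(kd, "b")
  expect_error(ktheta_test(da, db, kd), "undecidable")
  dec <- ktheta_test(da, db, kd, singlet_fallback = TRUE)
  expect_equal(dec$theta_used, theta_from_pi(2 / (591 * 2)))
  expect_true(dec$low_power)
  expect_equal(dec$verdict, "distinct")
})

test_that("delimit splits a balanced 4-tip tree across a deep gap", {
  ids <- c("a1", "a2", "b1", "b2")
  D <- matrix(0.20, 4, 4, dimnames = list(ids, ids))
  D[1:2, 1:2] <- 0.01; D[3:4, 3:4] <- 0.01
  diag(D) <- 0
  kd <- make_kd(D, L = 100)  # at L = 100 the within-pair floor test merges
  tr <- ape::read.tree(text = "((a1:0.005,a2:0.005):0.095,(b1:0.005,b2:0.005):0.095);")
  part <- delimit(tr, kd)
  expect_setequal_partition(part, list(c("a1", "a2"), c("b1", "b2")))
  top <- part$decisions[part$decisions$n1 == 2 & part$decisions$n2 == 2, ]
  expect_equal(top$ratio, correct_distance(0.2, "JC") / theta_from_pi(0.02),
               tolerance = 1e-6)
  expect_true(top$ratio > 4.1 && top$verdict == "distinct")
})

test_that("delimit merges everything when no test can pass", {
  ids <- paste0("t", 1:6)
  D <- matrix(0.005, 6, 6, dimnames = list(ids, ids))
  diag(D) <- 0
  kd <- make_kd(D, L = 591)
  tr <- neighbor_joining(kd)
  part <- delimit(tr, kd)
  expect_length(part$species, 1L)
  expect_setequal(part$species[[1L]], ids)
  expect_true(all(part$decisions$verdict == "merged"))
})

test_that("a deep star polytomy yields flagged singlet species", {
  ids <- c("a", "b", "c")
  D <- sym_matrix(3, rep(0.2, 3), ids = ids)
  kd <- make_kd(D, L = 591)
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  part <- delimit(tr, kd)
  expect_length(part$species, 3L)
  expect_true(all(lengths(part$species) == 1L))
  expect_true(any(part$decisions$theta_source == "singlet fallback"))
  expect_true(all(part$decisions$verdict == "distinct"))
})

test_that("every tip lands in exactly one species on random inputs", {
  for (seed in 1:8) {
    sim <- simulate_two_population_alignment(4, 4, tau = seed %% 5,
                                             theta = 0.02, L = 300,
                                             seed = seed)
    kd <- distance_matrix(sim$aln, model = "JC")
    tr <- bootstrap_support(sim$aln, replicates = 30, seed = seed + 100)
    part <- delimit(tr, kd, sim$aln)
    tips <- unlist(part$species, use.names = FALSE)
    expect_setequal(tips, sim$aln$ids)
    expect_equal(length(tips), length(unique(tips)))
    labs <- partition_labels(part)
    expect_setequal(names(labs), sim$aln$ids)
  }
})

test_that("raising the multiplier never increases the species count", {
  for (seed in c(2, 5, 9)) {
    sim <- simulate_two_population_alignment(5, 5, tau = 6, theta = 0.02,
                                             L = 300, seed = seed)
    kd <- distance_matrix(sim$aln, model = "JC")
    tr <- bootstrap_support(sim$aln, replicates = 30, seed = seed + 50)
    n_lo <- length(delimit(tr, kd, multiplier = 4)$species)
    n_hi <- length(delimit(tr, kd, multiplier = 8)$species)
    expect_lte(n_hi, n_lo)
  }
})

test_that("delimit is deterministic and validates its inputs", {
  sim <- simulate_two_population_alignment(3, 3, tau = 8, theta = 0.01,
                                           L = 400, seed = 4)
  kd <- distance_matrix(sim$aln, model = "JC")
  tr <- bootstrap_support(sim$aln, replicates = 30, seed = 7)
  p1 <- delimit(tr, kd)
  p2 <- delimit(tr, kd)
  expect_identical(p1$species, p2$species)
  expect_identical(p1$decisions, p2$decisions)
  bad <- ape::rtree(4)
  expect_error(delimit(bad, kd), "do not match")
})

test_that("pairwise histograms bin, split and conserve counts", {
  ids <- paste0("t", 1:3)
  kd0 <- make_kd(sym_matrix(3, rep(0, 3), ids = ids), model = "none")
  h0 <- pairwise_histogram(kd0)
  expect_equal(h0$count[1], 3L)
  expect_equal(sum(h0$count), 3L)

  kd1 <- make_kd(sym_matrix(3, c(0.005, 0.015, 0.25), ids = ids),
                 model = "none")
  h1 <- pairwise_histogram(kd1, bin_width = 0.01)
  expect_equal(h1$count[c(1, 2, 26)], c(1L, 1L, 1L))
  expect_equal(sum(h1$count), 3L)
  expect_error(pairwise_histogram(kd1, bin_width = 0), "positive")

  part_labels <- stats::setNames(c("x", "x", "y"), ids)
  h2 <- pairwise_histogram(kd1, bin_width = 0.01, partition = part_labels)
  expect_equal(sum(h2$within), 1L)
  expect_equal(sum(h2$between), 2L)
  expect_equal(h2$within + h2$between, h2$count)
})

test_that("lineages-through-time counts are correct on known trees", {
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  lt <- lineages_through_time(bal)
  expect_equal(lt$lineages, c(2L, 4L))
  expect_equal(lt$time, c(0, 1))

  cat4 <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);")
  lt2 <- lineages_through_time(cat4)
  expect_equal(lt2$lineages, c(2L, 3L, 4L))
  expect_true(all(diff(lt2$time) > 0))

  phy <- two_population_genealogy(
    coalescent_config(tau = 2, n1 = 3, n2 = 3, background = 3, seed = 11))
  lt3 <- lineages_through_time(phy)
  expect_equal(lt3$lineages[length(lt3$lineages)], 6L)
  expect_true(all(diff(lt3$lineages) >= 0))

  noel <- ape::read.tree(text = "((a,b),c);")
  expect_error(lineages_through_time(noel), "branch lengths")
})

test_that("partition outputs round-trip to disk", {
  sim <- simulate_two_population_alignment(3, 3, tau = 10, theta = 0.01,
                                           L = 400, seed = 21)
  kd <- distance_matrix(sim$aln, model = "JC")
  tr <- bootstrap_support(sim$aln, replicates = 30, seed = 22)
  part <- delimit(tr, kd)
  d <- tempfile(); dir.create(d)
  write_species_partition_tsv(part, file.path(d, "sp.tsv"))
  write_decision_log_tsv(part, file.path(d, "dec.tsv"))
  write_annotated_newick(part, file.path(d, "sp.nwk"))
  sp <- read.delim(file.path(d, "sp.tsv"))
  expect_setequal(sp$tip_id, sim$aln$ids)
  dec <- read.delim(file.path(d, "dec.tsv"))
  expect_true(all(dec$verdict %in% c("distinct", "merged")))
  ann <- ape::read.tree(file.path(d, "sp.nwk"))
  expect_true(all(grepl("\\|sp\\d+", ann$tip.label)))
})
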