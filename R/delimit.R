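## The K/theta (4x) decision rule and the recursive delimitation procedure.

#' Sample-size-adjusted multiplier for the K/theta test
#'
#' Returns the multiplier m such that two sister clades are called distinct
#' species when K/theta > m, given the two sample sizes (order does not
#' matter). The thresholds encode the conditional reciprocal-monophyly
#' probabilities for small samples: 4.0 for samples of (>=3, >=2) or
#' (>=5, 1); 4.1 for (2, 2); 4.3 for (2-4, 1). Two singletons (1, 1) also
#' use 4.3 but carry essentially no information; a low-power warning is
#' emitted.
#'
#' @param n1,n2 Sample sizes of the two clades (positive integers).
#' @return The multiplier: 4.0, 4.1 or 4.3.
#' @export
multiplier_for <- function(n1, n2) {
  if (n1 < 1 || n2 < 1) stop("sample sizes must be >= 1")
  lo <- min(n1, n2); hi <- max(n1, n2)
  if (lo >= 2) {
    if (hi >= 3) return(4.0)
    return(4.1)                      # (2, 2)
  }
  # lo == 1
  if (hi >= 5) return(4.0)
  if (hi >= 2) return(4.3)           # (2-4, 1)
  warning("both clades are singletons: the K/theta test has very low power")
  4.3                                # (1, 1)
}

#' K/theta test between two clades
#'
#' Computes the mean corrected between-clade divergence `K`, the theta of
#' the sisters (the larger of the two defined values), the sample-size
#' multiplier, and the verdict: `"distinct"` iff `K/theta` strictly
#' exceeds the multiplier. The uncorrected ratio `D/theta` is reported
#' alongside for transparency.
#'
#' When both clades are singletons no theta is defined; by default this is
#' an error. With `singlet_fallback = TRUE` the zero-diversity floor
#' `pi = 2/(L * 2 * 1)` for the would-be merged pair is used instead and
#' the decision is flagged.
#'
#' @param div_a,div_b [clade_diversity()] summaries of the two clades
#'   (disjoint tip sets, all present in `kd`).
#' @param kd A `kdist` object holding the pairwise distances.
#' @param multiplier Optional numeric override of the multiplier table
#'   (used for sensitivity analyses).
#' @param singlet_fallback Resolve singleton-vs-singleton comparisons with
#'   the zero-diversity floor instead of erroring (default FALSE).
#' @return An object of class `ktheta_decision` (a list; see fields in
#'   the decision log produced by [delimit()]).
#' @export
ktheta_test <- function(div_a, div_b, kd, multiplier = NULL,
                        singlet_fallback = FALSE) {
  ta <- div_a$tip_ids; tb <- div_b$tip_ids
  if (length(intersect(ta, tb)) > 0L)
    stop("clades must have disjoint tip sets")
  thetas <- c(a = div_a$theta, b = div_b$theta)
  theta_source <- "larger sister"
  low_power <- FALSE
  if (all(is.na(thetas))) {
    if (!singlet_fallback)
      stop("both clades are singletons: theta is undecidable (no within-clade pairs)")
    theta_used <- theta_from_pi(2 / (kd$L * 2 * 1))
    theta_source <- "singlet fallback"
    low_power <- TRUE
  } else {
    theta_used <- max(thetas, na.rm = TRUE)
    theta_source <- if (is.na(thetas["a"])) "b"
                    else if (is.na(thetas["b"])) "a"
                    else if (thetas["a"] >= thetas["b"]) "a" else "b"
  }
  n1 <- max(div_a$n, div_b$n); n2 <- min(div_a$n, div_b$n)
  m <- if (!is.null(multiplier)) multiplier
       else suppressWarnings(multiplier_for(n1, n2))
  if (n1 == 1 && n2 == 1) low_power <- TRUE
  K_between <- mean_between(kd, ta, tb, "K")
  D_between <- mean_between(kd, ta, tb, "D")
  ratio <- K_between / theta_used
  structure(list(
    clade_a_tips = ta, clade_b_tips = tb,
    n1 = n1, n2 = n2,
    theta_used = theta_used, theta_source = theta_source,
    D_between = D_between, K_between = K_between,
    multiplier = m,
    ratio = ratio, ratio_D = D_between / theta_used,
    low_power = low_power,
    verdict = if (ratio > m) "distinct" else "merged"
  ), class = "ktheta_decision")
}

#' @export
print.ktheta_decision <- function(x, ...) {
  cat(sprintf("K/theta test: K = %.5g, theta = %.5g, ratio = %.3g %s %.3g -> %s\n",
              x$K_between, x$theta_used, x$ratio,
              if (x$verdict == "distinct") ">" else "<=",
              x$multiplier, x$verdict))
  invisible(x)
}

decision_row <- function(dec, note = "") {
  data.frame(
    clade_a = paste(sort(dec$clade_a_tips), collapse = ","),
    clade_b = paste(sort(dec$clade_b_tips), collapse = ","),
    n1 = dec$n1, n2 = dec$n2,
    theta_used = dec$theta_used, theta_source = dec$theta_source,
    D = dec$D_between, K = dec$K_between,
    multiplier = dec$multiplier,
    ratio = dec$ratio, ratio_D = dec$ratio_D,
    low_power = dec$low_power,
    verdict = dec$verdict,
    note = note,
    stringsAsFactors = FALSE
  )
}

#' Delimit evolutionary-genetic species on a supported tree
#'
#' Applies the K/theta rule recursively over a (support-collapsed, rooted)
#' tree. The traversal is post-order: at each internal node, child clades
#' that are still single candidates are tested against the sibling clade
#' with the smallest mean corrected divergence `K` (for a binary node,
#' simply the sister). A failing test merges the two clades into one
#' candidate whose diversity is recomputed over the union; a passing test
#' fixes both sides as species. Once a subtree contains established
#' species, candidates meeting it are tested against (and, on failure,
#' absorbed into) its nearest species component. Singleton-vs-singleton
#' comparisons are decided with the zero-diversity floor and flagged as
#' low power.
#'
#' Unrooted input trees are midpoint rooted; if the tree carries bootstrap
#' support labels, edges below `support_threshold` are collapsed first so
#' unsupported structure cannot create species.
#'
#' @param tree A `phylo` tree whose tips match `kd$ids`; typically from
#'   [bootstrap_support()] or [read_support_newick()].
#' @param kd A `kdist` object (use a corrected model, e.g. `"JC"`, so the
#'   `K` matrix is meaningful).
#' @param aln Optional [aligned_seqs] object (used only to cross-check the
#'   tip set).
#' @param support_threshold Bootstrap support below which internal edges
#'   are collapsed (default 0.7).
#' @param multiplier Optional numeric override applied to every test
#'   (sensitivity analyses; default NULL = sample-size table).
#' @return An object of class `species_partition`: a list with `species`
#'   (named list of tip-id vectors), `diversity` (per-species
#'   [clade_diversity()]), `decisions` (the decision log as a data frame),
#'   and `tree` (the collapsed rooted tree used).
#' @export
delimit <- function(tree, kd, aln = NULL, support_threshold = 0.7,
                    multiplier = NULL) {
  if (!setequal(tree$tip.label, kd$ids))
    stop("tree tips and distance-matrix ids do not match")
  if (!is.null(aln) && !setequal(aln$ids, kd$ids))
    stop("alignment ids and distance-matrix ids do not match")
  if (!ape::is.rooted(tree)) tree <- root_tree(tree, "midpoint")
  if (!is.null(support_values(tree)))
    tree <- collapse_low_support(tree, support_threshold)
  n <- length(tree$tip.label)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  note_log <- function(dec, note) {
    log_env$rows[[length(log_env$rows) + 1L]] <- decision_row(dec, note)
  }

  # a unit is list(tips, locked); locked units are established species
  rec <- function(v) {
    kids <- children[[as.character(v)]]
    if (is.null(kids)) {
      return(list(list(tips = tree$tip.label[v], locked = FALSE)))
    }
    units <- list()
    origin_candidate <- logical(0)
    for (k in kids) {
      ku <- rec(k)
      resolved <- length(ku) > 1L || ku[[1L]]$locked
      for (u in ku) {
        if (resolved) u$locked <- TRUE
        units[[length(units) + 1L]] <- u
        origin_candidate <- c(origin_candidate, !resolved)
      }
    }
    alive <- rep(TRUE, length(units))
    tested <- character(0)
    for (i in seq_along(units)) {
      if (!origin_candidate[i] || !alive[i]) next
      others <- which(alive & seq_along(units) != i)
      if (length(others) == 0L) next
      # sibling with the smallest mean corrected divergence K;
      # ties broken by the lexicographically smallest first tip label
      kmeans <- vapply(others, function(j)
        mean_between(kd, units[[i]]$tips, units[[j]]$tips, "K"), numeric(1))
      firsts <- vapply(others, function(j) min(units[[j]]$tips), character(1))
      j <- others[order(kmeans, firsts)][1L]
      pkey <- paste(sort(c(i, j)), collapse = "|")
      if (pkey %in% tested) next
      tested <- c(tested, pkey)
      dec <- ktheta_test(clade_diversity(kd, units[[i]]$tips),
                         clade_diversity(kd, units[[j]]$tips),
                         kd, multiplier = multiplier,
                         singlet_fallback = TRUE)
      note <- if (length(kids) > 2L) "polytomy: smallest-K sibling" else ""
      if (units[[j]]$locked) note <- paste0(note,
        if (nzchar(note)) "; " else "", "tested against established species")
      note_log(dec, note)
      if (dec$verdict == "merged") {
        units[[j]]$tips <- c(units[[j]]$tips, units[[i]]$tips)
        alive[i] <- FALSE
      }
    }
    out <- units[alive]
    if (length(out) > 1L)
      out <- lapply(out, function(u) { u$locked <- TRUE; u })
    out
  }

  units <- rec(n + 1L)
  # stable species labels by first-tip order along the tree
  first_pos <- vapply(units, function(u)
    min(match(u$tips, tree$tip.label)), numeric(1))
  units <- units[order(first_pos)]
  labels <- sprintf("sp%02d", seq_along(units))
  species <- stats::setNames(lapply(units, function(u)
    sort(u$tips)), labels)
  diversity <- stats::setNames(lapply(species, function(tp)
    clade_diversity(kd, tp)), labels)
  decisions <- if (length(log_env$rows) > 0L)
    do.call(rbind, log_env$rows) else decision_row_empty()
  structure(list(species = species, diversity = diversity,
                 decisions = decisions, tree = tree, L = kd$L),
            class = "species_partition")
}

decision_row_empty <- function() {
  data.frame(clade_a = character(0), clade_b = character(0),
             n1 = integer(0), n2 = integer(0),
             theta_used = numeric(0), theta_source = character(0),
             D = numeric(0), K = numeric(0), multiplier = numeric(0),
             ratio = numeric(0), ratio_D = numeric(0),
             low_power = logical(0), verdict = character(0),
             note = character(0), stringsAsFactors = FALSE)
}

#' @export
print.species_partition <- function(x, ...) {
  ns <- lengths(x$species)
  cat(sprintf("species_partition: %d species (%d singlets) over %d tips\n",
              length(x$species), sum(ns == 1L), sum(ns)))
  for (lab in names(x$species)) {
    cat(sprintf("  %s (n = %d): %s\n", lab, ns[[lab]],
                paste(x$species[[lab]], collapse = ", ")))
  }
  invisible(x)
}

#' Tip-to-species assignment of a partition
#'
#' @param partition A `species_partition`.
#' @return Named character vector mapping tip id to species label.
#' @export
partition_labels <- function(partition) {
  labs <- rep(names(partition$species), lengths(partition$species))
  stats::setNames(labs, unlist(partition$species, use.names = FALSE))
}

#' Histogram of pairwise differences
#'
#' Bins the uncorrected pairwise distances into half-open bins
#' `[k*w, (k+1)*w)`. A strongly bimodal histogram (a "barcode gap") is the
#' expected signature of distinct species: a within-species mode near
#' theta and a between-species mode much deeper. When a partition is
#' supplied, counts are split into within- and between-species pairs.
#'
#' @param kd A `kdist` object.
#' @param bin_width Bin width as a fraction (default 0.01 = 1% bins).
#' @param partition Optional `species_partition` (or named tip-to-label
#'   vector) used to split the counts.
#' @return A data frame with `bin_low`, `bin_high`, `count` and, when a
#'   partition is given, `within` and `between`.
#' @export
pairwise_histogram <- function(kd, bin_width = 0.01, partition = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  ut <- upper.tri(kd$D)
  vals <- kd$D[ut]
  bins <- floor(vals / bin_width)
  nb <- max(bins) + 1L
  count <- tabulate(bins + 1L, nbins = nb)
  out <- data.frame(bin_low = (seq_len(nb) - 1L) * bin_width,
                    bin_high = seq_len(nb) * bin_width,
                    count = count)
  if (!is.null(partition)) {
    labs <- if (inherits(partition, "species_partition"))
      partition_labels(partition) else partition
    same <- outer(labs[kd$ids], labs[kd$ids], "==")[ut]
    out$within <- tabulate(bins[same] + 1L, nbins = nb)
    out$between <- tabulate(bins[!same] + 1L, nbins = nb)
  }
  out
}

#' Lineages-through-time from a tree
#'
#' Counts ancestral lineages against time (node depth from the root). For
#' ultrametric trees this is the standard LTT; for non-ultrametric trees
#' node depths are used as-is, which is an explicit approximation. A sharp
#' recent increase in the number of lineages marks the species/population
#' boundary.
#'
#' @param tree A rooted `phylo` tree with branch lengths (unrooted trees
#'   are midpoint rooted first).
#' @return A data frame with `time` (depth from the root) and `lineages`
#'   (count after the nodes at that depth), non-decreasing from the number
#'   of root children to the number of tips.
#' @export
lineages_through_time <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(tree)) tree <- root_tree(tree, "midpoint")
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  kids <- table(factor(tree$edge[, 1L], levels = internal))
  ord <- order(depth[internal])
  times <- depth[internal][ord]
  added <- (as.integer(kids) - 1L)[ord]
  cum <- 1L + cumsum(added)
  keep <- !duplicated(times, fromLast = TRUE)
  data.frame(time = times[keep], lineages = cum[keep])
}

#' Write delimitation outputs
#'
#' `write_species_partition_tsv()` writes one row per tip with its species
#' assignment and the species' diversity; `write_decision_log_tsv()`
#' writes the K/theta decision log; `write_annotated_newick()` writes the
#' tree used for delimitation with species labels appended to tip names.
#'
#' @param partition A `species_partition`.
#' @param path Output file path.
#' @export
write_species_partition_tsv <- function(partition, path) {
  labs <- partition_labels(partition)
  rows <- lapply(names(partition$species), function(lab) {
    tips <- partition$species[[lab]]
    dv <- partition$diversity[[lab]]
    data.frame(tip_id = tips, species_label = lab,
               is_singlet = length(tips) == 1L,
               n = dv$n, pi = dv$pi, theta = dv$theta,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_partition_tsv
#' @export
write_decision_log_tsv <- function(partition, path) {
  utils::write.table(partition$decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_partition_tsv
#' @export
write_annotated_newick <- function(partition, path) {
  labs <- partition_labels(partition)
  tr <- partition$tree
  tr$tip.label <- paste(tr$tip.label, labs[tr$tip.label], sep = "|")
  write_support_newick(tr, path)
  invisible(path)
}
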