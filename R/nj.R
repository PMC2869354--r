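## Neighbor-joining, bootstrap support, support-based collapsing and rooting.
## Trees are ape "phylo" objects; internal-node bootstrap support lives in
## node.label as a numeric vector (fraction in [0, 1], NA where undefined,
## e.g. at the root).

## Core Saitou-Nei agglomeration on a plain distance matrix.
## Deterministic: exact ties in the Q criterion are broken by the lowest
## (i, j) index pair (row-major over the current matrix ordering).
## Returns the newick string plus the list of tip-label clusters formed by
## each join (= the non-trivial splits of the unrooted tree).
nj_core <- function(d, labels) {
  r <- nrow(d)
  frag <- labels
  clusters <- as.list(labels)
  splits <- list()
  # negative lengths clamped to zero; sub-epsilon float noise snapped to 0
  fmt <- function(x) sprintf("%.12g", if (x < 1e-12) 0 else x)
  while (r > 3L) {
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    qm <- min(Q)
    cand <- which(Q == qm, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    vi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- d[i, j] - vi
    newfrag <- paste0("(", frag[i], ":", fmt(vi), ",", frag[j], ":", fmt(vj), ")")
    newclust <- c(clusters[[i]], clusters[[j]])
    splits[[length(splits) + 1L]] <- newclust
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d[i, ] <- dn; d[, i] <- dn; d[i, i] <- 0
    keep <- setdiff(seq_len(r), j)
    d <- d[keep, keep, drop = FALSE]
    frag[i] <- newfrag
    clusters[[i]] <- newclust
    frag <- frag[keep]
    clusters <- clusters[keep]
    r <- r - 1L
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(v1), ",", frag[2], ":", fmt(v2), ",",
                frag[3], ":", fmt(v3), ");")
  list(newick = nwk, splits = splits)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining on the uncorrected (`use = "D"`) or
#' corrected (`use = "K"`) distances. Negative branch lengths are clamped
#' to zero; exact ties in the Q criterion are broken deterministically by
#' the lowest index pair, so the result is reproducible.
#'
#' @param kd A `kdist` object (or a plain symmetric numeric matrix with
#'   dimnames).
#' @param use Which distances to use: `"D"` (default) or `"K"`.
#' @return An unrooted `phylo` tree (basal trichotomy).
#' @export
neighbor_joining <- function(kd, use = c("D", "K")) {
  use <- match.arg(use)
  d <- if (inherits(kd, "kdist")) kd[[use]] else as.matrix(kd)
  if (nrow(d) < 3L) stop("neighbor joining requires at least 3 tips")
  if (is.null(rownames(d))) stop("distance matrix must have tip names")
  res <- nj_core(d, rownames(d))
  phy <- ape::read.tree(text = res$newick)
  attr(phy, "splits") <- res$splits
  phy
}

## canonical key of a bipartition given the full (sorted) label set:
## take the side not containing the alphabetically first label
split_key <- function(tips, all_tips, anchor = min(all_tips)) {
  side <- if (anchor %in% tips) setdiff(all_tips, tips) else tips
  paste(sort(side), collapse = ";")
}

## descendant tip labels for every internal node, in node-number order
node_tip_sets <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  lapply(pp, function(ix) labs[ix])
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `replicates` times, rebuilds an NJ tree from each resampled
#' distance matrix, and records for every internal edge of the full-data
#' tree the fraction of replicate trees containing the same bipartition.
#' Support values are stored in `node.label` (NA at the basal node).
#'
#' @param aln An [aligned_seqs] object.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param model Distance model for both the full tree and the replicates;
#'   default `"none"` (uncorrected distances).
#' @param seed Integer seed for the resampling RNG.
#' @param use Which distances the trees are built from (`"D"` or `"K"`).
#' @return A `phylo` tree with numeric `node.label` support fractions.
#' @export
bootstrap_support <- function(aln, replicates = 1000, model = "none",
                              seed = NULL, use = "D") {
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  kd <- distance_matrix(aln, model = model)
  phy <- neighbor_joining(kd, use = use)
  all_tips <- sort(aln$ids)
  anchor <- all_tips[1L]
  code <- encode_alignment(aln)
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(replicates)) {
    cols <- sample.int(aln$L, aln$L, replace = TRUE)
    db <- suppressWarnings(
      pairwise_matrix_on_columns(code, cols, aln$ids, model, use))
    res <- nj_core(db, aln$ids)
    for (cl in res$splits) {
      key <- split_key(cl, all_tips, anchor)
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  sets <- node_tip_sets(phy)
  sup <- vapply(sets, function(tips) {
    if (length(tips) >= length(all_tips)) return(NA_real_)  # basal node
    key <- split_key(tips, all_tips, anchor)
    cnt <- counts[[key]]
    (if (is.null(cnt)) 0L else cnt) / replicates
  }, numeric(1))
  phy$node.label <- sup
  phy
}

## distance matrix (D or K) restricted to a set of alignment columns;
## replicate-level helper for the bootstrap (saturated pairs fall back to
## uncorrected values silently)
pairwise_matrix_on_columns <- function(code, cols, ids, model, use) {
  n <- nrow(code)
  sub <- code[, cols, drop = FALSE]
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  cls <- c(1, 2, 1, 2)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(sub[i, ]) & !is.na(sub[j, ])
      n_ok <- sum(ok)
      if (n_ok == 0L)
        stop(sprintf("no comparable sites between '%s' and '%s' in resample",
                     ids[i], ids[j]))
      diff <- sub[i, ok] != sub[j, ok]
      d <- sum(diff) / n_ok
      v <- d
      if (use == "K" || model != "none") {
        v <- tryCatch({
          if (model == "K2P" && d > 0) {
            ts <- sum(diff & cls[sub[i, ok]] == cls[sub[j, ok]]) / sum(diff)
            correct_distance(d, "K2P", transition_fraction = ts)
          } else if (model != "none") {
            correct_distance(d, model)
          } else d
        }, error = function(e) d)
      }
      out[i, j] <- out[j, i] <- if (use == "K") v else d
    }
  }
  out
}

#' Collapse weakly supported nodes into polytomies
#'
#' Contracts every internal edge whose child node has bootstrap support
#' strictly below `threshold`. The contracted edge's length is added to
#' the lengths of the child's own edges, so root-to-tip path lengths are
#' preserved. Tips are never removed. Nodes with undefined (NA) support
#' are kept.
#'
#' @param tree A `phylo` tree with numeric support in `node.label`.
#' @param threshold Support threshold (default 0.7); nodes with
#'   `support < threshold` are collapsed.
#' @return A `phylo` tree, possibly with polytomies.
#' @export
collapse_low_support <- function(tree, threshold = 0.7) {
  sup <- support_values(tree)
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- n + 1L
  if (is.null(sup)) return(tree)
  condemned <- rep(FALSE, n + nnode)
  internal <- (n + 1L):(n + nnode)
  condemned[internal] <- !is.na(sup) & sup < threshold
  condemned[root] <- FALSE
  if (!any(condemned)) return(tree)
  parent <- integer(n + nnode)
  elen <- rep(NA_real_, n + nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2L]] <- tree$edge.length
  # surviving parent and accumulated length for every surviving non-root node
  newparent <- integer(n + nnode)
  newlen <- rep(NA_real_, n + nnode)
  for (v in c(seq_len(n), internal)) {
    if (v == root || condemned[v]) next
    p <- parent[v]
    len <- elen[v]
    while (condemned[p]) {
      len <- len + elen[p]
      p <- parent[p]
    }
    newparent[v] <- p
    newlen[v] <- len
  }
  keep <- c(seq_len(n), internal[!condemned[internal]])
  children <- split(keep[keep != root], newparent[keep[keep != root]])
  fmt <- function(x) sprintf("%.12g", x)
  lab <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    s <- sup[v - n]
    if (is.na(s)) "" else fmt(s)
  }
  build <- function(v) {
    kids <- children[[as.character(v)]]
    if (is.null(kids)) return(tree$tip.label[v])
    inner <- vapply(kids, function(k) {
      paste0(build(k), if (!is.na(newlen[k])) paste0(":", fmt(newlen[k])) else "")
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")", if (v != root) lab(v) else "")
  }
  out <- ape::read.tree(text = paste0(build(root), ";"))
  out$node.label <- suppressWarnings(as.numeric(out$node.label))
  out
}

#' Support values of a tree
#'
#' Returns the per-internal-node support as a numeric vector (NA where
#' undefined), or NULL if the tree carries no support labels.
#'
#' @param tree A `phylo` tree.
#' @export
support_values <- function(tree) {
  if (is.null(tree$node.label)) return(NULL)
  suppressWarnings(as.numeric(tree$node.label))
}

#' Root a tree
#'
#' Midpoint rooting (default) or outgroup rooting. For outgroup rooting
#' the outgroup tips must form a clade (a split) of the unrooted tree.
#' Support labels are carried through edge-consistently.
#'
#' @param tree A `phylo` tree (rooted or unrooted).
#' @param method `"midpoint"` or `"outgroup"`.
#' @param outgroup Character vector of outgroup tip labels (for
#'   `method = "outgroup"`).
#' @return A rooted `phylo` tree with the same tip set.
#' @export
root_tree <- function(tree, method = c("midpoint", "outgroup"),
                      outgroup = NULL) {
  method <- match.arg(method)
  had_support <- !is.null(tree$node.label)
  if (method == "midpoint") {
    # sub-epsilon branch lengths upset phangorn's midpoint search
    if (!is.null(tree$edge.length))
      tree$edge.length[tree$edge.length < 1e-12] <- 0
    out <- phangorn::midpoint(tree, node.labels = "support")
  } else {
    if (is.null(outgroup)) stop("outgroup rooting requires outgroup tip ids")
    missing <- setdiff(outgroup, tree$tip.label)
    if (length(missing) > 0L)
      stop("outgroup tips not in tree: ", paste(missing, collapse = ", "))
    if (!is_unrooted_clade(tree, outgroup))
      stop("outgroup is not monophyletic in the unrooted tree")
    out <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                     edgelabel = TRUE)
  }
  if (had_support && !is.null(out$node.label))
    out$node.label <- suppressWarnings(as.numeric(out$node.label))
  out
}

## does `tips` form one side of a bipartition of the unrooted tree?
is_unrooted_clade <- function(tree, tips) {
  tips <- unique(tips)
  all_tips <- tree$tip.label
  if (length(tips) == 1L || length(tips) == length(all_tips) - 1L) return(TRUE)
  key <- split_key(tips, sort(all_tips))
  sets <- node_tip_sets(tree)
  keys <- vapply(sets, function(s) {
    if (length(s) >= length(all_tips)) NA_character_
    else split_key(s, sort(all_tips))
  }, character(1))
  key %in% stats::na.omit(keys)
}

#' Read / write Newick trees with support values
#'
#' `dialect = "label"` stores support as internal node labels (the common
#' convention); `dialect = "comment"` accepts/produces support in square
#' brackets after the branch length (`...):0.12[0.95]`).
#'
#' @param path File path.
#' @param dialect `"label"` or `"comment"`.
#' @param tree A `phylo` tree with numeric `node.label` (writer).
#' @return A `phylo` tree with numeric `node.label` (reader).
#' @export
read_support_newick <- function(path, dialect = c("label", "comment")) {
  dialect <- match.arg(dialect)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (dialect == "comment") {
    txt <- gsub("\\)\\s*:\\s*([0-9.eE+-]+)\\s*\\[([0-9.eE+-]+)\\]",
                ")\\2:\\1", txt)
  }
  phy <- ape::read.tree(text = txt)
  if (!is.null(phy$node.label))
    phy$node.label <- suppressWarnings(as.numeric(phy$node.label))
  phy
}

#' @rdname read_support_newick
#' @export
write_support_newick <- function(tree, path, dialect = c("label", "comment")) {
  dialect <- match.arg(dialect)
  sup <- support_values(tree)
  out <- tree
  if (!is.null(sup))
    out$node.label <- ifelse(is.na(sup), "", sprintf("%.10g", sup))
  txt <- ape::write.tree(out)
  if (dialect == "comment" && !is.null(sup)) {
    # move internal node labels into bracket comments after the length
    txt <- gsub("\\)([0-9.eE+-]+):([0-9.eE+-]+)", "):\\2[\\1]", txt)
  }
  writeLines(txt, path)
  invisible(path)
}
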