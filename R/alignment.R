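#' Aligned sequence sets
#'
#' An `aligned_seqs` object stores an alignment of equal-length nucleotide
#' sequences as a character matrix (rows = sequences, columns = sites) with
#' unique row names. Residues are uppercase; `-` and `N` (and any other
#' non-ACGT symbol) are treated as missing data in distance computations.
#'
#' @param seqs Character matrix of single characters, or a named character
#'   vector of sequence strings (one string per sequence).
#' @param ids Optional character vector of identifiers; defaults to the
#'   names/rownames of `seqs`.
#' @return An object of class `aligned_seqs`: a list with elements
#'   `seqs` (character matrix), `ids`, `n` (number of sequences) and
#'   `L` (alignment length in sites).
#' @examples
#' aln <- aligned_seqs(c(a = "ACGT", b = "ACGA"))
#' aln$L
#' @export
aligned_seqs <- function(seqs, ids = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(ids)) ids <- names(seqs)
    if (is.null(ids)) stop("sequence ids are required")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- ids[which(lens != lens[1L])[1L]]
      stop(sprintf("alignment is ragged: sequence '%s' has length %d, expected %d",
                   bad, lens[which(lens != lens[1L])[1L]], lens[1L]))
    }
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(seqs) <- ids
  } else {
    if (!is.null(ids)) rownames(seqs) <- ids
    seqs[] <- toupper(seqs)
  }
  ids <- rownames(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("sequence ids must be non-empty")
  if (anyDuplicated(ids)) stop("sequence ids must be unique: ",
                               ids[duplicated(ids)][1L])
  if (ncol(seqs) < 1L) stop("alignment must contain at least one site")
  structure(list(seqs = seqs, ids = ids, n = nrow(seqs), L = ncol(seqs)),
            class = "aligned_seqs")
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat(sprintf("aligned_seqs: %d sequences, %d sites\n", x$n, x$L))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped) into an
#' [aligned_seqs] object. Residues are uppercased; all sequences must have
#' identical length.
#'
#' @param path Path to a FASTA file.
#' @return An [aligned_seqs] object with records in file order.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(dna) || length(dna) == 0L)
    stop("no sequences found in ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf("alignment is ragged: sequence '%s' has length %d, expected %d",
                 names(dna)[bad], lens[bad], lens[1L]))
  }
  m <- toupper(as.character(as.matrix(dna)))
  aligned_seqs(m)
}

#' Write an alignment to FASTA
#'
#' @param aln An [aligned_seqs] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(aln$n)) {
    writeLines(c(paste0(">", aln$ids[i]),
                 paste(aln$seqs[i, ], collapse = "")), con)
  }
  invisible(path)
}

## integer-encode an alignment: A,C,G,T -> 1..4, everything else NA
encode_alignment <- function(aln) {
  code <- match(aln$seqs, c("A", "C", "G", "T"))
  dim(code) <- dim(aln$seqs)
  rownames(code) <- aln$ids
  code
}

#' Uncorrected pairwise distance between two sequences
#'
#' Computes the proportion of differing sites among sites where both
#' sequences carry an unambiguous base (pairwise deletion of gaps, `N` and
#' other ambiguity codes).
#'
#' @param a,b Sequences: single strings or character vectors of equal length.
#' @return A list with `D` (fraction of differing comparable sites) and
#'   `comparable_sites` (number of sites compared).
#' @examples
#' p_distance("A-CG", "ATCG")  # D = 0, 3 comparable sites
#' @export
p_distance <- function(a, b) {
  a <- as_site_vector(a)
  b <- as_site_vector(b)
  if (length(a) != length(b))
    stop("sequences have different lengths (", length(a), " vs ", length(b), ")")
  ca <- match(toupper(a), c("A", "C", "G", "T"))
  cb <- match(toupper(b), c("A", "C", "G", "T"))
  ok <- !is.na(ca) & !is.na(cb)
  n_ok <- sum(ok)
  if (n_ok == 0L)
    stop("no comparable sites: every site has a gap or ambiguity in at least one sequence")
  list(D = sum(ca[ok] != cb[ok]) / n_ok, comparable_sites = n_ok)
}

as_site_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1L]] else as.character(x)
}

#' Correct an observed distance for multiple hits
#'
#' Converts an observed (uncorrected) per-site difference `D` into an
#' estimate `K` of the true number of substitutions per site. `model =
#' "none"` returns `D` unchanged; `"JC"` applies the one-parameter
#' Jukes-Cantor correction `K = -(3/4) log(1 - 4 D / 3)`; `"K2P"` applies
#' the Kimura two-parameter correction with the transition fraction of the
#' observed differences supplied via `transition_fraction`.
#'
#' @param D Observed per-site difference(s), in `[0, 1)`.
#' @param model One of `"JC"`, `"K2P"`, `"none"`.
#' @param transition_fraction For `"K2P"`: fraction of the observed
#'   differences that are transitions (default 0.5).
#' @return Corrected distance(s) `K`, with `K >= D`.
#' @examples
#' correct_distance(0.10, "JC")  # ~0.10732
#' @export
correct_distance <- function(D, model = c("JC", "K2P", "none"),
                             transition_fraction = 0.5) {
  model <- match.arg(model)
  if (any(D < 0)) stop("D must be non-negative")
  if (model == "none") return(D)
  if (model == "JC") {
    if (any(D >= 0.75))
      stop("distance saturated: Jukes-Cantor correction undefined for D >= 0.75")
    return(-0.75 * log(1 - 4 * D / 3))
  }
  # K2P: P transitions, Q transversions per site
  f <- transition_fraction
  if (any(f < 0) || any(f > 1)) stop("transition_fraction must be in [0, 1]")
  P <- f * D
  Q <- (1 - f) * D
  if (any(1 - 2 * P - Q <= 0) || any(1 - 2 * Q <= 0))
    stop("distance saturated: K2P correction undefined for these arguments")
  0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
}

#' Pairwise distance matrix for an alignment
#'
#' Computes uncorrected (`D`) and corrected (`K`) per-site differences for
#' every pair of sequences, with pairwise deletion of gaps and ambiguous
#' sites. For `model = "K2P"` the transition fraction is measured per pair
#' from the data.
#'
#' @param aln An [aligned_seqs] object with at least two sequences.
#' @param model Correction model for `K`: `"JC"` (default), `"K2P"` or
#'   `"none"`.
#' @param on_saturation What to do when a pair is beyond the model's
#'   domain: `"error"` (default) or `"uncorrected"` (fall back to `D` for
#'   that pair, with a warning).
#' @return An object of class `kdist`: a list with `ids`, symmetric
#'   matrices `D`, `K` and `comparable_sites`, the alignment length `L`,
#'   and the `model` used.
#' @export
distance_matrix <- function(aln, model = c("JC", "K2P", "none"),
                            on_saturation = c("error", "uncorrected")) {
  model <- match.arg(model)
  on_saturation <- match.arg(on_saturation)
  if (aln$n < 2L) stop("need at least two sequences")
  code <- encode_alignment(aln)
  n <- aln$n
  D <- K <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  cs <- matrix(aln$L, n, n, dimnames = list(aln$ids, aln$ids))
  # purine/pyrimidine class for transition calls (A,G = 1; C,T = 2)
  cls <- c(1, 2, 1, 2)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(code[i, ]) & !is.na(code[j, ])
      n_ok <- sum(ok)
      if (n_ok == 0L)
        stop(sprintf("no comparable sites between '%s' and '%s'",
                     aln$ids[i], aln$ids[j]))
      xi <- code[i, ok]; xj <- code[j, ok]
      diff <- xi != xj
      d <- sum(diff) / n_ok
      k <- tryCatch({
        if (model == "K2P" && d > 0) {
          ts <- sum(diff & cls[xi] == cls[xj]) / sum(diff)
          correct_distance(d, "K2P", transition_fraction = ts)
        } else {
          correct_distance(d, model)
        }
      }, error = function(e) {
        if (on_saturation == "uncorrected") {
          warning(sprintf("pair ('%s', '%s'): %s; using uncorrected distance",
                          aln$ids[i], aln$ids[j], conditionMessage(e)),
                  call. = FALSE)
          d
        } else {
          stop(sprintf("pair ('%s', '%s'): %s", aln$ids[i], aln$ids[j],
                       conditionMessage(e)), call. = FALSE)
        }
      })
      D[i, j] <- D[j, i] <- d
      K[i, j] <- K[j, i] <- k
      cs[i, j] <- cs[j, i] <- n_ok
    }
  }
  structure(list(ids = aln$ids, D = D, K = K, comparable_sites = cs,
                 L = aln$L, model = model),
            class = "kdist")
}

#' @export
print.kdist <- function(x, ...) {
  cat(sprintf("kdist: %d sequences, L = %d, model = %s\n",
              length(x$ids), x$L, x$model))
  cat(sprintf("  D range: [%g, %g]\n", min(x$D), max(x$D)))
  invisible(x)
}

## construct a kdist directly from matrices (used by tests and internally)
kdist_from_matrices <- function(D, K = D, L, comparable_sites = NULL,
                                model = "none") {
  ids <- rownames(D)
  if (is.null(ids)) {
    ids <- paste0("t", seq_len(nrow(D)))
    dimnames(D) <- dimnames(K) <- list(ids, ids)
  }
  if (is.null(comparable_sites))
    comparable_sites <- matrix(L, nrow(D), ncol(D), dimnames = dimnames(D))
  structure(list(ids = ids, D = D, K = K, comparable_sites = comparable_sites,
                 L = L, model = model),
            class = "kdist")
}

#' Write / read a distance matrix as TSV
#'
#' The TSV layout has sequence ids as both the header row and the first
#' column; values are written at full precision. [read_distance_tsv()]
#' round-trips a matrix written by [write_distance_tsv()].
#'
#' @param kd A `kdist` object.
#' @param path Output file path.
#' @param which Which matrix to write: `"D"` (default) or `"K"`.
#' @return `path` invisibly (writer); a numeric matrix (reader).
#' @export
write_distance_tsv <- function(kd, path, which = c("D", "K")) {
  which <- match.arg(which)
  m <- kd[[which]]
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param kd A `kdist` object.
#' @param path Output file path.
#' @param which Which matrix to write: `"D"` (default) or `"K"`.
#' @export
write_distance_phylip <- function(kd, path, which = c("D", "K")) {
  which <- match.arg(which)
  m <- kd[[which]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(formatC(rownames(m)[i], width = -10),
                       format(m[i, ], digits = 10)), collapse = " "), con)
  }
  invisible(path)
}
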