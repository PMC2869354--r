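#' Mean pairwise difference within a set of tips
#'
#' Arithmetic mean of the uncorrected per-site difference `D` over all
#' unordered pairs drawn from `tips`.
#'
#' @param kd A `kdist` distance object.
#' @param tips Character vector of at least two tip ids present in `kd`.
#' @return The mean pairwise difference `d` (per site).
#' @export
mean_pairwise_difference <- function(kd, tips) {
  tips <- unique(as.character(tips))
  missing <- setdiff(tips, kd$ids)
  if (length(missing) > 0L)
    stop("tips not in distance matrix: ", paste(missing, collapse = ", "))
  if (length(tips) < 2L)
    stop("need at least two tips to form a pair")
  m <- kd$D[tips, tips]
  mean(m[upper.tri(m)])
}

## mean distance between two disjoint tip sets (cross pairs only)
mean_between <- function(kd, tips_a, tips_b, which = c("K", "D")) {
  which <- match.arg(which)
  mean(kd[[which]][tips_a, tips_b, drop = FALSE])
}

#' Nucleotide diversity from the mean pairwise difference
#'
#' Applies the sample-size correction `pi = d * n / (n - 1)`. When the
#' observed mean difference is exactly zero, a non-zero floor is used by
#' assuming one pairwise difference across the whole sample:
#' `pi = 2 / (L * n * (n - 1))`.
#'
#' @param d Mean pairwise (uncorrected) difference per site.
#' @param n Sample size (number of sequences), `n >= 2`.
#' @param L Alignment length in sites (used only for the zero-diversity
#'   floor).
#' @return Nucleotide diversity `pi` (per site).
#' @examples
#' nucleotide_diversity(0.012, 2, 591)        # 0.024
#' nucleotide_diversity(0, 4, 591)            # 2 / (591 * 4 * 3)
#' @export
nucleotide_diversity <- function(d, n, L) {
  if (n < 2L) stop("nucleotide diversity requires n >= 2")
  if (L < 1L) stop("L must be >= 1")
  if (d < 0) stop("d must be non-negative")
  if (d > 0) d * n / (n - 1) else 2 / (L * n * (n - 1))
}

#' Estimate theta = 2 Ne mu from nucleotide diversity
#'
#' `theta = pi / (1 - 4 pi / 3)`; very close to `pi` when diversity is
#' small.
#'
#' @param pi Nucleotide diversity, `0 <= pi < 0.75`.
#' @return `theta` (per site), always `>= pi`.
#' @export
theta_from_pi <- function(pi) {
  if (any(pi < 0)) stop("pi must be non-negative")
  if (any(pi >= 0.75)) stop("theta undefined for pi >= 0.75")
  pi / (1 - 4 * pi / 3)
}

#' Divergence time from a molecular clock
#'
#' Converts a corrected divergence `K` (substitutions per site) into an
#' absolute time using a clock rate in substitutions per site per million
#' years. The default rate, 0.022/My (2.2% per My), is a commonly used
#' invertebrate mitochondrial cox1 calibration.
#'
#' @param K Corrected divergence (per site).
#' @param rate Clock rate in substitutions per site per My; must be > 0.
#' @return Time in millions of years.
#' @export
clock_time <- function(K, rate = 0.022) {
  if (rate <= 0) stop("clock rate must be positive")
  K / rate
}

#' Per-clade diversity summary
#'
#' Computes sample size `n`, mean pairwise uncorrected difference `d`,
#' nucleotide diversity `pi` and `theta` for a set of tips. Singleton
#' clades (`n = 1`) have no defined diversity: `d`, `pi` and `theta` are
#' `NA` and delimitation against a singleton uses only its sister's theta.
#'
#' @param kd A `kdist` distance object.
#' @param tips Character vector of tip ids.
#' @param L Alignment length for the zero-diversity floor; defaults to
#'   `kd$L`.
#' @return An object of class `clade_diversity`: a list with `tip_ids`,
#'   `n`, `d`, `pi`, `theta`, `L`.
#' @export
clade_diversity <- function(kd, tips, L = kd$L) {
  tips <- unique(as.character(tips))
  if (length(tips) == 1L) {
    out <- list(tip_ids = tips, n = 1L, d = NA_real_, pi = NA_real_,
                theta = NA_real_, L = L)
  } else {
    d <- mean_pairwise_difference(kd, tips)
    pi <- nucleotide_diversity(d, length(tips), L)
    out <- list(tip_ids = tips, n = length(tips), d = d, pi = pi,
                theta = theta_from_pi(pi), L = L)
  }
  structure(out, class = "clade_diversity")
}

#' @export
print.clade_diversity <- function(x, ...) {
  cat(sprintf("clade of %d tip(s): d = %s, pi = %s, theta = %s\n",
              x$n, format(x$d), format(x$pi), format(x$theta)))
  invisible(x)
}

#' Write per-clade diversity summaries as TSV
#'
#' @param divs A list of `clade_diversity` objects, named by clade label.
#' @param path Output file path.
#' @export
write_clade_diversity_tsv <- function(divs, path) {
  labs <- names(divs)
  if (is.null(labs)) labs <- paste0("clade", seq_along(divs))
  df <- data.frame(
    clade_id = labs,
    n = vapply(divs, `[[`, integer(1), "n"),
    d = vapply(divs, `[[`, numeric(1), "d"),
    pi = vapply(divs, `[[`, numeric(1), "pi"),
    theta = vapply(divs, `[[`, numeric(1), "theta"),
    L = vapply(divs, `[[`, numeric(1), "L")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
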