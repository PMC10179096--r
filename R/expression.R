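#' Compute RPKM from a long count table
#'
#' RPKM (reads per kilobase of exon model per million mapped reads) is the
#' length- and depth-normalised expression unit used throughout the package:
#' `RPKM = count * 1e9 / (length * library_size)`.
#'
#' @param counts A tibble with at least `gene_id`, `length`, `library_size`
#'   and `count` columns, one row per gene and sample (as produced by
#'   [simulate_counts()] or [read_counts()]).
#' @return The input tibble with an `rpkm` column appended.
#' @examples
#' tbl <- tibble::tibble(
#'   gene_id = "G1", length = 2000, library_size = 1e6, count = 10,
#'   sample = "A_00", accession = "A", species = "Gb", dpa = 0
#' )
#' compute_rpkm(tbl)$rpkm # 5
#' @export
compute_rpkm <- function(counts) {
  validate_counts(counts)
  dplyr::mutate(
    counts,
    rpkm = .data$count * 1e9 / (.data$length * .data$library_size)
  )
}

validate_counts <- function(counts) {
  needed <- c("gene_id", "length", "sample", "accession", "species", "dpa",
              "library_size", "count")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0) {
    abort(paste0("count table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(counts) == 0) {
    abort("count table is empty")
  }
  if (any(counts$count < 0)) abort("counts must be non-negative")
  if (any(counts$length <= 0)) abort("gene lengths must be positive")
  if (any(counts$library_size <= 0)) abort("library sizes must be positive")
  dup <- counts |>
    dplyr::count(.data$gene_id, .data$sample) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) abort("duplicate (gene_id, sample) rows in count table")
  invisible(counts)
}

#' z-score a vector of expression values
#'
#' Centres and scales with the sample standard deviation (n - 1 denominator);
#' a constant vector maps to all zeros rather than NaN so that flat profiles
#' stay plottable alongside trending ones.
#'
#' @param x Numeric vector of length >= 2 (one value per timepoint).
#' @return Numeric vector of z-scores, same length as `x`.
#' @export
zscore_profile <- function(x) {
  if (length(x) < 2) abort("zscore_profile() needs at least two values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Two-library differential expression test
#'
#' Unreplicated two-library comparison modelled as a pooled two-proportion
#' z-test on library-normalised counts, the classical test for a pair of
#' sequencing libraries without replicates. The fold change uses a 0.5
#' pseudo-count so that zero counts give finite values; the test statistic
#' does not.
#'
#' All arguments are vectorised and recycled by position.
#'
#' @param k1,k2 Read counts for the gene in library 1 and 2.
#' @param n1,n2 Total mapped reads (library sizes) for library 1 and 2.
#' @return A tibble with columns `log2fc`, `z` and `p` (two-sided). When
#'   `k1 + k2 == 0` the gene carries no information and the result is fixed at
#'   `log2fc = 0`, `p = 1`.
#' @examples
#' de_two_library(400, 1e6, 100, 1e6)
#' @export
de_two_library <- function(k1, n1, k2, n2) {
  n <- max(length(k1), length(k2), length(n1), length(n2))
  k1 <- rep_len(as.numeric(k1), n)
  k2 <- rep_len(as.numeric(k2), n)
  n1 <- rep_len(as.numeric(n1), n)
  n2 <- rep_len(as.numeric(n2), n)
  if (any(n1 <= 0) || any(n2 <= 0)) abort("library sizes must be positive")
  if (any(k1 < 0) || any(k2 < 0)) abort("counts must be non-negative")
  if (any(k1 > n1) || any(k2 > n2)) abort("counts cannot exceed library sizes")

  log2fc <- log2((k1 + 0.5) / n1) - log2((k2 + 0.5) / n2)
  phat <- (k1 + k2) / (n1 + n2)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (k1 / n1 - k2 / n2) / se, 0)
  p <- 2 * pnorm(-abs(z))

  empty <- (k1 + k2) == 0
  log2fc[empty] <- 0
  z[empty] <- 0
  p[empty] <- 1
  degenerate <- phat >= 1          # both libraries saturated; no signal
  z[degenerate] <- 0
  p[degenerate] <- 1
  tibble::tibble(log2fc = log2fc, z = z, p = pmin(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control across one family of tests; the
#' adjusted values are referred to as Q-values throughout.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of Q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call differential expression direction
#'
#' Applies the study thresholds: `up` when `log2fc > lfc` and `q <
#' q_threshold`, `down` when `log2fc < -lfc` and `q < q_threshold`, otherwise
#' `ns`.
#'
#' @param log2fc,q Numeric vectors of equal length.
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param q_threshold Q-value threshold (default 0.005).
#' @return Character vector of calls in `c("up", "down", "ns")`.
#' @export
call_de <- function(log2fc, q, lfc = 1, q_threshold = 0.005) {
  dplyr::case_when(
    log2fc > lfc & q < q_threshold ~ "up",
    log2fc < -lfc & q < q_threshold ~ "down",
    .default = "ns"
  )
}

#' Stage-wise differential expression calls against 0 DPA
#'
#' For every accession (or species, with counts and library sizes pooled
#' across the accessions of the species) and every timepoint other than the
#' reference, tests each gene's library at that timepoint against the
#' reference library with [de_two_library()]. Q-values are adjusted per
#' comparison (one timepoint pair, across all genes).
#'
#' @param counts Long count tibble (see [compute_rpkm()] for columns).
#' @param by `"accession"` (one call set per library pair) or `"species"`
#'   (counts pooled within species before testing).
#' @param ref_dpa Reference timepoint, default 0 (lint initiation).
#' @param lfc,q_threshold Thresholds passed to [call_de()].
#' @return A tibble with columns `gene_id`, `unit` (accession or species
#'   name), `dpa`, `log2fc`, `p`, `q`, `call`.
#' @export
stage_calls <- function(counts, by = c("accession", "species"), ref_dpa = 0,
                        lfc = 1, q_threshold = 0.005) {
  validate_counts(counts)
  by <- match.arg(by)
  unit_col <- if (by == "accession") "accession" else "species"

  pooled <- counts |>
    dplyr::group_by(unit = .data[[unit_col]], .data$dpa, .data$gene_id) |>
    dplyr::summarise(
      k = sum(.data$count),
      n = sum(.data$library_size),
      .groups = "drop"
    )

  ref <- pooled |>
    dplyr::filter(.data$dpa == ref_dpa) |>
    dplyr::select("unit", "gene_id", k_ref = "k", n_ref = "n")
  if (nrow(ref) == 0) abort("reference timepoint absent from count table")

  res <- pooled |>
    dplyr::filter(.data$dpa != ref_dpa) |>
    dplyr::inner_join(ref, by = c("unit", "gene_id"))
  de <- de_two_library(res$k, res$n, res$k_ref, res$n_ref)
  res |>
    dplyr::mutate(log2fc = de$log2fc, p = de$p) |>
    dplyr::group_by(.data$unit, .data$dpa) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(call = call_de(.data$log2fc, .data$q, lfc, q_threshold)) |>
    dplyr::select("gene_id", "unit", "dpa", "log2fc", "p", "q", "call") |>
    dplyr::arrange(.data$unit, .data$dpa, .data$gene_id)
}

#' Principal component analysis of samples
#'
#' PCA on `log2(RPKM + 1)` with genes as features and samples as
#' observations, mean-centred, components ordered by decreasing variance
#' explained.
#'
#' @param rpkm Tibble with an `rpkm` column as produced by [compute_rpkm()].
#' @return An object of class `fiber_pca`: list with `scores` (tibble of
#'   per-sample coordinates plus sample annotation) and `var_explained`
#'   (fraction of variance per component).
#' @export
sample_pca <- function(rpkm) {
  if (!"rpkm" %in% names(rpkm)) abort("input must carry an rpkm column")
  wide <- rpkm |>
    dplyr::mutate(value = log2(.data$rpkm + 1)) |>
    dplyr::select("gene_id", "sample", "value") |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "value")
  if (nrow(wide) < 2) abort("sample_pca() needs at least two samples")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  if (all(fit$sdev == 0)) ve <- rep(0, length(fit$sdev))
  ann <- rpkm |>
    dplyr::distinct(.data$sample, .data$accession, .data$species, .data$dpa)
  scores <- tibble::as_tibble(fit$x, rownames = "sample") |>
    dplyr::left_join(ann, by = "sample") |>
    dplyr::relocate("sample", "accession", "species", "dpa")
  structure(
    list(scores = scores, var_explained = ve),
    class = "fiber_pca"
  )
}

#' @export
print.fiber_pca <- function(x, ...) {
  cat(sprintf(
    "Sample PCA: %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    nrow(x$scores), 100 * x$var_explained[1],
    100 * (x$var_explained[2] %||% 0)
  ))
  print(dplyr::select(x$scores, 1:6))
  invisible(x)
}

#' @export
tidy.fiber_pca <- function(x, ...) x$scores

#' @export
glance.fiber_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = length(x$var_explained),
    pc1_var = x$var_explained[1],
    pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_
  )
}
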