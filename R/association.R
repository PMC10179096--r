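#' Split lines into donor carriers and non-carriers at a marker
#'
#' Carriers hold at least one donor allele (`Gb/Gb` or `Gb/Gh`);
#' non-carriers are `Gh/Gh`; `Missing` calls drop out of both groups. This
#' pools the homozygous and heterozygous introgression classes, matching
#' how introgression effects are assessed in a predominantly homozygous
#' BC3F5 background.
#'
#' @param genotypes Tibble with `line`, `marker` and a genotype column
#'   (`genotype` or `call`).
#' @param marker Marker id.
#' @return List with `carrier` and `noncarrier` character vectors of line
#'   ids.
#' @export
group_lines_by_genotype <- function(genotypes, marker) {
  gcol <- intersect(c("genotype", "call"), names(genotypes))[1]
  if (is.na(gcol)) abort("genotype table needs a genotype or call column")
  g <- genotypes[genotypes$marker == marker, ]
  if (nrow(g) == 0) abort(sprintf("unknown marker: %s", marker))
  list(
    carrier = g$line[g[[gcol]] %in% c("Gb/Gb", "Gb/Gh")],
    noncarrier = g$line[g[[gcol]] == "Gh/Gh"]
  )
}

#' Two-tailed two-sample t-test
#'
#' Pooled-variance Student t by default, Welch as an option. Groups smaller
#' than two observations cannot be tested; the result is flagged rather than
#' raising an error, so population-wide scans keep running when a genotype
#' class is (almost) empty.
#'
#' @param x,y Numeric vectors.
#' @param variant `"pooled"` or `"welch"`.
#' @return One-row tibble: `n_x`, `n_y`, `mean_x`, `mean_y`, `t`, `df`,
#'   `p`, `testable`.
#' @export
two_tailed_ttest <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  base <- tibble::tibble(
    n_x = length(x), n_y = length(y),
    mean_x = if (length(x)) mean(x) else NA_real_,
    mean_y = if (length(y)) mean(y) else NA_real_,
    t = NA_real_, df = NA_real_, p = NA_real_, testable = FALSE
  )
  if (length(x) < 2 || length(y) < 2) return(base)
  if (stats::sd(c(x, y)) == 0) {
    # all values identical: no evidence of difference
    base$t <- 0; base$df <- length(x) + length(y) - 2; base$p <- 1
    base$testable <- TRUE
    return(base)
  }
  fit <- t.test(x, y, var.equal = (variant == "pooled"),
                alternative = "two.sided")
  base$t <- unname(fit$statistic)
  base$df <- unname(fit$parameter)
  base$p <- fit$p.value
  base$testable <- TRUE
  base
}

#' Marker-trait association scan across a population
#'
#' For every combination of marker, trait and environment, compares the
#' phenotype of donor carriers against non-carriers with a two-tailed
#' t-test ([two_tailed_ttest()]). No multiple-testing correction is applied
#' by default (each marker is reported on its own); `adjust = TRUE` adds a
#' Benjamini-Hochberg Q-value across all reported tests.
#'
#' @param genotypes Tibble with `line`, `marker`, genotype/call column.
#' @param phenotypes Tibble with `line`, `environment` and one column per
#'   trait.
#' @param markers Markers to test (default: all in `genotypes`).
#' @param traits Traits to test (default: all phenotype columns).
#' @param environments Environments to test (default: all present).
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @param adjust Add BH-adjusted `q` column.
#' @return Tibble of class `fiber_assoc`: one row per (marker, trait,
#'   environment) with group sizes, means, `t`, `df`, `p`, `direction`
#'   (sign of carrier mean minus non-carrier mean) and `testable`.
#' @export
associate_traits <- function(genotypes, phenotypes, markers = NULL,
                             traits = NULL, environments = NULL,
                             variant = c("pooled", "welch"),
                             adjust = FALSE) {
  variant <- match.arg(variant)
  markers <- markers %||% unique(genotypes$marker)
  traits <- traits %||% setdiff(names(phenotypes), c("line", "environment"))
  environments <- environments %||% unique(phenotypes$environment)

  grid <- tidyr::crossing(marker = markers, trait = traits,
                          environment = environments)
  res <- purrr::pmap_dfr(grid, function(marker, trait, environment) {
    grp <- group_lines_by_genotype(genotypes, marker)
    ph <- phenotypes[phenotypes$environment == environment, ]
    x <- ph[[trait]][ph$line %in% grp$carrier]
    y <- ph[[trait]][ph$line %in% grp$noncarrier]
    tt <- two_tailed_ttest(x, y, variant)
    tibble::tibble(
      marker = marker, trait = trait, environment = environment,
      n_carrier = tt$n_x, n_noncarrier = tt$n_y,
      mean_carrier = tt$mean_x, mean_noncarrier = tt$mean_y,
      t = tt$t, df = tt$df, p = tt$p,
      direction = sign(tt$mean_x - tt$mean_y),
      testable = tt$testable
    )
  })
  if (adjust) {
    res$q <- NA_real_
    res$q[res$testable] <- bh_adjust(res$p[res$testable])
  }
  class(res) <- c("fiber_assoc", class(res))
  res
}

#' @export
tidy.fiber_assoc <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.fiber_assoc <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_testable = sum(x$testable),
    n_significant = sum(x$testable & x$p < 0.05, na.rm = TRUE),
    min_p = if (any(x$testable)) min(x$p[x$testable]) else NA_real_
  )
}
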