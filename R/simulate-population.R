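#' Configuration for the BC3F5 introgression population simulator
#'
#' Models the study cross: a *G. barbadense* donor crossed to a
#' *G. hirsutum* recurrent parent, backcrossed `n_backcross` times and
#' self-pollinated `n_self` times (defaults 3 and 4, giving BC3F5). Each
#' line is simulated by gamete-level descent: every meiosis draws a
#' recombinant gamete per chromosome with crossover probabilities from the
#' Haldane map function on the marker spacing in centimorgan. After
#' `b` backcrosses the expected donor allele frequency is `(1/2)^(1+b)`
#' (1/16 at BC3) and selfing leaves it unchanged while halving
#' heterozygosity per generation (heterozygote probability
#' `(1/2)^(1+b) * (1/2)^s` = 1/128 at BC3F5).
#'
#' @param n_lines Number of lines (default 167, the study population size).
#' @param n_chromosomes Number of chromosomes (allotetraploid cotton has 26).
#' @param markers_per_chromosome Markers per chromosome.
#' @param marker_spacing_cm Genetic distance between adjacent markers (cM).
#' @param n_backcross,n_self Generations of backcrossing and selfing.
#' @param effect_markers Tibble with `marker`, `trait`, `effect` columns:
#'   additive phenotype shift for lines carrying the donor allele (Gb/Gb or
#'   Gb/Gh) at that marker, shared across environments.
#' @param environments Tibble with `environment` plus one baseline column per
#'   trait.
#' @param residual_sd Named numeric vector of residual standard deviations
#'   per trait.
#' @param seed Integer seed.
#' @return A list of class `fiber_pop_config`.
#' @export
population_config <- function(n_lines = 167L,
                              n_chromosomes = 26L,
                              markers_per_chromosome = 2L,
                              marker_spacing_cm = 50,
                              n_backcross = 3L,
                              n_self = 4L,
                              effect_markers = default_effect_markers(),
                              environments = default_environments(),
                              residual_sd = default_residual_sd(),
                              seed = 1L) {
  if (n_backcross < 0 || n_self < 0) {
    abort("generation counts must be non-negative")
  }
  if (marker_spacing_cm < 0) abort("marker spacing must be non-negative")
  traits <- setdiff(names(environments), "environment")
  if (!all(names(residual_sd) %in% traits) ||
      !all(traits %in% names(residual_sd))) {
    abort("residual_sd must name exactly the traits in environments")
  }
  if (nrow(effect_markers) > 0 &&
      !all(effect_markers$trait %in% traits)) {
    abort("effect marker traits must be phenotyped traits")
  }
  structure(
    list(
      n_lines = as.integer(n_lines),
      n_chromosomes = as.integer(n_chromosomes),
      markers_per_chromosome = as.integer(markers_per_chromosome),
      marker_spacing_cm = marker_spacing_cm,
      n_backcross = as.integer(n_backcross),
      n_self = as.integer(n_self),
      effect_markers = tibble::as_tibble(effect_markers),
      environments = tibble::as_tibble(environments),
      residual_sd = residual_sd,
      seed = as.integer(seed)
    ),
    class = "fiber_pop_config"
  )
}

#' @rdname population_config
#' @export
default_environments <- function() {
  # E1 (arid, irrigated) and E2 (semi-humid) trait baselines: fiber length
  # (mm), strength (cN/tex), micronaire, elongation (%), uniformity (%) at
  # levels typical of modern upland cotton.
  tibble::tibble(
    environment = c("E1", "E2"),
    length = c(29.5, 28.6),
    strength = c(30.5, 29.3),
    micronaire = c(4.1, 4.4),
    elongation = c(6.6, 6.5),
    uniformity = c(85.2, 84.6)
  )
}

#' @rdname population_config
#' @export
default_residual_sd <- function() {
  c(length = 0.9, strength = 1.1, micronaire = 0.2,
    elongation = 0.25, uniformity = 0.8)
}

#' @rdname population_config
#' @export
default_effect_markers <- function() {
  # One donor segment enhancing fiber strength and one lowering micronaire,
  # the two effect directions highlighted for the type I / type II SCW
  # candidates.
  tibble::tibble(
    marker = c("C01M01", "C02M01"),
    trait = c("strength", "micronaire"),
    effect = c(1.6, -0.35)
  )
}

marker_map <- function(config) {
  tidyr::crossing(
    chromosome = seq_len(config$n_chromosomes),
    idx = seq_len(config$markers_per_chromosome)
  ) |>
    dplyr::mutate(
      marker = sprintf("C%02dM%02d", .data$chromosome, .data$idx),
      position_cm = (.data$idx - 1) * config$marker_spacing_cm
    ) |>
    dplyr::select("marker", "chromosome", "position_cm")
}

haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

# Vectorised gamete draw across lines for one chromosome. h1, h2 are
# n_lines x m logical matrices (TRUE = donor allele); r is the vector of
# recombination fractions between adjacent markers (length m - 1).
gamete_matrix <- function(h1, h2, r) {
  n <- nrow(h1); m <- ncol(h1)
  g <- matrix(FALSE, n, m)
  cur <- runif(n) < 0.5           # which haplotype each line starts on
  g[, 1] <- ifelse(cur, h1[, 1], h2[, 1])
  if (m > 1) {
    for (k in 2:m) {
      cur <- xor(cur, runif(n) < r[k - 1])
      g[, k] <- ifelse(cur, h1[, k], h2[, k])
    }
  }
  g
}

#' Simulate a BC3F5 introgression population
#'
#' Generates line genotypes by explicit gamete-level descent (F1 fully
#' heterozygous, each backcross crossing a gamete with the recurrent
#' *G. hirsutum* haplotype, each selfing drawing two independent gametes)
#' and phenotypes as environment baseline plus the planted additive effects
#' for donor-carrying genotypes plus Gaussian residual noise.
#'
#' @param config A [population_config()].
#' @return A list with `genotypes` (tibble: `line`, `marker`, `genotype` in
#'   `Gb/Gb`, `Gb/Gh`, `Gh/Gh`), `phenotypes` (tibble: `line`,
#'   `environment`, one column per trait), `map` (marker map) and `truth`
#'   (the effect-marker table).
#' @export
simulate_population <- function(config = population_config()) {
  stopifnot(inherits(config, "fiber_pop_config"))
  withr::with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  map <- marker_map(config)
  n <- config$n_lines
  lines <- sprintf("BC3F5-%03d", seq_len(n))

  geno_chr <- purrr::map(seq_len(config$n_chromosomes), function(chr) {
    mm <- map[map$chromosome == chr, ]
    m <- nrow(mm)
    r <- haldane_r(diff(mm$position_cm))
    h1 <- matrix(TRUE, n, m)      # F1: donor haplotype
    h2 <- matrix(FALSE, n, m)     # recurrent haplotype
    for (b in seq_len(config$n_backcross)) {
      h1 <- gamete_matrix(h1, h2, r)
      h2 <- matrix(FALSE, n, m)
    }
    for (s in seq_len(config$n_self)) {
      new1 <- gamete_matrix(h1, h2, r)
      new2 <- gamete_matrix(h1, h2, r)
      h1 <- new1; h2 <- new2
    }
    n_donor <- h1 + h2
    tibble::tibble(
      line = rep(lines, m),
      marker = rep(mm$marker, each = n),
      genotype = c(c("Gh/Gh", "Gb/Gh", "Gb/Gb")[n_donor + 1])
    )
  })
  genotypes <- dplyr::bind_rows(geno_chr) |>
    dplyr::arrange(.data$line, .data$marker)

  traits <- setdiff(names(config$environments), "environment")
  carrier <- genotypes |>
    dplyr::filter(.data$genotype %in% c("Gb/Gb", "Gb/Gh"))
  effects <- if (nrow(config$effect_markers) > 0) {
    carrier |>
      dplyr::inner_join(config$effect_markers, by = "marker",
                        relationship = "many-to-many") |>
      dplyr::group_by(.data$line, .data$trait) |>
      dplyr::summarise(shift = sum(.data$effect), .groups = "drop")
  } else {
    tibble::tibble(line = character(), trait = character(), shift = numeric())
  }

  phenotypes <- tidyr::crossing(line = lines,
                                environment = config$environments$environment)
  for (tr in traits) {
    base <- config$environments[[tr]][
      match(phenotypes$environment, config$environments$environment)]
    shift <- effects |>
      dplyr::filter(.data$trait == tr)
    sh <- shift$shift[match(phenotypes$line, shift$line)]
    sh[is.na(sh)] <- 0
    phenotypes[[tr]] <- base + sh +
      rnorm(nrow(phenotypes), 0, config$residual_sd[[tr]])
  }

  list(genotypes = genotypes, phenotypes = phenotypes, map = map,
       truth = config$effect_markers)
}
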