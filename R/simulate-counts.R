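#' Simulation configuration for the fiber count time course
#'
#' Describes the study design the simulator emulates: four accessions (two
#' *G. barbadense*, two *G. hirsutum*), seven timepoints (0, 5, 10, 15, 20,
#' 25, 30 days post-anthesis), one pooled library per accession-timepoint
#' (no replicates), and a set of planted expression archetypes with known
#' trend-group and cross-species labels for recovery testing.
#'
#' @param n_genes Total number of genes (planted plus background).
#' @param accessions Tibble with `accession` and `species` (`"Gb"`/`"Gh"`)
#'   columns; default the four study accessions.
#' @param timepoints_dpa Strictly increasing integer timepoints including 0.
#' @param library_size Mapped reads per library.
#' @param planted_counts Named integer vector, genes per planted label.
#'   Labels: `elong_I/II/III`, `elong_IV_I/IV_II/IV_III`, `scw_I..scw_V`,
#'   `xs_elong`, `xs_scw_type1`, `xs_scw_type2`. Set to an empty vector for a
#'   pure-null configuration.
#' @param effect_log2fc Planted cross-species log2 fold change (Gb over Gh at
#'   the relevant stage timepoints) for the `xs_*` labels.
#' @param noise_model `"poisson"` or `"negative_binomial"`.
#' @param dispersion Negative-binomial dispersion (variance = mu + mu^2 *
#'   dispersion); ignored for Poisson noise.
#' @param seed Integer seed; all randomness in [simulate_counts()] derives
#'   from it.
#' @return A list of class `fiber_sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       accessions = default_accessions(),
                       timepoints_dpa = default_timepoints(),
                       library_size = 5e6,
                       planted_counts = default_planted_counts(),
                       effect_log2fc = 2,
                       noise_model = c("poisson", "negative_binomial"),
                       dispersion = 0.05,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  timepoints_dpa <- as.integer(timepoints_dpa)
  if (is.unsorted(timepoints_dpa, strictly = TRUE)) {
    abort("timepoints must be strictly increasing")
  }
  if (!0L %in% timepoints_dpa) abort("timepoints must include 0 DPA")
  if (library_size <= 0) abort("library_size must be positive")
  if (length(planted_counts) > 0) {
    unknown <- setdiff(names(planted_counts), names(trend_archetypes()))
    if (length(unknown) > 0) {
      abort(paste0("unknown planted labels: ", paste(unknown, collapse = ", ")))
    }
    if (sum(planted_counts) > n_genes) {
      abort("planted counts exceed n_genes")
    }
  }
  if (!all(c("accession", "species") %in% names(accessions))) {
    abort("accessions needs accession and species columns")
  }
  if (!all(accessions$species %in% c("Gb", "Gh"))) {
    abort("species must be Gb or Gh")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      accessions = tibble::as_tibble(accessions),
      timepoints_dpa = timepoints_dpa,
      library_size = library_size,
      planted_counts = planted_counts,
      effect_log2fc = effect_log2fc,
      noise_model = noise_model,
      dispersion = dispersion,
      seed = as.integer(seed)
    ),
    class = "fiber_sim_config"
  )
}

#' @rdname sim_config
#' @export
default_planted_counts <- function() {
  c(
    elong_I = 30L, elong_II = 30L, elong_III = 30L,
    elong_IV_I = 30L, elong_IV_II = 30L, elong_IV_III = 30L,
    scw_I = 30L, scw_II = 30L, scw_III = 30L, scw_IV = 30L, scw_V = 30L,
    xs_elong = 40L, xs_scw_type1 = 25L, xs_scw_type2 = 23L
  )
}

# Mean-RPKM archetypes over 0/5/10/15/20/25/30 DPA. Values are chosen so that
# every intended vs-0-DPA call clears the |log2FC| > 1 gate with a wide
# margin at the default library size, while "ns" timepoints sit at the 0 DPA
# baseline. xs_* labels reuse a group-IV shape and additionally carry the
# planted Gb-over-Gh fold change at their stage timepoints.
trend_archetypes <- function() {
  list(
    elong_I      = c(2, 30, 35, 40, 80, 90, 100),
    elong_II     = c(2, 80, 90, 100, 40, 35, 30),
    elong_III    = c(3, 60, 70, 60, 30, 20, 3),
    elong_IV_I   = c(2, 80, 78, 30, 2, 2, 2),
    elong_IV_II  = c(2, 30, 90, 35, 2, 2, 2),
    elong_IV_III = c(2, 30, 78, 80, 2, 2, 2),
    scw_I        = c(2, 80, 90, 100, 40, 35, 30),
    scw_II       = c(2, 30, 35, 40, 80, 90, 100),
    scw_III      = c(3, 30, 20, 3, 60, 70, 60),
    scw_IV       = c(2, 2, 2, 2, 80, 90, 80),
    scw_V        = c(2, 2, 2, 2, 40, 60, 100),
    xs_elong     = c(2, 30, 90, 35, 2, 2, 2),
    xs_scw_type1 = c(2, 2, 2, 2, 80, 90, 80),
    xs_scw_type2 = c(2, 2, 2, 2, 80, 90, 80)
  )
}

background_rpkm <- function() 20

# Expected-truth annotation for one planted label.
label_truth <- function(label) {
  switch(label,
    elong_I      = list(eg = "I",   sub = "none",  sg = "none", xs = FALSE, stage = NA, scw_type = "none"),
    elong_II     = list(eg = "II",  sub = "none",  sg = "none", xs = FALSE, stage = NA, scw_type = "none"),
    elong_III    = list(eg = "III", sub = "none",  sg = "none", xs = FALSE, stage = NA, scw_type = "none"),
    elong_IV_I   = list(eg = "IV",  sub = "IV-I",  sg = "none", xs = FALSE, stage = NA, scw_type = "none"),
    elong_IV_II  = list(eg = "IV",  sub = "IV-II", sg = "none", xs = FALSE, stage = NA, scw_type = "none"),
    elong_IV_III = list(eg = "IV",  sub = "IV-III", sg = "none", xs = FALSE, stage = NA, scw_type = "none"),
    scw_I        = list(eg = "none", sub = "none", sg = "I",   xs = FALSE, stage = NA, scw_type = "none"),
    scw_II       = list(eg = "none", sub = "none", sg = "II",  xs = FALSE, stage = NA, scw_type = "none"),
    scw_III      = list(eg = "none", sub = "none", sg = "III", xs = FALSE, stage = NA, scw_type = "none"),
    scw_IV       = list(eg = "none", sub = "none", sg = "IV",  xs = FALSE, stage = NA, scw_type = "none"),
    scw_V        = list(eg = "none", sub = "none", sg = "V",   xs = FALSE, stage = NA, scw_type = "none"),
    xs_elong     = list(eg = "IV",  sub = "IV-II", sg = "none", xs = TRUE, stage = "elongation", scw_type = "none"),
    xs_scw_type1 = list(eg = "none", sub = "none", sg = "IV",  xs = TRUE, stage = "scw", scw_type = "I"),
    xs_scw_type2 = list(eg = "none", sub = "none", sg = "IV",  xs = TRUE, stage = "scw", scw_type = "II"),
    abort(paste0("unknown label ", label))
  )
}

#' Simulate the two-species fiber count time course
#'
#' Generates one pooled RNA-seq library per accession-timepoint. Background
#' genes are flat at a moderate RPKM; planted genes follow their label's
#' mean-RPKM archetype (see `trend_archetypes()`), and cross-species (`xs_*`)
#' genes carry `effect_log2fc` extra Gb-over-Gh expression at their stage
#' timepoints: Gh means equal the Gb archetype divided by
#' `2^effect_log2fc` there (type-II SCW genes are instead flat in Gh, so
#' their Gh ortholog is not upregulated at all). Mean RPKM is converted to an
#' expected count by the inverse RPKM formula and counts are drawn from the
#' configured noise model.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (long tibble: `gene_id`, `length`, `sample`,
#'   `accession`, `species`, `dpa`, `library_size`, `count`) and `truth`
#'   (tibble: `gene_id`, `label`, `elongation_group`, `elongation_subgroup`,
#'   `scw_group`, `cross_species_up`, `xs_stage`, `scw_type`).
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "fiber_sim_config"))
  withr::with_seed(config$seed, simulate_counts_impl(config))
}

simulate_counts_impl <- function(config) {
  tps <- config$timepoints_dpa
  arch <- trend_archetypes()
  n_planted <- if (length(config$planted_counts)) sum(config$planted_counts) else 0L
  labels <- c(
    rep(names(config$planted_counts), times = config$planted_counts),
    rep("background", config$n_genes - n_planted)
  )
  gene_id <- sprintf("G%05d", seq_len(config$n_genes))
  lengths <- round(runif(config$n_genes, 600, 3000))

  # mean RPKM per gene x timepoint x species
  arch_at <- function(lbl) {
    if (lbl == "background") return(rep(background_rpkm(), length(tps)))
    full <- arch[[lbl]]
    # archetypes are defined on the default 7-timepoint grid; interpolate if
    # a non-default grid is requested
    if (length(tps) == 7L && all(tps == default_timepoints())) return(full)
    stats::approx(default_timepoints(), full, xout = tps, rule = 2)$y
  }
  mu_gb <- t(vapply(labels, arch_at, numeric(length(tps))))
  mu_gh <- mu_gb
  des <- stage_design()
  for (i in which(labels == "xs_elong")) {
    j <- tps %in% des$elongation
    mu_gh[i, j] <- mu_gb[i, j] / 2^config$effect_log2fc
  }
  for (i in which(labels == "xs_scw_type1")) {
    j <- tps %in% des$scw
    mu_gh[i, j] <- mu_gb[i, j] / 2^config$effect_log2fc
  }
  for (i in which(labels == "xs_scw_type2")) {
    mu_gh[i, ] <- mu_gb[i, 1]  # flat at baseline: no upregulation in Gh
  }

  draw <- function(mu) {
    if (config$noise_model == "poisson") {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
  }

  samples <- tidyr::crossing(config$accessions, dpa = tps)
  counts <- purrr::pmap_dfr(samples, function(accession, species, dpa) {
    j <- match(dpa, tps)
    mu_rpkm <- if (species == "Gb") mu_gb[, j] else mu_gh[, j]
    mu_count <- mu_rpkm * lengths * config$library_size / 1e9
    tibble::tibble(
      gene_id = gene_id,
      length = lengths,
      sample = sample_label(accession, dpa),
      accession = accession,
      species = species,
      dpa = dpa,
      library_size = config$library_size,
      count = draw(mu_count)
    )
  })

  truth <- purrr::map_dfr(labels, function(lbl) {
    if (lbl == "background") {
      return(tibble::tibble(
        label = "background", elongation_group = "none",
        elongation_subgroup = "none", scw_group = "none",
        cross_species_up = FALSE, xs_stage = NA_character_, scw_type = "none"
      ))
    }
    tr <- label_truth(lbl)
    tibble::tibble(
      label = lbl, elongation_group = tr$eg, elongation_subgroup = tr$sub,
      scw_group = tr$sg, cross_species_up = tr$xs,
      xs_stage = as.character(tr$stage), scw_type = tr$scw_type
    )
  })
  truth <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id), truth)

  list(counts = counts, truth = truth)
}
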