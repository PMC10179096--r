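#' Run the full candidate-discovery pipeline on simulated inputs
#'
#' Composes every stage end to end: simulate the two-species count time
#' course; quantify RPKM; call stage-wise differential expression per
#' accession and per species; intersect the per-accession elongation-up and
#' SCW-up sets; assign trend groups; filter group IV genes for
#' *G. barbadense*-over-*G. hirsutum* upregulation (elongation and SCW
#' stages); split SCW candidates into type I/II; simulate homeolog quartets
#' for the SCW candidates, design tri-primer allele-specific markers and
#' genotype a simulated BC3F5 population in silico; test marker-trait
#' associations. Every source of randomness derives from `seed`, so a rerun
#' with the same seed reproduces the report exactly.
#'
#' @param seed Integer master seed.
#' @param config Count-simulation configuration ([sim_config()]); its own
#'   seed is replaced by one derived from `seed`.
#' @param pop_n_lines Number of BC3F5 lines to simulate.
#' @param constraints Primer design constraints ([primer_constraints()]).
#' @param out_dir Optional directory; when given, the stage outputs (counts,
#'   DE calls, assignments, candidates, marker table, genotype/phenotype
#'   tables, association results and a JSON run report) are written there.
#' @return A list of class `fiber_run` carrying every stage output plus a
#'   `report` list with the filter-step counts.
#' @export
run_fiber_pipeline <- function(seed = 1L,
                               config = NULL,
                               pop_n_lines = 167L,
                               constraints = primer_constraints(),
                               out_dir = NULL) {
  seed <- as.integer(seed)
  if (is.null(config)) config <- sim_config(seed = seed)
  sim <- simulate_counts(config)
  counts <- sim$counts

  rpkm <- compute_rpkm(counts)
  calls_acc <- stage_calls(counts, by = "accession")
  calls_sp <- stage_calls(counts, by = "species")

  elong_common <- common_stage_up(calls_acc, config$accessions, "Gb",
                                  "elongation")
  scw_common <- common_stage_up(calls_acc, config$accessions, "Gb", "scw")

  trends <- assign_trends(counts, calls = calls_sp)
  elong_iv <- trends$gene_id[trends$elongation_group == "IV" &
                               trends$gene_id %in% elong_common$common]
  scw_iv <- trends$gene_id[trends$scw_group == "IV" &
                             trends$gene_id %in% scw_common$common]

  elong_cand <- cross_species_filter(elong_iv, counts, "elongation")
  scw_cand <- cross_species_filter(scw_iv, counts, "scw")
  scw_types <- split_scw_types(scw_cand$gene_id, calls_acc,
                               config$accessions)

  # marker design for the SCW candidates (one quartet per candidate locus)
  n_loci <- nrow(scw_cand)
  markers <- NULL; genotype_calls <- NULL; assoc <- NULL
  pop <- NULL; quartets <- NULL; concordance <- NA_real_
  if (n_loci > 0) {
    qsim <- simulate_quartets(n_loci = n_loci, seed = seed + 1L)
    quartets <- qsim$quartets
    markers <- design_markers(quartets, constraints)
    markers$gene_id <- scw_cand$gene_id
    designed <- markers[markers$status == "designed", , drop = FALSE]

    # place the designed markers on the genetic map of the simulated
    # population: round-robin over chromosomes, one marker per chromosome slot
    n_chr <- min(26L, max(1L, nrow(designed)))
    per_chr <- ceiling(nrow(designed) / n_chr)
    eff <- default_effect_markers()
    pcfg <- population_config(
      n_lines = pop_n_lines,
      n_chromosomes = n_chr,
      markers_per_chromosome = per_chr,
      effect_markers = eff[eff$marker %in% marker_map_names(n_chr, per_chr), ],
      seed = seed + 2L
    )
    pop <- simulate_population(pcfg)
    map_markers <- unique(pop$genotypes$marker)
    slot <- stats::setNames(
      map_markers[seq_len(nrow(designed))], designed$marker_id)
    truth_geno <- pop$genotypes |>
      dplyr::filter(.data$marker %in% slot) |>
      dplyr::mutate(marker = names(slot)[match(.data$marker, slot)])
    genotype_calls <- genotype_population(truth_geno, markers, quartets,
                                          constraints)
    joined <- dplyr::inner_join(
      truth_geno, genotype_calls, by = c("line", "marker"))
    concordance <- mean(joined$genotype == joined$call)
    assoc <- associate_traits(genotype_calls, pop$phenotypes)
  }

  report <- list(
    seed = seed,
    n_genes = config$n_genes,
    n_samples = dplyr::n_distinct(counts$sample),
    elong_up_per_accession = lengths(elong_common$per_accession),
    elong_up_common = length(elong_common$common),
    scw_up_per_accession = lengths(scw_common$per_accession),
    scw_up_common = length(scw_common$common),
    elong_group_iv = length(elong_iv),
    scw_group_iv = length(scw_iv),
    elong_candidates = nrow(elong_cand),
    scw_candidates = nrow(scw_cand),
    scw_type1 = sum(scw_types$scw_type == "I"),
    scw_type2 = sum(scw_types$scw_type == "II"),
    markers_designed = if (is.null(markers)) 0L
      else sum(markers$status == "designed"),
    genotype_concordance = concordance
  )

  run <- structure(
    list(
      config = config, counts = counts, rpkm = rpkm,
      calls_accession = calls_acc, calls_species = calls_sp,
      trends = trends, truth = sim$truth,
      elong_candidates = elong_cand, scw_candidates = scw_cand,
      scw_types = scw_types, quartets = quartets, markers = markers,
      population = pop, genotype_calls = genotype_calls,
      associations = assoc, report = report
    ),
    class = "fiber_run"
  )

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

marker_map_names <- function(n_chr, per_chr) {
  as.vector(outer(seq_len(per_chr), seq_len(n_chr),
                  function(i, c) sprintf("C%02dM%02d", c, i)))
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_counts(run$counts, file.path(out_dir, "counts"))
  readr::write_tsv(run$calls_accession, file.path(out_dir, "de_calls.tsv"))
  readr::write_tsv(run$trends, file.path(out_dir, "trend_assignments.tsv"))
  readr::write_tsv(tibble::as_tibble(run$elong_candidates),
                   file.path(out_dir, "elongation_candidates.tsv"))
  readr::write_tsv(
    dplyr::left_join(tibble::as_tibble(run$scw_candidates), run$scw_types,
                     by = "gene_id"),
    file.path(out_dir, "scw_candidates.tsv"))
  if (!is.null(run$markers)) {
    write_markers(run$markers, file.path(out_dir, "markers.tsv"))
    write_quartets_fasta(run$quartets, file.path(out_dir, "loci.fasta"))
  }
  if (!is.null(run$population)) {
    write_genotypes(run$genotype_calls, file.path(out_dir, "genotypes.tsv"))
    write_phenotypes(run$population$phenotypes,
                     file.path(out_dir, "phenotypes.csv"))
    readr::write_tsv(tibble::as_tibble(run$associations),
                     file.path(out_dir, "associations.tsv"))
  }
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.fiber_run <- function(x, ...) {
  r <- x$report
  cat("Fiber candidate-discovery run (seed ", r$seed, ")\n", sep = "")
  cat(sprintf("  genes: %d, samples: %d\n", r$n_genes, r$n_samples))
  cat(sprintf("  elongation-up common: %d -> group IV: %d -> candidates: %d\n",
              r$elong_up_common, r$elong_group_iv, r$elong_candidates))
  cat(sprintf("  SCW-up common: %d -> group IV: %d -> candidates: %d (type I %d / type II %d)\n",
              r$scw_up_common, r$scw_group_iv, r$scw_candidates,
              r$scw_type1, r$scw_type2))
  cat(sprintf("  markers designed: %d, genotype concordance: %s\n",
              r$markers_designed,
              ifelse(is.na(r$genotype_concordance), "NA",
                     sprintf("%.1f%%", 100 * r$genotype_concordance))))
  invisible(x)
}

#' @export
glance.fiber_run <- function(x, ...) {
  tibble::as_tibble(x$report[c(
    "seed", "n_genes", "elong_up_common", "elong_group_iv",
    "elong_candidates", "scw_up_common", "scw_group_iv", "scw_candidates",
    "scw_type1", "scw_type2", "markers_designed", "genotype_concordance")])
}
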