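#' Intersect per-accession gene sets
#'
#' The common genes of two or more accessions (e.g., the elongation-up sets
#' of the two *G. barbadense* accessions).
#'
#' @param sets List of two or more character vectors of gene ids.
#' @return Character vector of genes present in every set.
#' @export
intersect_accessions <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) {
    abort("intersect_accessions() needs a list of at least two sets")
  }
  Reduce(intersect, sets)
}

#' Genes upregulated across a whole stage, common to a species' accessions
#'
#' For each accession of `species`, collects the genes called up versus
#' 0 DPA at **every** timepoint of `stage`, then intersects across
#' accessions.
#'
#' @param calls Accession-level stage calls from
#'   `stage_calls(counts, by = "accession")`.
#' @param accessions Accession annotation tibble (`accession`, `species`).
#' @param species `"Gb"` or `"Gh"`.
#' @param stage `"elongation"` or `"scw"`.
#' @return A list with `per_accession` (named list of gene-id vectors) and
#'   `common` (their intersection).
#' @export
common_stage_up <- function(calls, accessions, species = "Gb",
                            stage = c("elongation", "scw")) {
  stage <- match.arg(stage)
  tps <- stage_design()[[stage]]
  accs <- accessions$accession[accessions$species == species]
  if (length(accs) < 2) abort("need at least two accessions for the species")
  per_accession <- purrr::map(accs, function(a) {
    calls |>
      dplyr::filter(.data$unit == a, .data$dpa %in% tps) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(all_up = all(.data$call == "up") &
                         dplyr::n() == length(tps), .groups = "drop") |>
      dplyr::filter(.data$all_up) |>
      dplyr::pull("gene_id")
  })
  names(per_accession) <- accs
  list(per_accession = per_accession,
       common = intersect_accessions(per_accession))
}

#' Filter genes upregulated in G. barbadense over G. hirsutum
#'
#' Counts are pooled within species at each stage timepoint (counts and
#' library sizes summed across the species' accessions) and the pooled Gb
#' library is tested against the pooled Gh library with [de_two_library()];
#' Q-values are adjusted per timepoint across all genes in the count table.
#' A gene passes when the call is `up` at **every** stage timepoint. With
#' `strict = TRUE` every Gb x Gh accession pair must additionally pass at
#' every timepoint.
#'
#' @param group_genes Character vector of candidate gene ids to filter.
#' @param counts Long count tibble containing both species.
#' @param stage `"elongation"` or `"scw"`.
#' @param lfc,q_threshold Thresholds passed to [call_de()].
#' @param strict Require all accession pairs to pass as well.
#' @return Tibble of passing genes with per-timepoint pooled statistics
#'   (`log2fc_<dpa>`, `q_<dpa>` columns), class `fiber_candidates`.
#' @export
cross_species_filter <- function(group_genes, counts,
                                 stage = c("elongation", "scw"),
                                 lfc = 1, q_threshold = 0.005,
                                 strict = FALSE) {
  stage <- match.arg(stage)
  validate_counts(counts)
  tps <- stage_design()[[stage]]
  have <- counts |> dplyr::distinct(.data$species, .data$dpa)
  for (tp in tps) {
    for (sp in c("Gb", "Gh")) {
      if (!any(have$species == sp & have$dpa == tp)) {
        abort(sprintf("counts lack species %s at %d DPA", sp, tp))
      }
    }
  }

  pooled <- counts |>
    dplyr::filter(.data$dpa %in% tps) |>
    dplyr::group_by(.data$species, .data$dpa, .data$gene_id) |>
    dplyr::summarise(k = sum(.data$count), n = sum(.data$library_size),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species", values_from = c("k", "n"))

  de <- de_two_library(pooled$k_Gb, pooled$n_Gb, pooled$k_Gh, pooled$n_Gh)
  stats <- pooled |>
    dplyr::mutate(log2fc = de$log2fc, p = de$p) |>
    dplyr::group_by(.data$dpa) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(call = call_de(.data$log2fc, .data$q, lfc, q_threshold))

  passing <- stats |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(pass = all(.data$call == "up") &
                       dplyr::n() == length(tps), .groups = "drop") |>
    dplyr::filter(.data$pass) |>
    dplyr::pull("gene_id")
  passing <- intersect(group_genes, passing)

  if (strict) {
    acc <- counts |> dplyr::distinct(.data$accession, .data$species)
    pairs <- tidyr::crossing(
      gb = acc$accession[acc$species == "Gb"],
      gh = acc$accession[acc$species == "Gh"]
    )
    per_sample <- counts |>
      dplyr::filter(.data$dpa %in% tps, .data$gene_id %in% passing)
    for (i in seq_len(nrow(pairs))) {
      w <- per_sample |>
        dplyr::filter(.data$accession %in% c(pairs$gb[i], pairs$gh[i])) |>
        dplyr::mutate(side = ifelse(.data$species == "Gb", "Gb", "Gh")) |>
        dplyr::select("gene_id", "dpa", "side", "count", "library_size") |>
        tidyr::pivot_wider(names_from = "side",
                           values_from = c("count", "library_size"))
      de_i <- de_two_library(w$count_Gb, w$library_size_Gb,
                             w$count_Gh, w$library_size_Gh)
      w <- w |>
        dplyr::mutate(log2fc = de_i$log2fc, p = de_i$p) |>
        dplyr::group_by(.data$dpa) |>
        dplyr::mutate(q = bh_adjust(.data$p)) |>
        dplyr::ungroup() |>
        dplyr::mutate(call = call_de(.data$log2fc, .data$q, lfc, q_threshold))
      ok <- w |>
        dplyr::group_by(.data$gene_id) |>
        dplyr::summarise(pass = all(.data$call == "up"), .groups = "drop") |>
        dplyr::filter(.data$pass) |>
        dplyr::pull("gene_id")
      passing <- intersect(passing, ok)
    }
  }

  out <- stats |>
    dplyr::filter(.data$gene_id %in% passing) |>
    dplyr::select("gene_id", "dpa", "log2fc", "q") |>
    tidyr::pivot_wider(names_from = "dpa", values_from = c("log2fc", "q"),
                       names_sep = "_") |>
    dplyr::mutate(stage = stage, .after = "gene_id") |>
    dplyr::arrange(.data$gene_id)
  class(out) <- c("fiber_candidates", class(out))
  out
}

#' Split SCW candidates into type I and type II
#'
#' Type I candidates have a *G. hirsutum* ortholog that is itself upregulated
#' during SCW biosynthesis (called up versus 0 DPA at two or more of the
#' three SCW timepoints in **both** Gh accessions); the remainder, whose
#' upregulation is specific to *G. barbadense*, are type II. Shared gene ids
#' between the species (single reference genome) stand in for the ortholog
#' mapping.
#'
#' @param candidate_genes Character vector of candidate gene ids.
#' @param calls Accession-level stage calls containing both Gh accessions.
#' @param accessions Accession annotation tibble.
#' @return Tibble: `gene_id`, `scw_type` (`"I"` or `"II"`).
#' @export
split_scw_types <- function(candidate_genes, calls, accessions) {
  gh_accs <- accessions$accession[accessions$species == "Gh"]
  if (length(gh_accs) < 1) abort("no G. hirsutum accessions supplied")
  tps <- stage_design()$scw
  gh <- calls |>
    dplyr::filter(.data$unit %in% gh_accs, .data$dpa %in% tps,
                  .data$gene_id %in% candidate_genes)
  if (!all(candidate_genes %in% gh$gene_id)) {
    abort("missing G. hirsutum ortholog calls for some candidates")
  }
  up2 <- gh |>
    dplyr::group_by(.data$gene_id, .data$unit) |>
    dplyr::summarise(n_up = sum(.data$call == "up"), .groups = "drop") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      type1 = all(.data$n_up >= 2) & dplyr::n() == length(gh_accs),
      .groups = "drop"
    )
  tibble::tibble(gene_id = candidate_genes) |>
    dplyr::left_join(up2, by = "gene_id") |>
    dplyr::mutate(scw_type = ifelse(.data$type1, "I", "II")) |>
    dplyr::select("gene_id", "scw_type")
}

#' Hypergeometric GO-style enrichment
#'
#' For each term with `M` annotated genes in a universe of `N`, the
#' probability of seeing `k` or more annotated genes in a study set of `n`
#' drawn without replacement is the hypergeometric upper tail
#' `P(X >= k)`. P-values are Benjamini-Hochberg adjusted across the tested
#' terms; terms with `Q < q_threshold` are flagged significant.
#'
#' @param study_set Character vector of study gene ids (subset of universe).
#' @param annotation Tibble with `term` and `gene` columns (one row per
#'   annotation), optionally a `term_name` column.
#' @param universe Character vector of all gene ids under consideration.
#' @param q_threshold Significance threshold on the Q-value (default 0.05).
#' @return Tibble: `term`, `k`, `n`, `M`, `N`, `p`, `q`, `significant`,
#'   sorted by `p`.
#' @export
hypergeom_enrich <- function(study_set, annotation, universe,
                             q_threshold = 0.05) {
  universe <- unique(universe)
  study_set <- unique(study_set)
  if (length(universe) == 0) abort("universe is empty")
  if (!all(study_set %in% universe)) {
    abort("study set must be a subset of the universe")
  }
  if (!all(c("term", "gene") %in% names(annotation))) {
    abort("annotation needs term and gene columns")
  }
  ann <- annotation |>
    dplyr::filter(.data$gene %in% universe) |>
    dplyr::distinct(.data$term, .data$gene)
  res <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      M = dplyr::n(),
      k = sum(.data$gene %in% study_set),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = length(study_set),
      N = length(universe),
      p = phyper(.data$k - 1, .data$M, .data$N - .data$M, .data$n,
                 lower.tail = FALSE),
      q = bh_adjust(.data$p),
      significant = .data$q < q_threshold
    ) |>
    dplyr::select("term", "k", "n", "M", "N", "p", "q", "significant") |>
    dplyr::arrange(.data$p, .data$term)
  if ("term_name" %in% names(annotation)) {
    res <- res |>
      dplyr::left_join(dplyr::distinct(annotation, .data$term, .data$term_name),
                       by = "term") |>
      dplyr::relocate("term_name", .after = "term")
  }
  res
}
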