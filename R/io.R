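#' Write and read the count time course as TSV
#'
#' Three tab-separated files: the count matrix (`gene_id` rows, one
#' `<accession>_<DPA>` column per library), a gene annotation table
#' (`gene_id`, `length`) and a sample annotation table (`sample`,
#' `accession`, `species`, `dpa`, `library_size`).
#'
#' @param counts Long count tibble.
#' @param dir Output directory (created if needed).
#' @return `write_counts()` returns the three paths invisibly;
#'   `read_counts()` returns the long count tibble.
#' @export
write_counts <- function(counts, dir) {
  validate_counts(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wide <- counts |>
    dplyr::select("gene_id", "sample", "count") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count")
  genes <- counts |> dplyr::distinct(.data$gene_id, .data$length)
  samples <- counts |>
    dplyr::distinct(.data$sample, .data$accession, .data$species, .data$dpa,
                    .data$library_size)
  paths <- file.path(dir, c("counts.tsv", "genes.tsv", "samples.tsv"))
  readr::write_tsv(wide, paths[1])
  readr::write_tsv(genes, paths[2])
  readr::write_tsv(samples, paths[3])
  invisible(paths)
}

#' @rdname write_counts
#' @export
read_counts <- function(dir) {
  paths <- file.path(dir, c("counts.tsv", "genes.tsv", "samples.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("missing count files: ", paste(missing, collapse = ", ")))
  }
  wide <- readr::read_tsv(paths[1], show_col_types = FALSE)
  genes <- readr::read_tsv(paths[2], show_col_types = FALSE)
  samples <- readr::read_tsv(paths[3], show_col_types = FALSE)
  counts <- wide |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample",
                        values_to = "count") |>
    dplyr::inner_join(genes, by = "gene_id") |>
    dplyr::inner_join(samples, by = "sample") |>
    dplyr::select("gene_id", "length", "sample", "accession", "species",
                  "dpa", "library_size", "count")
  validate_counts(counts)
  counts
}

#' Write and read population tables
#'
#' Genotypes as a line x marker TSV (values `Gb/Gb`, `Gb/Gh`, `Gh/Gh` or
#' `Missing`) and phenotypes as a CSV with one row per line and environment.
#'
#' @param genotypes Long genotype tibble (`line`, `marker`,
#'   genotype/call column).
#' @param phenotypes Phenotype tibble.
#' @param path Output file path.
#' @return Writers return `path` invisibly; readers return long tibbles.
#' @export
write_genotypes <- function(genotypes, path) {
  gcol <- intersect(c("genotype", "call"), names(genotypes))[1]
  wide <- genotypes |>
    dplyr::select("line", "marker", value = dplyr::all_of(gcol)) |>
    tidyr::pivot_wider(names_from = "marker", values_from = "value")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  wide |>
    tidyr::pivot_longer(-"line", names_to = "marker",
                        values_to = "genotype") |>
    dplyr::arrange(.data$line, .data$marker)
}

#' @rdname write_genotypes
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read a two-column GO-style annotation table
#'
#' @param path TSV with `term` and `gene` columns (optional `term_name`).
#' @return Annotation tibble.
#' @export
read_go_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("term", "gene") %in% names(ann))) {
    abort("annotation TSV needs term and gene columns")
  }
  ann
}

#' Bundled transcriptions of the published candidate-gene tables
#'
#' Three fixtures ship with the package: the 42 elongation-related
#' candidates with their peak-time subgroups (`"table1"`), the 25 type I
#' SCW-biosynthesis candidates (`"table2"`) and the 23 type II candidates
#' (`"table3"`); the SCW tables carry the `HEBAU` serial marker ids, with
#' `NA` where no assay was available.
#'
#' @param which `"table1"`, `"table2"` or `"table3"`.
#' @return Tibble of the requested table.
#' @export
candidate_fixture <- function(which = c("table1", "table2", "table3")) {
  which <- match.arg(which)
  file <- switch(which,
    table1 = "table1_elongation_candidates.tsv",
    table2 = "table2_scw_type1.tsv",
    table3 = "table3_scw_type2.tsv"
  )
  path <- system.file("extdata", file, package = "fiberdev", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, na = "NA")
}

#' Parse a `LOCUS|SPECIES|SUBGENOME` FASTA record id
#'
#' @param id Character vector of record ids.
#' @return Tibble with `locus`, `species`, `subgenome` columns.
#' @export
parse_locus_id <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) {
    abort(sprintf("malformed record id: %s", id[bad][1]))
  }
  tibble::tibble(
    locus = vapply(parts, `[`, character(1), 1),
    species = vapply(parts, `[`, character(1), 2),
    subgenome = vapply(parts, `[`, character(1), 3)
  )
}

#' Write a marker design table as TSV
#'
#' @param markers A `fiber_markers` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  readr::write_tsv(tibble::as_tibble(markers), path)
  invisible(path)
}
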