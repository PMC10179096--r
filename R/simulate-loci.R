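#' Simulate homeolog sequence quartets with planted SNPs
#'
#' Each candidate locus is represented by four gap-free aligned sequences:
#' the *G. barbadense* and *G. hirsutum* copies on the At and Dt subgenomes
#' of allotetraploid cotton. Planted variants come in three classes:
#'
#' * `interspecific_target` - Gb and Gh differ on the target subgenome, the
#'   other subgenome is invariant (the site the allele-specific primers P1/P2
#'   anchor on);
#' * `subgenomic` - At and Dt differ, conserved within each species (the
#'   site the common primer P3 anchors on to keep the homeologous copy out
#'   of the assay);
#' * `other` - all four copies differ (unusable for the assay).
#'
#' @param n_loci Number of loci.
#' @param locus_length Sequence length in bp.
#' @param snp_spec Optional list (one element per locus) of tibbles with
#'   `pos` and `class` columns; when `NULL`, `n_interspecific` and
#'   `n_subgenomic` sites are planted at random distinct positions.
#' @param n_interspecific,n_subgenomic Default planted sites per locus.
#' @param target_subgenome `"At"` or `"Dt"`.
#' @param seed Integer seed.
#' @return List with `quartets` (list of `fiber_quartet` objects) and
#'   `truth` (tibble: `locus`, `pos`, `class`).
#' @export
simulate_quartets <- function(n_loci = 48, locus_length = 600,
                              snp_spec = NULL,
                              n_interspecific = 2, n_subgenomic = 3,
                              target_subgenome = c("At", "Dt"),
                              seed = 1L) {
  target_subgenome <- match.arg(target_subgenome)
  withr::with_seed(as.integer(seed), {
    quartets <- vector("list", n_loci)
    truth <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      locus <- sprintf("L%04d", i)
      spec <- if (!is.null(snp_spec)) {
        tibble::as_tibble(snp_spec[[i]])
      } else {
        tibble::tibble(
          pos = sample(locus_length, n_interspecific + n_subgenomic),
          class = c(rep("interspecific_target", n_interspecific),
                    rep("subgenomic", n_subgenomic))
        )
      }
      q <- build_quartet(locus, locus_length, spec, target_subgenome)
      quartets[[i]] <- q
      truth[[i]] <- dplyr::mutate(spec, locus = locus, .before = 1)
    }
    list(quartets = quartets, truth = dplyr::bind_rows(truth))
  })
}

build_quartet <- function(locus, locus_length, spec, target_subgenome) {
  if (nrow(spec) > 0) {
    if (any(spec$pos < 1 | spec$pos > locus_length)) {
      abort("planted SNP positions must lie within the locus")
    }
    if (anyDuplicated(spec$pos)) {
      abort("conflicting class assignments at one position")
    }
    if (!all(spec$class %in% c("interspecific_target", "subgenomic", "other"))) {
      abort("SNP class must be interspecific_target, subgenomic or other")
    }
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, locus_length, replace = TRUE)
  seqs <- list(Gb_At = ref, Gb_Dt = ref, Gh_At = ref, Gh_Dt = ref)
  tgt <- target_subgenome
  oth <- setdiff(c("At", "Dt"), tgt)
  for (j in seq_len(nrow(spec))) {
    pos <- spec$pos[j]
    alt <- sample(setdiff(bases, ref[pos]), 3)
    switch(spec$class[j],
      subgenomic = {
        # At keeps ref, Dt carries alt in both species
        seqs$Gb_Dt[pos] <- alt[1]
        seqs$Gh_Dt[pos] <- alt[1]
      },
      interspecific_target = {
        # Gh target copy carries alt; everything else keeps ref
        seqs[[paste0("Gh_", tgt)]][pos] <- alt[1]
      },
      other = {
        # all four copies pairwise different
        seqs[[paste0("Gb_", tgt)]][pos] <- ref[pos]
        seqs[[paste0("Gh_", tgt)]][pos] <- alt[1]
        seqs[[paste0("Gb_", oth)]][pos] <- alt[2]
        seqs[[paste0("Gh_", oth)]][pos] <- alt[3]
      }
    )
  }
  fiber_quartet(
    locus = locus,
    seqs = vapply(seqs, paste, character(1), collapse = ""),
    target_subgenome = tgt
  )
}

#' Construct a homeolog quartet object
#'
#' @param locus Locus id.
#' @param seqs Named character vector of four equal-length ACGT sequences
#'   with names `Gb_At`, `Gb_Dt`, `Gh_At`, `Gh_Dt`.
#' @param target_subgenome Subgenome carrying the candidate gene.
#' @return Object of class `fiber_quartet`.
#' @export
fiber_quartet <- function(locus, seqs, target_subgenome = "At") {
  want <- c("Gb_At", "Gb_Dt", "Gh_At", "Gh_Dt")
  if (!all(want %in% names(seqs))) {
    abort("quartet needs sequences Gb_At, Gb_Dt, Gh_At, Gh_Dt")
  }
  seqs <- toupper(seqs[want])
  check_dna_alphabet(seqs, "quartet sequence")
  if (length(unique(nchar(seqs))) != 1) {
    abort("quartet sequences must have equal aligned length")
  }
  structure(
    list(locus = locus, seqs = seqs, target_subgenome = target_subgenome),
    class = "fiber_quartet"
  )
}

#' @export
print.fiber_quartet <- function(x, ...) {
  cat(sprintf("Homeolog quartet %s (%d bp, target %s)\n",
              x$locus, nchar(x$seqs[1]), x$target_subgenome))
  invisible(x)
}

#' Write / read quartets as FASTA
#'
#' Record ids follow the `LOCUS|SPECIES|SUBGENOME` convention (e.g.,
#' `L0001|Gb|At`); sequences are wrapped at 60 columns.
#'
#' @param quartets List of `fiber_quartet` objects.
#' @param path FASTA file path.
#' @param target_subgenome Target subgenome to attach on reading.
#' @return `write_quartets_fasta()` returns `path` invisibly;
#'   `read_quartets_fasta()` returns a list of `fiber_quartet` objects.
#' @export
write_quartets_fasta <- function(quartets, path) {
  recs <- unlist(lapply(quartets, function(q) {
    keys <- names(q$seqs)
    ids <- vapply(strsplit(keys, "_", fixed = TRUE), function(p) {
      paste(q$locus, p[1], p[2], sep = "|")
    }, character(1))
    stats::setNames(q$seqs, ids)
  }))
  set <- Biostrings::DNAStringSet(recs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' @rdname write_quartets_fasta
#' @export
read_quartets_fasta <- function(path, target_subgenome = "At") {
  set <- Biostrings::readDNAStringSet(path)
  ids <- strsplit(names(set), "|", fixed = TRUE)
  bad <- lengths(ids) != 3
  if (any(bad)) {
    abort(sprintf("malformed FASTA record id at record %d", which(bad)[1]))
  }
  meta <- tibble::tibble(
    locus = vapply(ids, `[`, character(1), 1),
    key = paste(vapply(ids, `[`, character(1), 2),
                vapply(ids, `[`, character(1), 3), sep = "_"),
    seq = as.character(set)
  )
  loci <- unique(meta$locus)
  lapply(loci, function(l) {
    m <- meta[meta$locus == l, ]
    fiber_quartet(l, stats::setNames(m$seq, m$key), target_subgenome)
  })
}
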