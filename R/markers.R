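#' Scan a homeolog quartet for classified SNP sites
#'
#' Walks every aligned position and classifies the variable ones:
#'
#' * `subgenomic` - At allele differs from Dt allele and each subgenome's
#'   allele is conserved between the species;
#' * `interspecific_target` - Gb and Gh differ on the target subgenome while
#'   the other subgenome is invariant between species;
#' * `other` - any remaining variable configuration.
#'
#' @param quartet A `fiber_quartet`.
#' @return Tibble: `pos` (1-based), `class`, and the four alleles
#'   (`gb_at`, `gb_dt`, `gh_at`, `gh_dt`).
#' @export
scan_snp_sites <- function(quartet) {
  stopifnot(inherits(quartet, "fiber_quartet"))
  ch <- lapply(quartet$seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  if (length(unique(lengths(ch))) != 1) abort("sequence length mismatch")
  tgt <- quartet$target_subgenome
  oth <- setdiff(c("At", "Dt"), tgt)
  gb_t <- ch[[paste0("Gb_", tgt)]]; gh_t <- ch[[paste0("Gh_", tgt)]]
  gb_o <- ch[[paste0("Gb_", oth)]]; gh_o <- ch[[paste0("Gh_", oth)]]

  variable <- !(gb_t == gh_t & gb_t == gb_o & gb_o == gh_o)
  subgenomic <- ch$Gb_At == ch$Gh_At & ch$Gb_Dt == ch$Gh_Dt &
    ch$Gb_At != ch$Gb_Dt
  interspecific <- gb_t != gh_t & gb_o == gh_o & !subgenomic

  pos <- which(variable)
  cls <- dplyr::case_when(
    subgenomic[pos] ~ "subgenomic",
    interspecific[pos] ~ "interspecific_target",
    .default = "other"
  )
  tibble::tibble(
    pos = pos,
    class = cls,
    gb_at = ch$Gb_At[pos], gb_dt = ch$Gb_Dt[pos],
    gh_at = ch$Gh_At[pos], gh_dt = ch$Gh_Dt[pos]
  )
}

#' Primer melting temperature
#'
#' GC-content formula `Tm = 64.9 + 41 * (GC - 16.4) / length` for primers of
#' 14 nt and longer; the Wallace rule `2 * (A + T) + 4 * (G + C)` for shorter
#' oligos.
#'
#' @param seq Character vector of ACGT primer sequences (length >= 8 nt).
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
melting_temperature <- function(seq) {
  check_dna_alphabet(toupper(seq), "primer")
  seq <- toupper(seq)
  len <- nchar(seq)
  if (any(len < 8)) abort("primers must be at least 8 nt")
  gc <- gc_fraction(seq) * len
  ifelse(len >= 14,
         64.9 + 41 * (gc - 16.4) / len,
         2 * (len - gc) + 4 * gc)
}

#' Default primer design constraints
#'
#' Common allele-specific PCR practice: primers of 18-25 nt, melting
#' temperatures within 55-65 degrees C and within 5 degrees of each other,
#' GC content 40-60%, and an anchor-to-anchor product span of 100-600 bp.
#' The amplification model tolerates at most `max_mismatch_3p5` mismatches in
#' the five 3'-terminal bases (the terminal base itself must match exactly)
#' and requires `min_identity` overall primer-template identity.
#'
#' @param len_min,len_max Primer length bounds (nt).
#' @param tm_min,tm_max Melting temperature window (degrees C).
#' @param max_tm_diff Maximum pairwise Tm difference (degrees C).
#' @param gc_min,gc_max GC-content bounds (fractions).
#' @param product_min,product_max Product-span window (bp, anchor to anchor).
#' @param max_mismatch_3p5 Mismatches tolerated in the 3'-terminal 5 nt.
#' @param min_identity Minimum overall primer-template identity.
#' @return Named list of constraints.
#' @export
primer_constraints <- function(len_min = 18L, len_max = 25L,
                               tm_min = 55, tm_max = 65, max_tm_diff = 5,
                               gc_min = 0.4, gc_max = 0.6,
                               product_min = 100L, product_max = 600L,
                               max_mismatch_3p5 = 1L, min_identity = 0.9) {
  list(len_min = len_min, len_max = len_max, tm_min = tm_min, tm_max = tm_max,
       max_tm_diff = max_tm_diff, gc_min = gc_min, gc_max = gc_max,
       product_min = product_min, product_max = product_max,
       max_mismatch_3p5 = max_mismatch_3p5, min_identity = min_identity)
}

# All 3'-anchor positions where `primer` binds the plus strand of
# `template_ch` as a forward primer: exact 3'-terminal match, bounded
# mismatches in the 3'-terminal five bases, bounded overall identity.
forward_sites <- function(primer, template_ch, constraints) {
  p <- strsplit(primer, "", fixed = TRUE)[[1]]
  L <- length(p)
  N <- length(template_ch)
  if (N < L) return(integer(0))
  ends <- L:N
  keep <- vapply(ends, function(e) {
    w <- template_ch[(e - L + 1):e]
    mism <- p != w
    if (mism[L]) return(FALSE)                           # 3'-terminal exact
    if (sum(mism[seq(max(1, L - 4), L)]) > constraints$max_mismatch_3p5) {
      return(FALSE)
    }
    mean(!mism) >= constraints$min_identity
  }, logical(1))
  ends[keep]
}

# All 3'-anchor positions (template coordinates) where `primer` binds the
# minus strand as a reverse primer. The primer's 3'-terminal base pairs with
# template position s; alignment compares revcomp(primer) laid 5'->3' on the
# template so the primer 3' end maps to the window start.
reverse_sites <- function(primer, template_ch, constraints) {
  rc <- strsplit(revcomp(primer), "", fixed = TRUE)[[1]]
  L <- length(rc)
  N <- length(template_ch)
  if (N < L) return(integer(0))
  starts <- 1:(N - L + 1)
  keep <- vapply(starts, function(s) {
    w <- template_ch[s:(s + L - 1)]
    mism <- rc != w
    if (mism[1]) return(FALSE)                           # 3'-terminal exact
    if (sum(mism[seq_len(min(5, L))]) > constraints$max_mismatch_3p5) {
      return(FALSE)
    }
    mean(!mism) >= constraints$min_identity
  }, logical(1))
  starts[keep]
}

#' Predict amplification of a primer pair on a template
#'
#' In-silico PCR under the package's mismatch model: a product is reported
#' when the forward and the reverse primer each bind the template (exact
#' 3'-terminal match, at most `max_mismatch_3p5` mismatches in the
#' 3'-terminal five bases, overall identity at least `min_identity`), the
#' primers converge, and the anchor-to-anchor span falls inside the product
#' window.
#'
#' @param fwd,rev Primer sequences written 5' to 3'.
#' @param template Template sequence (plus strand).
#' @param constraints A [primer_constraints()] list.
#' @return The smallest qualifying product span in bp, or `NA` if no product.
#' @export
predict_amplification <- function(fwd, rev, template,
                                  constraints = primer_constraints()) {
  check_dna_alphabet(toupper(c(fwd, rev, template)), "sequence")
  tch <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  f <- forward_sites(toupper(fwd), tch, constraints)
  r <- reverse_sites(toupper(rev), tch, constraints)
  if (length(f) == 0 || length(r) == 0) return(NA_integer_)
  spans <- outer(r, f, function(s, e) s - e + 1L)
  ok <- spans >= max(2L, constraints$product_min) &
    spans <= constraints$product_max
  if (!any(ok)) return(NA_integer_)
  as.integer(min(spans[ok]))
}

#' Design a tri-primer allele-specific marker for one locus
#'
#' Searches both layouts (allele-specific primers on the forward strand with
#' a reverse common primer, and the mirror image). P1 and P2 are anchored
#' with their 3'-terminal base on an interspecific SNP of the target
#' subgenome and differ only at that terminal base (Gb vs Gh allele); the
#' common primer P3 is 3'-anchored on a subgenomic SNP so that the
#' homeologous copy on the other subgenome never amplifies. Among feasible
#' designs the one with the smallest product span wins; ties break by
#' leftmost allele-specific anchor, then leftmost P3 anchor, then
#' lexicographically smallest primer sequences. A design is feasible only if
#' it also reproduces the expected amplification pattern on the four
#' template sequences under [predict_amplification()] (in-silico assay
#' validation).
#'
#' @param quartet A `fiber_quartet`.
#' @param constraints A [primer_constraints()] list.
#' @return A one-row tibble (`status = "designed"` with primers, anchors,
#'   Tm values and product span) or a one-row `status = "NA"` tibble when no
#'   site pair satisfies the constraints.
#' @export
design_triplet <- function(quartet, constraints = primer_constraints()) {
  sites <- scan_snp_sites(quartet)
  no_design <- tibble::tibble(
    locus = quartet$locus, target_subgenome = quartet$target_subgenome,
    status = "NA",
    p1 = NA_character_, p2 = NA_character_, p3 = NA_character_,
    layout = NA_character_, as_anchor = NA_integer_, p3_anchor = NA_integer_,
    tm_p1 = NA_real_, tm_p2 = NA_real_, tm_p3 = NA_real_,
    product_size = NA_integer_
  )
  inter <- sites$pos[sites$class == "interspecific_target"]
  sub <- sites$pos[sites$class == "subgenomic"]
  if (length(inter) == 0 || length(sub) == 0) return(no_design)

  tgt <- quartet$target_subgenome
  gb_t <- quartet$seqs[[paste0("Gb_", tgt)]]
  gh_t <- quartet$seqs[[paste0("Gh_", tgt)]]
  gb_ch <- strsplit(gb_t, "", fixed = TRUE)[[1]]
  gh_ch <- strsplit(gh_t, "", fixed = TRUE)[[1]]
  N <- length(gb_ch)

  pairs <- tidyr::crossing(i = inter, j = sub) |>
    dplyr::mutate(product = abs(.data$j - .data$i) + 1L) |>
    dplyr::filter(.data$product >= constraints$product_min,
                  .data$product <= constraints$product_max) |>
    dplyr::arrange(.data$product, .data$i, .data$j)

  lens <- seq(constraints$len_min, constraints$len_max)
  for (row in seq_len(nrow(pairs))) {
    i <- pairs$i[row]; j <- pairs$j[row]
    cands <- list()
    for (len1 in lens) {
      for (len3 in lens) {
        if (j > i) {
          # layout: AS primers forward, P3 reverse
          if (i - len1 + 1 < 1 || j + len3 - 1 > N) next
          p1 <- paste(gb_ch[(i - len1 + 1):i], collapse = "")
          p2 <- paste(c(gb_ch[(i - len1 + 1):(i - 1)], gh_ch[i]),
                      collapse = "")
          p3 <- revcomp(paste(gb_ch[j:(j + len3 - 1)], collapse = ""))
          layout <- "as_forward"
        } else {
          # mirrored layout: AS primers reverse, P3 forward
          if (i + len1 - 1 > N || j - len3 + 1 < 1) next
          p1 <- revcomp(paste(gb_ch[i:(i + len1 - 1)], collapse = ""))
          p2_plus <- c(gh_ch[i], gb_ch[(i + 1):(i + len1 - 1)])
          p2 <- revcomp(paste(p2_plus, collapse = ""))
          p3 <- paste(gb_ch[(j - len3 + 1):j], collapse = "")
          layout <- "as_reverse"
        }
        tms <- melting_temperature(c(p1, p2, p3))
        gcs <- gc_fraction(c(p1, p2, p3))
        if (any(tms < constraints$tm_min | tms > constraints$tm_max)) next
        if (max(tms) - min(tms) > constraints$max_tm_diff) next
        if (any(gcs < constraints$gc_min | gcs > constraints$gc_max)) next
        cands[[length(cands) + 1]] <- list(
          p1 = p1, p2 = p2, p3 = p3, layout = layout, tms = tms
        )
      }
    }
    if (length(cands) == 0) next
    keys <- vapply(cands, function(cc) paste(cc$p1, cc$p2, cc$p3), character(1))
    for (idx in order(keys)) {
      cc <- cands[[idx]]
      if (validate_triplet(cc, quartet, constraints)) {
        return(tibble::tibble(
          locus = quartet$locus, target_subgenome = tgt, status = "designed",
          p1 = cc$p1, p2 = cc$p2, p3 = cc$p3,
          layout = cc$layout, as_anchor = i, p3_anchor = j,
          tm_p1 = cc$tms[1], tm_p2 = cc$tms[2], tm_p3 = cc$tms[3],
          product_size = pairs$product[row]
        ))
      }
    }
  }
  no_design
}

# Amplification pattern the assay requires: (P1,P3) amplifies the Gb target
# copy and nothing else; (P2,P3) amplifies the Gh target copy and nothing
# else; neither pair amplifies a non-target homeolog alone.
validate_triplet <- function(cand, quartet, constraints) {
  tgt <- quartet$target_subgenome
  oth <- setdiff(c("At", "Dt"), tgt)
  tmpl <- list(
    gb_t = quartet$seqs[[paste0("Gb_", tgt)]],
    gh_t = quartet$seqs[[paste0("Gh_", tgt)]],
    gb_o = quartet$seqs[[paste0("Gb_", oth)]],
    gh_o = quartet$seqs[[paste0("Gh_", oth)]]
  )
  amp <- function(asp, template) {
    if (cand$layout == "as_forward") {
      predict_amplification(asp, cand$p3, template, constraints)
    } else {
      predict_amplification(cand$p3, asp, template, constraints)
    }
  }
  ok <- !is.na(amp(cand$p1, tmpl$gb_t)) &&
    is.na(amp(cand$p1, tmpl$gh_t)) &&
    is.na(amp(cand$p1, tmpl$gb_o)) &&
    is.na(amp(cand$p1, tmpl$gh_o)) &&
    !is.na(amp(cand$p2, tmpl$gh_t)) &&
    is.na(amp(cand$p2, tmpl$gb_t)) &&
    is.na(amp(cand$p2, tmpl$gb_o)) &&
    is.na(amp(cand$p2, tmpl$gh_o))
  isTRUE(ok)
}

#' Design markers for a set of loci
#'
#' Runs [design_triplet()] on every quartet and assigns serial marker ids
#' (`HEBAU0001`, `HEBAU0002`, ...) to the designable loci; undesignable loci
#' keep `status = "NA"` and a missing marker id, mirroring assays that fail
#' in practice.
#'
#' @param quartets List of `fiber_quartet` objects.
#' @param constraints A [primer_constraints()] list.
#' @param prefix Marker id prefix.
#' @return Tibble with one row per locus, class `fiber_markers`.
#' @export
design_markers <- function(quartets, constraints = primer_constraints(),
                           prefix = "HEBAU") {
  res <- purrr::map_dfr(quartets, design_triplet, constraints = constraints)
  designed <- res$status == "designed"
  res <- res |>
    dplyr::mutate(
      marker_id = ifelse(designed,
                         sprintf("%s%04d", prefix, cumsum(designed)),
                         NA_character_),
      .after = "locus"
    )
  class(res) <- c("fiber_markers", class(res))
  res
}

#' Call a genotype from the two amplification outcomes
#'
#' The Gb/Gb homozygote yields a product only with the (P1, P3) pair, the
#' Gh/Gh homozygote only with (P2, P3), and the heterozygote with both; a
#' double failure is recorded as `Missing`.
#'
#' @param p1p3,p2p3 Logical (or product/NA) amplification outcomes;
#'   vectorised.
#' @return Character vector of calls: `"Gb/Gb"`, `"Gh/Gh"`, `"Gb/Gh"` or
#'   `"Missing"`.
#' @export
call_genotype <- function(p1p3, p2p3) {
  a <- if (is.logical(p1p3)) p1p3 else !is.na(p1p3)
  b <- if (is.logical(p2p3)) p2p3 else !is.na(p2p3)
  dplyr::case_when(
    a & !b ~ "Gb/Gb",
    !a & b ~ "Gh/Gh",
    a & b ~ "Gb/Gh",
    .default = "Missing"
  )
}

#' Genotype a population in silico
#'
#' For each designed marker, amplification of the two primer pairs is
#' predicted once per canonical template (Gb target copy, Gh target copy,
#' non-target homeolog) and then mapped onto every line's template set: a
#' line carrying genotype Gb/Gb at a locus presents the Gb target copy plus
#' the (always present) non-target homeolog, the heterozygote presents both
#' target copies, and so on. [call_genotype()] converts the two outcomes
#' into a genotype call.
#'
#' @param genotypes Tibble with `line`, `marker`, `genotype` columns giving
#'   each line's true genotype at each marker locus (`Gb/Gb`, `Gb/Gh`,
#'   `Gh/Gh`).
#' @param markers A `fiber_markers` design table whose `marker_id` values
#'   cover the markers in `genotypes`.
#' @param quartets The quartet list the designs came from.
#' @param constraints A [primer_constraints()] list.
#' @return Tibble: `line`, `marker`, `call`.
#' @export
genotype_population <- function(genotypes, markers, quartets,
                                constraints = primer_constraints()) {
  stopifnot(all(c("line", "marker", "genotype") %in% names(genotypes)))
  loci <- stats::setNames(quartets, vapply(quartets, `[[`, character(1), "locus"))
  des <- markers[markers$status == "designed", , drop = FALSE]
  patt <- purrr::map_dfr(seq_len(nrow(des)), function(r) {
    m <- des[r, ]
    q <- loci[[m$locus]]
    tgt <- q$target_subgenome
    oth <- setdiff(c("At", "Dt"), tgt)
    amp <- function(asp, template) {
      if (m$layout == "as_forward") {
        !is.na(predict_amplification(asp, m$p3, template, constraints))
      } else {
        !is.na(predict_amplification(m$p3, asp, template, constraints))
      }
    }
    tibble::tibble(
      marker = m$marker_id,
      p1_gb = amp(m$p1, q$seqs[[paste0("Gb_", tgt)]]),
      p1_gh = amp(m$p1, q$seqs[[paste0("Gh_", tgt)]]),
      p1_nt = amp(m$p1, q$seqs[[paste0("Gh_", oth)]]),
      p2_gb = amp(m$p2, q$seqs[[paste0("Gb_", tgt)]]),
      p2_gh = amp(m$p2, q$seqs[[paste0("Gh_", tgt)]]),
      p2_nt = amp(m$p2, q$seqs[[paste0("Gh_", oth)]])
    )
  })
  gt <- genotypes |>
    dplyr::inner_join(patt, by = "marker") |>
    dplyr::mutate(
      has_gb = .data$genotype %in% c("Gb/Gb", "Gb/Gh"),
      has_gh = .data$genotype %in% c("Gh/Gh", "Gb/Gh"),
      p1p3 = (.data$has_gb & .data$p1_gb) | (.data$has_gh & .data$p1_gh) |
        .data$p1_nt,
      p2p3 = (.data$has_gb & .data$p2_gb) | (.data$has_gh & .data$p2_gh) |
        .data$p2_nt,
      call = call_genotype(.data$p1p3, .data$p2p3)
    ) |>
    dplyr::select("line", "marker", "call")
  gt
}
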