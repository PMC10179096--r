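test_that("SNP scanning classifies all three site configurations", {
  seqs <- toy_quartet_seqs()
  q <- fiber_quartet("L0001", seqs, "At")
  sites <- scan_snp_sites(q)
  expect_equal(sites$pos, c(30, 250))
  expect_equal(sites$class, c("interspecific_target", "subgenomic"))

  # a position where all four sequences differ pairwise is "other"
  ch <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  alleles <- c("A", "C", "G", "T")
  for (k in seq_along(ch)) ch[[k]][100] <- alleles[k]
  q2 <- fiber_quartet("L0002",
                      vapply(ch, paste, character(1), collapse = ""), "At")
  s2 <- scan_snp_sites(q2)
  expect_equal(s2$class[s2$pos == 100], "other")

  # identical sequences scan empty
  q3 <- fiber_quartet("L0003", rep(stats::setNames(seqs[1], NULL), 4) |>
                        stats::setNames(names(seqs)), "At")
  expect_equal(nrow(scan_snp_sites(q3)), 0)
})

test_that("melting temperature follows the GC formula and the Wallace rule", {
  p20 <- paste0(strrep("AT", 5), strrep("GC", 5)) # 20-mer, 10 GC
  expect_equal(melting_temperature(p20), 64.9 + 41 * (10 - 16.4) / 20,
               tolerance = 1e-12)
  expect_equal(melting_temperature(p20), 51.78, tolerance = 1e-10)
  expect_equal(melting_temperature("ATATATATAT"), 20)
  # monotone in GC at fixed length
  tms <- melting_temperature(c("ATATATATATATATATATAT",
                               "GTATATATATATATATATAT",
                               "GCATATATATATATATATAT"))
  expect_true(all(diff(tms) > 0))
  expect_error(melting_temperature("ATATNNAT"), "A/C/G/T")
  expect_error(melting_temperature("ATAT"), "at least 8")
})

test_that("the toy locus yields the expected anchors and product span", {
  q <- fiber_quartet("L0001", toy_quartet_seqs(), "At")
  d <- design_triplet(q)
  expect_equal(d$status, "designed")
  expect_equal(d$as_anchor, 30)
  expect_equal(d$p3_anchor, 250)
  expect_equal(d$product_size, 221)
  # P1 and P2 differ exactly at the 3'-terminal base
  n <- nchar(d$p1)
  expect_equal(substr(d$p1, 1, n - 1), substr(d$p2, 1, n - 1))
  expect_false(substr(d$p1, n, n) == substr(d$p2, n, n))
})

test_that("design equals the exhaustive-search oracle on small loci", {
  set.seed(99)
  n_checked <- 0
  for (rep in 1:6) {
    qs <- simulate_quartets(n_loci = 1, locus_length = 400,
                            seed = 100 + rep)
    q <- qs$quartets[[1]]
    d <- design_triplet(q)
    o <- oracle_design(q$seqs, q$target_subgenome)
    if (is.null(o)) {
      expect_equal(d$status, "NA")
    } else {
      n_checked <- n_checked + 1
      expect_equal(d$status, "designed")
      expect_equal(d$product_size, o$prod)
      expect_equal(d$as_anchor, o$i)
      expect_equal(d$p3_anchor, o$j)
      expect_equal(d$p1, o$p1)
      expect_equal(d$p2, o$p2)
      expect_equal(d$p3, o$p3)
    }
  }
  expect_gte(n_checked, 2) # the comparison must actually exercise designs
})

test_that("design is a pure function and fails cleanly without a subgenomic site", {
  q <- fiber_quartet("L0001", toy_quartet_seqs(), "At")
  expect_identical(design_triplet(q), design_triplet(q))
  # no subgenomic SNP: only the interspecific site present
  spec <- list(tibble::tibble(pos = 30, class = "interspecific_target"))
  qs <- simulate_quartets(1, 400, snp_spec = spec, seed = 2)
  d <- design_triplet(qs$quartets[[1]])
  expect_equal(d$status, "NA")
  expect_true(is.na(d$p1))
})

test_that("amplification prediction honours the 3' anchor and genotype patterns", {
  q <- fiber_quartet("L0001", toy_quartet_seqs(), "At")
  d <- design_triplet(q)
  amp <- function(asp, tpl) {
    if (d$layout == "as_forward") {
      predict_amplification(asp, d$p3, tpl)
    } else {
      predict_amplification(d$p3, asp, tpl)
    }
  }
  # Gb target template: product with P1/P3, none with P2/P3
  expect_false(is.na(amp(d$p1, q$seqs[["Gb_At"]])))
  expect_true(is.na(amp(d$p2, q$seqs[["Gb_At"]])))
  # Gh target template: the mirror image
  expect_false(is.na(amp(d$p2, q$seqs[["Gh_At"]])))
  expect_true(is.na(amp(d$p1, q$seqs[["Gh_At"]])))
  # the non-target homeolog alone never amplifies (P3 3' mismatch)
  expect_true(is.na(amp(d$p1, q$seqs[["Gb_Dt"]])))
  expect_true(is.na(amp(d$p1, q$seqs[["Gh_Dt"]])))
  expect_true(is.na(amp(d$p2, q$seqs[["Gb_Dt"]])))
  expect_true(is.na(amp(d$p2, q$seqs[["Gh_Dt"]])))
})

test_that("genotype calls map the two band patterns onto the three classes", {
  expect_equal(call_genotype(TRUE, FALSE), "Gb/Gb")
  expect_equal(call_genotype(FALSE, TRUE), "Gh/Gh")
  expect_equal(call_genotype(TRUE, TRUE), "Gb/Gh")
  expect_equal(call_genotype(FALSE, FALSE), "Missing")
  # product/NA inputs behave like logicals
  expect_equal(call_genotype(221L, NA_integer_), "Gb/Gb")
  expect_equal(call_genotype(NA_integer_, NA_integer_), "Missing")
})

test_that("in-silico genotyping reproduces simulated truth exactly", {
  qs <- simulate_quartets(n_loci = 12, seed = 61)
  des <- design_markers(qs$quartets)
  designed <- des$marker_id[des$status == "designed"]
  expect_gte(length(designed), 6)

  pop <- simulate_population(population_config(
    n_lines = 80, n_chromosomes = length(designed),
    markers_per_chromosome = 1, seed = 62))
  map_markers <- sort(unique(pop$genotypes$marker))[seq_along(designed)]
  truth <- dplyr::filter(pop$genotypes, marker %in% map_markers)
  truth$marker <- designed[match(truth$marker, map_markers)]
  calls <- genotype_population(truth, des, qs$quartets)
  j <- dplyr::inner_join(truth, calls, by = c("line", "marker"))
  expect_equal(nrow(j), 80 * length(designed))
  expect_equal(mean(j$genotype == j$call), 1)
})

test_that("marker ids are zero-padded serials over the designable loci", {
  qs <- simulate_quartets(n_loci = 6, seed = 77)
  des <- design_markers(qs$quartets)
  got <- des$marker_id[!is.na(des$marker_id)]
  expect_equal(got, sprintf("HEBAU%04d", seq_along(got)))
})
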