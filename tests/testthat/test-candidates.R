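test_that("set intersection across accessions behaves as a set identity", {
  expect_setequal(intersect_accessions(list(c("A", "B", "C"),
                                            c("B", "C", "D"))), c("B", "C"))
  expect_length(intersect_accessions(list(c("A"), c("B"))), 0)
  expect_setequal(intersect_accessions(list(c("A", "B"), c("A", "B"),
                                            c("B", "A"))), c("A", "B"))
  expect_error(intersect_accessions(list(c("A"))), "at least two")
})

test_that("cross-species filter passes planted genes and only subsets its input", {
  cfg <- sim_config(
    n_genes = 400,
    planted_counts = c(xs_elong = 20, elong_IV_II = 20),
    seed = 13
  )
  sim <- simulate_counts(cfg)
  truth <- sim$truth
  group_genes <- truth$gene_id[truth$elongation_group == "IV"]
  cand <- cross_species_filter(group_genes, sim$counts, "elongation")
  expect_true(all(cand$gene_id %in% group_genes))
  planted <- truth$gene_id[truth$cross_species_up]
  expect_gte(mean(planted %in% cand$gene_id), 0.9)
  # equal-expression genes must fail
  flat <- truth$gene_id[truth$label == "elong_IV_II"]
  expect_length(intersect(cand$gene_id, flat), 0)
  # per-timepoint statistics are reported for the stage
  expect_true(all(c("log2fc_5", "log2fc_10", "log2fc_15",
                    "q_5", "q_10", "q_15") %in% names(cand)))
  expect_error(
    cross_species_filter(group_genes,
                         dplyr::filter(sim$counts, species == "Gb"),
                         "elongation"),
    "lack species")
})

test_that("strict mode is at most as permissive as pooling", {
  cfg <- sim_config(n_genes = 300, planted_counts = c(xs_scw_type2 = 15),
                    seed = 17)
  sim <- simulate_counts(cfg)
  genes <- sim$truth$gene_id
  pooled <- cross_species_filter(genes, sim$counts, "scw")
  strict <- cross_species_filter(genes, sim$counts, "scw", strict = TRUE)
  expect_true(all(strict$gene_id %in% pooled$gene_id))
})

test_that("SCW type split separates Gh-shared from Gb-specific upregulation", {
  cfg <- sim_config(
    n_genes = 300,
    planted_counts = c(xs_scw_type1 = 20, xs_scw_type2 = 20),
    seed = 19
  )
  sim <- simulate_counts(cfg)
  calls <- stage_calls(sim$counts, by = "accession")
  truth <- sim$truth
  cands <- truth$gene_id[truth$cross_species_up]
  types <- split_scw_types(cands, calls, cfg$accessions)
  j <- dplyr::inner_join(types, truth, by = "gene_id")
  expect_gte(mean(j$scw_type.x == j$scw_type.y), 0.9)
  expect_error(split_scw_types(c("NOPE"), calls, cfg$accessions), "missing")
})

test_that("type rules follow the two-of-three / both-accessions convention", {
  mk_calls <- function(n_up_acc1, n_up_acc2) {
    tps <- c(20, 25, 30)
    tibble::tibble(
      gene_id = "g",
      unit = rep(c("HY405", "ND13"), each = 3),
      dpa = rep(tps, 2),
      call = c(ifelse(seq_len(3) <= n_up_acc1, "up", "ns"),
               ifelse(seq_len(3) <= n_up_acc2, "up", "ns"))
    )
  }
  accs <- default_accessions()
  expect_equal(split_scw_types("g", mk_calls(3, 3), accs)$scw_type, "I")
  expect_equal(split_scw_types("g", mk_calls(2, 2), accs)$scw_type, "I")
  expect_equal(split_scw_types("g", mk_calls(0, 0), accs)$scw_type, "II")
  expect_equal(split_scw_types("g", mk_calls(2, 0), accs)$scw_type, "II")
})

test_that("hypergeometric enrichment matches brute-force enumeration", {
  # the worked example: N = 10, M = 4, n = 5, k = 3
  genes <- sprintf("g%02d", 1:10)
  ann <- tibble::tibble(term = "T1", gene = genes[1:4])
  study <- c(genes[1:3], genes[5:6])   # 3 annotated of 5 drawn
  res <- hypergeom_enrich(study, ann, genes)
  expect_equal(res$k, 3)
  expect_equal(res$p, 66 / 252, tolerance = 1e-12)
  expect_equal(res$p, oracle_hyper_enum(10, 4, 5, 3), tolerance = 1e-12)

  # random small configurations against the enumeration oracle
  set.seed(23)
  for (i in 1:12) {
    N <- sample(8:20, 1)
    M <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    uni <- sprintf("u%02d", 1:N)
    ann_i <- tibble::tibble(term = "T", gene = uni[1:M])
    st <- sample(uni, n)
    k <- sum(st %in% uni[1:M])
    p_pkg <- hypergeom_enrich(st, ann_i, uni)$p
    expect_equal(p_pkg, oracle_hyper_enum(N, M, n, k), tolerance = 1e-12)
  }

  # forced cases
  res0 <- hypergeom_enrich(genes[5:9], ann, genes)  # k = 0
  expect_equal(res0$p, 1)
  ann_all <- tibble::tibble(term = "T", gene = genes)
  expect_equal(hypergeom_enrich(genes[1:5], ann_all, genes)$p, 1)
  expect_error(hypergeom_enrich("x", ann, genes), "subset")
  expect_error(hypergeom_enrich(character(0), ann, character(0)), "empty")
})
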