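test_that("RPKM follows the defining formula and conserves total counts", {
  tbl <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    length = c(2000, 1500, 1000),
    sample = "A_00", accession = "A", species = "Gb", dpa = 0,
    library_size = c(1e6, 2e7, 1e6),
    count = c(10, 300, 0)
  )
  r <- compute_rpkm(tbl)
  expect_equal(r$rpkm[1], 5.0)
  expect_equal(r$rpkm[2], 10.0)
  expect_equal(r$rpkm[3], 0.0)
  # zero iff zero
  expect_identical(r$rpkm == 0, r$count == 0)
  # conservation: rpkm * length * lib / 1e9 recovers the counts
  expect_equal(r$rpkm * r$length * r$library_size / 1e9, r$count,
               tolerance = 1e-6)
})

test_that("RPKM validates its inputs", {
  tbl <- tibble::tibble(
    gene_id = "g", length = 100, sample = "s", accession = "a",
    species = "Gb", dpa = 0, library_size = 0, count = 1
  )
  expect_error(compute_rpkm(tbl), "library sizes")
  expect_error(compute_rpkm(tbl[0, ]), "empty")
  expect_error(compute_rpkm(dplyr::select(tbl, -"count")), "missing columns")
})

test_that("z-score uses sample sd, centres exactly, maps constants to zero", {
  expect_equal(zscore_profile(rep(2, 7)), rep(0, 7))
  expect_equal(zscore_profile(c(1, 3)), c(-1, 1) / sqrt(2), tolerance = 1e-6)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(7, sd = runif(1, 0.5, 5))
    z <- zscore_profile(x)
    expect_lt(abs(sum(z)), 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
  expect_error(zscore_profile(numeric(0)))
})

test_that("two-library DE matches the stated formulas", {
  # symmetric case
  r0 <- de_two_library(20, 1e6, 20, 1e6)
  expect_equal(r0$log2fc, 0)
  expect_equal(r0$p, 1, tolerance = 1e-12)
  # hand-checkable case: 400 vs 100 reads per million
  r1 <- de_two_library(400, 1e6, 100, 1e6)
  expect_equal(r1$log2fc, log2(400.5 / 100.5), tolerance = 1e-12)
  phat <- 500 / 2e6
  z <- (400e-6 - 100e-6) / sqrt(phat * (1 - phat) * 2e-6)
  expect_equal(r1$z, z, tolerance = 1e-12)
  expect_lt(r1$p, 1e-10)
  expect_equal(r1$log2fc, 1.995, tolerance = 1e-3)
  # antisymmetry
  r2 <- de_two_library(100, 1e6, 400, 1e6)
  expect_equal(r2$log2fc, -r1$log2fc)
  expect_equal(r2$p, r1$p)
  # no-information case is pinned to the null
  r3 <- de_two_library(0, 1e6, 0, 2e6)
  expect_equal(r3$log2fc, 0)
  expect_equal(r3$p, 1)
  expect_error(de_two_library(1, 0, 1, 10), "positive")
})

test_that("two-library DE agrees with a Fisher-exact oracle", {
  # within the numerically meaningful range (p >= 1e-12) the normal test
  # tracks Fisher's exact test to half a decade; in the far tail a normal
  # approximation cannot track the exact log-tail, but both tests must agree
  # that the result is overwhelmingly significant
  grid <- expand.grid(
    k1 = c(10, 25, 60, 150, 400),
    k2 = c(10, 25, 60, 150, 400),
    n = c(1e5, 1e6)
  )
  for (i in seq_len(nrow(grid))) {
    k1 <- grid$k1[i]; k2 <- grid$k2[i]; n <- grid$n[i]
    phat <- (k1 + k2) / (2 * n)
    if (phat * n < 10) next
    p_norm <- de_two_library(k1, n, k2, n)$p
    p_fish <- fisher.test(matrix(c(k1, n - k1, k2, n - k2), 2))$p.value
    if (p_fish >= 1e-12) {
      expect_lt(abs(log10(p_norm) - log10(p_fish)), 0.5)
    } else {
      expect_lt(p_norm, 1e-8)
    }
  }
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  set.seed(7)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(q >= p))
    expect_true(all(q >= 0 & q <= 1))
    # monotone along sorted p
    expect_false(is.unsorted(q[order(p)]))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("DE calls apply both the fold-change and the Q gates", {
  expect_equal(call_de(2.0, 0.001), "up")
  expect_equal(call_de(0.9, 1e-8), "ns")
  expect_equal(call_de(-1.5, 0.004), "down")
  expect_equal(call_de(-1.5, 0.006), "ns")
  expect_equal(call_de(1.0, 0.001), "ns") # strict inequality
})

test_that("stage calls adjust per comparison and detect planted shifts", {
  cfg <- sim_config(
    n_genes = 400,
    planted_counts = c(elong_IV_II = 20),
    seed = 5
  )
  sim <- simulate_counts(cfg)
  calls <- stage_calls(sim$counts, by = "accession")
  expect_setequal(unique(calls$dpa), c(5, 10, 15, 20, 25, 30))
  expect_setequal(unique(calls$unit), cfg$accessions$accession)
  # Q >= p always, within each comparison family
  expect_true(all(calls$q >= calls$p - 1e-12))
  planted <- sim$truth$gene_id[sim$truth$label == "elong_IV_II"]
  up10 <- calls$gene_id[calls$dpa == 10 & calls$call == "up" &
                          calls$unit == "Pima90-53"]
  expect_gt(mean(planted %in% up10), 0.9)
})

test_that("sample PCA is centred, ordered and linear", {
  # two identical samples: zero variance, equal coordinates
  r2 <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), 2),
    sample = rep(c("s1", "s2"), each = 2),
    accession = "A", species = "Gb", dpa = rep(c(0, 0), each = 2),
    rpkm = c(1, 2, 1, 2)
  )
  p2 <- sample_pca(r2)
  expect_equal(p2$scores$PC1[1], p2$scores$PC1[2])
  expect_equal(sum(p2$var_explained), 0)

  # sample C equal to the average of A and B on the log scale
  set.seed(3)
  va <- rnorm(30, 5, 2); vb <- rnorm(30, 5, 2); vc <- (va + vb) / 2
  r3 <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:30), 3),
    sample = rep(c("A", "B", "C"), each = 30),
    accession = rep(c("A", "B", "C"), each = 30),
    species = "Gb", dpa = 0,
    rpkm = 2^c(va, vb, vc) - 1
  )
  p3 <- sample_pca(r3)
  sc <- p3$scores
  expect_equal(sc$PC1[sc$sample == "C"],
               mean(sc$PC1[sc$sample %in% c("A", "B")]), tolerance = 1e-8)
  # variance explained: non-increasing, sums to <= 1
  expect_false(is.unsorted(rev(p3$var_explained)))
  expect_lte(sum(p3$var_explained), 1 + 1e-12)

  # agreement with a direct eigendecomposition oracle (up to sign)
  m <- log2(matrix(2^c(va, vb, vc) - 1, nrow = 3, byrow = TRUE) + 1)
  mc <- sweep(m, 2, colMeans(m))
  ev <- eigen(tcrossprod(mc))   # sample-space eigenvectors
  pc1_oracle <- ev$vectors[, 1] * sqrt(ev$values[1])
  cors <- abs(cor(sc$PC1, pc1_oracle))
  expect_equal(cors, 1, tolerance = 1e-8)
  expect_error(sample_pca(r3[r3$sample == "A", ]), "two samples")
})
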