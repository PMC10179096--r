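calls_vec <- function(...) {
  v <- c(...)
  names(v) <- c("5", "10", "15", "20", "25", "30")
  v
}

test_that("six-category DEG typing follows the stage-status rules", {
  cases <- list(
    list(calls_vec("up", "up", "up", "ns", "ns", "ns"), "I"),
    list(calls_vec("up", "up", "up", "up", "up", "up"), "II"),
    list(calls_vec("ns", "ns", "ns", "up", "up", "up"), "III"),
    list(calls_vec("down", "down", "down", "ns", "ns", "ns"), "IV"),
    list(calls_vec("down", "down", "down", "down", "down", "down"), "V"),
    list(calls_vec("ns", "ns", "ns", "down", "down", "down"), "VI"),
    list(calls_vec("up", "ns", "up", "ns", "ns", "ns"), "none"),
    list(calls_vec("up", "up", "up", "up", "up", "ns"), "I")
  )
  for (cs in cases) {
    expect_equal(classify_deg_type(cs[[1]]), cs[[2]])
  }
  expect_error(classify_deg_type(c("5" = "up")), "timepoints")
})

test_that("elongation groups partition by SCW up-count and mean expression", {
  r <- c("5" = 50, "10" = 50, "15" = 50, "20" = 120, "25" = 120, "30" = 120)
  up_e <- calls_vec("up", "up", "up", "up", "up", "up")
  expect_equal(assign_elongation_group(up_e, r), "I")
  r2 <- r; r2[c("20", "25", "30")] <- 30
  expect_equal(assign_elongation_group(up_e, r2), "II")
  expect_equal(
    assign_elongation_group(calls_vec("up", "up", "up", "up", "up", "ns"), r),
    "III")
  expect_equal(
    assign_elongation_group(calls_vec("up", "up", "up", "ns", "ns", "ns"), r),
    "IV")
  expect_error(
    assign_elongation_group(calls_vec("up", "ns", "up", "ns", "ns", "ns"), r),
    "not elongation-up")
})

test_that("SCW groups split the u = 0 genes on the 30 DPA peak", {
  r <- c("0" = 2, "5" = 3, "10" = 3, "15" = 3, "20" = 80, "25" = 90,
         "30" = 70)
  up_s <- calls_vec("ns", "ns", "ns", "up", "up", "up")
  expect_equal(assign_scw_group(up_s, r), "IV")
  r30 <- r; r30["30"] <- 120
  expect_equal(assign_scw_group(up_s, r30), "V")
  r_el <- c("0" = 2, "5" = 90, "10" = 95, "15" = 92, "20" = 40, "25" = 45,
            "30" = 42)
  both <- calls_vec("up", "up", "up", "up", "up", "up")
  expect_equal(assign_scw_group(both, r_el), "I")
  expect_equal(assign_scw_group(both, r), "II")
  expect_equal(
    assign_scw_group(calls_vec("up", "up", "ns", "up", "up", "up"), r), "III")
  expect_error(
    assign_scw_group(calls_vec("up", "up", "ns", "up", "ns", "up"), r),
    "not SCW-up")
})

test_that("peak subgroups use the 90% peak set with the flat-top tie-break", {
  expect_equal(assign_peak_subgroup(c(100, 98, 40)), "IV-I")
  expect_equal(assign_peak_subgroup(c(40, 100, 50)), "IV-II")
  expect_equal(assign_peak_subgroup(c(30, 95, 100)), "IV-III")
  expect_equal(assign_peak_subgroup(c(100, 60, 95)), "IV-II") # both ends peak
  expect_error(assign_peak_subgroup(c(0, 0, 0)), "all-zero")
  expect_error(assign_peak_subgroup(c(1, 2)), "three")
})

test_that("assign_trends recovers planted archetypes and keeps axes consistent", {
  cfg <- sim_config(
    n_genes = 800,
    planted_counts = c(
      elong_I = 15, elong_II = 15, elong_III = 15, elong_IV_I = 15,
      elong_IV_II = 15, elong_IV_III = 15, scw_I = 15, scw_II = 15,
      scw_III = 15, scw_IV = 15, scw_V = 15
    ),
    seed = 31
  )
  sim <- simulate_counts(cfg)
  tr <- assign_trends(sim$counts)

  # partition invariants
  expect_true(all(tr$elongation_subgroup == "none" |
                    tr$elongation_group == "IV"))
  expect_true(all(tr$elongation_group != "IV" |
                    tr$elongation_subgroup != "none"))
  # axis consistency: elongation group IV implies DEG type I; elongation
  # group II implies DEG type II
  expect_true(all(tr$deg_type[tr$elongation_group == "IV"] == "I"))
  expect_true(all(tr$deg_type[tr$elongation_group == "II"] == "II"))

  truth <- sim$truth[sim$truth$label != "background", ]
  j <- dplyr::inner_join(tr, truth, by = "gene_id",
                         suffix = c("_hat", "_true"))
  ok <- (j$elongation_group_true == "none" |
           j$elongation_group_hat == j$elongation_group_true) &
    (j$elongation_subgroup_true == "none" |
       j$elongation_subgroup_hat == j$elongation_subgroup_true) &
    (j$scw_group_true == "none" | j$scw_group_hat == j$scw_group_true)
  expect_gte(mean(ok), 0.9)
})
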