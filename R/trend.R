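#' Classify a gene's six-category DEG type
#'
#' Stage-level status is strict: a stage counts as "up" ("down") only when
#' the gene is called up (down) versus 0 DPA at **all** of the stage's
#' timepoints. Types: I elongation-up only, II up at both stages, III SCW-up
#' only, IV elongation-down only, V down at both, VI SCW-down only, `none`
#' otherwise. Rules are evaluated in that order.
#'
#' @param calls Named character vector of vs-0-DPA calls (`"up"`, `"down"`,
#'   `"ns"`) with names `"5","10","15","20","25","30"`.
#' @return One of `"I".."VI"` or `"none"`.
#' @export
classify_deg_type <- function(calls) {
  calls <- check_call_vector(calls)
  des <- stage_design()
  e <- calls[as.character(des$elongation)]
  s <- calls[as.character(des$scw)]
  e_up <- all(e == "up"); s_up <- all(s == "up")
  e_dn <- all(e == "down"); s_dn <- all(s == "down")
  if (e_up && !s_up) return("I")
  if (e_up && s_up) return("II")
  if (s_up && !e_up) return("III")
  if (e_dn && !s_dn) return("IV")
  if (e_dn && s_dn) return("V")
  if (s_dn && !e_dn) return("VI")
  "none"
}

check_call_vector <- function(calls) {
  want <- as.character(c(stage_design()$elongation, stage_design()$scw))
  if (!all(want %in% names(calls))) {
    abort("calls must cover timepoints 5, 10, 15, 20, 25 and 30 DPA")
  }
  calls <- calls[want]
  if (!all(calls %in% c("up", "down", "ns"))) {
    abort("calls must be up, down or ns")
  }
  calls
}

#' Assign an elongation-up gene to expression group I-IV
#'
#' Groups partition the genes upregulated at all three elongation timepoints
#' by how strongly they also rise during SCW biosynthesis: with `u` the
#' number of SCW timepoints called up, group I has `u = 3` and a higher mean
#' RPKM during SCW than elongation, group II has `u = 3` otherwise, group III
#' has `u` of 1 or 2, and group IV (`u = 0`) is elongation-specific.
#'
#' @param calls Named call vector (see [classify_deg_type()]).
#' @param rpkm Named numeric vector of per-timepoint RPKM with names
#'   `"5".."30"` (mean over the *G. barbadense* accessions in the pipeline).
#' @return One of `"I".."IV"`.
#' @export
assign_elongation_group <- function(calls, rpkm) {
  calls <- check_call_vector(calls)
  des <- stage_design()
  e <- as.character(des$elongation); s <- as.character(des$scw)
  if (!all(calls[e] == "up")) {
    abort("gene is not elongation-up; group assignment undefined")
  }
  u <- sum(calls[s] == "up")
  if (u == 3) {
    if (mean(rpkm[s]) > mean(rpkm[e])) "I" else "II"
  } else if (u >= 1) {
    "III"
  } else {
    "IV"
  }
}

#' Assign an SCW-up gene to expression group I-V
#'
#' Mirrors [assign_elongation_group()] for genes upregulated at all three
#' SCW timepoints, with `u` now counting elongation timepoints called up.
#' Group V captures the `u = 0` genes whose expression peaks at 30 DPA
#' (maturation-leaning); the remaining `u = 0` genes form group IV.
#'
#' @inheritParams assign_elongation_group
#' @param rpkm Named numeric vector over all seven timepoints (`"0".."30"`).
#' @return One of `"I".."V"`.
#' @export
assign_scw_group <- function(calls, rpkm) {
  calls <- check_call_vector(calls)
  des <- stage_design()
  e <- as.character(des$elongation); s <- as.character(des$scw)
  if (!all(calls[s] == "up")) {
    abort("gene is not SCW-up; group assignment undefined")
  }
  u <- sum(calls[e] == "up")
  if (u == 3) {
    if (mean(rpkm[e]) > mean(rpkm[s])) "I" else "II"
  } else if (u >= 1) {
    "III"
  } else {
    all_tps <- as.character(default_timepoints())
    peak <- names(rpkm[all_tps])[which.max(rpkm[all_tps])]
    if (identical(peak, "30")) "V" else "IV"
  }
}

#' Assign a group-IV gene to a peak-time subgroup
#'
#' The peak set holds the elongation timepoints whose RPKM is within 90% of
#' the elongation maximum: IV-I peaks early (5 in the set, 15 not), IV-II
#' peaks at 10 only, IV-III peaks late (15 in, 5 not). When both 5 and 15
#' reach the peak set the profile is effectively flat-topped and the gene is
#' assigned IV-II.
#'
#' @param rpkm_elong Numeric vector of RPKM at 5, 10, 15 DPA (in that order).
#' @return One of `"IV-I"`, `"IV-II"`, `"IV-III"`.
#' @export
assign_peak_subgroup <- function(rpkm_elong) {
  if (length(rpkm_elong) != 3 || any(rpkm_elong < 0)) {
    abort("rpkm_elong must be three non-negative values")
  }
  if (all(rpkm_elong == 0)) {
    abort("all-zero elongation profile cannot be elongation-up")
  }
  peak <- rpkm_elong >= 0.9 * max(rpkm_elong)
  in5 <- peak[1]; in15 <- peak[3]
  if (in5 && !in15) return("IV-I")
  if (in15 && !in5) return("IV-III")
  "IV-II"
}

#' Full trend assignment for every gene
#'
#' Combines species-pooled *G. barbadense* stage calls with mean Gb RPKM to
#' label each gene on three axes: the six-category DEG type, the elongation
#' group (I-IV, subgroup IV-I/II/III for group IV), and the SCW group (I-V).
#' Genes that are not elongation-up (resp. SCW-up) receive `"none"` on that
#' axis.
#'
#' @param counts Long count tibble.
#' @param calls Optional precomputed species-pooled stage calls
#'   (`stage_calls(counts, by = "species")`); computed if missing.
#' @param lfc,q_threshold Thresholds passed to [stage_calls()].
#' @return Tibble: `gene_id`, `deg_type`, `elongation_group`,
#'   `elongation_subgroup`, `scw_group`.
#' @export
assign_trends <- function(counts, calls = NULL, lfc = 1, q_threshold = 0.005) {
  if (is.null(calls)) {
    calls <- stage_calls(counts, by = "species", lfc = lfc,
                         q_threshold = q_threshold)
  }
  gb_calls <- calls |>
    dplyr::filter(.data$unit == "Gb") |>
    dplyr::select("gene_id", "dpa", "call") |>
    tidyr::pivot_wider(names_from = "dpa", values_from = "call",
                       names_prefix = "c")

  rpkm_mean <- counts |>
    dplyr::filter(.data$species == "Gb") |>
    compute_rpkm() |>
    dplyr::group_by(.data$gene_id, .data$dpa) |>
    dplyr::summarise(rpkm = mean(.data$rpkm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "dpa", values_from = "rpkm",
                       names_prefix = "r")

  d <- dplyr::inner_join(gb_calls, rpkm_mean, by = "gene_id")
  need <- c(paste0("c", c(5, 10, 15, 20, 25, 30)),
            paste0("r", c(0, 5, 10, 15, 20, 25, 30)))
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    abort(paste0("missing timepoints in calls/RPKM: ",
                 paste(missing, collapse = ", ")))
  }

  e_up <- d$c5 == "up" & d$c10 == "up" & d$c15 == "up"
  s_up <- d$c20 == "up" & d$c25 == "up" & d$c30 == "up"
  e_dn <- d$c5 == "down" & d$c10 == "down" & d$c15 == "down"
  s_dn <- d$c20 == "down" & d$c25 == "down" & d$c30 == "down"
  u_scw <- (d$c20 == "up") + (d$c25 == "up") + (d$c30 == "up")
  u_el <- (d$c5 == "up") + (d$c10 == "up") + (d$c15 == "up")
  mean_e <- (d$r5 + d$r10 + d$r15) / 3
  mean_s <- (d$r20 + d$r25 + d$r30) / 3

  deg_type <- dplyr::case_when(
    e_up & !s_up ~ "I",
    e_up & s_up ~ "II",
    s_up & !e_up ~ "III",
    e_dn & !s_dn ~ "IV",
    e_dn & s_dn ~ "V",
    s_dn & !e_dn ~ "VI",
    .default = "none"
  )
  elongation_group <- dplyr::case_when(
    !e_up ~ "none",
    u_scw == 3 & mean_s > mean_e ~ "I",
    u_scw == 3 ~ "II",
    u_scw >= 1 ~ "III",
    .default = "IV"
  )
  peak_max <- pmax(d$r5, d$r10, d$r15)
  in5 <- d$r5 >= 0.9 * peak_max
  in15 <- d$r15 >= 0.9 * peak_max
  elongation_subgroup <- dplyr::case_when(
    elongation_group != "IV" ~ "none",
    in5 & !in15 ~ "IV-I",
    in15 & !in5 ~ "IV-III",
    .default = "IV-II"
  )
  all_r <- as.matrix(d[, paste0("r", default_timepoints())])
  peak_tp <- default_timepoints()[max.col(all_r, ties.method = "first")]
  scw_group <- dplyr::case_when(
    !s_up ~ "none",
    u_el == 3 & mean_e > mean_s ~ "I",
    u_el == 3 ~ "II",
    u_el >= 1 ~ "III",
    peak_tp == 30L ~ "V",
    .default = "IV"
  )

  tibble::tibble(
    gene_id = d$gene_id,
    deg_type = deg_type,
    elongation_group = elongation_group,
    elongation_subgroup = elongation_subgroup,
    scw_group = scw_group
  )
}
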