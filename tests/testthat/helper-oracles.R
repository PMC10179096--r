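# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, without calling the package's code path.

# Benjamini-Hochberg step-up from its definition: sort ascending,
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1, original order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail P(X >= k) by brute-force enumeration of all
# C(N, n) draws of the study set from the universe.
oracle_hyper_enum <- function(N, M, n, k) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(M)  # wlog the first M genes are annotated
  hits <- colSums(matrix(draws %in% annotated, nrow = n))
  mean(hits >= k)
}

# Pooled-variance two-sample t-test from the closed form.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Position-by-position SNP classification of a quartet, written directly
# from the class definitions.
oracle_scan <- function(seqs, target = "At") {
  ch <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  oth <- setdiff(c("At", "Dt"), target)
  out <- list()
  for (pos in seq_along(ch[[1]])) {
    a <- vapply(ch, `[`, character(1), pos)
    if (length(unique(a)) == 1) next
    cls <- if (a["Gb_At"] == a["Gh_At"] && a["Gb_Dt"] == a["Gh_Dt"] &&
               a["Gb_At"] != a["Gb_Dt"]) {
      "subgenomic"
    } else if (a[paste0("Gb_", target)] != a[paste0("Gh_", target)] &&
               a[paste0("Gb_", oth)] == a[paste0("Gh_", oth)]) {
      "interspecific_target"
    } else {
      "other"
    }
    out[[length(out) + 1]] <- data.frame(pos = pos, class = cls)
  }
  if (length(out) == 0) {
    return(data.frame(pos = integer(0), class = character(0)))
  }
  do.call(rbind, out)
}

# Independent GC / Tm computations for the primer-design oracle.
oracle_gc_count <- function(s) {
  sum(strsplit(s, "")[[1]] %in% c("G", "C"))
}
oracle_tm <- function(s) {
  L <- nchar(s)
  gc <- oracle_gc_count(s)
  if (L >= 14) 64.9 + 41 * (gc - 16.4) / L else 2 * (L - gc) + 4 * gc
}
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Naive binding check: does `primer` bind `template` anywhere with an exact
# 3'-terminal match, <= 1 mismatch in the 3'-terminal five bases and >= 90%
# identity? Returns 3'-anchor template positions.
oracle_bind_fwd <- function(primer, template) {
  p <- strsplit(primer, "")[[1]]; tpl <- strsplit(template, "")[[1]]
  L <- length(p); hits <- integer(0)
  for (e in L:length(tpl)) {
    w <- tpl[(e - L + 1):e]
    mm <- p != w
    if (!mm[L] && sum(mm[(L - 4):L]) <= 1 && mean(!mm) >= 0.9) {
      hits <- c(hits, e)
    }
  }
  hits
}
oracle_bind_rev <- function(primer, template) {
  rc <- strsplit(oracle_revcomp(primer), "")[[1]]
  tpl <- strsplit(template, "")[[1]]
  L <- length(rc); hits <- integer(0)
  for (s in 1:(length(tpl) - L + 1)) {
    w <- tpl[s:(s + L - 1)]
    mm <- rc != w
    if (!mm[1] && sum(mm[1:5]) <= 1 && mean(!mm) >= 0.9) hits <- c(hits, s)
  }
  hits
}
oracle_amplifies <- function(fwd, rev, template, product_min, product_max) {
  f <- oracle_bind_fwd(fwd, template)
  r <- oracle_bind_rev(rev, template)
  for (e in f) for (s in r) {
    span <- s - e + 1
    if (span >= max(2, product_min) && span <= product_max) return(TRUE)
  }
  FALSE
}

# Exhaustive tri-primer design search: every (interspecific anchor,
# subgenomic anchor, AS length, P3 length) combination, default constraints,
# ranked by product span, then AS anchor, then P3 anchor, then primer
# lexicographic order. Feasibility includes the assay-pattern validation on
# all four template sequences.
oracle_design <- function(seqs, target = "At",
                          len_range = 18:25, tm_range = c(55, 65),
                          tm_diff = 5, gc_range = c(0.4, 0.6),
                          product_range = c(100, 600)) {
  sites <- oracle_scan(seqs, target)
  inter <- sites$pos[sites$class == "interspecific_target"]
  sub <- sites$pos[sites$class == "subgenomic"]
  oth <- setdiff(c("At", "Dt"), target)
  gb <- strsplit(seqs[[paste0("Gb_", target)]], "")[[1]]
  gh <- strsplit(seqs[[paste0("Gh_", target)]], "")[[1]]
  templates <- list(
    gb_t = seqs[[paste0("Gb_", target)]],
    gh_t = seqs[[paste0("Gh_", target)]],
    gb_o = seqs[[paste0("Gb_", oth)]],
    gh_o = seqs[[paste0("Gh_", oth)]]
  )
  N <- length(gb)
  best <- NULL
  for (i in inter) for (j in sub) {
    prod <- abs(j - i) + 1
    if (prod < product_range[1] || prod > product_range[2]) next
    for (l1 in len_range) for (l3 in len_range) {
      if (j > i) {
        if (i - l1 + 1 < 1 || j + l3 - 1 > N) next
        p1 <- paste(gb[(i - l1 + 1):i], collapse = "")
        p2 <- paste(c(gb[(i - l1 + 1):(i - 1)], gh[i]), collapse = "")
        p3 <- oracle_revcomp(paste(gb[j:(j + l3 - 1)], collapse = ""))
        fwd1 <- p1; fwd2 <- p2; rev12 <- p3
        pair <- function(asp) list(fwd = asp, rev = p3)
      } else {
        if (i + l1 - 1 > N || j - l3 + 1 < 1) next
        p1 <- oracle_revcomp(paste(gb[i:(i + l1 - 1)], collapse = ""))
        p2 <- oracle_revcomp(paste(c(gh[i], gb[(i + 1):(i + l1 - 1)]),
                                   collapse = ""))
        p3 <- paste(gb[(j - l3 + 1):j], collapse = "")
        pair <- function(asp) list(fwd = p3, rev = asp)
      }
      tms <- vapply(c(p1, p2, p3), oracle_tm, numeric(1))
      gcs <- vapply(c(p1, p2, p3), function(s) {
        oracle_gc_count(s) / nchar(s)
      }, numeric(1))
      if (any(tms < tm_range[1] | tms > tm_range[2])) next
      if (max(tms) - min(tms) > tm_diff) next
      if (any(gcs < gc_range[1] | gcs > gc_range[2])) next
      amp <- function(asp, tpl) {
        pp <- pair(asp)
        oracle_amplifies(pp$fwd, pp$rev, tpl,
                         product_range[1], product_range[2])
      }
      ok <- amp(p1, templates$gb_t) && !amp(p1, templates$gh_t) &&
        !amp(p1, templates$gb_o) && !amp(p1, templates$gh_o) &&
        amp(p2, templates$gh_t) && !amp(p2, templates$gb_t) &&
        !amp(p2, templates$gb_o) && !amp(p2, templates$gh_o)
      if (!ok) next
      key <- list(prod = prod, i = i, j = j,
                  lex = paste(p1, p2, p3))
      better <- is.null(best) ||
        key$prod < best$prod ||
        (key$prod == best$prod && key$i < best$i) ||
        (key$prod == best$prod && key$i == best$i && key$j < best$j) ||
        (key$prod == best$prod && key$i == best$i && key$j == best$j &&
           key$lex < best$lex)
      if (better) {
        best <- c(key, list(p1 = p1, p2 = p2, p3 = p3))
      }
    }
  }
  best
}

# Shared small fixture: a toy quartet with one interspecific SNP and one
# subgenomic SNP at chosen positions. The background composition is mildly
# GC-enriched so that primer windows near the anchors satisfy the default
# Tm/GC constraints (the example presumes a designable locus).
toy_quartet_seqs <- function(len = 400, inter_pos = 30, sub_pos = 250,
                             seed = 1) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c(0.22, 0.28, 0.28, 0.22))
  gb_at <- gb_dt <- gh_at <- gh_dt <- ref
  gh_at[inter_pos] <- setdiff(c("A", "C", "G", "T"), ref[inter_pos])[1]
  alt <- setdiff(c("A", "C", "G", "T"), ref[sub_pos])[1]
  gb_dt[sub_pos] <- alt
  gh_dt[sub_pos] <- alt
  c(Gb_At = paste(gb_at, collapse = ""),
    Gb_Dt = paste(gb_dt, collapse = ""),
    Gh_At = paste(gh_at, collapse = ""),
    Gh_Dt = paste(gh_dt, collapse = ""))
}
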