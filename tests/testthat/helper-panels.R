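# Shared fixtures, all generated in code. Heavier objects are memoised per
# test run so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# a small clean panel: no background noise, plants only
small_clean_config <- function(seed = 11) {
  panel_config(seed = seed, n_drug_plants = 6, n_fiber_plants = 6,
               n_drug_seeds = 0, n_fiber_seeds = 0,
               het_rate = 0, background_mutation_rate = 0)
}

small_clean_panel <- function() {
  memo("small_clean_panel", simulate_panel(small_clean_config()))
}

# the default-scale plant panel used by the acceptance checks
plants_config <- function(seed = 1) {
  panel_config(seed = seed, n_drug_seeds = 0, n_fiber_seeds = 0)
}

plants_panel <- function() {
  memo("plants_panel", simulate_panel(plants_config()))
}

# variant calls + genotype matrix for the default plant panel, via the
# full alignment path
plants_genotypes <- function() {
  memo("plants_genotypes", {
    panel <- plants_panel()
    calls <- call_panel_variants(panel$sequences, panel$references)
    build_matrix(calls, labels = panel$metadata[, c("sample_id", "class")])
  })
}

plants_scan <- function() {
  memo("plants_scan", scan_loci(plants_genotypes()))
}

# independent alignment oracle: exhaustive enumeration of all global
# alignments of two short sequences under affine gap scoring (a gap of
# length L costs gap_open + L * gap_extend)
brute_force_align_score <- function(a, b, match = 2, mismatch = -3,
                                    gap_open = -5, gap_extend = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  score_cols <- function(pa, pb) {
    s <- 0; in_gap_a <- FALSE; in_gap_b <- FALSE
    for (i in seq_along(pa)) {
      if (pa[i] == "-") {
        s <- s + gap_extend + if (!in_gap_a) gap_open else 0
        in_gap_a <- TRUE; in_gap_b <- FALSE
      } else if (pb[i] == "-") {
        s <- s + gap_extend + if (!in_gap_b) gap_open else 0
        in_gap_b <- TRUE; in_gap_a <- FALSE
      } else {
        s <- s + if (pa[i] == pb[i]) match else mismatch
        in_gap_a <- FALSE; in_gap_b <- FALSE
      }
    }
    s
  }
  best <- -Inf
  recurse <- function(i, j, pa, pb) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score_cols(pa, pb))
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      recurse(i + 1, j + 1, c(pa, a[i]), c(pb, b[j]))
    }
    if (i <= length(a)) recurse(i + 1, j, c(pa, a[i]), c(pb, "-"))
    if (j <= length(b)) recurse(i, j + 1, c(pa, "-"), c(pb, b[j]))
  }
  recurse(1, 1, character(0), character(0))
  best
}

# independent AUC oracle: exhaustive enumeration of positive/negative
# pairs with ties counted one half
pair_enum_auc <- function(scores, labels, positive = "drug") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (x in sp) for (y in sn) {
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# independent Firth oracle: grid maximization of the penalized
# log-likelihood for an intercept + single-indicator design
grid_firth <- function(X, y, b0 = seq(-6, 6, 0.05), b1 = seq(-12, 12, 0.05)) {
  fl <- getFromNamespace(".firth_loglik", "cannamark")
  best <- c(NA, NA); best_ll <- -Inf
  for (i in b0) for (j in b1) {
    ll <- fl(c(i, j), X, y)
    if (ll > best_ll) { best_ll <- ll; best <- c(i, j) }
  }
  list(beta = best, loglik = best_ll)
}
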