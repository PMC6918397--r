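# Consensus-based discriminant scoring: per-locus points against the
# drug/fiber consensus alleles, weighted sums with AUC-optimized weights
# under a sign constraint, and threshold evaluation with stratified
# percentile-bootstrap confidence intervals.

# fixed allele ordering used to break consensus ties deterministically
.allele_order <- c("A", "C", "G", "T",
                   "B", "D", "H", "K", "M", "N", "R", "S", "V", "W", "Y",
                   "del", "ins", "ref")

#' Class consensus alleles at selected loci
#'
#' For each selected locus, the modal (most frequent) allele within the
#' drug class and within the fiber class. Ties are broken by a fixed
#' allele ordering (A < C < G < T < IUPAC codes < del/ins < ref) with a
#' warning, so the profile is deterministic.
#'
#' @param genotypes A genotype matrix from [build_matrix()].
#' @param loci Character vector of locus column names (typically the
#'   significant loci from [scan_loci()]).
#' @return A tibble with columns `locus`, `kind`, `drug_allele`,
#'   `fiber_allele`.
#' @export
consensus_profile <- function(genotypes, loci) {
  stopifnot(is.data.frame(genotypes), "class" %in% names(genotypes))
  missing <- setdiff(loci, names(genotypes))
  if (length(missing) > 0) {
    abort(paste0("locus absent from matrix: ", paste(missing, collapse = ", ")))
  }
  classes <- sort(unique(genotypes$class))
  if (!all(c("drug", "fiber") %in% classes)) {
    abort("genotype matrix must contain both 'drug' and 'fiber' samples")
  }
  info <- locus_info(genotypes)
  modal <- function(x, locus, cls) {
    tab <- table(x)
    top <- max(tab)
    cand <- names(tab)[tab == top]
    if (length(cand) > 1) {
      ord <- match(cand, .allele_order)
      cand <- cand[order(ord)]
      warn(paste0("consensus tie at ", locus, " in ", cls,
                  " class; kept '", cand[1], "' by allele ordering"))
    }
    cand[1]
  }
  drug_rows <- genotypes$class == "drug"
  tibble(
    locus = loci,
    kind = info$kind[match(loci, info$locus)],
    drug_allele = vapply(loci, function(l) {
      modal(genotypes[[l]][drug_rows], l, "drug")
    }, character(1), USE.NAMES = FALSE),
    fiber_allele = vapply(loci, function(l) {
      modal(genotypes[[l]][!drug_rows], l, "fiber")
    }, character(1), USE.NAMES = FALSE))
}

#' Points of a genotype cell against a consensus profile
#'
#' The three-way scoring rule: +1 if the cell equals the drug consensus
#' allele, -1 if it equals the fiber consensus allele, 0 otherwise (so a
#' heterozygous code matching neither consensus scores 0).
#'
#' @param cell Allele symbol(s) observed in the sample.
#' @param drug_allele,fiber_allele Consensus alleles at the locus.
#' @return Integer vector in \{-1, 0, 1\}.
#' @examples
#' locus_points(c("T", "C", "R"), drug_allele = "T", fiber_allele = "C")
#' @export
locus_points <- function(cell, drug_allele, fiber_allele) {
  ifelse(cell == drug_allele, 1L, ifelse(cell == fiber_allele, -1L, 0L))
}

#' Build a discriminant score specification
#'
#' Pairs an ordered set of loci with real weights and a decision threshold
#' (classification rule: score strictly greater than the threshold means
#' drug-type). SNP loci are scored through the consensus three-way rule of
#' [locus_points()]; indel loci (`*_del` / `*_ins` columns) contribute 1
#' when the variant is present and 0 otherwise, with the weight carrying
#' the sign.
#'
#' @param loci Character vector of locus column names.
#' @param weights Numeric weights, one per locus.
#' @param threshold Decision threshold (default 0).
#' @param auc Optional achieved AUC (filled by [optimize_weights()]).
#' @return An object of class `score_spec`.
#' @export
score_spec <- function(loci, weights, threshold = 0, auc = NA_real_) {
  if (length(loci) < 1 || length(loci) != length(weights)) {
    abort("need k >= 1 loci and one weight per locus")
  }
  kind <- dplyr::case_when(grepl("_del$", loci) ~ "deletion",
                           grepl("_ins$", loci) ~ "insertion",
                           TRUE ~ "snp")
  structure(list(loci = loci, kind = kind, weights = weights,
                 threshold = threshold, k = length(loci), auc = auc),
            class = "score_spec")
}

#' The published-style CBDAS indel score
#'
#' Convenience [score_spec()] assigning +1.1 points to carrying the 4-bp
#' CBDAS deletion and -1 point to carrying the AAC insertion, with decision
#' threshold 0. Over presence/absence genotypes the attainable scores are
#' exactly -1, 0, 0.1 and 1.1.
#'
#' @param del_locus,ins_locus Locus column names of the deletion and
#'   insertion.
#' @param del_weight,ins_weight Weights (defaults +1.1 and -1).
#' @return A `score_spec`.
#' @examples
#' indel_score_spec()
#' @export
indel_score_spec <- function(del_locus = "CBDAS_153_del",
                             ins_locus = "CBDAS_755_ins",
                             del_weight = 1.1, ins_weight = -1) {
  score_spec(c(del_locus, ins_locus), c(del_weight, ins_weight),
             threshold = 0)
}

#' @export
print.score_spec <- function(x, ...) {
  cat(sprintf("Discriminant score: %d loci, threshold %g%s\n", x$k,
              x$threshold,
              if (is.na(x$auc)) "" else sprintf(", AUC %.4f", x$auc)))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.score_spec <- function(x, ...) {
  tibble(locus = x$loci, kind = x$kind, weight = x$weights)
}

#' @exportS3Method generics::glance
glance.score_spec <- function(x, ...) {
  tibble(k = x$k, threshold = x$threshold, auc = x$auc,
         n_negative_weights = sum(x$weights < 0))
}

# per-sample, per-locus points matrix for a spec
.points_matrix <- function(genotypes, spec, profile = NULL) {
  missing <- setdiff(spec$loci, names(genotypes))
  if (length(missing) > 0) {
    warn(paste0("loci missing from matrix score 0 points: ",
                paste(missing, collapse = ", ")))
  }
  n <- nrow(genotypes)
  P <- matrix(0, nrow = n, ncol = spec$k)
  for (j in seq_len(spec$k)) {
    l <- spec$loci[j]
    if (!l %in% names(genotypes)) next
    cells <- genotypes[[l]]
    if (spec$kind[j] == "snp") {
      if (is.null(profile) || !l %in% profile$locus) {
        abort(paste0("consensus profile required for SNP locus ", l))
      }
      row <- profile[profile$locus == l, ]
      P[, j] <- locus_points(cells, row$drug_allele, row$fiber_allele)
    } else {
      P[, j] <- as.integer(cells != "ref")
    }
  }
  colnames(P) <- spec$loci
  P
}

#' Score every sample of a panel
#'
#' Computes the weighted sum of per-locus points for each sample under a
#' [score_spec()], using a consensus profile for SNP loci and
#' presence/absence for indel loci, and classifies each sample as
#' drug-type when its score exceeds the spec's threshold.
#'
#' @param genotypes A genotype matrix from [build_matrix()].
#' @param spec A [score_spec()].
#' @param profile A [consensus_profile()] covering the spec's SNP loci
#'   (not needed for an indel-only spec).
#' @return A tibble with columns `sample_id`, `class`, `score`,
#'   `predicted`.
#' @export
score_samples <- function(genotypes, spec, profile = NULL) {
  stopifnot(inherits(spec, "score_spec"))
  P <- .points_matrix(genotypes, spec, profile)
  s <- drop(P %*% spec$weights)
  tibble(sample_id = genotypes$sample_id, class = genotypes$class,
         score = s,
         predicted = ifelse(s > spec$threshold, "drug", "fiber"))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive-class score exceeds a
#' randomly chosen negative-class score, with ties counted one half --
#' computed from midranks, so it agrees exactly with exhaustive pair
#' enumeration.
#'
#' @param scores Numeric scores.
#' @param labels Class labels (two classes).
#' @param positive The positive (drug) class label; default `"drug"`.
#' @return AUC as a fraction in \[0, 1\].
#' @examples
#' auc_mw(c(2, 1, 1, 0), c("drug", "drug", "fiber", "fiber"))
#' @export
auc_mw <- function(scores, labels, positive = "drug") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select loci and weights maximizing the AUC
#'
#' Greedy forward selection of `k` loci by marginal AUC gain with, at each
#' step, a deterministic coordinate ascent over a fixed weight grid
#' (steps of 0.1 on \[-2, 2\]), under the constraint that at most
#' `allow_negative` weights are negative ("most weights non-negative").
#' Ties are broken toward the earlier candidate locus and the current
#' weight, so the result is reproducible for a given matrix order.
#'
#' @param genotypes A genotype matrix from [build_matrix()].
#' @param profile A [consensus_profile()] covering the candidate SNP loci.
#' @param k Number of loci to select (at least 1, at most the number of
#'   candidates).
#' @param candidates Candidate locus names; default all loci of `profile`.
#' @param allow_negative Maximum number of negative weights; default
#'   `floor((k - 1) / 2)`, except `k = 2` where one negative weight is
#'   admitted (the deletion/insertion pairing).
#' @param grid Weight grid searched per coordinate.
#' @param threshold Decision threshold stored in the returned spec.
#' @return A [score_spec()] with the achieved AUC in `$auc`.
#' @export
optimize_weights <- function(genotypes, profile, k,
                             candidates = profile$locus,
                             allow_negative = NULL,
                             grid = seq(-2, 2, by = 0.1),
                             threshold = 0) {
  if (k < 1) abort("k must be at least 1")
  if (k > length(candidates)) {
    abort(paste0("k = ", k, " exceeds the ", length(candidates),
                 " available loci"))
  }
  if (is.null(allow_negative)) {
    allow_negative <- if (k == 2) 1L else floor((k - 1) / 2)
  }
  grid <- sort(unique(round(grid, 10)))
  labels <- genotypes$class
  full_spec <- score_spec(candidates, rep(1, length(candidates)))
  P_all <- .points_matrix(genotypes, full_spec, profile)

  tune <- function(idx, w_init = NULL) {
    # coordinate ascent over the grid for the locus subset idx; warm
    # starting from the previous step's weights keeps the achieved AUC
    # non-decreasing as k grows
    P <- P_all[, idx, drop = FALSE]
    w <- w_init %||% rep(1, length(idx))
    best <- auc_mw(drop(P %*% w), labels)
    for (pass in 1:3) {
      changed <- FALSE
      for (i in seq_along(w)) {
        base <- drop(P[, -i, drop = FALSE] %*% w[-i])
        n_neg_other <- sum(w[-i] < 0)
        for (g in grid) {
          if (g < 0 && n_neg_other + 1 > allow_negative) next
          a <- auc_mw(base + g * P[, i], labels)
          if (a > best + 1e-12) {
            best <- a; w[i] <- g; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    list(w = w, auc = best)
  }

  selected <- integer(0)
  sel_w <- numeric(0)
  sel_auc <- -Inf
  for (step in seq_len(k)) {
    best_cand <- NA_integer_; best_fit <- NULL
    for (ci in setdiff(seq_along(candidates), selected)) {
      fit <- tune(c(selected, ci), w_init = c(sel_w, 1))
      if (is.null(best_fit) || fit$auc > best_fit$auc + 1e-12) {
        best_fit <- fit; best_cand <- ci
      }
    }
    selected <- c(selected, best_cand)
    sel_w <- best_fit$w
    sel_auc <- best_fit$auc
  }
  score_spec(candidates[selected], sel_w, threshold = threshold,
             auc = sel_auc)
}

#' Evaluate a score at its threshold with bootstrap confidence intervals
#'
#' Computes the AUC, and the sensitivity (drug samples with score above the
#' threshold) and specificity (fiber samples at or below it), with
#' class-stratified percentile-bootstrap 95% confidence intervals. When a
#' metric is constant across resamples its interval degenerates to the
#' point estimate.
#'
#' @param scores A tibble from [score_samples()] (columns `class`,
#'   `score`), or any data frame with those columns.
#' @param threshold Decision threshold (default 0).
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed Integer seed for the resampling; mandatory.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `score_eval`; see [tidy.score_eval()].
#' @export
evaluate_score <- function(scores, threshold = 0, B = 2000, seed,
                           conf = 0.95) {
  stopifnot(is.data.frame(scores), all(c("class", "score") %in% names(scores)))
  if (missing(seed)) abort("evaluate_score() requires an explicit seed")
  if (B < 1) abort("B must be at least 1")
  cls <- scores$class; s <- scores$score
  if (!all(c("drug", "fiber") %in% cls)) {
    abort("scores must contain both drug and fiber samples")
  }
  metrics <- function(cls, s) {
    c(auc = auc_mw(s, cls),
      sensitivity = mean(s[cls == "drug"] > threshold),
      specificity = mean(s[cls == "fiber"] <= threshold))
  }
  point <- metrics(cls, s)
  idx_d <- which(cls == "drug"); idx_f <- which(cls == "fiber")
  boot <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      take <- c(sample(idx_d, length(idx_d), replace = TRUE),
                sample(idx_f, length(idx_f), replace = TRUE))
      metrics(cls[take], s[take])
    }, numeric(3))
  })
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  res <- tibble(metric = names(point), estimate = unname(point),
                ci_low = unname(pmin(ci[1, ], point)),
                ci_high = unname(pmax(ci[2, ], point)))
  structure(list(metrics = res, threshold = threshold, B = B, seed = seed,
                 conf = conf, n_drug = length(idx_d), n_fiber = length(idx_f)),
            class = "score_eval")
}

#' @export
print.score_eval <- function(x, ...) {
  cat(sprintf(
    "Score evaluation at threshold %g (%d drug / %d fiber, B = %d)\n",
    x$threshold, x$n_drug, x$n_fiber, x$B))
  print(x$metrics)
  invisible(x)
}

#' Tidy a score evaluation
#'
#' @param x A `score_eval` from [evaluate_score()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per metric (`auc`,
#'   `sensitivity`, `specificity`) and percentile-bootstrap bounds.
#'   `glance()`: a one-row tibble with the point estimates and settings.
#' @exportS3Method generics::tidy
tidy.score_eval <- function(x, ...) x$metrics

#' @rdname tidy.score_eval
#' @exportS3Method generics::glance
glance.score_eval <- function(x, ...) {
  est <- setNames(x$metrics$estimate, x$metrics$metric)
  tibble(auc = est[["auc"]], sensitivity = est[["sensitivity"]],
         specificity = est[["specificity"]], threshold = x$threshold,
         B = x$B, conf = x$conf)
}
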