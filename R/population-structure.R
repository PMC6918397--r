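# Diversity and structure summaries: Gower distances over categorical
# loci, classical MDS coordinates for the biplot, Shannon-entropy variation
# summaries, and THC/CBD chemotype arithmetic with ratio-based grouping.

#' Gower distance between samples over categorical loci
#'
#' For all-categorical loci the Gower dissimilarity of two samples is the
#' fraction of compared loci at which their allele symbols differ; loci
#' where either sample is missing (`NA`) are excluded from that pair's
#' denominator. Computed with `cluster::daisy(metric = "gower")`.
#'
#' @param genotypes A genotype matrix from [build_matrix()] (or any data
#'   frame whose non-`sample_id`/`class` columns are categorical).
#' @return A symmetric matrix of pairwise distances in \[0, 1\] with sample
#'   ids as dimnames.
#' @export
gower_distance <- function(genotypes) {
  stopifnot(is.data.frame(genotypes))
  if (nrow(genotypes) < 2) abort("need at least 2 samples")
  ids <- if ("sample_id" %in% names(genotypes)) {
    genotypes$sample_id
  } else {
    as.character(seq_len(nrow(genotypes)))
  }
  cols <- .locus_cols(genotypes)
  if (length(cols) == 0) abort("no locus columns to compare")
  df <- as.data.frame(lapply(genotypes[cols], factor))
  d <- as.matrix(cluster::daisy(df, metric = "gower", warnBin = FALSE,
                                warnAsym = FALSE, warnConst = FALSE))
  dimnames(d) <- list(ids, ids)
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    abort(paste0("no comparable loci for pair ", ids[bad[1]], " / ",
                 ids[bad[2]]))
  }
  d
}

#' Classical (metric) multidimensional scaling of a distance matrix
#'
#' Double-centered eigendecomposition via `stats::cmdscale()`, with
#' coordinates ordered by eigenvalue and a deterministic sign convention
#' (each axis is flipped so its largest-magnitude loading is positive).
#' If fewer positive eigenvalues than `dims` exist, the missing axes are
#' zero-padded with a warning.
#'
#' @param d A symmetric distance matrix (e.g. from [gower_distance()]).
#' @param dims Number of output dimensions (default 2).
#' @return A tibble with columns `sample_id` and `MDS1` ... `MDSdims`, with
#'   the eigenvalues in attribute `"eig"`.
#' @export
classical_mds <- function(d, dims = 2) {
  d <- as.matrix(d)
  fit <- cmdscale(d, k = min(dims, nrow(d) - 1), eig = TRUE)
  pts <- fit$points
  n_pos <- ncol(pts)
  if (n_pos < dims) {
    warn(paste0("only ", n_pos, " positive-eigenvalue axes; padding ",
                dims - n_pos, " with zeros"))
    pts <- cbind(pts, matrix(0, nrow = nrow(d), ncol = dims - n_pos))
  }
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  out <- as_tibble(pts, .name_repair = ~ paste0("MDS", seq_len(ncol(pts))))
  out <- bind_cols(tibble(sample_id = rownames(d) %||%
                            as.character(seq_len(nrow(d)))), out)
  attr(out, "eig") <- fit$eig
  out
}

# per-locus Shannon entropy of the allele frequencies in x
.locus_entropy <- function(x, base = exp(1)) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Entropy-based variation summaries
#'
#' "Mean entropy" is the per-locus Shannon entropy of allele frequencies
#' (natural log by default) averaged over loci. The overall value uses all
#' samples; within-group values are computed inside each group; the
#' between-group value is the mean per-locus entropy of the group-consensus
#' (modal) alleles, so it is 0 when every group has the same consensus
#' everywhere.
#'
#' @param genotypes A genotype matrix from [build_matrix()].
#' @param groups A vector (one entry per sample) partitioning the samples,
#'   e.g. chemotype groups or variety.
#' @param base Logarithm base; default natural log.
#' @return A list with `overall` (scalar), `within` (named numeric per
#'   group), `between` (scalar).
#' @export
entropy_summary <- function(genotypes, groups, base = exp(1)) {
  cols <- .locus_cols(genotypes)
  if (length(cols) == 0) abort("no locus columns")
  groups <- as.character(groups)
  if (length(groups) != nrow(genotypes)) {
    abort("groups must have one entry per sample")
  }
  if (any(table(groups) == 0)) abort("empty group")
  cells <- as.matrix(genotypes[cols])
  overall <- mean(apply(cells, 2, .locus_entropy, base = base))
  lev <- unique(groups)
  within <- vapply(lev, function(g) {
    mean(apply(cells[groups == g, , drop = FALSE], 2, .locus_entropy,
               base = base))
  }, numeric(1))
  consensus <- vapply(lev, function(g) {
    apply(cells[groups == g, , drop = FALSE], 2, function(x) {
      tab <- table(x)
      cand <- names(tab)[tab == max(tab)]
      cand[order(match(cand, .allele_order))][1]
    })
  }, character(length(cols)))
  consensus <- matrix(consensus, nrow = length(cols))
  between <- mean(apply(consensus, 1, .locus_entropy, base = base))
  list(overall = overall, within = within, between = between)
}

#' THC/CBD ratio and chemotype grouping
#'
#' Adds to a per-variety chemotype table the THC/CBD ratio of the variety
#' means and the standard four chemotype groups: group 1 with ratio up to
#' 0.05, group 2 up to 0.2, group 3 up to 10, and group 4 above 10
#' (boundaries belong to the lower group). When mean CBD is 0 the ratio is
#' 0 if mean THC is also 0 and infinite otherwise.
#'
#' @param chem A data frame with columns `thc` and `cbd` (percent of dry
#'   weight), e.g. from [simulate_chemotable()] or [chemotype_reference()].
#' @return The input tibble with `ratio` and `group` columns appended.
#' @examples
#' chem_ratio_and_group(chemotype_reference())
#' @export
chem_ratio_and_group <- function(chem) {
  stopifnot(is.data.frame(chem), all(c("thc", "cbd") %in% names(chem)))
  if (any(chem$thc < 0, na.rm = TRUE) || any(chem$cbd < 0, na.rm = TRUE)) {
    abort("THC and CBD percentages must be non-negative")
  }
  ratio <- ifelse(chem$cbd == 0,
                  ifelse(chem$thc == 0, 0, Inf),
                  chem$thc / chem$cbd)
  group <- cut(ratio, breaks = c(-Inf, 0.05, 0.2, 10, Inf),
               labels = FALSE)
  as_tibble(chem) |> mutate(ratio = ratio, group = as.integer(group))
}

#' Plot MDS biplot coordinates
#'
#' Scatter of the first two MDS axes, coloured by class (and shaped by an
#' optional grouping), mirroring the usual marker-panel biplot.
#'
#' @param coords A tibble from [classical_mds()].
#' @param metadata Optional data frame with `sample_id` plus `class`
#'   and/or `group` columns to join on.
#' @return A ggplot object.
#' @export
plot_mds <- function(coords, metadata = NULL) {
  df <- coords
  if (!is.null(metadata)) {
    df <- left_join(df, metadata, by = "sample_id")
  }
  aes_args <- ggplot2::aes(x = .data$MDS1, y = .data$MDS2)
  p <- ggplot2::ggplot(df, aes_args)
  if ("class" %in% names(df) && "group" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(
      colour = .data$class, shape = factor(.data$group)), size = 2)
  } else if ("class" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(shape = "chemotype group") + ggplot2::theme_minimal()
}

#' Plot per-sample discriminant scores
#'
#' Jittered strip plot of scores by class with the decision threshold.
#'
#' @param scores A tibble from [score_samples()].
#' @param threshold Decision threshold to draw (default 0).
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, threshold = 0) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$class, y = .data$score,
                                       colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = "discriminant score")
}

#' Plot chemotype composition
#'
#' Per-variety mean THC vs CBD, coloured by class and labelled with the
#' chemotype group.
#'
#' @param chem A chemotype tibble with `ratio`/`group` columns (see
#'   [chem_ratio_and_group()]); they are added if absent.
#' @return A ggplot object.
#' @export
plot_chemotypes <- function(chem) {
  if (!"group" %in% names(chem)) chem <- chem_ratio_and_group(chem)
  ggplot2::ggplot(chem, ggplot2::aes(x = .data$cbd, y = .data$thc,
                                     colour = .data$class,
                                     shape = factor(.data$group))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "CBD (% dry weight)", y = "THC (% dry weight)",
                  shape = "chemotype group")
}
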