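# Per-locus association between genotype and class: Firth's
# penalized-likelihood logistic regression with a penalized
# likelihood-ratio test per locus, and Benjamini-Hochberg control of the
# false discovery rate across loci.
#
# Firth's penalty (the Jeffreys prior, 0.5 * log det of the Fisher
# information) keeps the estimates finite under complete separation --
# exactly the situation a perfectly discriminating marker creates, where
# ordinary maximum likelihood diverges.

# penalized log-likelihood at beta for design X, response y
.firth_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  XtWX <- crossprod(X * sqrt(w))
  ll <- sum(y * eta - log1p(exp(eta)))
  ll + 0.5 * determinant(XtWX, logarithm = TRUE)$modulus[1]
}

# modified score and ingredients at beta; the hat diagonals always come
# from the full design so constrained fits share the same objective
.firth_score <- function(beta, X, y) {
  k <- ncol(X)
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  Xw <- X * sqrt(w)
  XtWX <- crossprod(Xw)
  XtWX_inv <- tryCatch(solve(XtWX), error = function(e) {
    solve(XtWX + diag(1e-10, k))
  })
  # hat diagonals of W^1/2 X (X'WX)^-1 X' W^1/2
  h <- rowSums((Xw %*% XtWX_inv) * Xw)
  list(U = drop(crossprod(X, y - p + h * (0.5 - p))), XtWX = XtWX)
}

# Newton iteration on the Firth-modified score with step damping: a step
# is accepted if it improves the penalized likelihood or shrinks the score
# norm (the information matrix is not the exact penalized Hessian, so an
# undamped Newton step can cycle around the optimum without this).
#
# `free` selects the coordinates being maximized over; the others stay at
# zero but the Jeffreys penalty is always that of the FULL design, so a
# fit with free = 1 is the profile (constrained) optimum used by the
# penalized likelihood-ratio test -- guaranteeing LR >= 0 because both
# fits maximize the same objective over nested parameter sets.
.firth_newton <- function(X, y, free = seq_len(ncol(X)), tol = 1e-8,
                          max_iter = 50) {
  beta <- numeric(ncol(X))
  ll <- .firth_loglik(beta, X, y)
  sc <- .firth_score(beta, X, y)
  for (iter in seq_len(max_iter)) {
    u_norm <- max(abs(sc$U[free]))
    if (u_norm < tol) {
      return(list(beta = beta, loglik = ll, iter = iter, converged = TRUE))
    }
    H_inv <- tryCatch(solve(sc$XtWX[free, free, drop = FALSE]),
                      error = function(e) {
                        solve(sc$XtWX[free, free, drop = FALSE] +
                                diag(1e-10, length(free)))
                      })
    delta <- numeric(ncol(X))
    delta[free] <- drop(H_inv %*% sc$U[free])
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- .firth_loglik(cand, X, y)
      sc_new <- .firth_score(cand, X, y)
      if (ll_new > ll + 1e-12 || max(abs(sc_new$U[free])) < u_norm ||
          step < 1e-6) {
        break
      }
      step <- step / 2
    }
    beta <- cand
    ll <- ll_new
    sc <- sc_new
  }
  list(beta = beta, loglik = ll, iter = max_iter,
       converged = max(abs(sc$U[free])) < tol)
}

#' Firth penalized-likelihood logistic regression for one locus
#'
#' Fits `class ~ locus` where the locus is a categorical variable coded as
#' indicator contrasts against a baseline allele, maximizing the
#' Jeffreys-prior-penalized log-likelihood by Newton iteration on the
#' Firth-modified score. The p-value is the profile penalized
#' likelihood-ratio test of the whole locus term (degrees of freedom =
#' number of alleles minus one): the null value maximizes the same
#' penalized objective with the locus coefficients constrained to zero,
#' so the statistic is non-negative by construction and the test stays
#' well-defined even under complete separation.
#'
#' @param y Binary response: logical, 0/1, or a factor/character with two
#'   levels (the second level in sort order is modelled as 1; for
#'   drug/fiber labels, fiber = 1).
#' @param x Categorical locus: character or factor of allele symbols.
#' @param baseline Optional baseline allele for the indicator coding;
#'   default is the most frequent allele among the samples with `y = 0`
#'   (the class-0 consensus).
#' @param tol Convergence tolerance on the max absolute modified score.
#' @param max_iter Maximum Newton iterations.
#' @return A list with `coefficients` (named: intercept then one indicator
#'   per non-baseline allele), `loglik`, `loglik_null`, `p_raw`, `df`,
#'   `converged`, `iter`.
#' @examples
#' y <- rep(c(0, 1), each = 10)
#' x <- rep(c("C", "T"), each = 10)   # complete separation
#' firth_fit(y, x)$p_raw
#' @export
firth_fit <- function(y, x, baseline = NULL, tol = 1e-8, max_iter = 50) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    lev <- sort(unique(y))
    if (length(lev) != 2) abort("y must have exactly two distinct values")
    y <- as.integer(y == lev[2])
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("y must contain both classes")
  x <- as.character(x)
  if (length(x) != length(y)) abort("x and y lengths differ")
  alleles <- sort(unique(x))
  if (length(alleles) < 2) {
    abort("monomorphic locus is untestable; exclude it before fitting")
  }
  if (is.null(baseline)) {
    x0 <- x[y == 0]
    tab <- sort(table(factor(x0, levels = alleles)), decreasing = TRUE)
    baseline <- names(tab)[1]
  }
  others <- setdiff(alleles, baseline)
  X <- cbind(`(Intercept)` = 1,
             vapply(others, function(a) as.numeric(x == a),
                    numeric(length(x))))
  colnames(X) <- c("(Intercept)", others)

  fit <- .firth_newton(X, y, tol = tol, max_iter = max_iter)
  if (!fit$converged) {
    abort(paste0("Firth fit did not converge in ", max_iter,
                 " iterations (last penalized log-likelihood ",
                 signif(fit$loglik, 8), ")"))
  }
  # profile LRT: the null maximizes the same penalized objective with the
  # locus coefficients pinned at zero, so the statistic is never negative
  null <- .firth_newton(X, y, free = 1L, tol = tol, max_iter = max_iter)
  df <- length(others)
  lr <- max(0, 2 * (fit$loglik - null$loglik))
  p <- pchisq(lr, df = df, lower.tail = FALSE)
  list(coefficients = setNames(fit$beta, colnames(X)),
       loglik = fit$loglik, loglik_null = null$loglik,
       p_raw = min(1, max(p, .Machine$double.xmin)),
       df = df, converged = TRUE, iter = fit$iter)
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up false-discovery-rate adjustment (with the usual monotonicity
#' enforcement, via `stats::p.adjust(method = "BH")`), flagging values with
#' adjusted p at or below `q`.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return A tibble with columns `p_raw`, `p_adj`, `significant`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) {
    return(tibble(p_raw = numeric(), p_adj = numeric(),
                  significant = logical()))
  }
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble(p_raw = p_values, p_adj = adj, significant = adj <= q)
}

#' Scan every polymorphic locus for association with class
#'
#' Runs [firth_fit()] on each polymorphic locus of a genotype matrix
#' (heterozygous IUPAC symbols and indel symbols are distinct categories)
#' and applies Benjamini-Hochberg correction jointly across all tested
#' loci of both genes. Monomorphic loci are untestable and excluded from
#' the multiplicity correction.
#'
#' @param genotypes A genotype matrix from [build_matrix()] (columns
#'   `sample_id`, `class`, then one column per locus).
#' @param q FDR level (default 0.05).
#' @param tol,max_iter Passed to [firth_fit()].
#' @return A tibble with one row per tested locus: `locus`, `gene`, `pos`,
#'   `kind`, `p_raw`, `p_adj`, `significant`.
#' @export
scan_loci <- function(genotypes, q = 0.05, tol = 1e-8, max_iter = 50) {
  stopifnot(is.data.frame(genotypes), "class" %in% names(genotypes))
  if (length(unique(genotypes$class)) != 2) {
    abort("genotype matrix must carry both classes")
  }
  info <- locus_info(genotypes)
  cols <- .locus_cols(genotypes)
  y <- as.integer(genotypes$class == sort(unique(genotypes$class))[2])

  poly <- cols[vapply(cols, function(cn) {
    length(unique(genotypes[[cn]])) >= 2
  }, logical(1))]
  if (length(poly) == 0) {
    warn("no polymorphic loci to test")
    return(tibble(locus = character(), gene = character(), pos = integer(),
                  kind = character(), p_raw = numeric(), p_adj = numeric(),
                  significant = logical()))
  }

  p_raw <- vapply(poly, function(cn) {
    x <- genotypes[[cn]]
    alleles <- sort(unique(x))
    # baseline: consensus allele of the second sorted class (fiber, for
    # drug/fiber labels); the joint LRT p-value is invariant to this choice
    x0 <- x[y == 1]
    tab <- sort(table(factor(x0, levels = alleles)), decreasing = TRUE)
    others <- setdiff(alleles, names(tab)[1])
    X <- cbind(1, vapply(others, function(a) as.numeric(x == a),
                         numeric(length(x))))
    fit <- .firth_newton(X, y, tol = tol, max_iter = max_iter)
    if (!fit$converged) {
      abort(paste0("Firth fit did not converge for locus ", cn))
    }
    null <- .firth_newton(X, y, free = 1L, tol = tol, max_iter = max_iter)
    lr <- max(0, 2 * (fit$loglik - null$loglik))
    min(1, max(pchisq(lr, df = length(others), lower.tail = FALSE),
               .Machine$double.xmin))
  }, numeric(1))

  adj <- bh_adjust(unname(p_raw), q = q)
  res <- tibble(locus = poly) |>
    left_join(info, by = "locus") |>
    select("locus", "gene", "pos", "kind") |>
    bind_cols(adj)
  arrange(res, .data$p_adj, .data$gene, .data$pos)
}
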