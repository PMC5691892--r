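#' Critical Pearson correlation coefficient at a given alpha
#'
#' The coefficient magnitude at which the two-sided correlation test
#' attains significance level `alpha` for `n` samples, from the exact
#' t-inversion: with `t* = qt(1 - alpha/2, n - 2)`,
#' `r* = t* / sqrt(t*^2 + n - 2)`. Strictly decreasing in `n`.
#'
#' @param n Sample count (>= 4).
#' @param alpha Two-sided significance level; default 0.05.
#' @return The critical |r|.
#' @examples
#' critical_r(10) # 0.632
#' @export
critical_r <- function(n, alpha = 0.05) {
  n <- .check_count(n, "n", min = 4)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  tcrit / sqrt(tcrit^2 + n - 2)
}

#' Pairwise expression correlation matrix with exact significance
#'
#' Pearson correlations between all pairs of a gene panel across samples,
#' with two-sided p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` and a significance mask
#' `|r| > critical_r(n, alpha)` -- exactly equivalent to `p < alpha` per
#' pair. No correction across the matrix by default (each pair is judged at
#' the per-pair level); `adjust = "BH"` switches the mask to BH-adjusted
#' `p < alpha`.
#'
#' @param x An [expression_matrix()].
#' @param panel Character vector of gene ids to correlate; all must be
#'   present with nonzero variance.
#' @param alpha Two-sided significance level; default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `correlation_result` with fields `panel`, `n`, `r`, `p`,
#'   `r_crit`, `significant` (logical matrix, diagonal `FALSE`), `alpha`,
#'   `adjust`. Use [tidy()] for the long pair table.
#' @export
correlation_matrix <- function(x, panel, alpha = 0.05,
                               adjust = c("none", "BH")) {
  stopifnot(inherits(x, "expr_mat"))
  adjust <- match.arg(adjust)
  panel <- as.character(panel)
  missing <- setdiff(panel, gene_ids(x))
  if (length(missing)) {
    stop("panel gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- ncol(x$values)
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  m <- t(x$values[panel, , drop = FALSE])
  vars <- apply(m, 2, stats::var)
  if (any(vars == 0)) {
    stop("zero-variance gene(s): ",
         paste(panel[vars == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(m)
  rc <- pmin(pmax(r, -1), 1)
  tstat <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  r_crit <- critical_r(n, alpha)
  if (adjust == "BH") {
    off <- upper.tri(p)
    p_adj <- p
    p_adj[off] <- bh_adjust(p[off])
    p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
    significant <- p_adj < alpha
  } else {
    significant <- abs(r) > r_crit
  }
  diag(significant) <- FALSE
  structure(list(panel = panel, n = n, r = r, p = p, r_crit = r_crit,
                 significant = significant, alpha = alpha, adjust = adjust),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> ", length(x$panel), " genes, n = ", x$n,
      ", |r| > ", format(x$r_crit, digits = 3), " at alpha = ", x$alpha,
      "\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' Tidy a correlation matrix into unordered gene pairs
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return A tibble with columns `gene_1`, `gene_2`, `r`, `p`,
#'   `significant`, one row per unordered off-diagonal pair.
#' @export
tidy.correlation_result <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    gene_1 = x$panel[idx[, 1]],
    gene_2 = x$panel[idx[, 2]],
    r = x$r[idx],
    p = x$p[idx],
    significant = x$significant[idx])
}

#' @rdname tidy.correlation_result
#' @export
glance.correlation_result <- function(x, ...) {
  off <- upper.tri(x$r)
  tibble::tibble(
    n_genes = length(x$panel), n_samples = x$n, alpha = x$alpha,
    r_crit = x$r_crit,
    n_pairs = sum(off),
    n_significant = sum(x$significant[off]))
}
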