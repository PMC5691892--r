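#' Single-sample GSEA raw enrichment scores
#'
#' For each sample, genes are ranked by that sample's expression, descending
#' (rank 1 = highest; within-sample ties broken by lexicographic gene id for
#' determinism). Walking the ordered list, in-set steps carry weight
#' `r_i^alpha` with `r_i = N - rank_i + 1`, normalized to sum to 1;
#' out-of-set steps are `1 / (N - k)`. The raw score is the sum over all N
#' positions of the difference between the in-set and out-of-set cumulative
#' step distributions (no division by N). Because only within-sample ranks
#' enter, the score is invariant under any strictly increasing transform of
#' a sample's expression values.
#'
#' @param x An [expression_matrix()].
#' @param set A [gene_set()] or character vector of gene ids; must intersect
#'   the matrix genes without covering them all.
#' @param alpha Rank-weighting exponent; 0.25 is the canonical ssGSEA value.
#' @return Named numeric vector of raw enrichment scores, one per sample.
#' @export
ssgsea_score <- function(x, set, alpha = 0.25) {
  stopifnot(inherits(x, "expr_mat"))
  genes <- gene_ids(x)
  n <- length(genes)
  members <- unique(set_genes(set))
  in_set <- genes %in% members
  k <- sum(in_set)
  if (k == 0) {
    stop("ssgsea_score: gene set does not intersect the matrix genes",
         call. = FALSE)
  }
  if (k == n) {
    stop("ssgsea_score: gene set covers every gene in the matrix",
         call. = FALSE)
  }
  # lexicographic gene order as the tie-break key: order(-expr, gene)
  gene_order_key <- order(genes)
  rank_key <- integer(n)
  rank_key[gene_order_key] <- seq_len(n)
  apply_one <- function(expr) {
    ord <- order(-expr, rank_key)
    hit <- in_set[ord]
    r <- n - seq_len(n) + 1  # r_i = N - rank + 1, rank 1 = highest
    w <- ifelse(hit, r^alpha, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!hit) / (n - k)
    sum(p_in - p_out)
  }
  out <- vapply(seq_len(ncol(x$values)), function(j) apply_one(x$values[, j]),
                numeric(1))
  names(out) <- sample_ids(x)
  out
}

#' Normalize raw ssGSEA scores by the pooled score range
#'
#' Each raw score is divided by the span (max - min) of the pooled raw
#' scores of the dataset -- both signature directions together -- making the
#' fit-score thresholds scale-free. The span is recorded in the `span`
#' attribute.
#'
#' @param raw Numeric vector of pooled raw enrichment scores (>= 2 values
#'   spanning a nonzero range).
#' @return `raw / (max(raw) - min(raw))`, with attribute `span`.
#' @export
normalize_scores <- function(raw) {
  if (length(raw) < 2) {
    stop("normalize_scores: need at least 2 raw scores", call. = FALSE)
  }
  span <- max(raw) - min(raw)
  if (span == 0) {
    stop("normalize_scores: zero span (all raw scores equal)", call. = FALSE)
  }
  out <- raw / span
  attr(out, "span") <- span
  out
}

#' Bidirectional signature fit scores per sample
#'
#' Scores the up and down gene sets of a signature on every sample with
#' [ssgsea_score()], normalizes the pooled raw scores by their range
#' ([normalize_scores()]), and takes per sample
#' `fit = normalized up ES - normalized down ES`, a measure of joint
#' enrichment of the up-signature and depletion of the down-signature.
#' Samples are classed `high` when `fit > ` the high threshold, `moderate`
#' when above the moderate threshold but not high, and `none` otherwise
#' (strict inequalities: a fit of exactly 0.25 is `none`, exactly 0.40 is
#' `moderate`).
#'
#' @param sig A [bidirectional_signature()].
#' @param x An [expression_matrix()].
#' @param alpha Rank-weighting exponent passed to [ssgsea_score()].
#' @param thresholds Named numeric vector `c(moderate = , high = )`;
#'   defaults to the moderate > 0.25 and high > 0.40 fitness cutoffs.
#' @return A `fit_tbl` tibble with one row per sample: `sample`, `group`
#'   (when the matrix is annotated), `up_es`, `down_es`, `up_norm`,
#'   `down_norm`, `fit`, `fit_class`. Attributes record `alpha`, the
#'   normalization `span`, the signature name and the thresholds.
#' @export
fit_score <- function(sig, x, alpha = 0.25,
                      thresholds = c(moderate = 0.25, high = 0.40)) {
  stopifnot(inherits(sig, "bidir_signature"), inherits(x, "expr_mat"))
  if (!all(c("moderate", "high") %in% names(thresholds))) {
    stop("`thresholds` must name `moderate` and `high`", call. = FALSE)
  }
  up_es <- ssgsea_score(x, sig$up, alpha = alpha)
  down_es <- ssgsea_score(x, sig$down, alpha = alpha)
  norm <- normalize_scores(c(up_es, down_es))
  span <- attr(norm, "span")
  m <- length(up_es)
  up_norm <- as.numeric(norm[seq_len(m)])
  down_norm <- as.numeric(norm[m + seq_len(m)])
  fit <- up_norm - down_norm
  fit_class <- classify_fit(fit, thresholds)
  out <- tibble::tibble(
    sample = sample_ids(x),
    up_es = as.numeric(up_es), down_es = as.numeric(down_es),
    up_norm = up_norm, down_norm = down_norm,
    fit = fit,
    fit_class = factor(fit_class, levels = c("none", "moderate", "high")))
  if (!is.null(x$groups)) {
    out <- tibble::add_column(out, group = as.character(x$groups[out$sample]),
                              .after = "sample")
  }
  attr(out, "alpha") <- alpha
  attr(out, "span") <- span
  attr(out, "signature") <- sig$name
  attr(out, "thresholds") <- thresholds
  class(out) <- c("fit_tbl", class(out))
  out
}

#' Classify fit scores by the moderate/high thresholds
#'
#' Strict inequalities: `high` when `fit > high` threshold, `moderate` when
#' `moderate < fit <= high`, else `none`. A fit of exactly 0.25 is `none`
#' and exactly 0.40 is `moderate` under the defaults.
#'
#' @param fit Numeric vector of fit scores.
#' @param thresholds Named numeric vector `c(moderate = , high = )`.
#' @return Factor with levels `none`, `moderate`, `high`.
#' @export
classify_fit <- function(fit, thresholds = c(moderate = 0.25, high = 0.40)) {
  if (!all(c("moderate", "high") %in% names(thresholds))) {
    stop("`thresholds` must name `moderate` and `high`", call. = FALSE)
  }
  factor(dplyr::case_when(fit > thresholds[["high"]] ~ "high",
                          fit > thresholds[["moderate"]] ~ "moderate",
                          TRUE ~ "none"),
         levels = c("none", "moderate", "high"))
}

#' Group comparison of fit scores (or any per-sample value)
#'
#' Runs Bartlett's homogeneity-of-variance test, one-way ANOVA, and Tukey's
#' honest significant difference (HSD) test with studentized-range adjusted
#' p-values over all unordered group pairs -- the battery used to identify
#' groups with significant signature enrichment.
#'
#' @param x A `fit_tbl` from [fit_score()] (its `fit` column is compared
#'   across its `group` column), or a numeric vector of per-sample values.
#' @param groups Group labels; required when `x` is a numeric vector,
#'   optional override for a `fit_tbl`. Every group needs >= 2 samples and
#'   there must be >= 2 groups.
#' @return A `group_comparison` object; [tidy()] gives the Tukey pairwise
#'   table, [glance()] the Bartlett and ANOVA statistics.
#' @export
compare_groups <- function(x, groups = NULL) {
  if (inherits(x, "fit_tbl")) {
    values <- x$fit
    if (is.null(groups)) {
      if (is.null(x[["group"]])) {
        stop("fit table has no group column; supply `groups`", call. = FALSE)
      }
      groups <- x$group
    }
  } else {
    values <- as.numeric(x)
    if (is.null(groups)) stop("supply `groups`", call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(groups) != length(values)) {
    stop("`groups` must match the values in length", call. = FALSE)
  }
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 samples (offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")", call. = FALSE)
  }
  g <- factor(groups)
  bart <- stats::bartlett.test(values, g)
  fit <- stats::aov(values ~ g)
  anova_tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairs <- rownames(tk)
  tukey <- tibble::tibble(
    pair = pairs,
    group_1 = sub("-.*$", "", pairs),
    group_2 = sub("^[^-]*-", "", pairs),
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"]))
  structure(list(
    bartlett = list(statistic = unname(bart$statistic),
                    df = unname(bart$parameter),
                    p = unname(bart$p.value)),
    anova = list(f = anova_tab[["F value"]][1],
                 df1 = anova_tab[["Df"]][1], df2 = anova_tab[["Df"]][2],
                 p = anova_tab[["Pr(>F)"]][1]),
    tukey = tukey,
    group_means = tapply(values, g, mean),
    n = as.vector(sizes)), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  cat(sprintf("  Bartlett K^2 = %.3f (df %d), p = %.3g\n",
              x$bartlett$statistic, x$bartlett$df, x$bartlett$p))
  cat(sprintf("  ANOVA F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$f, x$anova$p))
  cat("  Tukey HSD:\n")
  print(x$tukey, n = Inf)
  invisible(x)
}

#' @rdname compare_groups
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) x$tukey

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    bartlett_statistic = x$bartlett$statistic,
    bartlett_p = x$bartlett$p,
    anova_f = x$anova$f,
    anova_p = x$anova$p,
    n_groups = length(x$group_means),
    n = sum(x$n))
}
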