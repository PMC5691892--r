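#' Signal-to-noise ratio between two sample classes
#'
#' The GSEA ranking metric (mu_A - mu_B) / (sd_A + sd_B). Each class
#' standard deviation is floored at 0.2 * |mu| of its class, and at an
#' absolute floor of 0.2 when the class mean is zero, the standard guard
#' against near-zero denominators.
#'
#' @param a,b Numeric vectors of expression values for class A and class B;
#'   each needs at least 2 samples.
#' @return A single numeric metric value. Swapping `a` and `b` negates it.
#' @examples
#' signal_to_noise(c(2, 2), c(1, 1)) # (2-1)/(0.4+0.2)
#' @export
signal_to_noise <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("signal_to_noise: each class needs at least 2 samples",
         call. = FALSE)
  }
  .s2n(mean(a), mean(b), stats::sd(a), stats::sd(b))
}

# Floored signal-to-noise on precomputed moments (vectorized over genes).
.s2n <- function(mu_a, mu_b, sd_a, sd_b) {
  floor_a <- ifelse(mu_a == 0, 0.2, 0.2 * abs(mu_a))
  floor_b <- ifelse(mu_b == 0, 0.2, 0.2 * abs(mu_b))
  (mu_a - mu_b) / (pmax(sd_a, floor_a) + pmax(sd_b, floor_b))
}

# Resolve a two-class contrast: returns list(a = sample idx, b = sample idx).
.two_class_idx <- function(labels, sample_ids, class_a, class_b) {
  labels <- as.character(labels)
  if (!is.null(names(labels))) labels <- labels[sample_ids]
  if (length(labels) != length(sample_ids)) {
    stop("labels must cover every sample", call. = FALSE)
  }
  classes <- unique(labels)
  if (is.null(class_a) && is.null(class_b)) {
    if (length(classes) != 2) {
      stop("expected exactly 2 classes, found ", length(classes),
           call. = FALSE)
    }
    class_a <- classes[1]
    class_b <- classes[2]
  } else if (is.null(class_a) || is.null(class_b)) {
    stop("supply both `class_a` and `class_b`, or neither", call. = FALSE)
  }
  if (!all(c(class_a, class_b) %in% classes)) {
    stop("class not present in labels", call. = FALSE)
  }
  a <- which(labels == class_a)
  b <- which(labels == class_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  list(a = a, b = b, class_a = class_a, class_b = class_b)
}

# Per-gene means and sds for a column subset.
.row_moments <- function(v) {
  n <- ncol(v)
  mu <- rowMeans(v)
  s2 <- rowSums((v - mu)^2) / (n - 1)
  list(mu = mu, sd = sqrt(s2), var = s2, n = n)
}

#' Rank genes by a two-class metric
#'
#' Sorts genes by the signal-to-noise metric, descending (position 1 is the
#' most class-A-upregulated gene). Ties are broken by lexicographic gene id
#' so the ranking is deterministic across runs and platforms.
#'
#' @param x An [expression_matrix()].
#' @param labels Two-class sample labels (named by sample id, or positional).
#'   Defaults to the matrix annotations.
#' @param class_a,class_b Which label is class A (e.g. tumor) and class B
#'   (control); the metric sign is A-relative. Default: first two distinct
#'   labels in order of appearance.
#' @param metric Ranking metric; currently `"signal_to_noise"`.
#' @return A `ranked_list` tibble with columns `gene` and `metric`, ordered
#'   best-first, with the contrast recorded in attributes.
#' @export
rank_genes <- function(x, labels = NULL, class_a = NULL, class_b = NULL,
                       metric = "signal_to_noise") {
  stopifnot(inherits(x, "expr_mat"))
  metric <- match.arg(metric, "signal_to_noise")
  if (is.null(labels)) labels <- x$groups
  if (is.null(labels)) stop("no labels supplied or annotated", call. = FALSE)
  idx <- .two_class_idx(labels, sample_ids(x), class_a, class_b)
  ma <- .row_moments(x$values[, idx$a, drop = FALSE])
  mb <- .row_moments(x$values[, idx$b, drop = FALSE])
  m <- unname(.s2n(ma$mu, mb$mu, ma$sd, mb$sd))
  ord <- order(-m, gene_ids(x))
  out <- tibble::tibble(gene = gene_ids(x)[ord], metric = m[ord])
  attr(out, "class_a") <- idx$class_a
  attr(out, "class_b") <- idx$class_b
  attr(out, "tie_rule") <- "lexicographic gene id"
  class(out) <- c("ranked_list", class(out))
  out
}

#' Construct a ranked list directly
#'
#' @param genes Character vector of unique gene ids, best-first.
#' @param metric Numeric metric values, non-increasing along `genes`.
#' @return A `ranked_list` tibble.
#' @export
ranked_list <- function(genes, metric) {
  genes <- as.character(genes)
  if (length(genes) < 2) stop("ranked list needs >= 2 genes", call. = FALSE)
  if (anyDuplicated(genes)) stop("ranked list genes must be unique",
                                 call. = FALSE)
  if (length(metric) != length(genes)) {
    stop("`metric` must match `genes` in length", call. = FALSE)
  }
  if (is.unsorted(rev(metric))) {
    stop("metric must be non-increasing along the ranking", call. = FALSE)
  }
  out <- tibble::tibble(gene = genes, metric = as.numeric(metric))
  class(out) <- c("ranked_list", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1
#' (delegates to [stats::p.adjust()] after validation).
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise >= `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Fold-change differential-expression filter
#'
#' Defines up/down gene sets by the plain fold-change rule: with log2-scale
#' input, log2FC = mean_A - mean_B per gene, and a gene is "up" when its
#' linear fold change strictly exceeds `fc_threshold` (log2FC > log2(thr)),
#' "down" when below 1/thr. A Welch two-sample test p and its BH adjustment
#' are reported per gene but play no part in set membership: the selection
#' criterion is fold change only.
#'
#' @inheritParams rank_genes
#' @param fc_threshold Linear-scale fold-change threshold (> 1); default 2.
#' @return A list with `up` and `down` [gene_set()]s and `table`, a tibble
#'   with columns `gene`, `log2fc`, `p`, `p_adj`, `direction`.
#' @export
fold_change_filter <- function(x, labels = NULL, fc_threshold = 2,
                               class_a = NULL, class_b = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  if (fc_threshold <= 1) {
    stop("`fc_threshold` must exceed 1 (linear scale)", call. = FALSE)
  }
  if (is.null(labels)) labels <- x$groups
  if (is.null(labels)) stop("no labels supplied or annotated", call. = FALSE)
  idx <- .two_class_idx(labels, sample_ids(x), class_a, class_b)
  ma <- .row_moments(x$values[, idx$a, drop = FALSE])
  mb <- .row_moments(x$values[, idx$b, drop = FALSE])
  log2fc <- unname(ma$mu - mb$mu)
  # Welch t: closed form; zero pooled s.e. degenerates to p = 0/1.
  se2 <- unname(ma$var / ma$n + mb$var / mb$n)
  tstat <- ifelse(se2 > 0, log2fc / sqrt(se2), Inf * sign(log2fc))
  df <- unname(se2^2 / (ma$var^2 / (ma$n^2 * (ma$n - 1)) +
                          mb$var^2 / (mb$n^2 * (mb$n - 1))))
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df),
              ifelse(log2fc == 0, 1, 0))
  cut <- log2(fc_threshold)
  direction <- dplyr::case_when(log2fc > cut ~ "up",
                                log2fc < -cut ~ "down",
                                TRUE ~ "none")
  table <- tibble::tibble(gene = gene_ids(x), log2fc = log2fc, p = p,
                          p_adj = bh_adjust(p), direction = direction)
  up <- table$gene[table$direction == "up"]
  down <- table$gene[table$direction == "down"]
  list(
    up = if (length(up)) gene_set("FC_UP", up,
                                  paste0("linear FC > ", fc_threshold)) else NULL,
    down = if (length(down)) gene_set("FC_DN", down,
                                      paste0("linear FC < 1/", fc_threshold)) else NULL,
    table = table
  )
}
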