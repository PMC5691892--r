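#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the metric-ranked gene list: at each gene-set hit the running sum
#' gains `|m_i|^weight_p / N_R` (with `N_R` the total hit weight), at each
#' miss it loses `1 / (N - N_H)`. The enrichment score (ES) is the running
#' sum's signed value of maximal absolute deviation from zero; a positive ES
#' means the set concentrates at the top of the ranking.
#'
#' Set genes absent from the ranked list are ignored with a message giving
#' the count.
#'
#' @param ranked A [ranked_list()] (or [rank_genes()] output).
#' @param set A [gene_set()] or character vector of gene ids.
#' @param weight_p Weighting exponent on the metric; `0` gives the classic
#'   unweighted Kolmogorov-Smirnov statistic, `1` (default) the standard
#'   GSEA weighting.
#' @return A list with elements `es`, `peak_position` (index of the running
#'   sum extremum), `running_sum` (length-N numeric), `n_hits`, and
#'   `n_missing` (set genes absent from the ranking).
#' @examples
#' rl <- ranked_list(paste0("G", 1:5), c(5, 4, 3, 2, 1))
#' enrichment_score(rl, c("G1", "G3"))$es
#' @export
enrichment_score <- function(ranked, set, weight_p = 1) {
  genes <- ranked$gene
  metric <- ranked$metric
  n <- length(genes)
  members <- unique(set_genes(set))
  hit <- genes %in% members
  n_hits <- sum(hit)
  n_missing <- length(members) - n_hits
  if (n_missing > 0) {
    message("enrichment_score: ", n_missing,
            " set gene(s) absent from the ranked list")
  }
  if (n_hits == 0) {
    stop("enrichment_score: gene set does not intersect the ranked list",
         call. = FALSE)
  }
  if (n_hits == n) {
    stop("enrichment_score: gene set covers the whole ranked list",
         call. = FALSE)
  }
  w <- if (weight_p == 0) rep(1, n) else abs(metric)^weight_p
  n_r <- sum(w[hit])
  if (n_r == 0) {
    stop("enrichment_score: all hit weights are zero (N_R = 0)",
         call. = FALSE)
  }
  steps <- ifelse(hit, w / n_r, -1 / (n - n_hits))
  rs <- cumsum(steps)
  # earliest position among near-tied extrema: |rs| ties (e.g. +0.5 at the
  # top vs -0.5 at the bottom) are structural and must not be broken by
  # floating-point noise
  peak <- which(abs(rs) >= max(abs(rs)) - 1e-12)[1]
  list(es = rs[peak], peak_position = peak, running_sum = rs,
       n_hits = n_hits, n_missing = n_missing)
}

# ES from sorted hit positions and their weights: O(k) per draw. Used for
# the permutation null; agrees exactly with enrichment_score() (tested).
.es_from_positions <- function(pos, w, n) {
  k <- length(pos)
  d <- 1 / (n - k)
  cw <- cumsum(w) / sum(w)
  # running-sum value at each hit, and just before each hit
  at_hit <- cw - (pos - seq_len(k)) * d
  before <- c(0, cw[-k]) - (pos - seq_len(k)) * d
  jmax <- which(at_hit >= max(at_hit) - 1e-12)[1]
  es_max <- at_hit[jmax]
  pos_max <- pos[jmax]
  valid <- pos > 1
  if (any(valid)) {
    bv <- ifelse(valid, before, Inf)
    jmin <- which(bv <= min(bv) + 1e-12)[1]
    es_min <- before[jmin]
    pos_min <- pos[jmin] - 1
  } else {
    es_min <- 0
    pos_min <- n
  }
  if (abs(es_max) > abs(es_min) + 1e-12) {
    es_max
  } else if (abs(es_min) > abs(es_max) + 1e-12) {
    es_min
  } else if (pos_max <= pos_min) es_max else es_min
}

#' Gene-permutation GSEA over one or more gene sets
#'
#' For each gene set of size k, the null distribution is the ES of `n_perm`
#' uniformly drawn size-k gene subsets of the ranked list (equivalent to
#' permuting gene labels). The p-value uses the add-one estimator on the
#' same-sign null tail, `p = (1 + #extreme) / (1 + #same-sign)`, which never
#' returns 0 at finite `n_perm`. NES divides the observed ES by the mean
#' magnitude of same-sign null scores. The FDR q is the pooled-null NES
#' ratio across all tested sets (tail fraction of pooled permuted NES beyond
#' the observed NES over the fraction of observed NES at least as extreme),
#' clipped to \[0, 1\]; with a single set, q equals p (noted by message).
#'
#' @inheritParams enrichment_score
#' @param sets A list of [gene_set()]s (or a single set / character vector).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; identical seed and inputs give bitwise-identical
#'   results. The caller's RNG state is left untouched.
#' @param min_overlap_warn Warn when less than this fraction of a set is
#'   found in the ranked list (cross-species mapping loses genes).
#' @return A `gsea_result` tibble with one row per set: `set`, `size`
#'   (genes found in the ranking), `es`, `nes`, `p`, `q`, `peak_position`,
#'   `leading_edge` (list column, rank-ordered), `n_perm`, `seed`.
#' @export
gsea <- function(ranked, sets, n_perm = 1000, weight_p = 1, seed = 1,
                 min_overlap_warn = 0.5) {
  n_perm <- .check_count(n_perm, "n_perm")
  if (inherits(sets, "gene_set") || is.character(sets)) sets <- list(sets)
  set_names <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "gene_set")) s$name else paste0("set_", i)
  }, character(1))
  n <- nrow(ranked)
  w_all <- if (weight_p == 0) rep(1, n) else abs(ranked$metric)^weight_p

  rows <- vector("list", length(sets))
  null_nes_pool <- vector("list", length(sets))
  .with_seed(seed, {
    for (i in seq_along(sets)) {
      members <- unique(set_genes(sets[[i]]))
      found <- sum(ranked$gene %in% members)
      if (found > 0 && found < min_overlap_warn * length(members)) {
        warning("gsea: set '", set_names[i], "': only ", found, " of ",
                length(members), " genes found in the ranked list",
                call. = FALSE)
      }
      obs <- enrichment_score(ranked, members, weight_p = weight_p)
      k <- obs$n_hits
      null_es <- vapply(seq_len(n_perm), function(b) {
        pos <- sort.int(sample.int(n, k))
        .es_from_positions(pos, w_all[pos], n)
      }, numeric(1))
      pos_null <- null_es[null_es > 0]
      neg_null <- null_es[null_es < 0]
      if (obs$es > 0) {
        same <- pos_null
        p <- if (length(same)) (1 + sum(same >= obs$es)) / (1 + length(same)) else NA_real_
        nes <- if (length(same)) obs$es / mean(same) else NA_real_
      } else if (obs$es < 0) {
        same <- neg_null
        p <- if (length(same)) (1 + sum(same <= obs$es)) / (1 + length(same)) else NA_real_
        nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
      } else {
        p <- NA_real_
        nes <- NA_real_
      }
      if (is.na(p)) {
        message("gsea: set '", set_names[i],
                "': no same-sign null ES; p and NES undefined")
      }
      # per-set normalized null, pooled across sets for the FDR step
      pm <- if (length(pos_null)) mean(pos_null) else NA_real_
      nm <- if (length(neg_null)) mean(abs(neg_null)) else NA_real_
      null_nes_pool[[i]] <- ifelse(null_es > 0, null_es / pm,
                                   ifelse(null_es < 0, null_es / nm, 0))
      le <- leading_edge(ranked, members, obs)
      rows[[i]] <- tibble::tibble(
        set = set_names[i], size = k, es = obs$es, nes = nes, p = p,
        peak_position = obs$peak_position, leading_edge = list(le),
        n_perm = n_perm, seed = seed)
    }
  })
  out <- dplyr::bind_rows(rows)
  pooled <- unlist(null_nes_pool, use.names = FALSE)
  pooled <- pooled[is.finite(pooled)]
  out$q <- .nes_fdr(out$nes, pooled, out$p)
  out <- out[, c("set", "size", "es", "nes", "p", "q", "peak_position",
                 "leading_edge", "n_perm", "seed")]
  class(out) <- c("gsea_result", class(out))
  out
}

# Pooled-null NES-ratio FDR, clipped to [0, 1]; q = p for a single set.
.nes_fdr <- function(nes, pooled_null, p) {
  if (length(nes) == 1) {
    message("gsea: single gene set tested; q set equal to p")
    return(p)
  }
  vapply(seq_along(nes), function(i) {
    x <- nes[i]
    if (is.na(x)) return(NA_real_)
    if (x > 0) {
      denom_null <- sum(pooled_null >= 0)
      num <- if (denom_null) sum(pooled_null >= x) / denom_null else NA_real_
      denom_obs <- sum(nes >= 0, na.rm = TRUE)
      den <- if (denom_obs) sum(nes >= x, na.rm = TRUE) / denom_obs else NA_real_
    } else {
      denom_null <- sum(pooled_null <= 0)
      num <- if (denom_null) sum(pooled_null <= x) / denom_null else NA_real_
      denom_obs <- sum(nes <= 0, na.rm = TRUE)
      den <- if (denom_obs) sum(nes <= x, na.rm = TRUE) / denom_obs else NA_real_
    }
    if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
    min(1, max(0, num / den))
  }, numeric(1))
}

#' Leading-edge (core enrichment) genes
#'
#' For a positive ES, the set members at or before the running-sum peak, in
#' rank order; for a negative ES, the members at or after the peak, in
#' reverse rank order. These are the genes driving the enrichment signal.
#'
#' @inheritParams enrichment_score
#' @param es_result Result of [enrichment_score()] on the same
#'   `ranked`/`set` pair.
#' @param top Truncate to the first `top` leading-edge genes (report views
#'   conventionally use 25); default keeps all.
#' @return Ordered character vector of leading-edge genes (empty, with a
#'   warning, when ES is exactly 0).
#' @export
leading_edge <- function(ranked, set, es_result, top = Inf) {
  members <- unique(set_genes(set))
  hit <- ranked$gene %in% members
  if (es_result$es > 0) {
    le <- ranked$gene[hit & seq_along(hit) <= es_result$peak_position]
  } else if (es_result$es < 0) {
    le <- rev(ranked$gene[hit & seq_along(hit) >= es_result$peak_position])
  } else {
    warning("leading_edge: ES is 0; empty leading edge", call. = FALSE)
    le <- character(0)
  }
  utils::head(le, top)
}

#' @export
print.gsea_result <- function(x, ...) {
  np <- if ("n_perm" %in% names(x)) x[["n_perm"]][1] else NA
  cat("<gsea_result> ", nrow(x), " gene set(s), ", np,
      " gene permutations\n", sep = "")
  NextMethod()
}

#' Tidy a GSEA result
#'
#' @param x A `gsea_result`.
#' @param top_leading Keep at most this many leading-edge genes in the
#'   `leading_edge` column (comma-joined); default 25.
#' @param ... Unused.
#' @return A tibble with one row per gene set and a flattened
#'   `leading_edge` character column.
#' @export
tidy.gsea_result <- function(x, top_leading = 25, ...) {
  out <- tibble::as_tibble(x)
  out$leading_edge <- vapply(out$leading_edge, function(le) {
    paste(utils::head(le, top_leading), collapse = ",")
  }, character(1))
  out
}
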