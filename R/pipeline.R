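# Run one pipeline stage, prefixing any error with the stage name so an
# end-to-end failure points at the step that broke.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the mouse stage: cross-study signature derivation and fit scoring
#'
#' Executes the mouse arm of the analysis on a synthetic (or equivalently
#' structured) study bundle: the fold-change filter on the second study
#' defines the input up/down gene sets; the primary study's tumor-vs-control
#' signal-to-noise ranking feeds [derive_shared_signature()]; the shared
#' signature is refined against the development contrast with
#' [refine_tumor_specific()]; and the refined signature is fit-scored back
#' on the primary mouse cohort.
#'
#' @param bundle A `study_bundle` from [simulate_study()].
#' @param n_perm,weight_p,seed GSEA parameters.
#' @param fc_threshold Linear fold-change cutoff for the second study's
#'   differential expression (default 2).
#' @param ssgsea_alpha Rank-weight exponent for the fit scores.
#' @param fdr_cutoff Optional FDR gate for development filtering, see
#'   [refine_tumor_specific()].
#' @param control_group Name of the tumor-free group in the primary study.
#' @return A `mouse_stage` list: `de` (DE filter output), `ranked`
#'   (primary-study ranking), `dev_ranked`, `shared` and `tumor_specific`
#'   signatures, and `mouse_fit` (fit table on the primary cohort).
#' @export
run_mouse_stage <- function(bundle, n_perm = 1000, weight_p = 1, seed = 1,
                            fc_threshold = 2, ssgsea_alpha = 0.25,
                            fdr_cutoff = NULL, control_group = "no_tumor") {
  stopifnot(inherits(bundle, "study_bundle"))
  de <- .stage("fold_change_filter",
               fold_change_filter(bundle$mouse_b,
                                  fc_threshold = fc_threshold))
  if (is.null(de$up) || is.null(de$down)) {
    stop("stage 'fold_change_filter' failed: empty ",
         if (is.null(de$up)) "up" else "down", " gene set", call. = FALSE)
  }
  groups_a <- sample_groups(bundle$mouse_a)
  tumor_labels <- ifelse(groups_a == control_group, control_group, "tumor")
  ranked <- .stage("rank_genes",
                   rank_genes(bundle$mouse_a, labels = tumor_labels,
                              class_a = "tumor", class_b = control_group))
  shared <- .stage("derive_shared_signature",
                   derive_shared_signature(ranked, de$up, de$down,
                                           name = "shared", n_perm = n_perm,
                                           weight_p = weight_p, seed = seed))
  dev_ranked <- .stage("rank_genes_dev", rank_genes(bundle$dev))
  tumor_specific <- .stage("refine_tumor_specific",
                           refine_tumor_specific(shared, dev_ranked,
                                                 n_perm = n_perm,
                                                 weight_p = weight_p,
                                                 seed = seed,
                                                 fdr_cutoff = fdr_cutoff))
  mouse_fit <- .stage("fit_score",
                      fit_score(tumor_specific, bundle$mouse_a,
                                alpha = ssgsea_alpha))
  structure(list(de = de, ranked = ranked, dev_ranked = dev_ranked,
                 shared = shared, tumor_specific = tumor_specific,
                 mouse_fit = mouse_fit),
            class = "mouse_stage")
}

# Criterion 1: subtype shows significantly lower VAV1 than >= 1 other
# subtype by Tukey HSD at `alpha`.
.crit_low_marker <- function(cmp, subtype, alpha = 0.05) {
  tk <- cmp$tukey
  lower_1 <- tk$group_1 == subtype & tk$diff < 0 & tk$p_adj < alpha
  lower_2 <- tk$group_2 == subtype & tk$diff > 0 & tk$p_adj < alpha
  any(lower_1 | lower_2)
}

# Criterion 2: subtype's mean fit exceeds every other subtype's with Tukey
# adjusted p < alpha on each pair.
.crit_fit_enriched <- function(cmp, subtype, alpha = 0.05) {
  tk <- cmp$tukey
  rows <- tk$group_1 == subtype | tk$group_2 == subtype
  if (!any(rows)) return(FALSE)
  tk <- tk[rows, ]
  higher <- ifelse(tk$group_1 == subtype, tk$diff > 0, tk$diff < 0)
  all(higher & tk$p_adj < alpha)
}

#' Run the human stage: signature transfer, fit scoring, three-way triage
#'
#' Maps the mouse signature onto human genes through the bundle's ortholog
#' table, fit-scores every human cohort, and evaluates each molecular
#' subtype against three classification criteria: (1) significantly lower
#' VAV1 than at least one other subtype (Tukey HSD at `alpha`); (2)
#' significant signature enrichment -- the subtype's mean fit score exceeds
#' every other subtype's with Tukey-adjusted p below `alpha`; (3) a
#' significant negative VAV1-HES1 Pearson correlation among the subtype's
#' signature-positive samples (fit class moderate or high). Cohorts listed
#' in `marker_datasets` have no trusted subtype annotation; their samples
#' are split TLX-positive/negative by [call_tlx_by_markers()] first. A
#' subtype with fewer than `min_corr_n` signature-positive samples has
#' criterion 3 recorded as not evaluable and cannot be a candidate.
#'
#' Overall candidates are the subtypes passing all three criteria in every
#' cohort.
#'
#' @param sig Mouse-gene [bidirectional_signature()] (e.g.
#'   `tumor_specific` from [run_mouse_stage()]).
#' @param bundle A `study_bundle`.
#' @param ssgsea_alpha Rank-weight exponent for the fit scores.
#' @param thresholds Fit-class thresholds, see [fit_score()].
#' @param alpha Significance level for all three criteria.
#' @param panel Gene panel for the correlation criterion; the first two
#'   entries are the pair tested (VAV1, HES1).
#' @param marker_datasets Cohort names whose subtype labels come from TLX
#'   marker abundance instead of annotation.
#' @param min_corr_n Minimum signature-positive samples for the
#'   correlation criterion.
#' @return A `triage_report`: `criteria` (tibble, one row per cohort and
#'   subtype with the three verdicts), `candidates` (character),
#'   `fits`, `fit_comparisons`, `vav1_comparisons`, `correlations`
#'   (per-cohort detail lists), and `signature` (the human-mapped
#'   signature). [tidy()] returns the criteria tibble.
#' @export
run_human_stage <- function(sig, bundle, ssgsea_alpha = 0.25,
                            thresholds = c(moderate = 0.25, high = 0.40),
                            alpha = 0.05, panel = c("VAV1", "HES1"),
                            marker_datasets = "dataset2",
                            min_corr_n = 4) {
  stopifnot(inherits(bundle, "study_bundle"))
  hsig <- .stage("map_orthologs",
                 map_orthologs(sig, bundle$ortholog_map))
  fits <- list()
  fit_cmps <- list()
  vav1_cmps <- list()
  corrs <- list()
  rows <- list()
  for (d in names(bundle$human)) {
    h <- bundle$human[[d]]
    if (d %in% marker_datasets) {
      labels <- call_tlx_by_markers(h, positive = bundle$truth$signal_subtype)
      h <- expression_matrix(h$values, groups = labels)
    }
    ft <- .stage(paste0("fit_score[", d, "]"),
                 fit_score(hsig, h, alpha = ssgsea_alpha,
                           thresholds = thresholds))
    fit_cmp <- .stage(paste0("compare_groups_fit[", d, "]"),
                      compare_groups(ft))
    vav1_cmp <- .stage(paste0("compare_groups_vav1[", d, "]"),
                       compare_groups(h$values[panel[1], ],
                                      groups = sample_groups(h)))
    corrs[[d]] <- list()
    for (s in unique(sample_groups(h))) {
      in_s <- ft$group == s
      positive <- in_s & ft$fit_class != "none"
      crit1 <- .crit_low_marker(vav1_cmp, s, alpha)
      crit2 <- .crit_fit_enriched(fit_cmp, s, alpha)
      if (sum(positive) >= min_corr_n) {
        sub <- expression_matrix(
          h$values[, ft$sample[positive], drop = FALSE])
        cr <- .stage(paste0("correlation[", d, ":", s, "]"),
                     correlation_matrix(sub, panel, alpha = alpha))
        corrs[[d]][[s]] <- cr
        r_vh <- cr$r[panel[1], panel[2]]
        crit3 <- isTRUE(r_vh < 0 && cr$significant[panel[1], panel[2]])
        corr_n <- cr$n
      } else {
        message("run_human_stage: ", d, "/", s, ": only ", sum(positive),
                " signature-positive sample(s); correlation not evaluable")
        r_vh <- NA_real_
        crit3 <- NA
        corr_n <- sum(positive)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        dataset = d, subtype = s, n = sum(in_s),
        mean_fit = mean(ft$fit[in_s]),
        n_moderate = sum(in_s & ft$fit_class == "moderate"),
        n_high = sum(in_s & ft$fit_class == "high"),
        low_vav1 = crit1, fit_enriched = crit2,
        vav1_hes1_r = r_vh, corr_n = corr_n,
        inverse_corr = crit3,
        candidate = isTRUE(crit1 && crit2 && crit3))
    }
    fits[[d]] <- ft
    fit_cmps[[d]] <- fit_cmp
    vav1_cmps[[d]] <- vav1_cmp
  }
  criteria <- dplyr::bind_rows(rows)
  candidates <- Reduce(intersect, lapply(
    unique(criteria$dataset),
    function(d) criteria$subtype[criteria$dataset == d & criteria$candidate]))
  structure(list(criteria = criteria, candidates = candidates,
                 fits = fits, fit_comparisons = fit_cmps,
                 vav1_comparisons = vav1_cmps, correlations = corrs,
                 signature = hsig),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat("<triage_report>\n")
  print(x$criteria, n = Inf)
  cat("candidate subtype(s) across all cohorts: ",
      if (length(x$candidates)) paste(x$candidates, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' @rdname run_human_stage
#' @param x A `triage_report`.
#' @param ... Unused.
#' @export
tidy.triage_report <- function(x, ...) x$criteria

#' @rdname run_human_stage
#' @export
glance.triage_report <- function(x, ...) {
  tibble::tibble(
    n_datasets = length(unique(x$criteria$dataset)),
    n_subtypes = length(unique(x$criteria$subtype)),
    n_candidates = length(x$candidates),
    candidates = paste(x$candidates, collapse = ","))
}

#' Run the whole study end to end
#'
#' [simulate_study()] (unless a bundle is supplied), then
#' [run_mouse_stage()], then [run_human_stage()] with the tumor-specific
#' signature.
#'
#' @param config A [sim_config()]; ignored when `bundle` is given.
#' @param bundle Optional pre-built `study_bundle`.
#' @param ... Passed to [run_mouse_stage()] and [run_human_stage()] where
#'   names match.
#' @param n_perm,seed GSEA parameters shared by both stages.
#' @return A list with `bundle`, `mouse` (the `mouse_stage`) and `human`
#'   (the `triage_report`).
#' @export
run_study <- function(config = sim_config(), bundle = NULL,
                      n_perm = 1000, seed = 1, ...) {
  if (is.null(bundle)) bundle <- simulate_study(config)
  mouse <- run_mouse_stage(bundle, n_perm = n_perm, seed = seed, ...)
  human <- run_human_stage(mouse$tumor_specific, bundle)
  list(bundle = bundle, mouse = mouse, human = human)
}

#' Write a categorical CLS phenotype file
#'
#' @param labels Character vector of class labels in sample-column order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cls <- function(labels, path) {
  labels <- as.character(labels)
  classes <- unique(labels)
  writeLines(c(paste(length(labels), length(classes), 1),
               paste(c("#", classes), collapse = " "),
               paste(match(labels, classes) - 1, collapse = " ")),
             path)
  invisible(path)
}

#' Write a study bundle to a directory of standard-format files
#'
#' One GCT + CLS pair per dataset, the ortholog table as TSV, and the truth
#' record and configuration as JSON. Every file is re-loadable by the
#' package's own readers.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_study_bundle needs the jsonlite package", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(x, stem) {
    write_gct(x, file.path(dir, paste0(stem, ".gct")))
    write_cls(sample_groups(x), file.path(dir, paste0(stem, ".cls")))
  }
  emit(bundle$mouse_a, "mouse_a")
  emit(bundle$mouse_b, "mouse_b")
  emit(bundle$dev, "dev")
  for (d in names(bundle$human)) emit(bundle$human[[d]], d)
  utils::write.table(
    data.frame(source_id = names(bundle$ortholog_map),
               target_id = unlist(bundle$ortholog_map, use.names = FALSE)),
    file.path(dir, "orthologs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(unclass(bundle$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
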