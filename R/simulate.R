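#' Configuration for the synthetic two-species study generator
#'
#' Bundles every knob of [simulate_study()] with defaults emulating the
#' study design the analysis assumes: a mouse tumor study with three groups
#' (no-tumor plus two tumor immunophenotypes) sharing a common deregulated
#' gene block; a second mouse study whose differential expression partially
#' overlaps it; a T-cell development contrast confounding part of the shared
#' block; and three human T-ALL cohorts of 64, 52 and 124 samples split
#' across molecular subtypes, where exactly one subtype carries the
#' ortholog-mapped signature, low VAV1 and an inverse VAV1-HES1
#' correlation.
#'
#' @param seed Integer seed; the bundle is a pure function of the config.
#' @param n_genes Genes per matrix (including the four marker genes Vav1,
#'   Hes1, Tlx1, Tlx3 and their human orthologs).
#' @param mouse_a_sizes Named group sizes for the primary tumor study.
#' @param mouse_b_sizes Named group sizes for the second mouse study
#'   (class A = preleukemic).
#' @param dev_sizes Named group sizes for the development contrast
#'   (class A = undifferentiated).
#' @param human_sizes Named list of named subtype-size vectors, one per
#'   human cohort; defaults split 64/52/124 samples roughly 30/30/40%
#'   across immature, TLX and TAL1 subtypes.
#' @param n_signature_up,n_signature_down Sizes of the embedded up/down
#'   blocks in the primary study.
#' @param overlap_fraction Fraction of each block also deregulated in the
#'   second study (the cross-study truth).
#' @param n_dev_confounders Number of shared-block genes also shifted in
#'   the development contrast (split evenly across directions); these are
#'   the genes tumor-specific refinement must remove.
#' @param effect_log2fc Embedded group shift in log2 units; the default 2
#'   (4-fold) clears the study's >2-fold differential-expression filter.
#' @param noise_sd I.i.d. Gaussian noise s.d. in log2 units.
#' @param vav1_hes1_r Target correlation of the VAV1/HES1 residual pair in
#'   the signature-positive subtype (in (-1, 1)).
#' @param vav1_shift,hes1_shift,tlx_marker_shift Log2 shifts applied in the
#'   signature-positive human subtype to VAV1 (down), HES1 (up), and to one
#'   of TLX1/TLX3 per sample (up).
#' @param signal_subtype Which human subtype carries the signature.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 2000,
                       mouse_a_sizes = c(no_tumor = 3, dn_tumor = 3,
                                         cd8_tumor = 3),
                       mouse_b_sizes = c(preleukemic = 3, control = 3),
                       dev_sizes = c(undifferentiated = 3,
                                     differentiated = 3),
                       human_sizes = list(
                         dataset1 = c(immature = 19, TLX = 19, TAL1 = 26),
                         dataset2 = c(immature = 16, TLX = 16, TAL1 = 20),
                         dataset3 = c(immature = 37, TLX = 37, TAL1 = 50)),
                       n_signature_up = 50,
                       n_signature_down = 50,
                       overlap_fraction = 0.6,
                       n_dev_confounders = 10,
                       effect_log2fc = 2,
                       noise_sd = 0.5,
                       vav1_hes1_r = -0.8,
                       vav1_shift = -1.5,
                       hes1_shift = 1,
                       tlx_marker_shift = 3,
                       signal_subtype = "TLX") {
  cfg <- list(seed = .check_count(seed, "seed", min = 0),
              n_genes = .check_count(n_genes, "n_genes", min = 20),
              mouse_a_sizes = mouse_a_sizes,
              mouse_b_sizes = mouse_b_sizes,
              dev_sizes = dev_sizes,
              human_sizes = human_sizes,
              n_signature_up = .check_count(n_signature_up, "n_signature_up"),
              n_signature_down = .check_count(n_signature_down,
                                              "n_signature_down"),
              overlap_fraction = overlap_fraction,
              n_dev_confounders = .check_count(n_dev_confounders,
                                               "n_dev_confounders", min = 0),
              effect_log2fc = effect_log2fc,
              noise_sd = noise_sd,
              vav1_hes1_r = vav1_hes1_r,
              vav1_shift = vav1_shift,
              hes1_shift = hes1_shift,
              tlx_marker_shift = tlx_marker_shift,
              signal_subtype = signal_subtype)
  all_sizes <- c(mouse_a_sizes, mouse_b_sizes, dev_sizes,
                 unlist(human_sizes))
  if (any(all_sizes < 2)) stop("every group needs size >= 2", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("`overlap_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be positive", call. = FALSE)
  }
  if (vav1_hes1_r <= -1 || vav1_hes1_r >= 1) {
    stop("`vav1_hes1_r` must lie in (-1, 1)", call. = FALSE)
  }
  n_blocks <- n_signature_up + n_signature_down
  extra <- ceiling((1 - overlap_fraction) * n_signature_up) +
    ceiling((1 - overlap_fraction) * n_signature_down)
  if (n_blocks + extra + 4 > n_genes) {
    stop("signature blocks exceed `n_genes`", call. = FALSE)
  }
  if (n_dev_confounders >
      floor(overlap_fraction * n_signature_up) +
      floor(overlap_fraction * n_signature_down)) {
    stop("`n_dev_confounders` exceeds the shared blocks", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Mouse marker genes carried by every synthetic bundle.
.markers_mouse <- c("Vav1", "Hes1", "Tlx1", "Tlx3")

# Baseline + iid noise matrix for one dataset.
.sim_matrix <- function(genes, sizes, noise_sd, prefix) {
  n_samples <- sum(sizes)
  groups <- rep(names(sizes), times = sizes)
  sid <- sprintf("%s_%02d", prefix, seq_len(n_samples))
  baseline <- stats::runif(length(genes), 4, 12)
  values <- baseline + matrix(stats::rnorm(length(genes) * n_samples,
                                           sd = noise_sd),
                              length(genes), n_samples)
  dimnames(values) <- list(genes, sid)
  expression_matrix(values, groups = stats::setNames(groups, sid))
}

# Shift a gene block in the columns of the given groups.
.shift_block <- function(x, block, groups_to_shift, delta) {
  cols <- which(x$groups %in% groups_to_shift)
  x$values[block, cols] <- x$values[block, cols] + delta
  x
}

#' Simulate a complete two-species study bundle
#'
#' Generates, from a single seed, every matrix the pipeline consumes with
#' the statistical structure the analysis assumes, plus a truth record of
#' the embedded gene identities. Expression is simulated directly on log2
#' scale: per-gene baseline means uniform in \[4, 12\] log2 units with
#' i.i.d. Gaussian noise, so fold-change semantics are exact. See
#' [sim_config()] for the embedded structure.
#'
#' In the signature-positive human subtype, the VAV1/HES1 pair receives
#' correlated bivariate-normal residuals targeting `vav1_hes1_r`; every
#' other subtype's genes are independent. Each signature-positive sample
#' also raises one of the TLX1/TLX3 markers so marker-based TLX calling is
#' exercised.
#'
#' @param config A [sim_config()].
#' @return A `study_bundle`: `mouse_a`, `mouse_b`, `dev`
#'   ([expression_matrix()]s with group annotations), `human` (named list
#'   of annotated matrices), `ortholog_map` (mouse symbol -> uppercase
#'   human symbol), `truth` (embedded gene identities and effects), and
#'   `config`. Identical configs give bitwise-identical bundles.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genes_m <- c(.markers_mouse,
               sprintf("Gene%04d", seq_len(cfg$n_genes - 4)))
  genes_h <- toupper(genes_m)
  ortholog_map <- stats::setNames(as.list(genes_h), genes_m)

  .with_seed(cfg$seed, {
    pool <- sample(setdiff(genes_m, .markers_mouse))
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    up_a <- take(cfg$n_signature_up)
    down_a <- take(cfg$n_signature_down)
    n_sh_up <- floor(cfg$overlap_fraction * cfg$n_signature_up)
    n_sh_dn <- floor(cfg$overlap_fraction * cfg$n_signature_down)
    shared_up <- up_a[seq_len(n_sh_up)]
    shared_down <- down_a[seq_len(n_sh_dn)]
    b_up <- c(shared_up, take(cfg$n_signature_up - n_sh_up))
    b_down <- c(shared_down, take(cfg$n_signature_down - n_sh_dn))
    n_cf_up <- min(ceiling(cfg$n_dev_confounders / 2), n_sh_up)
    n_cf_dn <- min(cfg$n_dev_confounders - n_cf_up, n_sh_dn)
    conf_up <- shared_up[seq_len(n_cf_up)]
    conf_down <- shared_down[seq_len(n_cf_dn)]

    eff <- cfg$effect_log2fc
    tumor_groups <- setdiff(names(cfg$mouse_a_sizes), "no_tumor")

    mouse_a <- .sim_matrix(genes_m, cfg$mouse_a_sizes, cfg$noise_sd, "mA")
    mouse_a <- .shift_block(mouse_a, up_a, tumor_groups, eff)
    mouse_a <- .shift_block(mouse_a, down_a, tumor_groups, -eff)

    mouse_b <- .sim_matrix(genes_m, cfg$mouse_b_sizes, cfg$noise_sd, "mB")
    mouse_b <- .shift_block(mouse_b, b_up, "preleukemic", eff)
    mouse_b <- .shift_block(mouse_b, b_down, "preleukemic", -eff)

    dev <- .sim_matrix(genes_m, cfg$dev_sizes, cfg$noise_sd, "dev")
    if (length(conf_up)) {
      dev <- .shift_block(dev, conf_up, "undifferentiated", eff)
    }
    if (length(conf_down)) {
      dev <- .shift_block(dev, conf_down, "undifferentiated", -eff)
    }

    human_up <- toupper(shared_up)
    human_down <- toupper(shared_down)
    human <- lapply(seq_along(cfg$human_sizes), function(d) {
      sizes <- cfg$human_sizes[[d]]
      h <- .sim_matrix(genes_h, sizes, cfg$noise_sd,
                       names(cfg$human_sizes)[d])
      pos <- which(h$groups == cfg$signal_subtype)
      h <- .shift_block(h, human_up, cfg$signal_subtype, eff)
      h <- .shift_block(h, human_down, cfg$signal_subtype, -eff)
      h$values["VAV1", pos] <- h$values["VAV1", pos] + cfg$vav1_shift
      h$values["HES1", pos] <- h$values["HES1", pos] + cfg$hes1_shift
      # correlated residual pair replacing the iid noise for VAV1/HES1
      z1 <- stats::rnorm(length(pos))
      z2 <- cfg$vav1_hes1_r * z1 +
        sqrt(1 - cfg$vav1_hes1_r^2) * stats::rnorm(length(pos))
      mu_v <- mean(h$values["VAV1", pos])
      mu_h <- mean(h$values["HES1", pos])
      h$values["VAV1", pos] <- mu_v + cfg$noise_sd * z1
      h$values["HES1", pos] <- mu_h + cfg$noise_sd * z2
      which_marker <- sample(c("TLX1", "TLX3"), length(pos), replace = TRUE)
      for (m in c("TLX1", "TLX3")) {
        sel <- pos[which_marker == m]
        h$values[m, sel] <- h$values[m, sel] + cfg$tlx_marker_shift
      }
      h
    })
    names(human) <- names(cfg$human_sizes)

    truth <- list(
      up_a = up_a, down_a = down_a,
      b_up = b_up, b_down = b_down,
      shared_up = shared_up, shared_down = shared_down,
      conf_up = conf_up, conf_down = conf_down,
      tumor_specific_up = setdiff(shared_up, conf_up),
      tumor_specific_down = setdiff(shared_down, conf_down),
      human_up = human_up, human_down = human_down,
      signal_subtype = cfg$signal_subtype,
      effect_log2fc = eff)

    structure(list(mouse_a = mouse_a, mouse_b = mouse_b, dev = dev,
                   human = human, ortholog_map = ortholog_map,
                   truth = truth, config = cfg),
              class = "study_bundle")
  })
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle> seed ", x$config$seed, ", ", x$config$n_genes,
      " genes\n", sep = "")
  cat("  mouse_a: ", ncol(x$mouse_a$values), " samples; mouse_b: ",
      ncol(x$mouse_b$values), "; dev: ", ncol(x$dev$values), "\n", sep = "")
  cat("  human: ",
      paste(names(x$human),
            vapply(x$human, function(h) ncol(h$values), integer(1)),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate a pure-noise expression matrix
#'
#' No embedded structure: per-gene baseline means uniform in \[4, 12\] log2
#' units plus i.i.d. Gaussian noise. Used for type-I-error and
#' correlation-null calibration.
#'
#' @param n_genes,n_samples Matrix dimensions (`n_samples >= 4`).
#' @param seed Integer seed.
#' @param noise_sd Noise s.d. in log2 units.
#' @return An [expression_matrix()] without annotations.
#' @export
simulate_null_dataset <- function(n_genes, n_samples, seed, noise_sd = 0.5) {
  n_genes <- .check_count(n_genes, "n_genes", min = 2)
  n_samples <- .check_count(n_samples, "n_samples", min = 4)
  .with_seed(seed, {
    baseline <- stats::runif(n_genes, 4, 12)
    values <- baseline + matrix(stats::rnorm(n_genes * n_samples,
                                             sd = noise_sd),
                                n_genes, n_samples)
    dimnames(values) <- list(sprintf("Gene%04d", seq_len(n_genes)),
                             sprintf("null_%02d", seq_len(n_samples)))
    expression_matrix(values)
  })
}

#' Call TLX-positive samples from marker abundance
#'
#' For cohorts lacking molecular subtype annotation, samples are called
#' TLX-positive when either TLX1 or TLX3 is highly abundant. Abundance is
#' judged per transcript relative to its own cohort distribution
#' (heatmap-style): each marker row is median-centered, the per-sample
#' score is the maximum centered marker value, and the cutoff is the
#' deterministic two-class split maximizing between-class variance (Otsu's
#' criterion on the sorted scores), with the threshold at the midpoint of
#' the two class means.
#'
#' @param x An [expression_matrix()] containing the marker genes.
#' @param markers Marker gene ids; default `c("TLX1", "TLX3")`.
#' @param positive,negative Labels to assign.
#' @return Named character vector of labels, one per sample.
#' @export
call_tlx_by_markers <- function(x, markers = c("TLX1", "TLX3"),
                                positive = "TLX", negative = "other") {
  stopifnot(inherits(x, "expr_mat"))
  missing <- setdiff(markers, gene_ids(x))
  if (length(missing)) {
    stop("marker gene(s) absent: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  centered <- x$values[markers, , drop = FALSE] -
    apply(x$values[markers, , drop = FALSE], 1, stats::median)
  score <- apply(centered, 2, max)
  s <- sort(score)
  n <- length(s)
  # Otsu: maximize between-class variance over the n - 1 split points
  best <- -Inf
  cut <- NA_real_
  for (i in seq_len(n - 1)) {
    m1 <- mean(s[1:i])
    m2 <- mean(s[(i + 1):n])
    bc <- i * (n - i) * (m1 - m2)^2
    if (bc > best) {
      best <- bc
      cut <- (m1 + m2) / 2
    }
  }
  stats::setNames(ifelse(score > cut, positive, negative), names(score))
}
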