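#' Derive a shared cross-study signature from GSEA leading edges
#'
#' Runs GSEA of a second study's differentially expressed up and down gene
#' sets against the first study's ranked gene list. Genes in the leading
#' edge (core enrichment) of each run -- the set members at or before the
#' running-sum extremum -- form the shared signature: `up` from the up set
#' (which must enrich at the top, ES > 0) and `down` from the down set
#' (which must enrich at the bottom, ES < 0). A wrong-sign or zero ES is an
#' error naming the direction. Genes landing in both directions are dropped
#' from both, with a message.
#'
#' @param ranked A [ranked_list()] from the first study's tumor contrast.
#' @param de_up,de_down [gene_set()]s (or character vectors) of genes up-
#'   and down-regulated in the second study.
#' @param name Signature name.
#' @param n_perm,weight_p,seed GSEA parameters, see [gsea()].
#' @return A [bidirectional_signature()]; the `runs` attribute holds the
#'   `gsea_result` (ES, NES, p, q of both runs) as provenance.
#' @export
derive_shared_signature <- function(ranked, de_up, de_down,
                                    name = "shared", n_perm = 1000,
                                    weight_p = 1, seed = 1) {
  sets <- list(gene_set(paste0(name, "_input_up"), set_genes(de_up)),
               gene_set(paste0(name, "_input_dn"), set_genes(de_down)))
  runs <- gsea(ranked, sets, n_perm = n_perm, weight_p = weight_p,
               seed = seed)
  if (is.na(runs$es[1]) || runs$es[1] <= 0) {
    stop("derive_shared_signature: up direction has non-positive ES (",
         format(runs$es[1], digits = 3), "); no top-of-list enrichment",
         call. = FALSE)
  }
  if (is.na(runs$es[2]) || runs$es[2] >= 0) {
    stop("derive_shared_signature: down direction has non-negative ES (",
         format(runs$es[2], digits = 3), "); no bottom-of-list enrichment",
         call. = FALSE)
  }
  up <- runs$leading_edge[[1]]
  down <- runs$leading_edge[[2]]
  both <- intersect(up, down)
  if (length(both)) {
    message("derive_shared_signature: dropping ", length(both),
            " gene(s) present in both leading edges")
    up <- setdiff(up, both)
    down <- setdiff(down, both)
  }
  if (!length(up) || !length(down)) {
    stop("derive_shared_signature: ",
         if (!length(up)) "up" else "down",
         " leading edge empty after conflict removal", call. = FALSE)
  }
  sig <- bidirectional_signature(
    name, up, down,
    provenance = sprintf(
      "leading edges of cross-study GSEA (up: ES=%.3f NES=%.3f p=%.3g q=%.3g; down: ES=%.3f NES=%.3f p=%.3g q=%.3g; n_perm=%d, weight_p=%g, seed=%d)",
      runs$es[1], runs$nes[1], runs$p[1], runs$q[1],
      runs$es[2], runs$nes[2], runs$p[2], runs$q[2],
      n_perm, weight_p, seed))
  attr(sig, "runs") <- runs
  sig
}

#' Refine a shared signature to its tumor-specific core
#'
#' Removes signature genes attributable to normal T-cell developmental stage
#' rather than transformation. Each signature direction is tested by GSEA
#' against a development contrast ranking (undifferentiated vs
#' differentiated); genes in the same-direction leading edge -- up-signature
#' genes core-enriched at the undifferentiated top (ES > 0), down-signature
#' genes core-enriched at the bottom (ES < 0) -- are deemed
#' development-associated and removed. A direction whose development ES has
#' the opposite sign carries no same-direction association and is kept
#' whole.
#'
#' @param shared A [bidirectional_signature()] from
#'   [derive_shared_signature()].
#' @param dev_ranked A [ranked_list()] for the development contrast
#'   (class A = undifferentiated).
#' @param n_perm,weight_p,seed GSEA parameters, see [gsea()].
#' @param fdr_cutoff Optional FDR gate: when set, leading-edge genes are
#'   only removed if the development run's q-value is at or below this
#'   cutoff. Default `NULL` removes on leading-edge membership alone.
#' @return A [bidirectional_signature()]; attributes `removed_up`,
#'   `removed_down` list the excised genes and `dev_runs` holds the
#'   development `gsea_result`.
#' @export
refine_tumor_specific <- function(shared, dev_ranked, n_perm = 1000,
                                  weight_p = 1, seed = 1,
                                  fdr_cutoff = NULL) {
  stopifnot(inherits(shared, "bidir_signature"))
  runs <- gsea(dev_ranked, list(shared$up, shared$down), n_perm = n_perm,
               weight_p = weight_p, seed = seed)
  dev_assoc <- function(i, want_sign) {
    es <- runs$es[i]
    if (is.na(es) || sign(es) != want_sign) return(character(0))
    if (!is.null(fdr_cutoff) &&
        (is.na(runs$q[i]) || runs$q[i] > fdr_cutoff)) {
      return(character(0))
    }
    runs$leading_edge[[i]]
  }
  remove_up <- dev_assoc(1, +1)
  remove_down <- dev_assoc(2, -1)
  up <- setdiff(shared$up$genes, remove_up)
  down <- setdiff(shared$down$genes, remove_down)
  if (length(remove_up) || length(remove_down)) {
    message("refine_tumor_specific: removing ", length(remove_up),
            " up and ", length(remove_down),
            " down development-associated gene(s)")
  }
  if (!length(up) || !length(down)) {
    stop("refine_tumor_specific: ",
         if (!length(up)) "up" else "down",
         " direction empty after development filtering", call. = FALSE)
  }
  sig <- bidirectional_signature(
    paste0(shared$name, "_tumor_specific"), up, down,
    provenance = paste0(
      shared$provenance,
      sprintf("; development-filtered (removed %d up, %d down; dev up ES=%.3f, dev down ES=%.3f, n_perm=%d, seed=%d)",
              length(remove_up), length(remove_down),
              runs$es[1], runs$es[2], n_perm, seed)))
  attr(sig, "removed_up") <- intersect(shared$up$genes, remove_up)
  attr(sig, "removed_down") <- intersect(shared$down$genes, remove_down)
  attr(sig, "dev_runs") <- runs
  sig
}
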