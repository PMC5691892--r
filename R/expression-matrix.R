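#' Log2-scale gene-by-sample expression matrix
#'
#' Lightweight container for a post-normalization (e.g. RMA) expression
#' matrix. Rows are genes, columns are samples, values are log2 expression
#' units. Optional sample annotations carry group or subtype labels.
#'
#' Invariants enforced at construction: gene and sample identifiers are
#' unique, all values are finite (missing values are rejected -- downstream
#' rank statistics are undefined on gaps), and annotations, when present,
#' cover every sample.
#'
#' @param values Numeric matrix with rownames (gene ids) and colnames
#'   (sample ids), on log2 scale.
#' @param groups Optional character vector of group labels, either named by
#'   sample id or positional (length = number of samples).
#' @return An object of class `expr_mat`.
#' @examples
#' m <- matrix(rnorm(12, 8), 4, 3,
#'   dimnames = list(paste0("G", 1:4), paste0("S", 1:3)))
#' em <- expression_matrix(m, groups = c("A", "A", "B"))
#' dim(em)
#' @export
expression_matrix <- function(values, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop("`values` must carry rownames (genes) and colnames (samples)",
         call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene ids: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must be finite; missing values are not supported",
         call. = FALSE)
  }
  if (!is.null(groups)) {
    groups <- stats::setNames(as.character(groups), names(groups))
    if (is.null(names(groups))) {
      if (length(groups) != ncol(values)) {
        stop("positional `groups` must have one label per sample",
             call. = FALSE)
      }
      names(groups) <- sid
    }
    missing <- setdiff(sid, names(groups))
    if (length(missing)) {
      stop("annotations must cover every sample; missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    groups <- groups[sid]
  }
  structure(list(values = values, groups = groups), class = "expr_mat")
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
dimnames.expr_mat <- function(x) dimnames(x$values)

#' @export
print.expr_mat <- function(x, ...) {
  cat("<expr_mat> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  if (!is.null(x$groups)) {
    tb <- table(x$groups)
    cat("groups: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Gene ids of an expression matrix
#' @param x An `expr_mat`.
#' @return Character vector of gene identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample ids of an expression matrix
#' @param x An `expr_mat`.
#' @return Character vector of sample identifiers.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Sample group labels of an expression matrix
#' @param x An `expr_mat`.
#' @return Named character vector of group labels, or `NULL`.
#' @export
sample_groups <- function(x) x$groups

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_mat`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `expression` and, when
#'   annotations exist, `group`.
#' @export
as_tibble.expr_mat <- function(x, ...) {
  out <- tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    expression = as.vector(x$values)
  )
  if (!is.null(x$groups)) out$group <- x$groups[out$sample]
  out
}

#' A named gene set
#'
#' @param name Set name.
#' @param genes Character vector of gene identifiers; duplicates are removed
#'   with a message.
#' @param description Free-text description.
#' @return An object of class `gene_set`.
#' @examples
#' gene_set("SIG_UP", c("HES1", "MYC"))
#' @export
gene_set <- function(name, genes, description = "na") {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene set '", name, "' is empty", call. = FALSE)
  if (anyDuplicated(genes)) {
    message("gene set '", name, "': dropping ",
            sum(duplicated(genes)), " duplicate gene(s)")
    genes <- unique(genes)
  }
  structure(list(name = as.character(name), genes = genes,
                 description = as.character(description)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, " (", length(x$genes), " genes)\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

# Coerce a gene_set or character vector to a plain gene id vector.
set_genes <- function(set) {
  if (inherits(set, "gene_set")) set$genes else as.character(set)
}

#' A bidirectional (up/down) gene signature
#'
#' Paired up-regulated and down-regulated gene sets derived from a contrast,
#' e.g. genes co-deregulated in two mouse tumor models.
#'
#' @param name Signature name.
#' @param up,down `gene_set` objects or character vectors; must be non-empty
#'   and disjoint.
#' @param provenance Free-text derivation record.
#' @return An object of class `bidir_signature`.
#' @export
bidirectional_signature <- function(name, up, down, provenance = "") {
  up <- set_genes(up)
  down <- set_genes(down)
  if (!length(up) || !length(down)) {
    stop("signature '", name, "': both directions must be non-empty",
         call. = FALSE)
  }
  both <- intersect(up, down)
  if (length(both)) {
    stop("signature '", name, "': up and down sets must be disjoint (",
         paste(both, collapse = ", "), ")", call. = FALSE)
  }
  structure(list(name = as.character(name),
                 up = gene_set(paste0(name, "_UP"), up),
                 down = gene_set(paste0(name, "_DN"), down),
                 provenance = provenance),
            class = "bidir_signature")
}

#' @export
print.bidir_signature <- function(x, ...) {
  cat("<bidir_signature> ", x$name, ": ", length(x$up$genes), " up / ",
      length(x$down$genes), " down\n", sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
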