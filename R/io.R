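#' Read a GCT 1.2 expression file
#'
#' GCT 1.2: line 1 is the literal header `#1.2`, line 2 declares the row and
#' column counts, line 3 holds `NAME`, `Description` and the sample ids, and
#' each following line is one gene. Parse failures name the offending line.
#'
#' @param path Path to a GCT file.
#' @return An [expression_matrix()].
#' @seealso [write_gct()]
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3) {
    stop("GCT parse error at line 1: file has fewer than 3 lines",
         call. = FALSE)
  }
  if (trimws(lines[1]) != "#1.2") {
    stop("GCT parse error at line 1: expected header '#1.2', got '",
         trimws(lines[1]), "'", call. = FALSE)
  }
  counts <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (length(counts) < 2 || anyNA(counts[1:2])) {
    stop("GCT parse error at line 2: expected two integer counts",
         call. = FALSE)
  }
  n_genes <- counts[1]
  n_samples <- counts[2]
  header <- strsplit(lines[3], "\t")[[1]]
  if (length(header) != n_samples + 2) {
    stop("GCT parse error at line 3: expected ", n_samples + 2,
         " columns, got ", length(header), call. = FALSE)
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_genes) {
    stop("GCT parse error: declared ", n_genes, " rows but found ",
         length(body), call. = FALSE)
  }
  sid <- header[-(1:2)]
  gid <- character(n_genes)
  values <- matrix(NA_real_, n_genes, n_samples)
  for (i in seq_len(n_genes)) {
    fields <- strsplit(body[i], "\t")[[1]]
    if (length(fields) != n_samples + 2) {
      stop("GCT parse error at line ", i + 3, ": expected ", n_samples + 2,
           " fields, got ", length(fields), call. = FALSE)
    }
    gid[i] <- fields[1]
    row <- suppressWarnings(as.numeric(fields[-(1:2)]))
    if (anyNA(row)) {
      stop("GCT parse error at line ", i + 3, ": non-numeric expression value",
           call. = FALSE)
    }
    values[i, ] <- row
  }
  dup <- which(duplicated(gid))
  if (length(dup)) {
    stop("GCT parse error at line ", dup[1] + 3, ": duplicate gene id '",
         gid[dup[1]], "'", call. = FALSE)
  }
  dimnames(values) <- list(gid, sid)
  expression_matrix(values)
}

#' Write a GCT 1.2 expression file
#'
#' `write_gct()` followed by [read_gct()] recovers the same gene ids, sample
#' ids and values (up to float formatting; 15 significant digits are kept).
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path) {
  stopifnot(inherits(x, "expr_mat"))
  v <- x$values
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], "na",
            format(v[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c("#1.2",
               paste(nrow(v), ncol(v), sep = "\t"),
               paste(c("NAME", "Description", colnames(v)), collapse = "\t"),
               rows),
             path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each tab-separated line is `name`, `description`, then one or more genes.
#' Duplicate genes within a line are removed with a message.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_set()] objects.
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t")[[1]]
    if (length(fields) < 3) {
      stop("GMT parse error at line ", i,
           ": expected at least 3 tab-separated fields", call. = FALSE)
    }
    sets[[i]] <- gene_set(fields[1], fields[-(1:2)], description = fields[2])
  }
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets A list of [gene_set()] objects (or a single one), or a
#'   [bidirectional_signature()] (written as its `_UP` and `_DN` lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "bidir_signature")) sets <- list(sets$up, sets$down)
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a categorical CLS phenotype file
#'
#' Standard categorical CLS: line 1 is `N k 1`, line 2 is `# name1 ... namek`,
#' line 3 has N space-separated labels, given either as 0-based class indices
#' or as the class names themselves (both dialects circulate).
#'
#' @param path Path to a CLS file.
#' @return Character vector of N class labels, positionally matching the
#'   sample columns of the companion expression matrix.
#' @export
read_cls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) {
    stop("CLS parse error: expected 3 lines, found ", length(lines),
         call. = FALSE)
  }
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) < 2 || anyNA(hdr[1:2])) {
    stop("CLS parse error at line 1: expected 'N k 1'", call. = FALSE)
  }
  n <- hdr[1]
  k <- hdr[2]
  name_line <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (name_line[1] != "#") {
    stop("CLS parse error at line 2: expected '# name1 ... namek'",
         call. = FALSE)
  }
  class_names <- name_line[-1]
  if (length(class_names) != k) {
    stop("CLS parse error at line 2: declared ", k, " classes but named ",
         length(class_names), call. = FALSE)
  }
  labels <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(labels) != n) {
    stop("CLS parse error at line 3: declared ", n, " samples but found ",
         length(labels), " labels", call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(labels))
  if (!anyNA(idx)) {
    if (any(idx < 0 | idx >= k)) {
      stop("CLS parse error at line 3: class index out of range [0, ",
           k - 1, "]", call. = FALSE)
    }
    return(class_names[idx + 1])
  }
  bad <- setdiff(labels, class_names)
  if (length(bad)) {
    stop("CLS parse error at line 3: unknown class label '", bad[1], "'",
         call. = FALSE)
  }
  labels
}

#' Collapse a probe-level matrix to gene level
#'
#' Microarray matrices are probe-level while signatures are gene-level. For
#' genes with several probes the probe with maximal mean expression across
#' samples is kept (the common GSEA convention; deterministic, with
#' lexicographic probe-id tie-break). Unmapped probes are dropped with a
#' message.
#'
#' @param x Probe-level [expression_matrix()].
#' @param probe_to_gene Named character vector: `names()` are probe ids,
#'   values are gene symbols.
#' @return Gene-level [expression_matrix()].
#' @export
collapse_probes <- function(x, probe_to_gene) {
  stopifnot(inherits(x, "expr_mat"))
  probes <- rownames(x$values)
  mapped <- probes[probes %in% names(probe_to_gene)]
  n_drop <- length(probes) - length(mapped)
  if (n_drop > 0) message("collapse_probes: dropping ", n_drop,
                          " unmapped probe(s)")
  if (!length(mapped)) {
    stop("collapse_probes: no probe maps to a gene", call. = FALSE)
  }
  gene <- as.character(probe_to_gene[mapped])
  means <- rowMeans(x$values[mapped, , drop = FALSE])
  ord <- order(gene, -means, mapped)
  keep <- !duplicated(gene[ord])
  chosen <- ord[keep]
  out <- x$values[mapped[chosen], , drop = FALSE]
  rownames(out) <- gene[chosen]
  expression_matrix(out, groups = x$groups)
}

#' Read a two-column ortholog table
#'
#' Tab-separated file with header columns `source_id` and `target_id`; one
#' row per ortholog pair (many-to-many allowed).
#'
#' @param path Path to the TSV file.
#' @return Named list mapping each source gene id to a character vector of
#'   target gene ids.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_id", "target_id") %in% names(df))) {
    stop("ortholog table must have columns source_id and target_id",
         call. = FALSE)
  }
  split(as.character(df$target_id), as.character(df$source_id))
}

#' Map a signature across species through an ortholog table
#'
#' Each source gene is replaced by all of its targets. Source genes without
#' orthologs are dropped with a message. A target reachable from both the up
#' and the down direction is dropped from both (conservative,
#' order-independent conflict rule), with a message.
#'
#' @param sig A [bidirectional_signature()] in source-species gene ids.
#' @param ortholog_map Named list as returned by [read_ortholog_map()].
#' @param uppercase If `TRUE`, uppercase-normalize target ids (mouse symbols
#'   are Title-case, human symbols upper-case). Matching is otherwise
#'   case-sensitive: silent case-folding hides mapping errors.
#' @return A [bidirectional_signature()] in target-species gene ids.
#' @export
map_orthologs <- function(sig, ortholog_map, uppercase = FALSE) {
  stopifnot(inherits(sig, "bidir_signature"))
  translate <- function(genes, dir) {
    hit <- genes[genes %in% names(ortholog_map)]
    n_drop <- length(genes) - length(hit)
    if (n_drop > 0) message("map_orthologs: ", dir, ": dropping ", n_drop,
                            " gene(s) without orthologs")
    out <- unique(unlist(ortholog_map[hit], use.names = FALSE))
    if (uppercase) out <- unique(toupper(out))
    out
  }
  up <- translate(sig$up$genes, "up")
  down <- translate(sig$down$genes, "down")
  conflict <- intersect(up, down)
  if (length(conflict)) {
    message("map_orthologs: dropping ", length(conflict),
            " target(s) reached from both directions")
    up <- setdiff(up, conflict)
    down <- setdiff(down, conflict)
  }
  if (!length(up) || !length(down)) {
    stop("map_orthologs: ",
         if (!length(up)) "up" else "down",
         " direction is empty after mapping", call. = FALSE)
  }
  bidirectional_signature(
    sig$name, up, down,
    provenance = paste0(sig$provenance,
                        "; ortholog-mapped (", length(up), " up, ",
                        length(down), " down)"))
}
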