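#' Gene-set collection constructor
#'
#' An ordered collection of named gene sets (term id, free-text description,
#' member protein ids). Member lists are deduplicated with a warning; empty
#' member lists and duplicated term ids are rejected.
#'
#' @param term_ids Character vector of unique term identifiers.
#' @param descriptions Character vector of descriptions (recycled if length 1).
#' @param members List of character vectors of member protein ids.
#' @return Object of class `gene_sets`: a named list of member vectors with a
#'   `descriptions` attribute.
#' @export
gene_sets <- function(term_ids, descriptions = "", members) {
  term_ids <- as.character(term_ids)
  if (anyDuplicated(term_ids)) {
    stop("duplicated term ids: ",
         paste(unique(term_ids[duplicated(term_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(members) != length(term_ids)) {
    stop("`members` must have one entry per term", call. = FALSE)
  }
  descriptions <- rep_len(as.character(descriptions), length(term_ids))
  members <- lapply(seq_along(members), function(i) {
    m <- as.character(members[[i]])
    if (length(m) == 0) {
      stop(sprintf("term '%s' has no members", term_ids[i]), call. = FALSE)
    }
    if (anyDuplicated(m)) {
      warning(sprintf("term '%s': duplicated members removed", term_ids[i]),
              call. = FALSE)
      m <- unique(m)
    }
    m
  })
  names(members) <- term_ids
  names(descriptions) <- term_ids
  structure(members, descriptions = descriptions, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("Gene-set collection: %d terms (sizes %d-%d)\n",
              length(x), if (length(x)) min(sizes) else 0,
              if (length(x)) max(sizes) else 0))
  invisible(x)
}

#' Read and write log2 abundance matrices as TSV
#'
#' The on-disk layout is one header row of protein ids (first column
#' `sample_id`) and one row per sample. Values are written with 15
#' significant digits so write-then-read round-trips to within float text
#' precision; missing values are written as `NA`.
#'
#' @param path File path.
#' @return `read_abundance()` returns a numeric samples x proteins matrix
#'   with sample ids as row names.
#' @export
read_abundance <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    stop("abundance file is empty or has no data rows: ", path, call. = FALSE)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "sample_id") {
    stop("abundance file must start with a 'sample_id' header column",
         call. = FALSE)
  }
  p_ids <- header[-1]
  if (anyDuplicated(p_ids)) {
    stop("duplicated protein ids in header: ",
         paste(unique(p_ids[duplicated(p_ids)]), collapse = ", "),
         call. = FALSE)
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != length(header))) {
    stop(sprintf("ragged abundance rows (expected %d fields): line %s",
                 length(header),
                 paste(which(widths != length(header)) + 1L, collapse = ", ")),
         call. = FALSE)
  }
  s_ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(s_ids)) {
    stop("duplicated sample ids: ",
         paste(unique(s_ids[duplicated(s_ids)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(rows, function(r) {
    v <- r[-1]
    v[v == ""] <- "NA"
    suppressWarnings(as.numeric(v))
  }, numeric(length(p_ids)))
  mat <- t(matrix(vals, nrow = length(p_ids)))
  dimnames(mat) <- list(s_ids, p_ids)
  if (any(is.infinite(mat))) {
    stop("non-finite abundance values", call. = FALSE)
  }
  mat
}

#' @rdname read_abundance
#' @param matrix Numeric samples x proteins matrix with dimnames.
#' @export
write_abundance <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  header <- paste(c("sample_id", colnames(matrix)), collapse = "\t")
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i],
            formatC(matrix[i, ], digits = 15, format = "g")),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write the sample metadata table as TSV
#'
#' @param path File path.
#' @return `read_metadata()` returns a data frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample ids in metadata", call. = FALSE)
  }
  df
}

#' @rdname read_metadata
#' @param records Data frame of sample records.
#' @export
write_metadata <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and write gene sets in GMT format
#'
#' GMT is tab-separated: term id, description, then member ids. Lines with
#' fewer than three fields are rejected with their line number; duplicated
#' members within a term are dropped with a warning.
#'
#' @param path File path.
#' @return `read_gmt()` returns a [gene_sets] collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) {
    stop(sprintf("GMT line %s: fewer than 3 tab-separated fields",
                 paste(lineno[bad], collapse = ", ")), call. = FALSE)
  }
  gene_sets(term_ids = vapply(fields, `[[`, "", 1L),
            descriptions = vapply(fields, `[[`, "", 2L),
            members = lapply(fields, function(f) f[-c(1, 2)]))
}

#' @rdname read_gmt
#' @param sets A [gene_sets] collection.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a pathway-clinical bipartite graph to GraphML
#'
#' Nodes carry the attribute `node_type` (`"pathway"` or `"clinical"`), edges
#' carry `weight` (signed aggregate w) and `n_proteins` (number of proteins
#' backing the edge). Any GraphML reader recovers them.
#'
#' @param graph An igraph object as produced by [build_graph()].
#' @param path Output file path.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  # GraphML carries only scalar attributes; drop in-memory extras such as
  # the protein-level edge_detail table.
  for (at in igraph::graph_attr_names(graph)) {
    if (!is.atomic(igraph::graph_attr(graph, at))) {
      graph <- igraph::delete_graph_attr(graph, at)
    }
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
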