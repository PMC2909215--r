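#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, members... Sets with no members are dropped
#' with a warning; duplicate set names are an error. The description
#' field is kept as the set's source annotation.
#'
#' @param path file path.
#' @return object of class `gene_set_collection`: named list of
#'   character member vectors with a parallel `info` data.frame
#'   (set_id, source).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); info <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop("malformed GMT line ", i, ": fewer than 2 fields")
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(members) == 0L) {
      warning("set '", f[1L], "' (line ", i, ") has no members; dropped")
      next
    }
    if (f[1L] %in% names(sets)) stop("duplicate set name: ", f[1L])
    sets[[f[1L]]] <- members
    info[[f[1L]]] <- data.frame(set_id = f[1L], source = f[2L],
                                n_members = length(members),
                                stringsAsFactors = FALSE)
  }
  structure(list(sets = sets, info = do.call(rbind, c(info, make.row.names = FALSE))),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param collection a `gene_set_collection`.
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    src <- collection$info$source[collection$info$set_id == id]
    paste(c(id, src, collection$sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene set collection: %d sets, %d distinct genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Fisher-exact gene-set enrichment of a gene list
#'
#' For every set in the collection, tests over-representation of the gene
#' list by the one-sided hypergeometric (Fisher exact) tail on the 2x2
#' table (in-list / not-in-list) x (in-set / not-in-set), restricted to
#' the universe; collection genes absent from the universe are ignored,
#' and sets disjoint from the universe are omitted. P-values are reported
#' uncorrected: heavily overlapping gene sets violate the independence
#' assumed by standard multiplicity corrections, so no adjustment is
#' applied. Rows with p below `p_threshold` are returned sorted by p.
#'
#' @param gene_list character vector, subset of `universe` (e.g. up- or
#'   down-regulated membranome genes).
#' @param universe the analyzed gene pool (e.g. on-array membranome).
#' @param collection a `gene_set_collection`.
#' @param p_threshold reporting threshold (default 0.05).
#' @param list_label label carried into the result rows.
#' @return data.frame with columns set_id, source, n_set, n_overlap,
#'   p_value, overlap_genes, list_label. Empty (with a flag attribute)
#'   when `gene_list` is empty.
#' @export
enrich <- function(gene_list, universe, collection, p_threshold = 0.05,
                   list_label = "gene_list") {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  gene_list <- unique(as.character(gene_list))
  if (length(setdiff(gene_list, universe)) > 0L)
    stop("gene_list must be a subset of the universe")
  empty <- data.frame(set_id = character(), source = character(),
                      n_set = integer(), n_overlap = integer(),
                      p_value = numeric(), overlap_genes = character(),
                      list_label = character(), stringsAsFactors = FALSE)
  if (length(gene_list) == 0L) {
    attr(empty, "empty_list") <- TRUE
    return(empty)
  }
  rows <- list()
  for (id in names(collection$sets)) {
    set_u <- intersect(collection$sets[[id]], universe)
    if (length(set_u) == 0L) next
    ov <- intersect(gene_list, set_u)
    res <- overlap_significance(gene_list, set_u, universe)
    if (res$p_value < p_threshold) {
      rows[[id]] <- data.frame(
        set_id = id,
        source = collection$info$source[collection$info$set_id == id],
        n_set = length(set_u), n_overlap = length(ov),
        p_value = res$p_value,
        overlap_genes = paste(sort(ov), collapse = ";"),
        list_label = list_label, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, c(rows, make.row.names = FALSE))
         else empty
  out[order(out$p_value), , drop = FALSE]
}
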