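#' Construct an expression dataset
#'
#' Binds a genes x samples matrix to a sample manifest. The manifest must
#' have columns `sample_id`, `tissue`, `sample_class` (one of `tumor`,
#' `cell_line`, `normal`), `study_id`, and optionally `replicate_group`
#' (identifier tying technical replicates; NA or "" for unreplicated
#' samples). `scale_state` tracks whether values are on the linear or log2
#' scale so the preprocessing chain can refuse to run stages out of order.
#'
#' @param matrix numeric matrix, rows = genes (rownames = gene IDs),
#'   columns = samples (colnames = sample IDs).
#' @param manifest data.frame as described above, one row per sample.
#' @param scale_state `"linear"` or `"log2"`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, manifest, scale_state = c("linear", "log2")) {
  scale_state <- match.arg(scale_state)
  stopifnot(is.matrix(matrix), is.numeric(matrix), is.data.frame(manifest))
  if (is.null(rownames(matrix))) stop("matrix must carry gene IDs as rownames")
  if (is.null(colnames(matrix))) stop("matrix must carry sample IDs as colnames")
  required <- c("sample_id", "tissue", "sample_class", "study_id")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0L)
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample_id in manifest")
  if (!setequal(colnames(matrix), manifest$sample_id))
    stop("matrix column names and manifest sample_ids differ")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene IDs in matrix rownames")
  bad <- setdiff(unique(manifest$sample_class), c("tumor", "cell_line", "normal"))
  if (length(bad) > 0L)
    stop("unknown sample_class value(s): ", paste(bad, collapse = ", "))
  if (anyNA(matrix)) stop("matrix contains missing values")
  manifest <- manifest[match(colnames(matrix), manifest$sample_id), , drop = FALSE]
  rownames(manifest) <- NULL
  if (!"replicate_group" %in% names(manifest))
    manifest$replicate_group <- NA_character_
  manifest$replicate_group[which(manifest$replicate_group == "")] <- NA_character_
  structure(list(matrix = matrix, manifest = manifest, scale_state = scale_state),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%s scale)\n",
              nrow(x$matrix), ncol(x$matrix), x$scale_state))
  print(table(x$manifest$tissue, x$manifest$sample_class))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Average technical replicates
#'
#' Collapses each replicate group to a single column holding the per-gene
#' arithmetic mean; the merged manifest row keeps the group's shared tissue,
#' class and study and takes the lexicographically first sample_id. A group
#' spanning different tissues or classes is an error.
#'
#' @param ds an `expression_dataset`.
#' @return an `expression_dataset` with one column per replicate group.
#' @export
average_replicates <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  man <- ds$manifest
  grp <- man$replicate_group
  if (all(is.na(grp))) return(ds)
  key <- ifelse(is.na(grp), paste0(".single.", man$sample_id), grp)
  pieces <- split(seq_len(nrow(man)), key)
  cols <- lapply(pieces, function(idx) {
    if (length(idx) > 1L) {
      if (length(unique(man$tissue[idx])) != 1L ||
          length(unique(man$sample_class[idx])) != 1L)
        stop("replicate group '", key[idx[1L]],
             "' spans different tissues or classes")
      rowMeans(ds$matrix[, idx, drop = FALSE])
    } else ds$matrix[, idx]
  })
  ids <- vapply(pieces, function(idx) sort(man$sample_id[idx])[1L], character(1L))
  new_man <- man[vapply(pieces, function(idx)
    idx[order(man$sample_id[idx])][1L], integer(1L)), , drop = FALSE]
  new_man$sample_id <- ids
  new_man$replicate_group <- NA_character_
  m <- do.call(cbind, cols)
  colnames(m) <- ids
  # restore original sample order (first appearance of each group)
  first <- vapply(pieces, min, integer(1L))
  ord <- order(first)
  expression_dataset(m[, ord, drop = FALSE], new_man[ord, , drop = FALSE],
                     ds$scale_state)
}

#' Scale each sample to a fixed trimmed mean
#'
#' Multiplies every column by `target / trimmed_mean(column)`, where the
#' trimmed mean discards the lowest and highest `trim_fraction` of values
#' (the scaling convention of array summarization, target 500 by default).
#' Requires linear-scale non-negative data.
#'
#' @param ds an `expression_dataset` with `scale_state == "linear"`.
#' @param target trimmed-mean value after scaling.
#' @param trim_fraction fraction of values discarded at each end.
#' @return rescaled `expression_dataset`; scale factors in
#'   `attr(, "scale_factors")`.
#' @export
scale_to_trimmed_mean <- function(ds, target = 500, trim_fraction = 0.02) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$scale_state != "linear")
    stop("trimmed-mean scaling requires linear-scale data")
  if (any(ds$matrix < 0)) stop("negative values on linear scale")
  tm <- apply(ds$matrix, 2L, mean, trim = trim_fraction)
  if (any(tm <= 0)) stop("non-positive trimmed mean in column(s): ",
                         paste(colnames(ds$matrix)[tm <= 0], collapse = ", "))
  f <- target / tm
  out <- expression_dataset(sweep(ds$matrix, 2L, f, `*`), ds$manifest, "linear")
  attr(out, "scale_factors") <- f
  out
}

#' Quantile normalization across samples
#'
#' Forces every sample column to share the same distribution of values (the
#' across-column mean of order statistics) while preserving within-column
#' ranks; tied values receive the mean of the corresponding mean order
#' statistics. Idempotent. A single-column dataset is returned unchanged
#' with a warning.
#'
#' @param ds an `expression_dataset` with no missing values.
#' @return quantile-normalized `expression_dataset`.
#' @export
quantile_normalize <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ncol(ds$matrix) < 2L) {
    warning("single-column dataset: quantile normalization is a no-op")
    return(ds)
  }
  m <- limma::normalizeQuantiles(ds$matrix, ties = TRUE)
  dimnames(m) <- dimnames(ds$matrix)
  expression_dataset(m, ds$manifest, ds$scale_state)
}

#' Log2 transform with a floor
#'
#' Applies `log2(max(value, floor))` to every entry and flips
#' `scale_state` to `"log2"`. The floor (default 1 on the linear scale)
#' avoids minus infinity at zero intensities.
#'
#' @param ds an `expression_dataset` with `scale_state == "linear"`.
#' @param floor positive value below which intensities are clamped.
#' @return log2-scale `expression_dataset`.
#' @export
log2_transform <- function(ds, floor = 1) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$scale_state != "linear") stop("data already log2 transformed")
  if (floor <= 0) stop("floor must be positive")
  expression_dataset(log2(pmax(ds$matrix, floor)), ds$manifest, "log2")
}

#' Full preprocessing chain
#'
#' Fixed stage order: average technical replicates, scale each array to a
#' trimmed mean of `target`, quantile normalize, log2 transform. The
#' `scale_state` guard prevents stages running out of order.
#'
#' @inheritParams scale_to_trimmed_mean
#' @inheritParams log2_transform
#' @return log2-scale preprocessed `expression_dataset`.
#' @export
preprocess <- function(ds, target = 500, trim_fraction = 0.02, floor = 1) {
  ds <- average_replicates(ds)
  ds <- scale_to_trimmed_mean(ds, target = target, trim_fraction = trim_fraction)
  ds <- quantile_normalize(ds)
  log2_transform(ds, floor = floor)
}

#' Read an expression matrix and manifest from TSV
#'
#' Matrix: first column `gene_id`, remaining columns one per sample with
#' sample IDs in the header. Manifest: TSV with columns `sample_id`,
#' `tissue`, `sample_class`, `study_id` and optional `replicate_group`.
#'
#' @param matrix_path,manifest_path file paths.
#' @param scale_state scale of the stored values.
#' @return an `expression_dataset`.
#' @export
read_expression_dataset <- function(matrix_path, manifest_path,
                                    scale_state = "linear") {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  expression_dataset(m, man, scale_state)
}

#' Write an expression dataset to TSV
#'
#' @param ds an `expression_dataset`.
#' @param matrix_path,manifest_path output file paths.
#' @export
write_expression_dataset <- function(ds, matrix_path, manifest_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  tab <- data.frame(gene_id = rownames(ds$matrix), ds$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Subset an expression dataset
#'
#' @param ds an `expression_dataset`.
#' @param genes optional character vector of gene IDs to keep.
#' @param samples optional character vector of sample IDs, or a logical or
#'   integer selector over manifest rows.
#' @return subsetted `expression_dataset`.
#' @export
subset_dataset <- function(ds, genes = NULL, samples = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  m <- ds$matrix
  man <- ds$manifest
  if (!is.null(genes)) {
    keep <- intersect(as.character(genes), rownames(m))
    m <- m[keep, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) keep_s <- intersect(samples, colnames(m))
    else keep_s <- man$sample_id[samples]
    m <- m[, keep_s, drop = FALSE]
    man <- man[match(keep_s, man$sample_id), , drop = FALSE]
  }
  expression_dataset(m, man, ds$scale_state)
}
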