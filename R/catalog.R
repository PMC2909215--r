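#' Construct catalog rules
#'
#' A rule set deciding membranome membership from annotation evidence.
#' Compartment accept/reject lists are plain character vectors of controlled
#' vocabulary identifiers (e.g. GO cellular-component IDs), shipped as editable
#' configuration rather than hard-coded ontology IDs because ontology versions
#' drift. Manual override lists correct false negatives (e.g. GPI-anchored
#' proteins lacking both predicted transmembrane segments and membrane
#' compartment annotation) and false positives.
#'
#' @param plasma_membrane_terms accept-list of compartment identifiers.
#' @param intracellular_terms reject-list of compartment identifiers.
#' @param include_overrides gene IDs always admitted.
#' @param exclude_overrides gene IDs always rejected.
#' @return An object of class `catalog_rules`.
#' @export
catalog_rules <- function(plasma_membrane_terms = character(),
                          intracellular_terms = character(),
                          include_overrides = character(),
                          exclude_overrides = character()) {
  include_overrides <- unique(as.character(include_overrides))
  exclude_overrides <- unique(as.character(exclude_overrides))
  both <- intersect(include_overrides, exclude_overrides)
  if (length(both) > 0L)
    stop("gene(s) in both include and exclude overrides: ",
         paste(both, collapse = ", "))
  structure(list(plasma_membrane_terms = unique(as.character(plasma_membrane_terms)),
                 intracellular_terms = unique(as.character(intracellular_terms)),
                 include_overrides = include_overrides,
                 exclude_overrides = exclude_overrides),
            class = "catalog_rules")
}

#' Classify a single gene as membranome or not
#'
#' Decision logic: manual overrides take precedence; otherwise a
#' plasma-membrane compartment term admits the gene; otherwise a predicted
#' transmembrane domain admits it unless the gene carries an
#' intracellular-compartment reject term. A signal peptide alone never
#' suffices (it marks secreted as well as membrane proteins).
#'
#' @param record a list or one-row data.frame with fields `gene_id`,
#'   `compartment_terms` (character vector, or a single
#'   semicolon-separated string), `has_tm_domain`, `has_signal_peptide`.
#' @param rules a [catalog_rules()] object.
#' @return list with `member` (logical) and `reason`, one of
#'   `override_include`, `override_exclude`, `compartment_match`,
#'   `tm_evidence`, `intracellular_reject`, `no_evidence`.
#' @export
classify_gene <- function(record, rules) {
  stopifnot(inherits(rules, "catalog_rules"))
  gene_id <- as.character(record$gene_id)
  terms <- record$compartment_terms
  if (is.list(terms)) terms <- terms[[1L]]
  terms <- .split_terms(terms)
  tm <- isTRUE(as.logical(record$has_tm_domain))
  if (gene_id %in% rules$exclude_overrides)
    return(list(member = FALSE, reason = "override_exclude"))
  if (gene_id %in% rules$include_overrides)
    return(list(member = TRUE, reason = "override_include"))
  if (length(intersect(terms, rules$plasma_membrane_terms)) > 0L)
    return(list(member = TRUE, reason = "compartment_match"))
  if (tm) {
    if (length(intersect(terms, rules$intracellular_terms)) > 0L)
      return(list(member = FALSE, reason = "intracellular_reject"))
    return(list(member = TRUE, reason = "tm_evidence"))
  }
  list(member = FALSE, reason = "no_evidence")
}

.split_terms <- function(terms) {
  if (is.null(terms) || length(terms) == 0L) return(character())
  if (length(terms) == 1L && is.character(terms) && grepl(";", terms, fixed = TRUE))
    terms <- strsplit(terms, ";", fixed = TRUE)[[1L]]
  terms <- trimws(as.character(terms))
  terms[nzchar(terms)]
}

#' Build the membranome catalog from an annotation table
#'
#' Applies [classify_gene()] to every record and records the admitting or
#' rejecting rule as per-gene evidence. Override gene IDs absent from the
#' annotation table raise a warning, not an error.
#'
#' @param annotations data.frame with columns `gene_id`, `compartment_terms`
#'   (semicolon-separated string), `has_tm_domain`, `has_signal_peptide`,
#'   `functional_category`, `on_array`. See [read_annotations()].
#' @param rules a [catalog_rules()] object.
#' @return An object of class `membranome_catalog`: list with `members`
#'   (character), `evidence` (data.frame gene_id/member/reason),
#'   `n_total_genes`, `n_on_array`, `membership_fraction`, and the
#'   `annotations` used.
#' @export
build_catalog <- function(annotations, rules) {
  stopifnot(is.data.frame(annotations), nrow(annotations) >= 1L)
  ids <- as.character(annotations$gene_id)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate gene_id in annotation table: ",
         paste(unique(dup), collapse = ", "))
  unknown <- setdiff(c(rules$include_overrides, rules$exclude_overrides), ids)
  if (length(unknown) > 0L)
    warning("override gene_id(s) not in annotation table: ",
            paste(unknown, collapse = ", "))
  decisions <- lapply(seq_len(nrow(annotations)), function(i)
    classify_gene(annotations[i, , drop = FALSE], rules))
  member <- vapply(decisions, `[[`, logical(1L), "member")
  reason <- vapply(decisions, `[[`, character(1L), "reason")
  members <- ids[member]
  on_array <- if ("on_array" %in% names(annotations))
    as.logical(annotations$on_array) else rep(TRUE, length(ids))
  structure(list(
    members = members,
    evidence = data.frame(gene_id = ids, member = member, reason = reason,
                          stringsAsFactors = FALSE),
    n_total_genes = length(ids),
    n_on_array = sum(member & on_array),
    membership_fraction = length(members) / length(ids),
    annotations = annotations
  ), class = "membranome_catalog")
}

#' @export
print.membranome_catalog <- function(x, ...) {
  cat("Membranome catalog\n")
  cat(sprintf("  members: %d of %d genes (%.1f%%)\n", length(x$members),
              x$n_total_genes, 100 * x$membership_fraction))
  cat(sprintf("  on expression platform: %d\n", x$n_on_array))
  invisible(x)
}

#' Platform coverage of a catalog
#'
#' Fraction of catalog members represented on an expression platform.
#' Percentages are reported unrounded and rounded to the nearest integer
#' (ties away from zero).
#'
#' @param catalog a `membranome_catalog`, or a character vector of member
#'   gene IDs.
#' @param array_genes character vector of gene IDs on the platform.
#' @return list with `n_members`, `n_covered`, `percentage`,
#'   `percentage_rounded`.
#' @export
array_coverage <- function(catalog, array_genes) {
  members <- if (inherits(catalog, "membranome_catalog")) catalog$members
             else as.character(catalog)
  if (length(members) == 0L) stop("empty catalog")
  n_cov <- length(intersect(members, as.character(array_genes)))
  pct <- 100 * n_cov / length(members)
  list(n_members = length(members), n_covered = n_cov,
       percentage = pct, percentage_rounded = round_half_away(pct))
}

#' Functional-category representation of the catalog on the platform
#'
#' For each functional category present among catalog members, compares its
#' share of the full catalog with its share of the on-platform subset by a
#' two-sided Fisher exact test on the 2x2 table
#' (category / not-category) x (on-array / off-array), restricted to catalog
#' members.
#'
#' @param catalog a `membranome_catalog` built from annotations carrying
#'   `functional_category` and `on_array`.
#' @param annotations optional annotation table; defaults to the one stored
#'   in the catalog.
#' @return data.frame with one row per category: counts and percentages in
#'   the full catalog and the on-array subset, and the exact-test p-value.
#' @export
category_representation <- function(catalog, annotations = catalog$annotations) {
  stopifnot(inherits(catalog, "membranome_catalog"))
  ann <- annotations[annotations$gene_id %in% catalog$members, , drop = FALSE]
  on_arr <- as.logical(ann$on_array)
  cats <- sort(unique(as.character(ann$functional_category)))
  n_tot <- nrow(ann)
  n_on <- sum(on_arr)
  rows <- lapply(cats, function(cc) {
    in_cat <- ann$functional_category == cc
    tab <- matrix(c(sum(in_cat & on_arr), sum(in_cat & !on_arr),
                    sum(!in_cat & on_arr), sum(!in_cat & !on_arr)),
                  nrow = 2L, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    data.frame(category = cc,
               n_catalog = sum(in_cat),
               n_on_array = sum(in_cat & on_arr),
               pct_catalog = 100 * sum(in_cat) / n_tot,
               pct_on_array = if (n_on > 0) 100 * sum(in_cat & on_arr) / n_on else NA_real_,
               p_value = min(1, p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a gene annotation table
#'
#' TSV with header columns `gene_id`, `compartment_terms`
#' (semicolon-separated), `has_tm_domain`, `has_signal_peptide`,
#' `functional_category`, `on_array`. Missing predictions are read as FALSE.
#'
#' @param path file path.
#' @return data.frame of annotation records.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("gene_id", "compartment_terms", "has_tm_domain",
                "has_signal_peptide", "functional_category", "on_array")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0L)
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  for (col in c("has_tm_domain", "has_signal_peptide", "on_array")) {
    v <- toupper(trimws(ann[[col]]))
    ann[[col]] <- v %in% c("TRUE", "T", "1", "YES")
  }
  ann
}

#' Write catalog membership decisions to TSV
#'
#' @param catalog a `membranome_catalog`.
#' @param path output file.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "membranome_catalog"))
  utils::write.table(catalog$evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Round to nearest integer, ties away from zero (not banker's rounding):
# reported percentages use this convention.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
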