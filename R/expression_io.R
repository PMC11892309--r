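#' Read an expression matrix from tab-delimited text
#'
#' Reads a TSV with one header row and one identifier column into an
#' [expr_mat()]. The file may store genes in rows (the package's native
#' layout) or samples in rows; either way the returned object is genes x
#' samples. Ensembl-style version suffixes (`".<integer>"`) are stripped from
#' gene identifiers; if stripping creates duplicates, the row with the highest
#' mean expression is kept with a warning.
#'
#' Lines starting with `#` are treated as comments (pipeline runs record their
#' parameters that way).
#'
#' @param path Path to a tab-delimited file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param unit Expression unit tag, see [expr_mat()].
#' @return An [expr_mat()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows", "samples_in_rows"),
                                   unit = "counts") {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE,
                         na = character(), name_repair = "minimal")
  if (ncol(raw) < 2L) abort("Expected an ID column plus at least one data column.")
  ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  values <- matrix(NA_real_, nrow(body), ncol(body),
                   dimnames = list(ids, names(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(sprintf("Non-numeric value '%s' at row '%s', column '%s' in %s.",
                    body[[j]][bad[1L]], ids[bad[1L]], names(body)[j], path))
    }
    values[, j] <- v
  }
  if (orientation == "samples_in_rows") values <- t(values)
  gene_ids <- strip_gene_versions(rownames(values))
  rownames(values) <- gene_ids
  values <- collapse_duplicate_genes(values)
  expr_mat(values, unit = unit)
}

#' Write an expression matrix to tab-delimited text
#'
#' Writes genes x samples, first column `gene_id`, full shortest-round-trip
#' float precision so that write-then-read is the identity on values.
#'
#' @param m An [expr_mat()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expr_mat(m)
  readr::write_tsv(tibble::as_tibble(as.data.frame(m)), path, progress = FALSE)
  invisible(path)
}

#' Strip Ensembl-style version suffixes from gene identifiers
#'
#' Removes a trailing `".<integer>"` from each identifier, preserving order.
#' Identifiers without a version suffix are returned unchanged.
#'
#' @param ids Character vector.
#' @return Character vector of the same length.
#' @export
#'
#' @examples
#' strip_gene_versions(c("ENSG00000123456.7", "GENE_A"))
strip_gene_versions <- function(ids) {
  sub("\\.[0-9]+$", "", as.character(ids))
}

# Resolve duplicate gene rows (e.g. created by version stripping) by keeping
# the row with the highest mean; deterministic and warns.
collapse_duplicate_genes <- function(values) {
  ids <- rownames(values)
  if (!anyDuplicated(ids)) return(values)
  dup <- unique(ids[duplicated(ids)])
  warn(sprintf("%d duplicate gene ID(s) after version stripping (%s%s); keeping the row with the highest mean.",
               length(dup), paste(head(dup, 3L), collapse = ", "),
               if (length(dup) > 3L) ", ..." else ""))
  means <- rowMeans(values)
  ord <- order(ids, -means)
  keep <- ord[!duplicated(ids[ord])]
  values[sort(keep), , drop = FALSE]
}

#' Restrict two expression matrices to their shared genes
#'
#' Both outputs contain exactly the intersection of the two gene sets, in the
#' same order (the order of appearance in `a`). Sample sets are unchanged.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param a,b [expr_mat()] objects.
#' @return A list with elements `a` and `b`.
#' @export
harmonize_genes <- function(a, b) {
  validate_expr_mat(a); validate_expr_mat(b)
  shared <- intersect(em_genes(a), em_genes(b))
  if (length(shared) == 0L) abort("No shared genes between the two matrices.")
  list(
    a = rewrap(em_values(a)[shared, , drop = FALSE], a),
    b = rewrap(em_values(b)[shared, , drop = FALSE], b)
  )
}

metadata_required_cols <- c("sample_id", "subject_id", "age", "sex")
metadata_leuko_cols <- c("pct_neut", "pct_lymph", "pct_mono", "pct_eos")

#' Read and validate a sample metadata table
#'
#' Tab-delimited with required columns `sample_id`, `subject_id`, `age`, `sex`
#' and optional `batch`, `disease_status`, `fev1_fvc` and four leukocyte
#' percentages (`pct_neut`, `pct_lymph`, `pct_mono`, `pct_eos`).
#'
#' @param path Path to a tab-delimited metadata file.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, comment = "#", progress = FALSE,
                          show_col_types = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta A data frame of per-sample metadata.
#' @export
validate_sample_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  missing_cols <- setdiff(metadata_required_cols, names(meta))
  if (length(missing_cols)) {
    abort(sprintf("Metadata is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("Metadata sample_id values must be unique.")
  }
  if (!all(meta$sex %in% c("male", "female", NA))) {
    abort("Metadata sex must be 'male' or 'female'.")
  }
  if ("fev1_fvc" %in% names(meta)) {
    r <- meta$fev1_fvc
    if (any(!is.na(r) & (r <= 0 | r > 2))) {
      abort("fev1_fvc values must lie in (0, 2].")
    }
  }
  present <- intersect(metadata_leuko_cols, names(meta))
  if (length(present) > 0L && length(present) < length(metadata_leuko_cols)) {
    abort("Leukocyte percentages must be provided together (all four columns).")
  }
  if (length(present) == 4L) {
    pcts <- as.matrix(meta[, metadata_leuko_cols])
    partial <- rowSums(is.na(pcts)) %in% 1:3
    if (any(partial)) {
      abort("Leukocyte percentages must be present together within each sample.")
    }
    if (any(pcts < 0 | pcts > 100, na.rm = TRUE)) {
      abort("Leukocyte percentages must lie in [0, 100].")
    }
  }
  meta
}
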