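#' Expression matrix container
#'
#' An `expr_mat` is a tibble with a `gene_id` character column followed by one
#' numeric column per sample, carrying a `unit` attribute that records what the
#' values are (`"counts"`, `"cpm"`, `"log2cpm"`, `"normalized"` or
#' `"imputed"`). Genes are rows, samples are columns, so the on-disk
#' tab-delimited exchange format and the in-memory object have the same shape.
#'
#' @param x A numeric matrix (genes x samples) or a data frame whose first
#'   column holds gene identifiers.
#' @param gene_ids Character vector of gene identifiers (used when `x` is a
#'   matrix without rownames).
#' @param sample_ids Character vector of sample identifiers (used when `x` is a
#'   matrix without colnames).
#' @param unit One of `"counts"`, `"cpm"`, `"log2cpm"`, `"normalized"`,
#'   `"imputed"`.
#'
#' @return A tibble of class `expr_mat`.
#' @export
#'
#' @examples
#' m <- expr_mat(matrix(1:6, nrow = 3,
#'                      dimnames = list(paste0("g", 1:3), c("s1", "s2"))),
#'               unit = "counts")
#' em_unit(m)
expr_mat <- function(x, gene_ids = NULL, sample_ids = NULL, unit) {
  unit <- match.arg(unit, expr_units())
  if (is.data.frame(x)) {
    gene_ids <- gene_ids %||% as.character(x[[1L]])
    values <- as.matrix(x[, -1L, drop = FALSE])
    sample_ids <- sample_ids %||% colnames(values)
  } else {
    values <- as.matrix(x)
    gene_ids <- gene_ids %||% rownames(values)
    sample_ids <- sample_ids %||% colnames(values)
  }
  if (is.null(gene_ids)) abort("`gene_ids` are required (no rownames found).")
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(ncol(values)))
  }
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("Duplicate sample IDs: %s.",
                  paste(unique(sample_ids[duplicated(sample_ids)]),
                        collapse = ", ")))
  }
  out <- tibble::tibble(gene_id = as.character(gene_ids))
  for (j in seq_along(sample_ids)) out[[sample_ids[j]]] <- values[, j]
  out <- tibble::new_tibble(out, unit = unit, class = "expr_mat")
  validate_expr_mat(out)
  out
}

expr_units <- function() c("counts", "cpm", "log2cpm", "normalized", "imputed")

validate_expr_mat <- function(m) {
  if (!"gene_id" %in% names(m) || names(m)[1L] != "gene_id") {
    abort("An expr_mat must have `gene_id` as its first column.")
  }
  unit <- em_unit(m)
  if (!unit %in% expr_units()) {
    abort(sprintf("Unknown expression unit '%s'.", unit))
  }
  gid <- m$gene_id
  if (anyDuplicated(gid)) {
    abort(sprintf("Duplicate gene IDs: %s.",
                  paste(unique(gid[duplicated(gid)])[1:5], collapse = ", ")))
  }
  sid <- em_samples(m)
  if (anyDuplicated(sid)) {
    abort(sprintf("Duplicate sample IDs: %s.",
                  paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  v <- em_values(m)
  if (anyNA(v) || any(!is.finite(v))) {
    abort("Expression values must be finite with no missing entries.")
  }
  if (unit == "counts" && any(v < 0)) {
    abort("Counts must be non-negative.")
  }
  invisible(m)
}

#' Accessors for `expr_mat` objects
#'
#' @param m An [expr_mat()].
#' @return `em_values()` the numeric genes x samples matrix with dimnames;
#'   `em_genes()` / `em_samples()` the identifier vectors; `em_unit()` the unit
#'   tag.
#' @export
em_values <- function(m) {
  v <- as.matrix(as.data.frame(m)[, -1L, drop = FALSE])
  rownames(v) <- m$gene_id
  v
}

#' @rdname em_values
#' @export
em_genes <- function(m) m$gene_id

#' @rdname em_values
#' @export
em_samples <- function(m) setdiff(names(m), "gene_id")

#' @rdname em_values
#' @export
em_unit <- function(m) attr(m, "unit")

# Rebuild an expr_mat from a values matrix, keeping ids, with a new unit.
rewrap <- function(values, template, unit = em_unit(template),
                   gene_ids = NULL, sample_ids = NULL) {
  fallback <- function(dn, tpl, n) {
    dn %||% (if (length(tpl) == n) tpl else character(n))
  }
  expr_mat(values,
           gene_ids = gene_ids %||%
             fallback(rownames(values), em_genes(template), nrow(values)),
           sample_ids = sample_ids %||%
             fallback(colnames(values), em_samples(template), ncol(values)),
           unit = unit)
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("# expr_mat: %d genes x %d samples [unit: %s]\n",
              nrow(x), length(em_samples(x)), em_unit(x)))
  NextMethod()
}

#' @export
as.matrix.expr_mat <- function(x, ...) em_values(x)
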