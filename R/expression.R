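#' Construct an expression matrix with sample phenotypes
#'
#' The basic substrate of the pipeline: a log2-scale genes x samples numeric
#' matrix plus an optional phenotype map assigning each sample to a group
#' label (typically `"KRAS_mut"` / `"KRAS_wt"`).
#'
#' @param values Numeric matrix (genes in rows, samples in columns) with
#'   unique, non-empty row and column names. Values are assumed to be on the
#'   log2 scale (e.g., RMA-normalized intensities).
#' @param phenotype Optional named character vector mapping sample ids to
#'   group labels. Every name must be a column of `values`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `phenotype`.
#' @examples
#' m <- matrix(rnorm(6, mean = 7), 3, 2,
#'             dimnames = list(c("AREG", "DUSP6", "FOSL1"), c("s1", "s2")))
#' em <- expression_matrix(m, c(s1 = "KRAS_mut", s2 = "KRAS_wt"))
#' @export
expression_matrix <- function(values, phenotype = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("`values` must have gene row names", call. = FALSE)
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("`values` must have sample column names", call. = FALSE)
  if (nrow(values) == 0 && is.null(rownames(values)))
    rownames(values) <- character(0)
  gid <- rownames(values)
  sid <- colnames(values)
  if (anyDuplicated(gid))
    stop("duplicate gene identifiers: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample identifiers: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (!is.null(phenotype)) {
    phenotype <- stats::setNames(as.character(phenotype), names(phenotype))
    if (is.null(names(phenotype)) || !all(names(phenotype) %in% sid))
      stop("every phenotype key must be a sample id of the matrix", call. = FALSE)
  }
  structure(list(values = values, phenotype = phenotype),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$phenotype)) {
    tab <- table(x$phenotype)
    cat("phenotype:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Attach (or replace) the phenotype map of an expression matrix
#'
#' @param em An `ExpressionMatrix`.
#' @param labels Either a named character vector (names are sample ids) or an
#'   unnamed vector of length `ncol` taken to be in column order.
#' @return The updated `ExpressionMatrix`.
#' @export
set_phenotype <- function(em, labels) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(names(labels))) {
    if (length(labels) != ncol(em$values))
      stop("unnamed phenotype vector must have one label per sample", call. = FALSE)
    names(labels) <- colnames(em$values)
  }
  expression_matrix(em$values, labels)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols. Symbols are
#'   uppercased (the package-wide symbol-matching convention) and de-duplicated
#'   within each set.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled `"na"` when absent).
#' @return Object of class `GeneSetCollection`: a named list of character
#'   vectors with a `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) && (is.null(names(sets)) || anyDuplicated(names(sets))))
    stop("gene-set names must be present and unique", call. = FALSE)
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  if (any(lengths(sets) == 0L))
    stop("every gene set must be non-empty", call. = FALSE)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  descriptions <- stats::setNames(rep_len(as.character(descriptions), length(sets)),
                                  names(sets))
  structure(sets, descriptions = descriptions, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d set(s)\n", length(x)))
  for (nm in utils::head(names(x), 10))
    cat(sprintf("  %s (%d genes)\n", nm, length(x[[nm]])))
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Map gene symbols across species
#'
#' Default cross-species behaviour is case-folded symbol equality (mouse
#' `Dusp6` matches human `DUSP6`); a user-supplied two-column table
#' (`from`, `to`) overrides this for symbols it covers.
#'
#' @param symbols Character vector of gene symbols.
#' @param mapping Optional data frame with columns `from` and `to`.
#' @return Uppercased (and, where covered, remapped) symbols.
#' @export
map_gene_symbols <- function(symbols, mapping = NULL) {
  out <- toupper(as.character(symbols))
  if (!is.null(mapping)) {
    if (!all(c("from", "to") %in% names(mapping)))
      stop("`mapping` must have columns `from` and `to`", call. = FALSE)
    key <- toupper(as.character(mapping$from))
    hit <- match(out, key)
    out[!is.na(hit)] <- toupper(as.character(mapping$to))[hit[!is.na(hit)]]
  }
  out
}
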