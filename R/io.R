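# Readers and writers for the plain-text formats the pipeline touches:
# expression TSV and GCT 1.2, GMT gene sets, CLS phenotype labels, clinical
# TSV tables. All symbols are uppercased on ingest.

collapse_duplicate_genes <- function(values) {
  gid <- rownames(values)
  if (!anyDuplicated(gid)) return(values)
  dup <- unique(gid[duplicated(gid)])
  warning(sprintf("collapsing %d duplicate gene id(s) by maximum mean expression: %s",
                  length(dup), paste(utils::head(dup, 5), collapse = ", ")),
          call. = FALSE)
  means <- rowMeans(values)
  keep <- !logical(nrow(values))
  for (g in dup) {
    idx <- which(gid == g)
    keep[idx] <- FALSE
    keep[idx[which.max(means[idx])]] <- TRUE
  }
  values[keep, , drop = FALSE]
}

parse_numeric_cells <- function(raw, path) {
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                                 dimnames = dimnames(raw)))
  bad <- which(is.na(num) & !is.na(raw) & raw != "", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s: non-numeric value '%s' at data row %d, column '%s'",
                 path, raw[bad[1, 1], bad[1, 2]], bad[1, 1],
                 colnames(raw)[bad[1, 2]]), call. = FALSE)
  }
  num
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' TSV layout: gene ids in the first column, sample ids in the header. GCT
#' must be dialect 1.2 (`#1.2` header, dimensions line, `Name`/`Description`
#' columns). Duplicate gene rows are collapsed keeping the row with the
#' largest mean expression (the usual probe-collapse convention), with a
#' warning.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`; default guesses from the file extension.
#' @return An [expression_matrix()] (phenotype unset; see [read_cls()] /
#'   [set_phenotype()]).
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3 || trimws(lines[1]) != "#1.2")
      stop(sprintf("%s: line 1 must be '#1.2' for GCT format", path), call. = FALSE)
    dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\t")[[1]]))
    if (length(dims) < 2 || any(is.na(dims[1:2])))
      stop(sprintf("%s: line 2 must carry '<ngenes>\t<nsamples>'", path), call. = FALSE)
    tab <- utils::read.delim(text = lines[-(1:2)], header = TRUE,
                             check.names = FALSE, colClasses = "character")
    if (!identical(toupper(names(tab)[1:2]), c("NAME", "DESCRIPTION")))
      stop(sprintf("%s: line 3 must start with 'Name\tDescription'", path), call. = FALSE)
    if (nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2])
      stop(sprintf("%s: dims line declares %d x %d but file has %d x %d",
                   path, dims[1], dims[2], nrow(tab), ncol(tab) - 2L), call. = FALSE)
    raw <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(raw) <- toupper(tab[[1]])
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 2)
      stop(sprintf("%s: TSV needs a gene-id column plus >=1 sample column", path),
           call. = FALSE)
    raw <- as.matrix(tab[, -1, drop = FALSE])
    rownames(raw) <- toupper(tab[[1]])
  }
  values <- parse_numeric_cells(raw, path)
  values <- collapse_duplicate_genes(values)
  expression_matrix(values)
}

#' Write an expression matrix to TSV or GCT 1.2 at full precision
#'
#' Values are written with 17 significant digits so a write/read round trip
#' is bit-identical.
#'
#' @param em An `ExpressionMatrix`.
#' @param path Output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(em, path, format = c("tsv", "gct")) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  format <- match.arg(format)
  chr <- matrix(formatC(em$values, digits = 17, format = "g"),
                nrow = nrow(em$values))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "gct") {
    writeLines(c("#1.2", paste(nrow(em$values), ncol(em$values), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(em$values)), collapse = "\t"), con)
    body <- cbind(rownames(em$values), "na", chr)
  } else {
    writeLines(paste(c("gene_id", colnames(em$values)), collapse = "\t"), con)
    body <- cbind(rownames(em$values), chr)
  }
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: `name TAB description TAB gene1 TAB gene2 ...`. Genes are
#' uppercased; duplicates within a line are dropped with a warning.
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_set_collection(list()))
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3)
      stop(sprintf("%s: line %d has %d field(s); GMT needs name, description and >=1 gene",
                   path, i, length(fields)), call. = FALSE)
    genes <- toupper(fields[-(1:2)])
    if (anyDuplicated(genes))
      warning(sprintf("%s: line %d ('%s') contains duplicate genes; de-duplicated",
                      path, i, fields[1]), call. = FALSE)
    sets[[fields[1]]] <- unique(genes)
    descs <- c(descs, fields[2])
  }
  gene_set_collection(sets, descs)
}

#' Write a gene-set collection to GMT
#' @param gsc A `GeneSetCollection`.
#' @param path Output path.
#' @export
write_gene_sets <- function(gsc, path) {
  stopifnot(inherits(gsc, "GeneSetCollection"))
  descs <- attr(gsc, "descriptions")
  lines <- vapply(names(gsc), function(nm)
    paste(c(nm, descs[[nm]], gsc[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CLS phenotype file
#'
#' Categorical CLS: line 1 `<n> <k> 1`, line 2 `# label1 label2 ...`, line 3
#' one entry per sample (either the class names or 0-based indices into the
#' line-2 labels).
#'
#' @param path File path.
#' @return Character vector of per-sample labels (unnamed, in file order).
#' @export
read_cls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3)
    stop(sprintf("%s: CLS needs 3 lines", path), call. = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  labels <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (labels[1] != "#")
    stop(sprintf("%s: CLS line 2 must start with '#'", path), call. = FALSE)
  labels <- labels[-1]
  entries <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(entries) != hdr[1])
    stop(sprintf("%s: CLS declares %d samples but line 3 has %d entries",
                 path, hdr[1], length(entries)), call. = FALSE)
  if (all(entries %in% as.character(seq_along(labels) - 1L)))
    entries <- labels[as.integer(entries) + 1L]
  entries
}

#' Read a clinical table
#'
#' TSV with required columns `sample_id`, `time`, `event` and optional
#' `age`, `sex`, `stage`, `status`, `score`. Times must be positive and
#' events in {0,1}.
#'
#' @param path File path.
#' @return A [survival_table()].
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  survival_table(tab)
}
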