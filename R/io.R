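# Structural checks shared by every consumer of a spot table.
validate_spot_table <- function(spots) {
  if (!is.data.frame(spots) || !all(c("spot_id", "x", "y") %in% names(spots)))
    stop_coloc("data_error", "spot table needs columns spot_id, x, y")
  if (nrow(spots) < 2)
    stop_coloc("data_error", "need at least 2 spots")
  if (anyDuplicated(spots$spot_id))
    stop_coloc("data_error", "spot_id values must be unique")
  if (any(!is.finite(spots$x)) || any(!is.finite(spots$y)))
    stop_coloc("data_error", "spot coordinates must be finite")
  invisible(spots)
}

validate_composition <- function(comp, spots = NULL, tol = 1e-6) {
  if (!is.matrix(comp) || is.null(rownames(comp)) || is.null(colnames(comp)))
    stop_coloc("data_error", "composition must be a matrix with spot and cell-type names")
  if (any(comp < -tol) || any(comp > 1 + tol))
    stop_coloc("data_error", "composition entries must lie in [0, 1]")
  if (any(abs(rowSums(comp) - 1) > tol))
    stop_coloc("data_error", "composition rows must sum to 1")
  if (!is.null(spots) && !setequal(rownames(comp), spots$spot_id))
    stop_coloc("data_error", "composition rows must match the spot table's spot ids")
  invisible(comp)
}

#' Read / write spot tables
#'
#' CSV with header `spot_id,x,y[,sample]`.
#'
#' @param path File path.
#' @return `read_spot_table()`: a validated spot table data.frame.
#' @export
read_spot_table <- function(path) {
  validate_spot_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_spot_table
#' @param spots Spot table to write.
#' @export
write_spot_table <- function(spots, path) {
  write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write composition matrices
#'
#' Wide CSV: `spot_id` first column, one column per cell type.
#'
#' @param path File path.
#' @return `read_composition()`: spots x cell types matrix of proportions.
#' @export
read_composition <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  validate_composition(m)
}

#' @rdname read_composition
#' @param comp Composition matrix to write.
#' @export
write_composition <- function(comp, path) {
  df <- data.frame(spot_id = rownames(comp), comp, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' Reading delegates to [fgsea::gmtPathways()]; writing emits the standard
#' tab-separated `name<TAB>description<TAB>gene...` lines.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of [signature_set()] objects.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(stats::setNames(names(sets), names(sets)),
         function(nm) signature_set(nm, unique(sets[[nm]])))
}

#' @rdname read_gmt
#' @param sets List of [signature_set()] objects (or character vectors).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    nm <- if (inherits(s, "signature_set")) s$name else names(sets)[i]
    genes <- if (inherits(s, "signature_set")) s$genes else s
    paste(c(nm, "na", genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with columns `gene`, `log2FC`, `pval`.
#'
#' @param path File path.
#' @return data.frame ready for [derive_signature()].
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "log2FC", "pval")
  if (!all(req %in% names(df)))
    stop_coloc("data_error", "DE table needs columns gene, log2FC, pval")
  df
}

#' Read / write expression matrices
#'
#' CSV (genes in rows, first column = gene id) or MatrixMarket triplet with
#' sidecar `<stem>.rownames.txt` / `<stem>.colnames.txt` files.
#'
#' @param path `.csv` or `.mtx` file path.
#' @return `read_expression()`: dense genes x samples matrix.
#' @export
read_expression <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".rownames.txt"))
    colnames(m) <- readLines(paste0(stem, ".colnames.txt"))
    m
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
}

#' @rdname read_expression
#' @param expr Matrix to write (CSV only).
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write signature scores as a two-column CSV
#'
#' @param scores A `score_vector`.
#' @param path File path.
#' @export
write_scores <- function(scores, path) {
  write.csv(data.frame(sample_id = names(scores), score = as.numeric(scores)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an enrichment curve as TSV
#'
#' Columns: `k`, `E`, `delta`, `stable`, `selected`.
#'
#' @param curve An `enrichment_curve` after [select_k()].
#' @param path File path.
#' @export
write_enrichment_curve <- function(curve, path) {
  stable <- if (isTRUE(curve$fallback)) rep(FALSE, length(curve$k_grid))
            else curve$k_grid >= curve$stable_start & curve$k_grid <= curve$stable_end
  df <- data.frame(k = curve$k_grid, E = curve$E,
                   delta = c(NA, curve$delta),
                   stable = stable,
                   selected = curve$k_grid == curve$k_star)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Strip the bulky null vector before serializing a permutation test.
as_record <- function(x) {
  if (inherits(x, "permutation_test")) {
    x$null_means <- NULL
    x$seed <- x$seed %||% NA
  }
  if (inherits(x, "moran_result")) x$seed <- x$seed %||% NA
  unclass(x)
}

#' Write a test result as a JSON record
#'
#' Serializes a `permutation_test` or `moran_result` (fields as documented,
#' plus seed and n_perm; the raw null means go to their own CSV in pipeline
#' runs).
#'
#' @param x Result object.
#' @param path File path.
#' @export
write_json_result <- function(x, path) {
  jsonlite::write_json(as_record(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
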