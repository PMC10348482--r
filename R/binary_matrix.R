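#' Binary genome-by-function matrices
#'
#' A `binary_matrix` is an integer matrix with entries in \{0, 1\}, rows
#' labelled by unique genome identifiers and columns by unique function
#' (pathway) identifiers. Rows are genomes and columns are functions; this
#' orientation is fixed throughout the package. A typical input is a
#' KEGG-Decoder style presence/absence table for a collection of MAGs, SAGs
#' and isolate genomes.
#'
#' All-zero rows and columns are retained (they still inform the per-aspect
#' presence probabilities) but trigger a warning so that upstream filtering
#' mistakes are visible.
#'
#' @param values numeric, integer or logical matrix with entries in \{0, 1\}.
#' @param genome_ids character vector of unique row labels. Defaults to the
#'   rownames of `values`, or `g1 ... gG` when absent.
#' @param function_ids character vector of unique column labels. Defaults to
#'   the colnames of `values`, or `f1 ... fF` when absent.
#'
#' @return An integer matrix of class `binary_matrix` with the given dimnames.
#' @examples
#' m <- binary_matrix(rbind(c(1, 0), c(1, 1)),
#'                    genome_ids = c("gA", "gB"),
#'                    function_ids = c("nifH", "dmdA"))
#' genome_ids(m)
#' @export
binary_matrix <- function(values, genome_ids = NULL, function_ids = NULL) {
  if (!is.matrix(values))
    stop("'values' must be a matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("a binary matrix needs at least one genome and one function",
         call. = FALSE)
  if (is.null(genome_ids))
    genome_ids <- rownames(values) %||% paste0("g", seq_len(nrow(values)))
  if (is.null(function_ids))
    function_ids <- colnames(values) %||% paste0("f", seq_len(ncol(values)))
  if (is.logical(values)) storage.mode(values) <- "integer"
  x <- values
  dimnames(x) <- list(as.character(genome_ids), as.character(function_ids))
  validate_binary_matrix(x)
  storage.mode(x) <- "integer"
  class(x) <- c("binary_matrix", class(matrix()))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_binary_matrix <- function(x) {
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("a binary matrix needs at least one genome and one function",
         call. = FALSE)
  bad <- which(!(x == 0 | x == 1) | is.na(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    g <- rownames(x)[bad[1L, 1L]]
    f <- colnames(x)[bad[1L, 2L]]
    stop(sprintf(
      "non-binary value %s at genome '%s', function '%s'",
      format(x[bad[1L, 1L], bad[1L, 2L]]), g, f), call. = FALSE)
  }
  if (anyDuplicated(rownames(x)))
    stop("duplicate genome IDs: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate function IDs: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  nz_r <- sum(rowSums(x) == 0)
  nz_c <- sum(colSums(x) == 0)
  if (nz_r > 0)
    warning(nz_r, " genome(s) carry no function; retained", call. = FALSE)
  if (nz_c > 0)
    warning(nz_c, " function(s) occur in no genome; retained", call. = FALSE)
  invisible(x)
}

#' Coerce to a binary matrix
#'
#' @param x a matrix-like object with 0/1 (or logical) entries.
#' @param ... unused.
#' @return a `binary_matrix`.
#' @export
as_binary_matrix <- function(x, ...) {
  if (inherits(x, "binary_matrix")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  suppressWarnings(binary_matrix(x))
}

#' @rdname binary_matrix
#' @param x a `binary_matrix`.
#' @export
genome_ids <- function(x) rownames(x)

#' @rdname binary_matrix
#' @export
function_ids <- function(x) colnames(x)

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("binary_matrix: %d genomes x %d functions, density %.3f\n",
              nrow(x), ncol(x), mean(x)))
  G <- min(nrow(x), 6L); F <- min(ncol(x), 8L)
  y <- unclass(x)[seq_len(G), seq_len(F), drop = FALSE]
  print(y)
  if (nrow(x) > G || ncol(x) > F)
    cat(sprintf("... (%d more genomes, %d more functions)\n",
                nrow(x) - G, ncol(x) - F))
  invisible(x)
}

#' Read a genome-by-function presence/absence matrix
#'
#' Reads a delimited table in the layout produced by KEGG-Decoder style
#' annotation summaries: a header row of function names, a first column of
#' genome identifiers, and 0/1 cells. Accepted cell spellings are `0`, `1`,
#' `0.0`, `1.0` and `TRUE`/`FALSE` (case-insensitive). Continuous pathway
#' completeness fractions are refused unless `binarize_threshold` is given;
#' silent re-thresholding would change downstream guilds, so the cut must be
#' explicit.
#'
#' @param path path to a TSV or CSV file.
#' @param dialect `"tsv"` or `"csv"`; by default guessed from the file
#'   extension (`.csv` means comma, anything else tab).
#' @param transpose if `TRUE` the file holds functions as rows and genomes as
#'   columns and is transposed after reading. Orientation is never guessed.
#' @param binarize_threshold optional numeric `t`; continuous cells are mapped
#'   to `1` when `value >= t` and `0` otherwise. Default `NULL` refuses
#'   non-binary cells.
#' @return a [binary_matrix] preserving the file's row and column order.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, dialect = NULL, transpose = FALSE,
                        binarize_threshold = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  sep <- dialect_sep(dialect %||%
                       if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
                       else "tsv")
  nf <- count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) != 1L)
    stop("ragged rows: lines have between ", min(nf), " and ", max(nf),
         " fields", call. = FALSE)
  raw <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", comment.char = "",
                    quote = "\"", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expected a genome-ID column plus at least one function column",
         call. = FALSE)
  ids <- raw[[1L]]
  fun <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(fun),
                 dimnames = list(ids, fun))
  for (j in seq_along(fun))
    vals[, j] <- parse_binary_cells(raw[[j + 1L]], ids, fun[j],
                                    binarize_threshold)
  if (transpose) vals <- t(vals)
  binary_matrix(vals)
}

dialect_sep <- function(dialect) {
  switch(match.arg(dialect, c("tsv", "csv")), tsv = "\t", csv = ",")
}

parse_binary_cells <- function(x, genome_ids, function_id, threshold) {
  out <- rep(NA_real_, length(x))
  low <- tolower(trimws(x))
  out[low %in% c("true", "t")] <- 1
  out[low %in% c("false", "f")] <- 0
  num <- suppressWarnings(as.numeric(low[is.na(out)]))
  out[is.na(out)] <- num
  bad <- which(is.na(out))
  if (length(bad) > 0L)
    stop(sprintf("unparseable cell '%s' at genome '%s', function '%s'",
                 x[bad[1L]], genome_ids[bad[1L]], function_id), call. = FALSE)
  cont <- which(!(out %in% c(0, 1)))
  if (length(cont) > 0L) {
    if (is.null(threshold))
      stop(sprintf(
        paste0("non-binary value %s at genome '%s', function '%s'; ",
               "pass binarize_threshold to binarize continuous input"),
        format(out[cont[1L]]), genome_ids[cont[1L]], function_id),
        call. = FALSE)
    out <- as.numeric(out >= threshold)
  } else if (!is.null(threshold)) {
    out <- as.numeric(out >= threshold)
  }
  out
}

#' Write a binary matrix
#'
#' Emits the same delimited layout [read_matrix()] accepts (header of function
#' names, first column `genome_id`), so that a write/read round trip is the
#' identity on values and labels.
#'
#' @param matrix a [binary_matrix].
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, dialect = "tsv") {
  m <- as_binary_matrix(matrix)
  sep <- dialect_sep(dialect)
  df <- data.frame(genome_id = rownames(m), unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("could not write '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}
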