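#' Read an embedding table
#'
#' Reads a long-format delimited table with one exemplar per row into an
#' [embedding_system()]. The header must declare `word`, `exemplar_id` and
#' `dim_0` ... `dim_{d-1}` columns. Word order follows first appearance in the
#' file. Tab-separated by default; `.csv` files are read comma-separated.
#'
#' @param path Path to the table.
#' @param modality `"linguistic"` or `"visual"`.
#' @param sep Field separator; defaults to tab, or comma for `.csv` paths.
#' @return An `embedding_system`.
#' @export
read_embedding_table <- function(path, modality = c("linguistic", "visual"),
                                 sep = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("embedding table not found: ", path)
  if (is.null(sep)) {
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  }
  nf <- utils::count.fields(path, sep = sep, quote = "")
  if (length(nf) == 0) stop("empty embedding table: ", path)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row in ", path, ": line ", bad, " has ", nf[bad],
         " fields but the header has ", nf[1])
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("embedding table has a header but no rows: ", path)
  dim_cols <- grep("^dim_[0-9]+$", names(tab), value = TRUE)
  missing <- setdiff(c("word", "exemplar_id"), names(tab))
  if (length(missing) || length(dim_cols) == 0) {
    stop("embedding table must have columns word, exemplar_id, dim_0...; ",
         "missing: ", paste(c(missing, if (!length(dim_cols)) "dim_*"),
                            collapse = ", "))
  }
  dim_cols <- dim_cols[order(as.integer(sub("^dim_", "", dim_cols)))]
  mat <- as.matrix(tab[, dim_cols, drop = FALSE])
  if (!is.numeric(mat) || !all(is.finite(mat))) {
    bad <- which(!is.finite(suppressWarnings(matrix(as.numeric(mat),
                                                    nrow(mat)))))[1]
    stop("non-finite or non-numeric embedding value at data row ",
         (bad - 1L) %% nrow(mat) + 1L, " of ", path)
  }
  words <- unique(tab$word)
  exemplars <- lapply(words, function(w) {
    unname(mat[tab$word == w, , drop = FALSE])
  })
  embedding_system(words, exemplars, modality = modality)
}

#' Write an embedding table
#'
#' Inverse of [read_embedding_table()]: writes one exemplar per row at full
#' precision (17 significant digits), so a read of the written file reproduces
#' the system exactly.
#'
#' @param system An `embedding_system`.
#' @param path Output path; `.csv` writes comma-separated, otherwise TSV.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(system, path) {
  stopifnot(inherits(system, "embedding_system"))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  mat <- do.call(rbind, system$exemplars)
  counts <- exemplar_counts(system)
  tab <- data.frame(
    word = rep(system$words, counts),
    exemplar_id = unlist(lapply(counts, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  vals <- apply(mat, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(mat))
  colnames(vals) <- paste0("dim_", seq_len(system$d) - 1L)
  out <- cbind(tab, as.data.frame(vals, stringsAsFactors = FALSE))
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write embedding table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
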