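#' Read a knowledge map from an NxN relationship-matrix CSV
#'
#' The dialect: the first row and first column carry concept labels (the
#' top-left corner cell is ignored); cell in row i, column j holds the weight
#' of the edge row-concept -> column-concept. Cells equal to 0, empty, or
#' whitespace produce no edge; the token `I` (case-insensitive, trimmed)
#' produces an indeterminate edge; anything else must parse as a number in
#' `[-1, 1]`. Labels containing commas or quotes use RFC-4180 quoting. Lines
#' starting with `#` are comments. Row labels must repeat the column header
#' in the same order.
#'
#' @param path path to a CSV file.
#' @return a [knowledge_map].
#' @seealso [save_map()]
#' @export
load_map <- function(path) {
  if (!file.exists(path)) {
    stop_ncm("io_error", "map file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  # a file holding only the empty header corner encodes the 0-node map
  if (!length(lines) || (length(lines) == 1L && !nzchar(trimws(lines[1L])))) {
    return(knowledge_map(character(0)))
  }
  txt <- paste(lines, collapse = "\n")
  nf <- utils::count.fields(textConnection(txt), sep = ",", quote = "\"",
                            blank.lines.skip = FALSE)
  if (length(unique(nf)) != 1L) {
    stop_ncm("format_error", sprintf(
      "ragged CSV: header has %d columns but some row has %d",
      nf[1L], nf[which(nf != nf[1L])[1L]]))
  }
  cells <- utils::read.csv(text = txt, header = FALSE,
                           colClasses = "character", check.names = FALSE)
  mat <- as.matrix(cells)
  n_body_rows <- nrow(mat) - 1L
  n_body_cols <- ncol(mat) - 1L
  if (n_body_rows != n_body_cols) {
    stop_ncm("format_error", sprintf(
      "matrix body is not square: %d rows x %d columns",
      n_body_rows, n_body_cols))
  }
  col_labels <- trimws(mat[1L, -1L])
  row_labels <- trimws(mat[-1L, 1L])
  if (!identical(unname(row_labels), unname(col_labels))) {
    stop_ncm("format_error",
             "row labels do not match column labels in order")
  }
  dup <- col_labels[duplicated(col_labels)]
  if (length(dup)) {
    stop_ncm("format_error", "duplicate concept label: ",
             paste(unique(dup), collapse = ", "))
  }
  body <- trimws(mat[-1L, -1L, drop = FALSE])
  tok <- as.vector(body)                       # column-major: index = i + (j-1)*n
  n <- length(col_labels)
  is_blank <- !nzchar(tok)
  is_ind <- toupper(tok) == "I"
  num <- suppressWarnings(as.numeric(tok))
  bad <- which(!is_blank & !is_ind & is.na(num))
  if (length(bad)) {
    b <- bad[1L]
    stop_ncm("format_error", sprintf(
      "unparseable cell at row '%s', column '%s': '%s'",
      row_labels[(b - 1L) %% n + 1L], col_labels[(b - 1L) %/% n + 1L],
      tok[b]))
  }
  out_of_range <- which(!is_blank & !is_ind & abs(num) > 1)
  if (length(out_of_range)) {
    b <- out_of_range[1L]
    stop_ncm("format_error", sprintf(
      "weight outside [-1, 1] at row '%s', column '%s': '%s'",
      row_labels[(b - 1L) %% n + 1L], col_labels[(b - 1L) %/% n + 1L],
      tok[b]))
  }
  keep <- is_ind | (!is_blank & num != 0)
  idx <- which(keep)
  edges <- data.frame(
    from = (idx - 1L) %% n + 1L,
    to = (idx - 1L) %/% n + 1L,
    weight = ifelse(is_ind[idx], NA_real_, num[idx])
  )
  knowledge_map(col_labels, edges)
}

#' Write a knowledge map to the NxN relationship-matrix CSV dialect
#'
#' Emits exactly the dialect [load_map()] reads: absent edges as `0`,
#' indeterminate edges as `I`, numeric weights at full (17 significant digit)
#' precision so that a save/load round trip reproduces the map bit-for-bit.
#'
#' @param map a [knowledge_map].
#' @param path output file path.
#' @param comment optional character vector written as leading `#` comment
#'   lines (used by fixtures to declare themselves synthetic).
#' @return `path`, invisibly.
#' @export
save_map <- function(map, path, comment = NULL) {
  validate_knowledge_map(map)
  n <- n_nodes(map)
  body <- matrix("0", n, n)
  e <- map$edges
  if (nrow(e)) {
    body[cbind(e$from, e$to)] <- ifelse(
      is.na(e$weight), "I", sprintf("%.17g", e$weight))
  }
  q <- csv_quote(map$labels)
  rows <- c(paste(c("", q), collapse = ","),
            if (n > 0) paste(q, apply(body, 1L, paste, collapse = ","),
                             sep = ","))
  out <- c(if (!is.null(comment)) paste0("# ", comment), rows)
  ok <- tryCatch({
    writeLines(out, path)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop_ncm("io_error", "cannot write ", path, ": ",
                            conditionMessage(ok))
  invisible(path)
}

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x) | grepl("^\\s|\\s$", x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}
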