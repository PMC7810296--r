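#' Morphological character matrix
#'
#' A `character_matrix` is a taxa-by-characters table of single-character
#' state tokens. Valid tokens are the digits `0`-`9` (observed states), `?`
#' (unknown) and `-` (inapplicable). Both missing codes are scored as full
#' ambiguity by the parsimony functions; they differ only in reporting.
#'
#' @param cells character matrix of state tokens with taxon labels as row
#'   names. Column names are optional and ignored.
#' @return an object of class `character_matrix`: a list with elements
#'   `taxa` (character vector), `n_char` (integer) and `cells` (character
#'   matrix, rows named by taxon).
#' @examples
#' m <- character_matrix(rbind(A = c("0", "1", "0"), B = c("0", "?", "-")))
#' m$n_char
#' @export
character_matrix <- function(cells) {
  if (!is.matrix(cells) || !is.character(cells)) {
    stop("`cells` must be a character matrix of state tokens", call. = FALSE)
  }
  taxa <- rownames(cells)
  if (is.null(taxa) || any(!nzchar(taxa))) {
    stop("every taxon label must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  }
  ok <- cells %in% c(as.character(0:9), "?", "-")
  dim(ok) <- dim(cells)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown state symbol '%s' at taxon '%s', character %d",
                 cells[bad[1L], bad[2L]], taxa[bad[1L]], bad[2L]),
         call. = FALSE)
  }
  observed <- cells %in% as.character(0:9)
  dim(observed) <- dim(cells)
  empty <- which(colSums(observed) == 0L)
  if (length(empty)) {
    stop("character ", empty[1L], " has no observed state in any taxon",
         call. = FALSE)
  }
  dimnames(cells) <- list(taxa, NULL)
  structure(list(taxa = taxa, n_char = ncol(cells), cells = cells),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character matrix: %d taxa x %d characters\n",
              length(x$taxa), x$n_char))
  shown <- utils::head(x$taxa, 6L)
  for (t in shown) {
    cat(sprintf("  %-24s %s\n", t,
                paste(utils::head(x$cells[t, ], 40L), collapse = "")))
  }
  if (length(x$taxa) > 6L) cat(sprintf("  ... and %d more taxa\n",
                                       length(x$taxa) - 6L))
  invisible(x)
}

# Spaces become underscores so matrices, trees, records and trait tables join
# on identical labels.
normalize_taxon <- function(x) gsub(" +", "_", trimws(x))

.matrix_from_rows <- function(taxa, rows, source) {
  taxa <- normalize_taxon(taxa)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    ref <- lens[1L]   # first row sets the expected width
    k <- which(lens != ref)[1L]
    stop(sprintf("ragged row in %s: taxon '%s' has %d tokens, expected %d",
                 source, taxa[k], lens[k], ref), call. = FALSE)
  }
  cells <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(cells) <- taxa
  character_matrix(cells)
}

#' Read a character matrix
#'
#' Supported dialects: `tsv` (rows of `taxon<TAB>tokens`, `#` comments
#' skipped), a minimal TNT `xread` subset, and the CHARACTERS/MATRIX block of
#' a NEXUS file. Taxon names are normalized (spaces to underscores) at read
#' time.
#'
#' @param path file to read.
#' @param dialect one of `"tsv"`, `"tnt"`, `"nexus"`.
#' @return a [character_matrix()].
#' @export
read_matrix <- function(path, dialect = c("tsv", "tnt", "nexus")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  switch(dialect,
         tsv = .read_matrix_tsv(lines, path),
         tnt = .read_matrix_tnt(lines, path),
         nexus = .read_matrix_nexus(lines, path))
}

.read_matrix_tsv <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty matrix file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  taxa <- vapply(parts, `[[`, "", 1L)
  rows <- vapply(parts, function(p) {
    if (length(p) < 2L) return("")
    toks <- p[-1L]
    # either one token string per row, or one column per character
    if (length(toks) == 1L) toks else paste(toks, collapse = "")
  }, "")
  if (any(!nzchar(rows))) {
    stop("row for taxon '", taxa[!nzchar(rows)][1L], "' carries no states",
         call. = FALSE)
  }
  .matrix_from_rows(taxa, rows, path)
}

.read_matrix_tnt <- function(lines, path) {
  txt <- paste(lines, collapse = "\n")
  m <- regmatches(txt, regexpr("xread.*?;", txt, ignore.case = TRUE))
  if (!length(m)) stop("no xread block found in ", path, call. = FALSE)
  body <- sub("^xread", "", m, ignore.case = TRUE)
  body <- sub("^\\s*'[^']*'", "", body)  # optional quoted title
  toks <- scan(text = sub(";\\s*$", "", body), what = "", quiet = TRUE)
  if (length(toks) < 2L) stop("malformed xread header in ", path, call. = FALSE)
  n_char <- suppressWarnings(as.integer(toks[1L]))
  n_tax <- suppressWarnings(as.integer(toks[2L]))
  if (is.na(n_char) || is.na(n_tax)) {
    stop("xread header must be '<nchar> <ntax>' in ", path, call. = FALSE)
  }
  rest <- toks[-(1:2)]
  if (length(rest) != 2L * n_tax) {
    stop(sprintf("xread block in %s has %d fields, expected %d (taxon/row pairs)",
                 path, length(rest), 2L * n_tax), call. = FALSE)
  }
  taxa <- rest[seq(1L, by = 2L, length.out = n_tax)]
  rows <- rest[seq(2L, by = 2L, length.out = n_tax)]
  x <- .matrix_from_rows(taxa, rows, path)
  if (x$n_char != n_char) {
    stop(sprintf("xread declares %d characters but rows carry %d",
                 n_char, x$n_char), call. = FALSE)
  }
  x
}

.read_matrix_nexus <- function(lines, path) {
  txt <- paste(lines, collapse = "\n")
  m <- regmatches(txt, regexpr("MATRIX(.|\n)*?;", txt, ignore.case = TRUE))
  if (!length(m)) stop("no MATRIX block found in ", path, call. = FALSE)
  body <- sub("^MATRIX", "", m, ignore.case = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- strsplit(body, "\n")[[1L]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows) & !startsWith(rows, "[")]
  parts <- regmatches(rows, regexpr("^\\S+", rows))
  states <- trimws(sub("^\\S+", "", rows))
  states <- gsub("[[:space:]]", "", states)
  keep <- nzchar(states)
  .matrix_from_rows(parts[keep], states[keep], path)
}

#' Write a character matrix
#'
#' @param x a [character_matrix()].
#' @param path output file.
#' @param dialect `"tsv"` or `"tnt"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, dialect = c("tsv", "tnt")) {
  stopifnot(inherits(x, "character_matrix"))
  dialect <- match.arg(dialect)
  rows <- apply(x$cells, 1L, paste, collapse = "")
  out <- switch(dialect,
                tsv = paste0(x$taxa, "\t", rows),
                tnt = c("xread", paste(x$n_char, length(x$taxa)),
                        paste(x$taxa, rows), ";"))
  writeLines(out, path)
  invisible(path)
}

#' Restrict a matrix to a subset of taxa
#'
#' @param x a [character_matrix()].
#' @param taxa taxon labels to keep.
#' @return a [character_matrix()] over `taxa`, in the given order.
#' @export
subset_matrix <- function(x, taxa) {
  stopifnot(inherits(x, "character_matrix"))
  taxa <- normalize_taxon(taxa)
  missing <- setdiff(taxa, x$taxa)
  if (length(missing)) {
    stop("taxa absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  character_matrix(x$cells[taxa, , drop = FALSE])
}
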