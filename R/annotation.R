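#' Parse a tab-delimited annotation file
#'
#' The annotation format is deliberately minimal: tab-separated fields,
#' gene symbol in the first column, any number of further annotation
#' columns. If the first line starts with `#` it is the column header
#' (the `#` is stripped); otherwise columns are auto-named
#' `col1..colK` from the first line's field count and that line is
#' data. Blank lines are skipped. Lines after the first that start
#' with `#` are data, not comments. A data line with fewer fields than
#' the header is right-padded with empty strings (with a warning); a
#' line with more fields is a format error naming the line.
#'
#' @param path Path to the file.
#' @param name Set name; defaults to the file name without extension.
#' @return An object of class `annotation_table`: a list with `name`,
#'   `columns`, `data` (character data frame, one column per header
#'   column, rows in file order), `header_present`, `n_blank`.
#' @export
parse_annotation_file <- function(path,
                                  name = tools::file_path_sans_ext(basename(path))) {
  lines <- read_text_lines(path)
  blank <- !nzchar(trimws(lines))
  n_blank <- sum(blank)
  keep_no <- which(!blank)
  lines <- lines[!blank]
  if (length(lines) == 0L) po_format_error("annotation file '%s' is empty", path)

  header_present <- startsWith(lines[[1L]], "#")
  if (header_present) {
    columns <- strsplit(sub("^#", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]
    data_lines <- lines[-1L]
    data_line_no <- keep_no[-1L]
  } else {
    k <- length(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
    columns <- paste0("col", seq_len(k))
    data_lines <- lines
    data_line_no <- keep_no
  }
  k <- length(columns)
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths > k)) {
    bad <- which(widths > k)[1L]
    po_format_error(
      "line %d of '%s' has %d fields but the header defines %d columns",
      data_line_no[bad], path, widths[bad], k)
  }
  if (any(widths < k)) {
    short <- which(widths < k)
    warning(sprintf(
      "%d line(s) in '%s' have fewer fields than the header (first: line %d); padded with empty strings",
      length(short), path, data_line_no[short[1L]]), call. = FALSE)
    fields[short] <- lapply(fields[short], function(f) c(f, rep("", k - length(f))))
  }
  mat <- if (length(fields) > 0L) {
    matrix(unlist(fields, use.names = FALSE), ncol = k, byrow = TRUE)
  } else {
    matrix(character(), ncol = k)
  }
  data <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(data) <- make.unique(columns)

  structure(
    list(name = name, columns = columns, data = data,
         header_present = header_present, n_blank = n_blank),
    class = "annotation_table"
  )
}

#' Write an annotation table back to TSV
#'
#' Inverse of [parse_annotation_file()]: emits the `#`-prefixed header
#' when one was present and the data rows in order, so a parse/write
#' cycle reproduces the file's data content.
#'
#' @param table An `annotation_table` (or the table inside an
#'   `annotation_set`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation <- function(table, path) {
  if (inherits(table, "annotation_set")) table <- table$table
  stopifnot(inherits(table, "annotation_table"))
  rows <- if (nrow(table$data) > 0L) {
    do.call(paste, c(unname(as.list(table$data)), sep = "\t"))
  } else {
    character()
  }
  lines <- character()
  if (table$header_present) {
    lines <- paste0("#", paste(table$columns, collapse = "\t"))
  }
  lines <- c(lines, rows)
  write_atomic(path, function(tmp) writeLines(lines, tmp))
}

#' Preview the first rows of an annotation file
#'
#' Mirrors the upload preview: the first data rows of the file are
#' returned so the user can check that column 1 really is the gene
#' symbol. The default preview length is 10 lines; the header line is
#' not counted.
#'
#' @param path Path to the annotation file.
#' @param n_lines Maximum number of data rows to return (default 10).
#' @return A character data frame of `min(n_lines, nrow)` rows.
#' @export
preview_annotation_file <- function(path, n_lines = 10L) {
  if (!is.numeric(n_lines) || length(n_lines) != 1L || n_lines < 1L) {
    po_input_error("n_lines must be a positive integer")
  }
  tab <- parse_annotation_file(path)
  utils::head(tab$data, n_lines)
}

#' Assign a display icon to an annotation table
#'
#' Every annotation set carries exactly one icon; assigning a second
#' icon replaces the first. The same icon may be shared by several
#' sets (recommended for identical data types). The icon must exist in
#' the registry — builtin glyph or user-registered image.
#'
#' @param table An `annotation_table`, or an existing `annotation_set`
#'   whose icon is being replaced.
#' @param icon Icon name.
#' @param registry An [icon_registry()]; defaults to the builtin set.
#' @return An object of class `annotation_set`.
#' @export
attach_icon <- function(table, icon, registry = icon_registry()) {
  if (is.null(get_icon(registry, icon))) {
    po_config_error("unknown icon '%s'; not in the icon registry", icon)
  }
  if (inherits(table, "annotation_set")) {
    table$icon <- icon
    return(table)
  }
  stopifnot(inherits(table, "annotation_table"))
  structure(
    list(table = table, icon = icon, gene_index = list(),
         row_status = rep(NA_character_, nrow(table$data)),
         normalized = FALSE),
    class = "annotation_set"
  )
}

#' Normalize an annotation set and report unmatched genes
#'
#' Runs the two-phase symbol normalizer over column 1 of the set.
#' Matched symbols are rewritten to their approved form and indexed in
#' `gene_index` (one gene may map to several rows; all are kept).
#' Rows whose symbol fails normalization are retained but flagged and
#' excluded from the index. The report partitions misses into
#' `invalid_symbols` (no HGNC match at all) and `out_of_pathway`
#' (valid HGNC genes absent from every loaded pathway) — the two lists
#' the user downloads after an upload completes.
#'
#' @param set An `annotation_set` from [attach_icon()].
#' @param norm A `gene_normalizer`.
#' @param pathway_universe Character vector: the union of genes over
#'   all loaded pathways.
#' @return A list with elements `set` (normalized) and `report`
#'   (class `unmatched_report`, fields `invalid_symbols`,
#'   `out_of_pathway`, both in order of first occurrence).
#' @export
normalize_annotation <- function(set, norm, pathway_universe = character()) {
  stopifnot(inherits(set, "annotation_set"))
  syms <- set$table$data[[1L]]
  res <- normalize_symbols(norm, syms)
  matched <- res$status != "unmatched"

  new_syms <- syms
  new_syms[matched] <- res$approved_symbol[matched]
  set$table$data[[1L]] <- new_syms
  set$row_status <- res$status

  idx <- split(which(matched), res$approved_symbol[matched])
  # split() sorts by key; restore first-occurrence order for stable output
  first <- vapply(idx, min, integer(1L))
  set$gene_index <- idx[order(first)]
  set$normalized <- TRUE

  invalid <- unique(syms[!matched])
  genes <- res$approved_symbol[matched]
  oop <- unique(genes[!(genes %in% pathway_universe)])

  report <- structure(
    list(invalid_symbols = invalid, out_of_pathway = oop),
    class = "unmatched_report"
  )
  list(set = set, report = report)
}

#' Distinct genes of a normalized annotation set
#'
#' @param set A normalized `annotation_set`.
#' @return Character vector of approved symbols (distinct genes, not rows).
#' @export
annotation_genes <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  names(set$gene_index)
}

#' Write the unmatched-gene report
#'
#' Two-column TSV (`symbol`, `category`) with categories
#' `invalid_symbol` and `out_of_pathway`, in order of first occurrence.
#'
#' @param report An `unmatched_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_unmatched_report <- function(report, path) {
  stopifnot(inherits(report, "unmatched_report"))
  lines <- c(
    "symbol\tcategory",
    if (length(report$invalid_symbols) > 0L)
      paste0(report$invalid_symbols, "\tinvalid_symbol"),
    if (length(report$out_of_pathway) > 0L)
      paste0(report$out_of_pathway, "\tout_of_pathway")
  )
  write_atomic(path, function(tmp) writeLines(lines, tmp))
}

#' Read an unmatched-gene report back
#'
#' @param path Path written by [write_unmatched_report()].
#' @return An `unmatched_report`.
#' @export
read_unmatched_report <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || lines[[1L]] != "symbol\tcategory") {
    po_format_error("'%s' is not an unmatched report", path)
  }
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  sym <- vapply(fields, `[`, character(1L), 1L)
  cat_ <- vapply(fields, `[`, character(1L), 2L)
  structure(
    list(invalid_symbols = sym[cat_ == "invalid_symbol"],
         out_of_pathway = sym[cat_ == "out_of_pathway"]),
    class = "unmatched_report"
  )
}
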