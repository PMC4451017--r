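#' Canonical form of a gene symbol
#'
#' Matching throughout the package is case-insensitive on
#' whitespace-trimmed symbols: the canonical form is the uppercased,
#' trimmed string. Output always uses the reference (HGNC) casing.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of canonical forms.
#' @export
canonical_symbol <- function(x) toupper(trimws(x))

#' Construct an HGNC reference table
#'
#' An `hgnc_table` holds one row per approved symbol together with its
#' synonym (alias) list. Approved symbols must be unique and non-empty.
#'
#' @param approved_symbol Character vector of approved symbols.
#' @param synonyms List of character vectors, one per approved symbol
#'   (may be empty vectors).
#' @return An object of class `hgnc_table`.
#' @examples
#' hgnc_table(c("TP53", "KRAS"), list(c("p53", "LFS1"), character()))
#' @export
hgnc_table <- function(approved_symbol, synonyms = vector("list", length(approved_symbol))) {
  approved_symbol <- as.character(approved_symbol)
  stopifnot(length(synonyms) == length(approved_symbol))
  if (any(!nzchar(trimws(approved_symbol)))) {
    po_format_error("approved symbols must be non-empty")
  }
  synonyms <- lapply(synonyms, as.character)
  tbl <- data.frame(approved_symbol = approved_symbol, stringsAsFactors = FALSE)
  tbl$synonyms <- synonyms
  class(tbl) <- c("hgnc_table", "data.frame")
  tbl
}

#' Read an HGNC reference table from TSV
#'
#' Expects a header line `approved_symbol<TAB>synonyms`; the synonym
#' column is a comma- or pipe-separated list (both separators accepted:
#' real HGNC exports use pipes, small hand-written tables typically
#' commas). A missing or empty second field means no synonyms.
#'
#' @param path Path to the TSV file.
#' @return An [hgnc_table()].
#' @export
read_hgnc_table <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) po_format_error("HGNC table '%s' is empty", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (canonical_symbol(header[1L]) == "APPROVED_SYMBOL") {
    lines <- lines[-1L]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  approved <- vapply(fields, `[`, character(1L), 1L)
  syns <- lapply(fields, function(f) {
    if (length(f) < 2L || !nzchar(trimws(f[2L]))) return(character())
    s <- strsplit(f[2L], "[,|]")[[1L]]
    s <- trimws(s)
    s[nzchar(s)]
  })
  hgnc_table(trimws(approved), syns)
}

#' Write an HGNC reference table to TSV
#'
#' @param table An [hgnc_table()].
#' @param path Output path.
#' @param sep Separator for the synonym list, `","` or `"|"`.
#' @return The path, invisibly.
#' @export
write_hgnc_table <- function(table, path, sep = ",") {
  lines <- c(
    "approved_symbol\tsynonyms",
    paste0(table$approved_symbol, "\t",
           vapply(table$synonyms, paste, character(1L), collapse = sep))
  )
  write_atomic(path, function(tmp) writeLines(lines, tmp))
}

#' Build a two-phase gene-symbol normalizer
#'
#' Compiles an HGNC reference into the lookup structure used for
#' symbol normalization: a set of approved symbols (phase 1) and a
#' synonym map (phase 2). Synonyms are disambiguated at build time:
#'
#' * a synonym listed under exactly one approved symbol maps to it;
#' * a synonym listed under two or more approved symbols is removed
#'   entirely (recorded in `dropped_ambiguous`) and will never resolve;
#' * a synonym whose canonical form equals any approved symbol is
#'   excluded from the synonym map — the approved match takes precedence.
#'
#' A synonym repeated under the same approved symbol counts once.
#'
#' @param table An [hgnc_table()].
#' @return An object of class `gene_normalizer` with elements
#'   `approved` (named character: canonical form -> reference casing),
#'   `synonym_map` (named character: canonical synonym -> approved
#'   symbol) and `dropped_ambiguous` (character, canonical forms).
#' @examples
#' tbl <- hgnc_table(c("TP53", "KRAS"), list(c("p53"), c("p53", "KRAS2")))
#' nm <- build_normalizer(tbl)
#' nm$dropped_ambiguous  # "P53" maps to both genes, so it is dropped
#' @export
build_normalizer <- function(table) {
  stopifnot(inherits(table, "hgnc_table"))
  appr_canon <- canonical_symbol(table$approved_symbol)
  dup <- appr_canon[duplicated(appr_canon)]
  if (length(dup) > 0L) {
    po_config_error("duplicate approved symbol in HGNC table: %s", dup[1L])
  }
  approved <- stats::setNames(table$approved_symbol, appr_canon)

  # One (synonym, approved) pair per row, deduplicated within a gene.
  syn_canon <- lapply(table$synonyms, function(s) unique(canonical_symbol(s)))
  n_per <- lengths(syn_canon)
  syn <- unlist(syn_canon, use.names = FALSE)
  owner <- rep(table$approved_symbol, n_per)
  if (is.null(syn)) syn <- character()

  # Approved-symbol collisions leave phase 2 entirely (phase 1 wins).
  keep <- !(syn %in% appr_canon)
  syn <- syn[keep]
  owner <- owner[keep]

  n_owners <- vapply(split(owner, syn), function(o) length(unique(o)), integer(1L))
  ambiguous <- names(n_owners)[n_owners >= 2L]
  unique_syn <- !(syn %in% ambiguous)
  synonym_map <- stats::setNames(owner[unique_syn], syn[unique_syn])

  structure(
    list(approved = approved,
         synonym_map = synonym_map,
         dropped_ambiguous = sort(ambiguous)),
    class = "gene_normalizer"
  )
}

#' @export
print.gene_normalizer <- function(x, ...) {
  cat(sprintf(
    "<gene_normalizer> %d approved symbols, %d synonyms (%d ambiguous dropped)\n",
    length(x$approved), length(x$synonym_map), length(x$dropped_ambiguous)))
  invisible(x)
}

#' Normalize one gene symbol
#'
#' Phase 1 matches the canonical form of `symbol` against the approved
#' symbols; on a hit the approved symbol is returned in reference
#' casing with status `"approved"`. Otherwise phase 2 consults the
#' disambiguated synonym map (status `"synonym"`). A symbol matching
#' neither is `"unmatched"` and carries no approved symbol.
#'
#' @param norm A `gene_normalizer` from [build_normalizer()].
#' @param symbol A single non-empty symbol string.
#' @return A list with `input_symbol`, `approved_symbol` (`NA` when
#'   unmatched) and `status` (one of `"approved"`, `"synonym"`,
#'   `"unmatched"`).
#' @export
normalize_symbol <- function(norm, symbol) {
  stopifnot(inherits(norm, "gene_normalizer"))
  if (length(symbol) != 1L || is.na(symbol) || !nzchar(trimws(symbol))) {
    po_input_error("gene symbol is empty or whitespace-only")
  }
  canon <- canonical_symbol(symbol)
  if (!is.na(hit <- norm$approved[canon])) {
    return(list(input_symbol = symbol, approved_symbol = unname(hit),
                status = "approved"))
  }
  if (!is.na(hit <- norm$synonym_map[canon])) {
    return(list(input_symbol = symbol, approved_symbol = unname(hit),
                status = "synonym"))
  }
  list(input_symbol = symbol, approved_symbol = NA_character_,
       status = "unmatched")
}

#' Normalize a vector of gene symbols
#'
#' Order-preserving, element-wise [normalize_symbol()]. Empty or
#' whitespace-only entries do not abort the batch: they come back as
#' `unmatched` with `invalid_input = TRUE`.
#'
#' @param norm A `gene_normalizer`.
#' @param symbols Character vector.
#' @return A data frame with columns `input_symbol`, `approved_symbol`,
#'   `status`, `invalid_input`.
#' @export
normalize_symbols <- function(norm, symbols) {
  symbols <- as.character(symbols)
  n <- length(symbols)
  out <- data.frame(
    input_symbol = symbols,
    approved_symbol = rep(NA_character_, n),
    status = rep("unmatched", n),
    invalid_input = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  bad <- is.na(symbols) | !nzchar(trimws(symbols))
  out$invalid_input <- bad
  canon <- canonical_symbol(symbols)
  appr <- norm$approved[canon]
  hit1 <- !bad & !is.na(appr)
  out$approved_symbol[hit1] <- unname(appr[hit1])
  out$status[hit1] <- "approved"
  syn <- norm$synonym_map[canon]
  hit2 <- !bad & !hit1 & !is.na(syn)
  out$approved_symbol[hit2] <- unname(syn[hit2])
  out$status[hit2] <- "synonym"
  out
}
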