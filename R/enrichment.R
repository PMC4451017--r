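#' Count annotated genes in a pathway
#'
#' The counting unit is the gene, never the row: a gene with five
#' variant rows in the annotation set contributes one to the count.
#'
#' @param pathway A [pathway()].
#' @param set A normalized `annotation_set`.
#' @return Integer: `|pathway genes ∩ distinct annotation genes|`.
#' @export
count_annotated <- function(pathway, set) {
  stopifnot(inherits(pathway, "pathway"))
  if (!isTRUE(set$normalized)) {
    po_input_error("annotation set '%s' has not been normalized", set$table$name)
  }
  sum(pathway$genes %in% annotation_genes(set))
}

#' One-sided Fisher's exact enrichment p-value
#'
#' Upper-tail (over-representation) probability of observing at least
#' `k` annotated genes in an `n`-gene pathway when `K` of the `N`
#' universe genes are annotated:
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' Terms are accumulated from log-binomial coefficients so the sum is
#' exact to well beyond 10 significant digits for any universe a
#' pathway collection produces.
#'
#' @param k Overlap count (annotated genes in the pathway).
#' @param K Annotated genes in the universe.
#' @param n Pathway gene count.
#' @param N Universe gene count.
#' @return A probability in `[0, 1]`.
#' @examples
#' fisher_enrichment_p(4, 5, 4, 10)  # 5 / choose(10, 4)
#' @export
fisher_enrichment_p <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != floor(v)) {
      po_input_error("contingency inputs must be single non-negative integers")
    }
  }
  if (N < 0) po_input_error("N must be >= 0")
  if (n > N) po_input_error("invalid contingency: n = %d exceeds N = %d", n, N)
  if (K > N) po_input_error("invalid contingency: K = %d exceeds N = %d", K, N)
  if (k < 0 || k > min(n, K)) {
    po_input_error("invalid contingency: k = %d outside [0, min(n, K) = %d]",
                   k, min(n, K))
  }
  # at or below the distribution's minimum support point the tail is all
  # of the mass: return exactly 1 rather than a rounded sum
  if (k <= max(0, n - (N - K))) return(1)
  i <- seq.int(k, min(n, K))
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  p <- sum(exp(log_terms))
  min(max(p, 0), 1)
}

#' Build the main summary table
#'
#' One row per pathway with its gene count, plus — per annotation set
#' — the number of member genes that set annotates, and optionally the
#' one-sided Fisher's exact enrichment p-value. The enrichment
#' background (`N`) is the union of genes over the loaded pathways;
#' annotation genes outside that universe do not count towards `K`.
#' Raw p-values are the primary output; Benjamini-Hochberg adjusted
#' values are available behind `adjust = "BH"` (off by default).
#'
#' @param collection A non-empty `pathway_collection`.
#' @param sets List of normalized `annotation_set`s.
#' @param with_enrichment Compute `<set>_p` columns?
#' @param adjust `"none"` (default) or `"BH"` for an additional
#'   `<set>_p_adj` column per set.
#' @return A `summary_table`: a data frame with columns `pathway_id`,
#'   `name`, `source`, `n_genes`, then `<set>_count` (and `<set>_p`,
#'   `<set>_p_adj`) per set, plus a `sort_state` attribute.
#' @export
build_summary_table <- function(collection, sets = list(),
                                with_enrichment = FALSE,
                                adjust = c("none", "BH")) {
  stopifnot(inherits(collection, "pathway_collection"))
  adjust <- match.arg(adjust)
  if (length(collection$pathways) == 0L) {
    po_input_error("cannot summarize an empty pathway collection")
  }
  set_names <- vapply(sets, function(s) s$table$name, character(1L))
  if (anyDuplicated(set_names)) {
    po_config_error("annotation set names must be unique: %s",
                    set_names[duplicated(set_names)][1L])
  }
  paths <- collection$pathways
  tab <- data.frame(
    pathway_id = vapply(paths, function(p) p$id, character(1L)),
    name = vapply(paths, function(p) p$display_name, character(1L)),
    source = vapply(paths, function(p) p$source, character(1L)),
    n_genes = vapply(paths, function(p) length(p$genes), integer(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  N <- length(collection$universe)
  for (s in seq_along(sets)) {
    set <- sets[[s]]
    counts <- vapply(paths, count_annotated, integer(1L), set = set)
    tab[[paste0(set_names[s], "_count")]] <- unname(counts)
    if (with_enrichment) {
      K <- sum(annotation_genes(set) %in% collection$universe)
      if (K == 0L) {
        warning(sprintf("annotation set '%s' has no genes in the pathway universe; p-values are all 1",
                        set_names[s]), call. = FALSE)
      }
      p <- vapply(seq_along(paths), function(i) {
        fisher_enrichment_p(counts[i], K, tab$n_genes[i], N)
      }, numeric(1L))
      tab[[paste0(set_names[s], "_p")]] <- p
      if (adjust == "BH") {
        tab[[paste0(set_names[s], "_p_adj")]] <- stats::p.adjust(p, method = "BH")
      }
    }
  }
  structure(tab, sort_state = NULL,
            class = c("summary_table", "data.frame"))
}

#' Sort a summary table by one column
#'
#' Stable sort: rows with equal keys keep their current relative
#' order, so repeated identical sorts are idempotent. Numeric columns
#' sort numerically, character columns lexicographically (C locale).
#'
#' @param table A `summary_table`.
#' @param column Column name to sort on.
#' @param direction `"asc"` or `"desc"`.
#' @return The sorted `summary_table`; its `sort_state` attribute
#'   records `(column, direction)`.
#' @export
sort_table <- function(table, column, direction = c("asc", "desc")) {
  stopifnot(inherits(table, "summary_table"))
  direction <- match.arg(direction)
  if (!(column %in% names(table))) {
    po_input_error("unknown summary column '%s'", column)
  }
  key <- table[[column]]
  ord <- order(key, decreasing = (direction == "desc"), method = "radix")
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sort_state") <- c(column = column, direction = direction)
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Write a summary table to TSV
#'
#' @param table A `summary_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_summary_table <- function(table, path) {
  write_atomic(path, function(tmp) {
    utils::write.table(table, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
}
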