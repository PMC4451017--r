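#' Construct a pathway
#'
#' A pathway is a named gene set, optionally carrying a drawing
#' topology (nodes/edges/coordinates) for the viewer.
#'
#' @param id Unique identifier within a collection.
#' @param display_name Human-readable name.
#' @param source Collection label (e.g. `"KEGG"`, `"custom"`).
#' @param genes Character vector of member gene symbols (deduplicated).
#' @param topology Optional `pathway_topology`.
#' @return An object of class `pathway`.
#' @export
pathway <- function(id, display_name = id, source = "custom", genes,
                    topology = NULL) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) {
    po_input_error("pathway '%s' has no genes", id)
  }
  structure(
    list(id = id, display_name = display_name, source = source,
         genes = genes, topology = topology),
    class = "pathway"
  )
}

#' Construct a pathway collection
#'
#' The collection is the registry the summary table and the pathway
#' filter operate on; its `universe` — the union of genes over all
#' member pathways — is the enrichment background.
#'
#' @param pathways List of [pathway()] objects (order is preserved).
#' @return An object of class `pathway_collection` with elements
#'   `pathways` and `universe`.
#' @export
pathway_collection <- function(pathways) {
  ids <- vapply(pathways, function(p) p$id, character(1L))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    po_config_error("duplicate pathway id in collection: %s", dup[1L])
  }
  universe <- unique(unlist(lapply(pathways, function(p) p$genes),
                            use.names = FALSE))
  if (is.null(universe)) universe <- character()
  structure(
    list(pathways = stats::setNames(pathways, ids), universe = universe),
    class = "pathway_collection"
  )
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, %d genes in universe\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One pathway per non-blank line: `name<TAB>description<TAB>gene...`.
#' Duplicate genes within a line are deduplicated. When a normalizer
#' is supplied, symbols that resolve are rewritten to their approved
#' form; unresolved symbols are kept verbatim (a pathway source may
#' legitimately use identifiers outside the reference).
#'
#' @param path Path to the GMT file.
#' @param source_label Collection label stored on each pathway.
#' @param norm Optional `gene_normalizer`.
#' @return List of [pathway()] objects.
#' @export
read_gmt <- function(path, source_label = tools::file_path_sans_ext(basename(path)),
                     norm = NULL) {
  lines <- read_text_lines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      po_format_error("line %d of '%s': GMT line needs name, description and >=1 gene",
                      line_no[i], path)
    }
    genes <- unique(f[-(1:2)])
    if (!is.null(norm)) {
      res <- normalize_symbols(norm, genes)
      hit <- res$status != "unmatched"
      genes <- unique(ifelse(hit, res$approved_symbol, genes))
    }
    out[[i]] <- pathway(id = f[1L], display_name = f[1L],
                        source = source_label, genes = genes)
  }
  out
}

#' Write pathways to a GMT file
#'
#' @param pathways List of [pathway()] objects, or a `pathway_collection`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  if (inherits(pathways, "pathway_collection")) pathways <- pathways$pathways
  lines <- vapply(pathways, function(p) {
    paste(c(p$id, p$display_name, p$genes), collapse = "\t")
  }, character(1L))
  write_atomic(path, function(tmp) writeLines(lines, tmp))
}

# Deterministic fallback layout for nodes missing coordinates: row-major
# grid with a fixed cell, so a topology is always renderable.
grid_cell <- c(w = 140, h = 70)

#' Read a Cytoscape XGMML topology
#'
#' Parses `node` and `edge` elements of an XGMML export. Coordinates
#' come from each node's `graphics` child (`x`, `y`, `w`, `h`) or,
#' failing that, from node-level `att` elements named `x`/`y`/`w`/`h`;
#' nodes missing coordinates are placed on a deterministic row-major
#' grid. The gene identity of a node comes from its label (or a
#' `label` att): the label is split on `/` and `,` so a family box
#' like `CDK4/6` can map to several genes, each token is normalized,
#' and the node carries every approved symbol that matched. Nodes
#' whose label matches nothing (compounds, ATP, ...) are kept as
#' non-gene nodes.
#'
#' @param path Path to the XGMML file.
#' @param norm Optional `gene_normalizer` used to resolve node labels;
#'   without one, labels are taken at face value (canonical form).
#' @param background_image Optional path to a backdrop image drawn
#'   beneath the nodes by the renderer.
#' @return An object of class `pathway_topology`: `nodes` (data frame
#'   with `node_id`, `label`, `x`, `y`, `width`, `height` and a
#'   list-column `genes`), `edges` (data frame `source`, `target`,
#'   `interaction`), `background_image`.
#' @export
read_xgmml <- function(path, norm = NULL, background_image = NULL) {
  if (!file.exists(path)) po_io_error("cannot read '%s': no such file", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) po_format_error("malformed XML in '%s': %s",
                                                      path, conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  node_els <- xml2::xml_find_all(doc, ".//node")
  edge_els <- xml2::xml_find_all(doc, ".//edge")

  att_of <- function(el, name) {
    a <- xml2::xml_find_first(el, sprintf("./att[@name='%s']", name))
    if (inherits(a, "xml_missing")) NA_character_ else xml2::xml_attr(a, "value")
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))

  n <- length(node_els)
  node_id <- character(n); label <- character(n)
  x <- y <- w <- h <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    el <- node_els[[i]]
    node_id[i] <- xml2::xml_attr(el, "id")
    lab <- xml2::xml_attr(el, "label")
    if (is.na(lab)) lab <- att_of(el, "label")
    if (is.na(lab)) lab <- node_id[i]
    label[i] <- lab
    g <- xml2::xml_find_first(el, "./graphics")
    if (!inherits(g, "xml_missing")) {
      x[i] <- num_or_na(xml2::xml_attr(g, "x"))
      y[i] <- num_or_na(xml2::xml_attr(g, "y"))
      w[i] <- num_or_na(xml2::xml_attr(g, "w"))
      h[i] <- num_or_na(xml2::xml_attr(g, "h"))
    }
    if (is.na(x[i])) x[i] <- num_or_na(att_of(el, "x"))
    if (is.na(y[i])) y[i] <- num_or_na(att_of(el, "y"))
    if (is.na(w[i])) w[i] <- num_or_na(att_of(el, "w"))
    if (is.na(h[i])) h[i] <- num_or_na(att_of(el, "h"))
  }
  if (any(is.na(node_id)) || anyDuplicated(node_id)) {
    po_format_error("'%s': node ids must be present and unique", path)
  }
  # fallback grid for missing coordinates; sizes default to one cell's box
  missing_xy <- which(is.na(x) | is.na(y))
  if (length(missing_xy) > 0L) {
    ncol_grid <- max(1L, ceiling(sqrt(length(missing_xy))))
    pos <- seq_along(missing_xy) - 1L
    x[missing_xy] <- (pos %% ncol_grid) * grid_cell[["w"]] + grid_cell[["w"]] / 2
    y[missing_xy] <- (pos %/% ncol_grid) * grid_cell[["h"]] + grid_cell[["h"]] / 2
  }
  w[is.na(w)] <- 60
  h[is.na(h)] <- 30
  if (any(!is.finite(c(x, y)))) {
    po_format_error("'%s': node coordinates must be finite", path)
  }

  genes <- lapply(label, function(lab) resolve_label_genes(lab, norm))

  nodes <- data.frame(node_id = node_id, label = label,
                      x = x, y = y, width = w, height = h,
                      stringsAsFactors = FALSE)
  nodes$genes <- genes

  m <- length(edge_els)
  src <- xml2::xml_attr(edge_els, "source")
  tgt <- xml2::xml_attr(edge_els, "target")
  inter <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    lab <- xml2::xml_attr(edge_els[[j]], "label")
    if (is.na(lab)) lab <- att_of(edge_els[[j]], "interaction")
    inter[j] <- lab
  }
  bad_end <- which(!(src %in% node_id) | !(tgt %in% node_id))
  if (length(bad_end) > 0L) {
    po_format_error("'%s': edge %s -> %s references an unknown node",
                    path, src[bad_end[1L]], tgt[bad_end[1L]])
  }
  edges <- data.frame(source = src, target = tgt, interaction = inter,
                      stringsAsFactors = FALSE)

  structure(
    list(nodes = nodes, edges = edges, background_image = background_image),
    class = "pathway_topology"
  )
}

# Split a node label on '/' and ',' and normalize each token; returns the
# approved symbols the label resolves to (possibly none).
resolve_label_genes <- function(label, norm) {
  tokens <- trimws(strsplit(label, "[/,]")[[1L]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) return(character())
  if (is.null(norm)) return(unique(canonical_symbol(tokens)))
  res <- normalize_symbols(norm, tokens)
  unique(res$approved_symbol[res$status != "unmatched"])
}

#' Derive a pathway's gene set from its topology
#'
#' Membership is the union of the genes carried by the topology's
#' nodes. A topology without a single gene-bearing node cannot be
#' counted against annotation sets and is rejected.
#'
#' @param topology A `pathway_topology`.
#' @param id,name,source Pathway identity fields.
#' @return A [pathway()] with the topology attached.
#' @export
pathway_from_topology <- function(topology, id, name = id, source = "custom") {
  stopifnot(inherits(topology, "pathway_topology"))
  genes <- unique(unlist(topology$nodes$genes, use.names = FALSE))
  if (is.null(genes) || length(genes) == 0L) {
    po_input_error("topology for '%s' has no gene-bearing nodes", id)
  }
  pathway(id = id, display_name = name, source = source,
          genes = genes, topology = topology)
}

#' Filter a collection by genes of interest
#'
#' The pathway filter of the main table: keep exactly the pathways
#' whose gene set intersects the query, in their original order. An
#' empty query (or no overlap) gives an empty collection.
#'
#' @param collection A `pathway_collection`.
#' @param query_genes Character vector of (normalized) gene symbols.
#' @return A `pathway_collection` restricted to matching pathways;
#'   its universe is recomputed from the surviving pathways.
#' @export
filter_pathways <- function(collection, query_genes) {
  stopifnot(inherits(collection, "pathway_collection"))
  query_genes <- unique(as.character(query_genes))
  keep <- vapply(collection$pathways,
                 function(p) any(p$genes %in% query_genes), logical(1L))
  pathway_collection(unname(collection$pathways[keep]))
}
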