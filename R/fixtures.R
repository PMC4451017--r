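#' Specification for the deterministic fixture generators
#'
#' One seeded specification drives every generator, so a whole test
#' bundle (HGNC reference, pathway collection, annotation files and
#' ground-truth manifest) is byte-identical across reruns with the
#' same seed.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of approved symbols (`GENE0001`, ...).
#' @param n_synonyms_per_gene Length-2 integer range of synonyms per gene.
#' @param ambiguous_synonym_count Synonyms deliberately shared by two
#'   genes (they must drop out of the normalizer).
#' @param n_pathways Pathways in the generated collection.
#' @param pathway_size Length-2 integer range of genes per pathway.
#' @param hit_rate Fraction of the pathway universe each annotation
#'   file covers, in `[0, 1]`.
#' @param invalid_symbol_count Bogus symbols injected per annotation file.
#' @param out_of_pathway_count HGNC-valid genes outside every pathway
#'   injected per annotation file (exercises the second partition of
#'   the unmatched report).
#' @param extra_column_count Annotation value columns beyond the gene
#'   symbol.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 60L,
                         n_synonyms_per_gene = c(1L, 3L),
                         ambiguous_synonym_count = 2L,
                         n_pathways = 10L, pathway_size = c(5L, 12L),
                         hit_rate = 0.3, invalid_symbol_count = 3L,
                         out_of_pathway_count = 2L,
                         extra_column_count = 2L) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_synonyms_per_gene = as.integer(n_synonyms_per_gene),
               ambiguous_synonym_count = as.integer(ambiguous_synonym_count),
               n_pathways = as.integer(n_pathways),
               pathway_size = as.integer(pathway_size),
               hit_rate = hit_rate,
               invalid_symbol_count = as.integer(invalid_symbol_count),
               out_of_pathway_count = as.integer(out_of_pathway_count),
               extra_column_count = as.integer(extra_column_count))
  counts <- unlist(spec[c("n_genes", "ambiguous_synonym_count", "n_pathways",
                          "invalid_symbol_count", "out_of_pathway_count",
                          "extra_column_count")])
  if (any(counts < 0L)) po_input_error("fixture counts must be non-negative")
  if (hit_rate < 0 || hit_rate > 1) po_input_error("hit_rate must be in [0, 1]")
  if (length(spec$n_synonyms_per_gene) != 2L || length(spec$pathway_size) != 2L) {
    po_input_error("ranges must have length 2")
  }
  class(spec) <- "fixture_spec"
  spec
}

# Draw one integer uniformly from [lo, hi]; avoids sample()'s scalar
# expansion when lo == hi.
sample_range <- function(lo, hi) {
  if (lo >= hi) return(lo)
  sample(seq.int(lo, hi), 1L)
}

# All generators draw from R's RNG seeded from spec$seed plus a fixed
# per-generator offset, so each file is reproducible on its own and the
# bundle as a whole is reproducible end to end.
with_fixture_seed <- function(spec, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(spec$seed %% 100000L * 17L + offset)
  expr
}

#' Generate an HGNC reference fixture
#'
#' Writes a two-column TSV of `n_genes` approved symbols with
#' synonyms. Synonyms mix lowercase variants and `ALT_`-prefixed
#' strings to exercise case-insensitive matching; exactly
#' `ambiguous_synonym_count` synonyms (`AMBSYN01`, ...) are assigned
#' to two distinct genes each and must be dropped by the normalizer.
#'
#' @param spec A [fixture_spec()].
#' @param path Output TSV path.
#' @return Invisibly, a list with `path` and the generated `table`.
#' @export
make_hgnc_fixture <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$ambiguous_synonym_count > 0L && spec$n_genes < 2L) {
    po_input_error("ambiguous synonyms need at least 2 genes")
  }
  with_fixture_seed(spec, 101L, {
    approved <- sprintf("GENE%04d", seq_len(spec$n_genes))
    syns <- vector("list", spec$n_genes)
    rng <- spec$n_synonyms_per_gene
    for (i in seq_len(spec$n_genes)) {
      k <- sample_range(rng[1L], rng[2L])
      if (k == 0L) { syns[[i]] <- character(); next }
      forms <- vapply(seq_len(k), function(j) {
        if (j %% 2L == 1L) paste0(tolower(approved[i]), "a", j)
        else paste0("ALT_", approved[i], "_", j)
      }, character(1L))
      syns[[i]] <- forms
    }
    for (a in seq_len(spec$ambiguous_synonym_count)) {
      pair <- sample(spec$n_genes, 2L)
      amb <- sprintf("AMBSYN%02d", a)
      syns[[pair[1L]]] <- c(syns[[pair[1L]]], amb)
      syns[[pair[2L]]] <- c(syns[[pair[2L]]], amb)
    }
    table <- hgnc_table(approved, syns)
    write_hgnc_table(table, path, sep = ",")
    invisible(list(path = path, table = table))
  })
}

#' Generate a pathway collection fixture (GMT + XGMML)
#'
#' Draws `n_pathways` gene sets without replacement from the approved
#' symbols and writes them as one GMT file plus one XGMML topology per
#' pathway. Each topology lays its genes out on a grid; roughly a
#' quarter of the node labels use a resolvable synonym instead of the
#' approved symbol (the parser must normalize them back), and every
#' topology carries one non-gene node (`ATP`).
#'
#' @param spec A [fixture_spec()].
#' @param hgnc Result of [make_hgnc_fixture()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with `gmt` (path), `xgmml` (paths) and
#'   `membership` (named list: pathway id -> genes, the generator's
#'   own record).
#' @export
make_pathway_fixture <- function(spec, hgnc, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rng <- spec$pathway_size
  if (rng[2L] > spec$n_genes) {
    po_input_error("pathway_size max (%d) exceeds n_genes (%d)", rng[2L], spec$n_genes)
  }
  approved <- hgnc$table$approved_symbol
  syn_by_gene <- stats::setNames(hgnc$table$synonyms, approved)
  nm <- build_normalizer(hgnc$table)
  with_fixture_seed(spec, 202L, {
    membership <- list()
    xgmml_paths <- character(spec$n_pathways)
    for (p in seq_len(spec$n_pathways)) {
      size <- sample_range(rng[1L], rng[2L])
      genes <- sort(sample(approved, size))
      id <- sprintf("PW%02d", p)
      membership[[id]] <- genes
      xgmml_paths[p] <- file.path(dir, sprintf("pathway_%02d.xgmml", p))
      labels <- vapply(genes, function(g) {
        s <- syn_by_gene[[g]]
        s <- s[!(canonical_symbol(s) %in% nm$dropped_ambiguous)]
        if (length(s) > 0L && stats::runif(1L) < 0.25) s[[1L]] else g
      }, character(1L))
      write_xgmml_fixture(xgmml_paths[p], id, labels)
    }
    gmt <- file.path(dir, "pathways.gmt")
    lines <- vapply(names(membership), function(id) {
      paste(c(id, paste0("fixture pathway ", id), membership[[id]]),
            collapse = "\t")
    }, character(1L))
    write_atomic(gmt, function(tmp) writeLines(lines, tmp))
    invisible(list(gmt = gmt, xgmml = xgmml_paths, membership = membership))
  })
}

# Emit a minimal Cytoscape-style XGMML file: gene nodes on a grid, one
# non-gene node, and a chain of edges.
write_xgmml_fixture <- function(path, graph_label, labels) {
  n <- length(labels)
  all_labels <- c(labels, "ATP")
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<graph label="%s" xmlns="http://www.cs.rpi.edu/XGMML" directed="1">',
            xml_escape(graph_label))
  )
  ncols <- max(1L, ceiling(sqrt(n + 1L)))
  for (i in seq_along(all_labels)) {
    cx <- ((i - 1L) %% ncols) * 140 + 80
    cy <- ((i - 1L) %/% ncols) * 80 + 50
    lines <- c(lines, sprintf(
      '  <node id="n%d" label="%s"><graphics type="RECTANGLE" x="%d" y="%d" w="90" h="34"/></node>',
      i, xml_escape(all_labels[i]), cx, cy))
  }
  for (i in seq_len(length(all_labels) - 1L)) {
    lines <- c(lines, sprintf(
      '  <edge source="n%d" target="n%d" label="pp"/>', i, i + 1L))
  }
  lines <- c(lines, "</graph>")
  write_atomic(path, function(tmp) writeLines(lines, tmp))
}

#' Generate an annotation-file fixture with ground truth
#'
#' Samples universe genes at `hit_rate`, writing each either as its
#' approved symbol (sometimes lowercased) or as a resolvable synonym,
#' then appends `out_of_pathway_count` HGNC-valid genes that belong to
#' no pathway and `invalid_symbol_count` bogus symbols. Value columns
#' are filled with deterministic numbers. The returned manifest
#' records, from the generator's own bookkeeping (not the parsers),
#' the true per-pathway overlap counts and both unmatched partitions.
#'
#' @param spec A [fixture_spec()].
#' @param hgnc Result of [make_hgnc_fixture()].
#' @param pathways Result of [make_pathway_fixture()].
#' @param path Output TSV path.
#' @param set_index Offset so several annotation files drawn from the
#'   same spec differ deterministically.
#' @return Invisibly, a list with `path` and `manifest` (fields
#'   `set_name`, `n_rows`, `true_genes`, `per_pathway_k`,
#'   `invalid_symbols`, `out_of_pathway`).
#' @export
make_annotation_fixture <- function(spec, hgnc, pathways, path, set_index = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  universe <- unique(unlist(pathways$membership, use.names = FALSE))
  if (is.null(universe)) universe <- character()
  if (spec$hit_rate > 0 && length(universe) == 0L) {
    po_input_error("hit_rate > 0 needs a non-empty pathway universe")
  }
  outside <- setdiff(hgnc$table$approved_symbol, universe)
  if (spec$out_of_pathway_count > length(outside)) {
    po_input_error("not enough genes outside the pathways (%d available)",
                   length(outside))
  }
  nm <- build_normalizer(hgnc$table)
  syn_by_gene <- stats::setNames(hgnc$table$synonyms, hgnc$table$approved_symbol)
  with_fixture_seed(spec, 303L + set_index * 7L, {
    n_hits <- round(spec$hit_rate * length(universe))
    hit_genes <- if (n_hits > 0L) sort(sample(universe, n_hits)) else character()
    oop_genes <- if (spec$out_of_pathway_count > 0L)
      sort(sample(outside, spec$out_of_pathway_count)) else character()
    invalid <- if (spec$invalid_symbol_count > 0L)
      sprintf("NOT_A_GENE_%02d_%d", seq_len(spec$invalid_symbol_count), set_index)
      else character()

    spell <- function(g) {
      s <- syn_by_gene[[g]]
      s <- s[!(canonical_symbol(s) %in% nm$dropped_ambiguous)]
      u <- stats::runif(1L)
      if (length(s) > 0L && u < 0.3) s[[1L]]
      else if (u < 0.5) tolower(g)
      else g
    }
    symbols <- c(vapply(hit_genes, spell, character(1L)),
                 vapply(oop_genes, spell, character(1L)),
                 invalid)
    src_gene <- c(hit_genes, oop_genes, invalid)  # approved identity per row
    ord <- if (length(symbols) > 0L) sample(length(symbols)) else integer()
    symbols <- symbols[ord]
    src_gene <- src_gene[ord]

    extra_names <- if (spec$extra_column_count > 0L)
      sprintf("ann%d", seq_len(spec$extra_column_count)) else character()
    header <- paste0("#", paste(c("Gene", extra_names), collapse = "\t"))
    values <- if (spec$extra_column_count > 0L) {
      vapply(seq_along(symbols), function(i) {
        paste(sprintf("%.3f", stats::runif(spec$extra_column_count)),
              collapse = "\t")
      }, character(1L))
    } else NULL
    rows <- if (is.null(values)) symbols else paste(symbols, values, sep = "\t")
    write_atomic(path, function(tmp) writeLines(c(header, rows), tmp))

    # both unmatched partitions in first-occurrence file order, as the
    # report will list them
    set_name <- tools::file_path_sans_ext(basename(path))
    manifest <- list(
      set_name = set_name,
      n_rows = length(symbols),
      true_genes = c(hit_genes, oop_genes),
      per_pathway_k = lapply(pathways$membership, function(g)
        sum(g %in% hit_genes)),
      invalid_symbols = invalid[order(match(invalid, src_gene))],
      out_of_pathway = oop_genes[order(match(oop_genes, src_gene))]
    )
    invisible(list(path = path, manifest = manifest))
  })
}

#' Generate a complete fixture bundle
#'
#' Orchestrates the three generators: HGNC reference, pathway
#' collection (GMT + XGMML) and `n_sets` annotation files, writing a
#' `manifest.json` of ground truth alongside.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @param n_sets Number of annotation files.
#' @return Invisibly, a list with `hgnc`, `pathways`, `annotations`
#'   (list per set) and `manifest_path`.
#' @export
make_fixture_bundle <- function(spec, dir, n_sets = 3L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hgnc <- make_hgnc_fixture(spec, file.path(dir, "hgnc.tsv"))
  pathways <- make_pathway_fixture(spec, hgnc, dir)
  annotations <- lapply(seq_len(n_sets), function(i) {
    make_annotation_fixture(spec, hgnc, pathways,
                            file.path(dir, sprintf("annot_%d.tsv", i)),
                            set_index = i)
  })
  manifest <- list(
    seed = spec$seed,
    pathways = pathways$membership,
    annotation_sets = lapply(annotations, function(a) a$manifest)
  )
  manifest_path <- file.path(dir, "manifest.json")
  write_atomic(manifest_path, function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  })
  invisible(list(hgnc = hgnc, pathways = pathways, annotations = annotations,
                 manifest_path = manifest_path))
}
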