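# Shared builders and independent oracles for the suite. The oracles are
# deliberately naive re-implementations (full scans, exhaustive subset
# enumeration) so they never share code with the paths they check.

tiny_hgnc <- function() {
  hgnc_table(
    c("TP53", "KRAS", "BRAF", "EGFR", "CDK4", "CDK6"),
    list(c("p53", "LFS1"),
         c("KRAS2", "K-RAS", "SHARED1"),
         c("BRAF1", "SHARED1"),   # SHARED1 is ambiguous -> dropped
         character(),
         c("cdk4syn"),
         character())
  )
}

write_tmp_lines <- function(lines, env = parent.frame(), fileext = ".tsv") {
  f <- withr::local_tempfile(fileext = fileext, .local_envir = env)
  writeLines(lines, f)
  f
}

# Naive phase-1/phase-2 scan over the raw reference table, applying the
# same precedence rules by direct search.
naive_normalize <- function(table, symbol) {
  canon <- canonical_symbol(symbol)
  appr <- canonical_symbol(table$approved_symbol)
  i <- which(appr == canon)
  if (length(i) >= 1L) {
    return(list(approved = table$approved_symbol[i[1L]], status = "approved"))
  }
  owners <- unique(table$approved_symbol[vapply(
    seq_along(table$synonyms),
    function(j) canon %in% canonical_symbol(table$synonyms[[j]]),
    logical(1L))])
  if (length(owners) == 1L) {
    list(approved = owners, status = "synonym")
  } else {
    list(approved = NA_character_, status = "unmatched")
  }
}

# Exact upper-tail hypergeometric probability by enumerating every n-subset
# of an N-gene universe whose first K genes are annotated.
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0L) return(if (k == 0L) 1 else NA_real_)
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# Minimal XGMML document for parser tests.
xgmml_lines <- function(nodes, edges = character(), graphics = TRUE) {
  body <- vapply(seq_along(nodes), function(i) {
    g <- if (graphics)
      sprintf('<graphics x="%d" y="%d" w="80" h="30"/>', i * 100, i * 50)
    else ""
    sprintf('<node id="n%d" label="%s">%s</node>', i, nodes[i], g)
  }, character(1L))
  c('<?xml version="1.0"?>',
    '<graph label="T" xmlns="http://www.cs.rpi.edu/XGMML">',
    body, edges, "</graph>")
}

# Full normalized mini-pipeline used by several rendering tests: tiny
# reference, one topology, two annotation sets sharing the CDK4 gene.
mini_overlay_inputs <- function(env = parent.frame()) {
  nm <- build_normalizer(tiny_hgnc())
  topo_path <- write_tmp_lines(xgmml_lines(
    c("TP53", "CDK4/6", "KRAS", "ATP"),
    c('<edge source="n1" target="n2"/>', '<edge source="n2" target="n3"/>')
  ), env = env, fileext = ".xgmml")
  topo <- read_xgmml(topo_path, norm = nm)
  mk_set <- function(name, lines, icon) {
    f <- write_tmp_lines(lines, env = env)
    tab <- parse_annotation_file(f, name = name)
    normalize_annotation(attach_icon(tab, icon), nm,
                         pathway_universe = unique(unlist(topo$nodes$genes)))$set
  }
  muts <- mk_set("mutations",
                 c("#Gene\tvariant\tVAF",
                   "TP53\tp.R175H\t0.41", "cdk4syn\tamp\t0.80"),
                 "circle")
  drugs <- mk_set("drugs",
                  c("#Gene\tdrug", "CDK4\tpalbociclib", "KRAS\tsotorasib"),
                  "pill")
  list(norm = nm, topology = topo, sets = list(muts, drugs))
}
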