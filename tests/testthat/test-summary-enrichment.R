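test_that("fisher_enrichment_p matches closed forms and degenerate margins", {
  # k = 0 sums the full tail
  expect_identical(fisher_enrichment_p(0, 5, 4, 10), 1)
  # everything annotated
  expect_identical(fisher_enrichment_p(4, 10, 4, 10), 1)
  # single-term tail: C(5,4) / C(10,4)
  expect_equal(fisher_enrichment_p(4, 5, 4, 10), 5 / choose(10, 4),
               tolerance = 1e-12)
  # lower support point k = max(0, n - (N - K)) gives p = 1
  expect_equal(fisher_enrichment_p(2, 6, 6, 10), 1, tolerance = 1e-12)

  expect_error(fisher_enrichment_p(5, 4, 4, 10), class = "po_input_error")
  expect_error(fisher_enrichment_p(0, 11, 4, 10), class = "po_input_error")
  expect_error(fisher_enrichment_p(0, 4, 11, 10), class = "po_input_error")
})

test_that("fisher_enrichment_p agrees with enumeration, phyper and fisher.test", {
  # spot grid against the exhaustive subset-enumeration oracle
  for (N in c(6L, 9L)) {
    for (n in 1:N) {
      for (K in 0:N) {
        for (k in 0:min(n, K)) {
          expect_equal(fisher_enrichment_p(k, K, n, N),
                       enum_hyper_tail(k, K, n, N), tolerance = 1e-12,
                       info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
  # independent library cross-checks on larger inputs
  cases <- list(c(3, 40, 25, 500), c(12, 60, 30, 800), c(1, 5, 100, 2000))
  for (cs in cases) {
    p <- fisher_enrichment_p(cs[1], cs[2], cs[3], cs[4])
    expect_equal(p, phyper(cs[1] - 1, cs[2], cs[4] - cs[2], cs[3],
                           lower.tail = FALSE), tolerance = 1e-10)
    m <- matrix(c(cs[1], cs[2] - cs[1],
                  cs[3] - cs[1], cs[4] - cs[2] - cs[3] + cs[1]), 2)
    expect_equal(p, fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-8)
  }
})

test_that("tail probability is monotone in k and symmetric in the margins", {
  for (K in c(3L, 7L)) {
    p <- vapply(0:min(5L, K), fisher_enrichment_p, numeric(1L),
                K = K, n = 5L, N = 15L)
    expect_true(all(diff(p) <= 1e-14))
  }
  grid <- expand.grid(k = 0:3, K = 3:6, n = 3:6)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(fisher_enrichment_p(g$k, g$K, g$n, 12L),
                 fisher_enrichment_p(g$k, g$n, g$K, 12L), tolerance = 1e-12)
  }
})

test_that("count_annotated counts distinct genes, never rows", {
  nm <- build_normalizer(tiny_hgnc())
  pw <- pathway("P", genes = c("TP53", "KRAS", "BRAF", "EGFR"))
  f <- write_tmp_lines(c("#Gene\tv", "TP53\t1", "TP53\t2", "BRAF\t3", "CDK4\t4"))
  set <- normalize_annotation(attach_icon(parse_annotation_file(f), "pill"),
                              nm, pw$genes)$set
  expect_identical(count_annotated(pw, set), 2L)

  # disjoint and saturating cases
  expect_identical(count_annotated(pathway("Q", genes = "CDK6"), set), 0L)
  expect_identical(count_annotated(pathway("R", genes = c("TP53", "BRAF", "CDK4")),
                                   set), 3L)
})

test_that("summary table counts match a brute-force recount and p-values are valid", {
  spec <- fixture_spec(seed = 11, n_pathways = 6)
  dir <- withr::local_tempdir()
  b <- make_fixture_bundle(spec, dir, n_sets = 2)
  nm <- build_normalizer(read_hgnc_table(b$hgnc$path))
  coll <- pathway_collection(read_gmt(b$pathways$gmt, norm = nm))
  sets <- lapply(b$annotations, function(a) {
    tab <- parse_annotation_file(a$path)
    normalize_annotation(attach_icon(tab, "pill"), nm, coll$universe)$set
  })
  st <- build_summary_table(coll, sets, with_enrichment = TRUE, adjust = "BH")
  expect_identical(nrow(st), 6L)
  for (s in seq_along(sets)) {
    genes <- annotation_genes(sets[[s]])
    cnt <- st[[paste0(sets[[s]]$table$name, "_count")]]
    pcol <- st[[paste0(sets[[s]]$table$name, "_p")]]
    for (i in seq_along(coll$pathways)) {
      expect_identical(cnt[i], sum(coll$pathways[[i]]$genes %in% genes))
    }
    expect_true(all(pcol >= 0 & pcol <= 1))
    expect_true(all(cnt <= st$n_genes))
    adj <- st[[paste0(sets[[s]]$table$name, "_p_adj")]]
    expect_identical(adj, p.adjust(pcol, method = "BH"))
  }

  # empty set: k = 0 everywhere, p = 1, with a warning about the universe
  fe <- write_tmp_lines(c("#Gene\tv", "ZZZ_UNKNOWN\t1"))
  empty <- normalize_annotation(attach_icon(parse_annotation_file(fe, name = "none"), "pill"),
                                nm, coll$universe)$set
  expect_warning(st2 <- build_summary_table(coll, list(empty),
                                            with_enrichment = TRUE),
                 "no genes")
  expect_true(all(st2$none_count == 0L))
  expect_true(all(st2$none_p == 1))

  expect_error(build_summary_table(pathway_collection(list()), list()),
               class = "po_input_error")
})

test_that("sorting is stable, idempotent and reverses on distinct keys", {
  paths <- list(pathway("A", genes = c("g1", "g2")),
                pathway("B", genes = c("g3", "g4")),
                pathway("C", genes = "g5"),
                pathway("D", genes = c("g6", "g7", "g8")))
  st <- build_summary_table(pathway_collection(paths))

  s1 <- sort_table(st, "n_genes", "desc")
  # ties (A, B both 2) keep original order under a stable sort
  expect_identical(s1$pathway_id, c("D", "A", "B", "C"))
  expect_identical(sort_table(s1, "n_genes", "desc")$pathway_id, s1$pathway_id)

  # ascending then descending is an exact reversal iff keys are distinct
  s_asc <- sort_table(st, "pathway_id", "asc")
  s_desc <- sort_table(st, "pathway_id", "desc")
  expect_identical(s_desc$pathway_id, rev(s_asc$pathway_id))

  # oracle comparison on an extracted column
  s2 <- sort_table(st, "pathway_id", "desc")
  expect_identical(s2$pathway_id, sort(st$pathway_id, decreasing = TRUE))

  expect_identical(attr(s1, "sort_state")[["column"]], "n_genes")
  expect_error(sort_table(st, "nope"), class = "po_input_error")
})
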