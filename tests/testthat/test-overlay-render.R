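test_that("icon registry accepts builtin glyphs and raster images only", {
  reg <- icon_registry()
  expect_true(all(builtin_icons() %in% names(reg$icons)))

  reg <- register_icon(reg, "mut", "circle")
  expect_identical(get_icon(reg, "mut")$kind, "builtin")

  png_path <- withr::local_tempfile(fileext = ".png")
  # tiny 1x1 PNG written from raw bytes
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a,
                    0x00, 0x00, 0x00, 0x0d, 0x49, 0x48, 0x44, 0x52,
                    0x00, 0x00, 0x00, 0x01, 0x00, 0x00, 0x00, 0x01,
                    0x08, 0x06, 0x00, 0x00, 0x00, 0x1f, 0x15, 0xc4,
                    0x89, 0x00, 0x00, 0x00, 0x0d, 0x49, 0x44, 0x41,
                    0x54, 0x78, 0x9c, 0x62, 0x00, 0x01, 0x00, 0x00,
                    0x05, 0x00, 0x01, 0x0d, 0x0a, 0x2d, 0xb4, 0x00,
                    0x00, 0x00, 0x00, 0x49, 0x45, 0x4e, 0x44, 0xae,
                    0x42, 0x60, 0x82)), png_path)
  reg <- register_icon(reg, "custom", png_path)
  asset <- get_icon(reg, "custom")
  expect_identical(asset$kind, "user-image")
  expect_identical(asset$format, "png")

  # re-registering replaces
  reg <- register_icon(reg, "custom", "star")
  expect_identical(get_icon(reg, "custom")$kind, "builtin")

  bmp <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", bmp)
  expect_error(register_icon(reg, "bad", bmp), class = "po_config_error")
  expect_null(get_icon(reg, "unknown"))
})

test_that("compute_overlay records one hit per (node, set) with all rows", {
  inp <- mini_overlay_inputs()
  doc <- compute_overlay(inp$topology, inp$sets)

  # brute-force double loop over (node, set)
  want <- 0L
  for (i in seq_len(nrow(inp$topology$nodes))) {
    for (s in inp$sets) {
      if (length(intersect(inp$topology$nodes$genes[[i]],
                           annotation_genes(s))) > 0L) want <- want + 1L
    }
  }
  expect_identical(overlay_hit_count(doc), want)

  # CDK4/6 node is in both sets -> exactly two hits there
  cdk_node <- doc$overlays[[which(vapply(doc$overlays, function(o)
    "CDK4" %in% o$genes, logical(1L)))]]
  expect_length(cdk_node$hits, 2L)
  expect_identical(vapply(cdk_node$hits, function(h) h$set_name, character(1L)),
                   c("mutations", "drugs"))

  # the ATP node never receives hits
  expect_false("n4" %in% vapply(doc$overlays, function(o) o$node_id, character(1L)))

  # zero sets -> empty overlays and legend
  doc0 <- compute_overlay(inp$topology, list())
  expect_identical(overlay_hit_count(doc0), 0L)
  expect_identical(nrow(doc0$legend), 0L)

  # legend lists every loaded set exactly once, in load order
  expect_identical(doc$legend$set_name, c("mutations", "drugs"))
})

test_that("rendered SVG conserves icons, is well-formed and deterministic", {
  inp <- mini_overlay_inputs()
  doc <- compute_overlay(inp$topology, inp$sets)
  svg <- render_svg(doc)

  x <- xml2::read_xml(svg)  # well-formed XML or this throws
  icons <- xml2::xml_find_all(x, "//*[@class='icon']")
  expect_length(icons, overlay_hit_count(doc))
  tips <- xml2::xml_find_all(x, "//*[@class='tooltip']")
  expect_length(tips, overlay_hit_count(doc))

  # byte-identical on a full re-run from the same inputs
  inp2 <- mini_overlay_inputs()
  svg2 <- render_svg(compute_overlay(inp2$topology, inp2$sets))
  expect_identical(svg, svg2)

  # zero hits -> zero icon elements
  doc0 <- compute_overlay(inp$topology, list())
  x0 <- xml2::read_xml(render_svg(doc0))
  expect_length(xml2::xml_find_all(x0, "//*[@class='icon']"), 0L)

  # unregistered icon fails before any output
  bad <- doc
  bad$legend$icon[1L] <- "missing-icon"
  expect_error(render_svg(bad), class = "po_config_error")
})

test_that("gene labels hyperlink via the URL template and tooltips carry rows", {
  inp <- mini_overlay_inputs()
  doc <- compute_overlay(inp$topology, inp$sets)
  svg <- render_svg(doc)
  x <- xml2::read_xml(svg)
  xml2::xml_ns_strip(x)

  hrefs <- xml2::xml_attr(xml2::xml_find_all(x, "//a"), "href")
  expect_true("https://www.genecards.org/cgi-bin/carddisp.pl?gene=TP53" %in% hrefs)
  # non-gene node gets no link
  expect_length(hrefs, 3L)

  # custom template is substituted
  doc2 <- compute_overlay(inp$topology, inp$sets,
                          link_template = "https://example.org/g/{gene}")
  h2 <- xml2::xml_attr(xml2::xml_find_all(
    {y <- xml2::read_xml(render_svg(doc2)); xml2::xml_ns_strip(y); y}, "//a"),
    "href")
  expect_true("https://example.org/g/TP53" %in% h2)

  # the mutations tooltip on TP53 shows header names and the data row
  titles <- xml2::xml_text(xml2::xml_find_all(x, "//*[@class='icon']/title"))
  tp53_tip <- titles[grepl("^mutations", titles) & grepl("TP53", titles)]
  expect_match(tp53_tip, "Gene | variant | VAF", fixed = TRUE)
  expect_match(tp53_tip, "p.R175H", fixed = TRUE)
})

test_that("HTML output is self-contained with one tooltip block per hit", {
  inp <- mini_overlay_inputs()
  doc <- compute_overlay(inp$topology, inp$sets)
  html <- render_html(doc)
  expect_match(html, "^<!DOCTYPE html>")
  parsed <- xml2::read_html(html)
  tips <- xml2::xml_find_all(parsed, "//*[@class='tooltip']")
  expect_length(tips, overlay_hit_count(doc))
  expect_false(grepl("<script", html, fixed = TRUE))

  # a 2-row gene aggregates both rows into its one tooltip
  f <- write_tmp_lines(c("#Gene\tnote", "TP53\tfirst", "TP53\tsecond"))
  set <- normalize_annotation(
    attach_icon(parse_annotation_file(f, name = "notes"), "square"),
    inp$norm, "TP53")$set
  doc2 <- compute_overlay(inp$topology, list(set))
  expect_identical(overlay_hit_count(doc2), 1L)
  svg2 <- render_svg(doc2)
  x2 <- xml2::read_xml(svg2)
  xml2::xml_ns_strip(x2)
  title <- xml2::xml_text(xml2::xml_find_first(x2, "//*[@class='icon']/title"))
  expect_match(title, "first")
  expect_match(title, "second")

  html0 <- render_html(compute_overlay(inp$topology, list()))
  expect_length(xml2::xml_find_all(xml2::read_html(html0),
                                   "//*[@class='tooltip']"), 0L)
})
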