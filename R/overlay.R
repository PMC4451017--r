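#' Builtin icon glyph names
#'
#' Simple vector glyphs shipped with the package; any of these names
#' can be assigned to an annotation set without registering an image.
#' @return Character vector of glyph names.
#' @export
builtin_icons <- function() {
  c("pill", "circle", "square", "diamond", "triangle", "star", "drop", "flag")
}

#' Create an icon registry
#'
#' The registry maps icon names to assets: builtin vector glyphs or
#' user-supplied raster images (`.png`, `.jpg`/`.jpeg`, `.gif` only).
#'
#' @return An object of class `icon_registry` pre-populated with the
#'   builtin glyphs.
#' @export
icon_registry <- function() {
  icons <- lapply(builtin_icons(), function(nm) {
    list(name = nm, kind = "builtin", format = NA_character_, source = nm)
  })
  structure(list(icons = stats::setNames(icons, builtin_icons())),
            class = "icon_registry")
}

#' Register an icon
#'
#' Adds a builtin glyph alias or a user image to the registry.
#' Re-registering an existing name replaces it. Image uploads are
#' restricted to the raster formats png, jpg and gif; anything else
#' (svg, bmp, ...) is rejected.
#'
#' @param registry An [icon_registry()].
#' @param name Name under which the icon is retrievable.
#' @param source A builtin glyph name, or a path to an image file.
#' @return The updated registry.
#' @export
register_icon <- function(registry, name, source) {
  stopifnot(inherits(registry, "icon_registry"))
  if (source %in% builtin_icons()) {
    asset <- list(name = name, kind = "builtin", format = NA_character_,
                  source = source)
  } else {
    ext <- tolower(tools::file_ext(source))
    if (!(ext %in% c("png", "jpg", "jpeg", "gif"))) {
      po_config_error("icon '%s': format '.%s' not allowed (use .png, .jpg or .gif)",
                      name, ext)
    }
    if (!file.exists(source)) {
      po_config_error("icon '%s': file '%s' not found", name, source)
    }
    asset <- list(name = name, kind = "user-image",
                  format = if (ext == "jpeg") "jpg" else ext, source = source)
  }
  registry$icons[[name]] <- asset
  registry
}

#' Look up an icon asset
#' @param registry An [icon_registry()].
#' @param name Icon name.
#' @return The asset, or `NULL` when unknown.
#' @export
get_icon <- function(registry, name) {
  if (length(name) != 1L || is.na(name)) return(NULL)
  registry$icons[[name]]
}

#' Join annotation sets onto a pathway topology
#'
#' For every gene-bearing node and every annotation set that annotates
#' at least one of the node's genes, one *hit* is recorded carrying the
#' set's icon and all matching annotation rows (a gene with several
#' rows yields one hit whose tooltip aggregates them). Non-gene nodes
#' never receive hits. The legend lists every loaded set exactly once,
#' in load order, whether or not it produced hits.
#'
#' @param topology A `pathway_topology`.
#' @param sets List of normalized `annotation_set`s, in load order.
#' @param link_template Gene-page URL template; `{gene}` is replaced by
#'   the approved symbol. Defaults to the GeneCards display page.
#' @return An object of class `overlay_document`: `topology`,
#'   `overlays` (per gene node with hits: `node_id`, `genes`, `hits`),
#'   `legend` (data frame `icon`, `set_name`), `link_template`.
#' @export
compute_overlay <- function(topology, sets = list(),
                            link_template = "https://www.genecards.org/cgi-bin/carddisp.pl?gene={gene}") {
  stopifnot(inherits(topology, "pathway_topology"))
  for (set in sets) {
    if (!isTRUE(set$normalized)) {
      po_input_error("annotation set '%s' has not been normalized", set$table$name)
    }
  }
  set_names <- vapply(sets, function(s) s$table$name, character(1L))
  overlays <- list()
  for (i in seq_len(nrow(topology$nodes))) {
    node_genes <- topology$nodes$genes[[i]]
    if (length(node_genes) == 0L) next
    hits <- list()
    for (s in seq_along(sets)) {
      set <- sets[[s]]
      matched <- intersect(node_genes, annotation_genes(set))
      if (length(matched) == 0L) next
      rows <- unlist(set$gene_index[matched], use.names = FALSE)
      hits[[length(hits) + 1L]] <- list(
        set_name = set_names[s],
        icon = set$icon,
        header = set$table$columns,
        rows = set$table$data[sort(rows), , drop = FALSE]
      )
    }
    if (length(hits) > 0L) {
      overlays[[length(overlays) + 1L]] <- list(
        node_id = topology$nodes$node_id[i],
        genes = node_genes,
        hits = hits
      )
    }
  }
  legend <- data.frame(
    icon = vapply(sets, function(s) s$icon, character(1L)),
    set_name = set_names,
    stringsAsFactors = FALSE
  )
  structure(
    list(topology = topology, overlays = overlays, legend = legend,
         link_template = link_template),
    class = "overlay_document"
  )
}

#' Total hits in an overlay document
#' @param doc An `overlay_document`.
#' @return Integer: number of (node, set) hits.
#' @export
overlay_hit_count <- function(doc) {
  sum(vapply(doc$overlays, function(o) length(o$hits), integer(1L)))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

# Fixed decimal formatting keeps the output byte-stable across platforms.
fmt_num <- function(v) {
  s <- sprintf("%.2f", v)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

default_render_options <- function() {
  list(icon_size = 14, icons_per_row = 4, margin = 20,
       legend_width = 160, font_size = 11,
       background_size = NULL)
}

# Vector glyph for a builtin icon, drawn inside the (x, y, size) box.
builtin_glyph_svg <- function(glyph, x, y, size) {
  cx <- x + size / 2; cy <- y + size / 2; r <- size / 2 - 1
  f <- fmt_num
  switch(glyph,
    circle = sprintf('<circle cx="%s" cy="%s" r="%s" fill="#c23b3b" stroke="#5a1414"/>',
                     f(cx), f(cy), f(r)),
    square = sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="#2e6db4" stroke="#12355c"/>',
                     f(x + 1), f(y + 1), f(size - 2), f(size - 2)),
    diamond = sprintf('<polygon points="%s,%s %s,%s %s,%s %s,%s" fill="#3a9d5d" stroke="#14502a"/>',
                      f(cx), f(y + 1), f(x + size - 1), f(cy), f(cx), f(y + size - 1), f(x + 1), f(cy)),
    triangle = sprintf('<polygon points="%s,%s %s,%s %s,%s" fill="#d98a2b" stroke="#6e4312"/>',
                       f(cx), f(y + 1), f(x + size - 1), f(y + size - 1), f(x + 1), f(y + size - 1)),
    star = sprintf('<polygon points="%s,%s %s,%s %s,%s %s,%s %s,%s" fill="#caa52c" stroke="#665213"/>',
                   f(cx), f(y + 1), f(x + size - 1), f(y + size - 1), f(x + 1), f(y + 0.38 * size),
                   f(x + size - 1), f(y + 0.38 * size), f(x + 1), f(y + size - 1)),
    drop = sprintf('<ellipse cx="%s" cy="%s" rx="%s" ry="%s" fill="#4aa3c7" stroke="#1d4f63"/>',
                   f(cx), f(cy + 1), f(r * 0.7), f(r)),
    flag = sprintf('<polygon points="%s,%s %s,%s %s,%s" fill="#8a4fb0" stroke="#40235c"/><line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#40235c"/>',
                   f(x + 3), f(y + 1), f(x + size - 1), f(y + 0.3 * size), f(x + 3), f(y + 0.6 * size),
                   f(x + 3), f(y + 1), f(x + 3), f(y + size - 1)),
    # default: the pill — two-tone capsule
    sprintf(paste0('<rect x="%s" y="%s" width="%s" height="%s" rx="%s" fill="#e8e8e8" stroke="#555"/>',
                   '<rect x="%s" y="%s" width="%s" height="%s" fill="#c23b3b"/>'),
            f(x + 1), f(y + size * 0.28), f(size - 2), f(size * 0.44), f(size * 0.22),
            f(x + 1 + (size - 2) / 2), f(y + size * 0.28 + 1), f((size - 2) / 2 - 1), f(size * 0.44 - 2))
  )
}

icon_svg <- function(asset, x, y, size) {
  if (asset$kind == "builtin") {
    builtin_glyph_svg(asset$source, x, y, size)
  } else {
    mime <- c(png = "image/png", jpg = "image/jpeg", gif = "image/gif")[[asset$format]]
    b64 <- jsonlite::base64_enc(readBin(asset$source, "raw",
                                        n = file.info(asset$source)$size))
    b64 <- gsub("[\r\n]", "", b64)
    sprintf('<image x="%s" y="%s" width="%s" height="%s" xlink:href="data:%s;base64,%s"/>',
            fmt_num(x), fmt_num(y), fmt_num(size), fmt_num(size), mime, b64)
  }
}

#' Render an overlay document to SVG
#'
#' Emits a static SVG 1.1 diagram: one box and label per node (labels
#' of gene nodes hyperlink to the gene page), one icon element per
#' (node, set) hit in a strip anchored at the node's top-right corner
#' (left-to-right in set load order, wrapping after a fixed number of
#' icons), a hidden tooltip block per hit that becomes visible on
#' hover (pure CSS, no scripts), and a legend pairing each loaded
#' set with its icon. The output is deterministic: identical inputs
#' give byte-identical SVG.
#'
#' @param doc An `overlay_document` from [compute_overlay()].
#' @param registry Icon registry resolving the legend's icon names.
#' @param options Named list overriding the default rendering geometry:
#'   `icon_size`, `icons_per_row`, `margin`, `legend_width`,
#'   `font_size`, `background_size`.
#' @return A single string of SVG markup.
#' @export
render_svg <- function(doc, registry = icon_registry(), options = list()) {
  stopifnot(inherits(doc, "overlay_document"))
  opt <- utils::modifyList(default_render_options(), options)
  needed <- unique(c(doc$legend$icon,
                     unlist(lapply(doc$overlays, function(o)
                       vapply(o$hits, function(h) h$icon, character(1L))),
                       use.names = FALSE)))
  for (nm in needed) {
    if (is.null(get_icon(registry, nm))) {
      po_config_error("icon '%s' is not registered", nm)
    }
  }

  nd <- doc$topology$nodes
  isz <- opt$icon_size
  # content bounding box (nodes are centred on x,y) plus icon headroom
  if (nrow(nd) > 0L) {
    x0 <- min(nd$x - nd$width / 2); y0 <- min(nd$y - nd$height / 2) - 2 * isz
    x1 <- max(nd$x + nd$width / 2) + opt$icons_per_row * isz
    y1 <- max(nd$y + nd$height / 2)
  } else {
    x0 <- 0; y0 <- 0; x1 <- 0; y1 <- 0
  }
  ox <- opt$legend_width + opt$margin - x0   # content offset
  oy <- opt$margin - y0
  width <- opt$legend_width + opt$margin * 2 + (x1 - x0)
  height <- max(opt$margin * 2 + (y1 - y0),
                opt$margin * 2 + nrow(doc$legend) * (isz + 8) + 20)

  out <- character()
  emit <- function(...) out[[length(out) + 1L]] <<- sprintf(...)
  emit('<svg xmlns="http://www.w3.org/2000/svg" xmlns:xlink="http://www.w3.org/1999/xlink" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
       fmt_num(width), fmt_num(height), fmt_num(width), fmt_num(height))
  emit('<style>.tooltip{visibility:hidden;}.hit:hover .tooltip{visibility:visible;}text{font-family:Helvetica,Arial,sans-serif;}</style>')
  emit('<rect x="0" y="0" width="%s" height="%s" fill="#ffffff"/>',
       fmt_num(width), fmt_num(height))

  # legend: every loaded set once, icon + name, top-left
  emit('<g class="legend">')
  emit('<text x="%s" y="%s" font-size="%s" font-weight="bold">Annotation sets</text>',
       fmt_num(opt$margin), fmt_num(opt$margin), fmt_num(opt$font_size + 1))
  for (i in seq_len(nrow(doc$legend))) {
    ly <- opt$margin + 8 + (i - 1L) * (isz + 8)
    asset <- get_icon(registry, doc$legend$icon[i])
    emit('<g class="legend-entry">%s<text x="%s" y="%s" font-size="%s">%s</text></g>',
         icon_svg(asset, opt$margin, ly, isz),
         fmt_num(opt$margin + isz + 6), fmt_num(ly + isz - 3),
         fmt_num(opt$font_size), xml_escape(doc$legend$set_name[i]))
  }
  emit('</g>')

  emit('<g class="pathway">')
  if (!is.null(doc$topology$background_image)) {
    bg <- doc$topology$background_image
    sz <- opt$background_size
    if (is.null(sz)) sz <- c(x1 - x0, y1 - y0)
    emit('<image x="%s" y="%s" width="%s" height="%s" xlink:href="%s"/>',
         fmt_num(x0 + ox), fmt_num(y0 + oy), fmt_num(sz[1]), fmt_num(sz[2]),
         xml_escape(bg))
  }

  # edges beneath nodes
  node_at <- stats::setNames(seq_len(nrow(nd)), nd$node_id)
  ed <- doc$topology$edges
  for (j in seq_len(nrow(ed))) {
    a <- node_at[[ed$source[j]]]; b <- node_at[[ed$target[j]]]
    emit('<line class="edge" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#999999"/>',
         fmt_num(nd$x[a] + ox), fmt_num(nd$y[a] + oy),
         fmt_num(nd$x[b] + ox), fmt_num(nd$y[b] + oy))
  }

  # node boxes and labels (gene labels hyperlink out)
  for (i in seq_len(nrow(nd))) {
    bx <- nd$x[i] - nd$width[i] / 2 + ox
    by <- nd$y[i] - nd$height[i] / 2 + oy
    emit('<g class="node" id="node-%s">', xml_escape(nd$node_id[i]))
    emit('<rect x="%s" y="%s" width="%s" height="%s" fill="#eef3ea" stroke="#3c5a3c"/>',
         fmt_num(bx), fmt_num(by), fmt_num(nd$width[i]), fmt_num(nd$height[i]))
    label <- sprintf('<text x="%s" y="%s" font-size="%s" text-anchor="middle">%s</text>',
                     fmt_num(nd$x[i] + ox),
                     fmt_num(nd$y[i] + oy + opt$font_size / 2 - 1),
                     fmt_num(opt$font_size), xml_escape(nd$label[i]))
    if (length(nd$genes[[i]]) > 0L) {
      url <- gsub("{gene}", nd$genes[[i]][1L], doc$link_template, fixed = TRUE)
      emit('<a xlink:href="%s" target="_blank">%s</a>', xml_escape(url), label)
    } else {
      emit('%s', label)
    }
    emit('</g>')
  }

  # hits: icon strip at each node's top-right corner, plus its tooltip
  for (o in doc$overlays) {
    i <- node_at[[o$node_id]]
    ax <- nd$x[i] + nd$width[i] / 2 + ox  # strip anchor
    ay <- nd$y[i] - nd$height[i] / 2 + oy - isz
    for (h in seq_along(o$hits)) {
      hit <- o$hits[[h]]
      col <- (h - 1L) %% opt$icons_per_row
      row <- (h - 1L) %/% opt$icons_per_row
      ix <- ax + col * isz
      iy <- ay - row * isz
      tip_lines <- c(sprintf("%s — %s", hit$set_name, paste(o$genes, collapse = ", ")),
                     paste(hit$header, collapse = " | "),
                     if (nrow(hit$rows) > 0L)
                       do.call(paste, c(unname(as.list(hit$rows)), sep = " | ")))
      emit('<g class="hit">')
      emit('<g class="icon"><title>%s</title>%s</g>',
           xml_escape(paste(tip_lines, collapse = "\n")),
           icon_svg(get_icon(registry, hit$icon), ix, iy, isz))
      tw <- max(nchar(tip_lines)) * opt$font_size * 0.62 + 12
      th <- length(tip_lines) * (opt$font_size + 4) + 8
      tx <- min(ix + isz + 4, width - tw - 2)
      ty <- max(iy - th / 2, 2)
      tip <- sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="#d9d9d9" stroke="#666666"/>',
                     fmt_num(tx), fmt_num(ty), fmt_num(tw), fmt_num(th))
      for (l in seq_along(tip_lines)) {
        tip <- paste0(tip, sprintf('<text x="%s" y="%s" font-size="%s">%s</text>',
                                   fmt_num(tx + 6),
                                   fmt_num(ty + l * (opt$font_size + 4)),
                                   fmt_num(opt$font_size),
                                   xml_escape(tip_lines[l])))
      }
      emit('<g class="tooltip">%s</g>', tip)
      emit('</g>')
    }
  }
  emit('</g>')
  emit('</svg>')
  paste(out, collapse = "\n")
}

#' Render an overlay document to a self-contained HTML page
#'
#' Wraps the SVG of [render_svg()] in a minimal HTML5 document. The
#' hover tooltips are pure CSS, so the page works offline in any
#' browser with no script or network dependency.
#'
#' @inheritParams render_svg
#' @param title Page title.
#' @return A single string of HTML markup.
#' @export
render_html <- function(doc, registry = icon_registry(), options = list(),
                        title = "Pathway viewer") {
  svg <- render_svg(doc, registry = registry, options = options)
  paste(
    "<!DOCTYPE html>",
    '<html lang="en">',
    "<head>",
    '<meta charset="utf-8"/>',
    sprintf("<title>%s</title>", xml_escape(title)),
    "<style>body{margin:12px;background:#fafafa;}</style>",
    "</head>",
    "<body>",
    svg,
    "</body>",
    "</html>",
    sep = "\n"
  )
}
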