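#' @title Deterministic layered layout and diagram rendering
#'
#' @description
#' Diagrams use a simple Reingold-Tilford-style tree layout: support depth
#' defines the horizontal layer (root topmost, y growing downward), each
#' parent is centred over the span of its supporting children, siblings
#' keep insertion order left-to-right, and context-family attachments sit
#' in the same vertical band as their source, to its right. Subtrees under
#' collapsed nodes are omitted. The layout is a pure function of the
#' graph, so equal graphs always render byte-identically.
#'
#' @name gsn-render
NULL

CHAR_W <- 7      # canvas units per character
LINE_H <- 14     # canvas units per text line
PAD <- 10        # inner padding of a shape
H_GAP <- 24      # horizontal gap between sibling subtrees
CTX_GAP <- 16    # gap between a node and its context attachments
V_GAP <- 46      # vertical gap between layers
MARGIN <- 20

wrap_statement <- function(text, width) {
  out <- strwrap(text, width = width)
  if (length(out) == 0) out <- ""
  out
}

# wrapped lines + box size for one node
node_box_geom <- function(n) {
  wrap_w <- if (n$kind == "evidence") 16 else 26
  lines <- wrap_statement(n$statement, wrap_w)
  if (n$kind == "assumption") lines <- c(lines, "[A]")
  if (n$kind == "justification") lines <- c(lines, "[J]")
  has_label <- nzchar(n$label)
  n_lines <- length(lines) + as.integer(has_label)
  maxchars <- max(nchar(c(lines, if (has_label) n$label else character())))
  w <- max(70, maxchars * CHAR_W + 2 * PAD)
  h <- max(40, n_lines * LINE_H + 2 * PAD)
  if (n$kind == "strategy") w <- w + 18          # room for the skew
  if (n$kind == "evidence") {                     # circle: inscribe the text
    d <- ceiling(sqrt(w^2 + h^2))
    w <- h <- d
  }
  list(lines = lines, width = w, height = h, has_label = has_label)
}

# uids hidden by collapsed ancestors (the collapsed node itself stays)
hidden_uids <- function(g) {
  hidden <- character()
  # context attachments of a collapsed node remain visible; only nodes
  # below it in the support tree (and their attachments) are hidden
  walk2 <- function(uid) {
    if (isTRUE(g$nodes[[uid]]$collapsed)) {
      for (kid in children_of(g, uid, "supported_by")) mark_all(kid)
    } else {
      for (kid in children_of(g, uid, "supported_by")) walk2(kid)
    }
  }
  mark_all <- function(uid) {
    hidden <<- c(hidden, uid)
    for (kid in children_of(g, uid)) mark_all(kid)
  }
  walk2(g$root)
  unique(hidden)
}

#' Compute a diagram layout for an argument graph
#'
#' @param g A well-formed `gsn_graph`.
#' @return A `gsn_layout`: list with `boxes` (data frame `uid`, `x`, `y`,
#'   `width`, `height`; y grows downward), `width` and `height` of the
#'   canvas. Nodes hidden under collapsed ancestors have no box.
#' @export
gsn_layout <- function(g) {
  stopifnot(inherits(g, "gsn_graph"))
  stop_unless_wellformed(g)
  hidden <- hidden_uids(g)
  geom <- lapply(g$nodes, node_box_geom)

  vis_children <- function(uid, kind) setdiff(children_of(g, uid, kind), hidden)

  # unit = node plus its context attachments, laid out horizontally
  unit_width <- function(uid) {
    w <- geom[[uid]]$width
    for (cu in vis_children(uid, "in_context_of")) {
      w <- w + CTX_GAP + geom[[cu]]$width
    }
    w
  }
  subtree_width <- function(uid) {
    kids <- vis_children(uid, "supported_by")
    kw <- if (length(kids))
      sum(vapply(kids, subtree_width, numeric(1))) + H_GAP * (length(kids) - 1)
    else 0
    max(unit_width(uid), kw)
  }

  # support depth of every visible node (context nodes share their source's)
  depth <- integer()
  assign_depth <- function(uid, d) {
    depth[[uid]] <<- d
    for (cu in vis_children(uid, "in_context_of")) depth[[cu]] <<- d
    for (kid in vis_children(uid, "supported_by")) assign_depth(kid, d + 1L)
  }
  assign_depth(g$root, 1L)

  n_layers <- max(depth)
  band_h <- vapply(seq_len(n_layers), function(d) {
    max(vapply(names(depth)[depth == d], function(u) geom[[u]]$height,
               numeric(1)))
  }, numeric(1))
  band_top <- MARGIN + cumsum(c(0, utils::head(band_h + V_GAP, -1)))

  boxes <- list()
  place <- function(uid, x0) {
    w <- subtree_width(uid)
    uw <- unit_width(uid)
    ux <- x0 + (w - uw) / 2
    y <- band_top[depth[[uid]]]
    boxes[[uid]] <<- c(x = ux, y = y,
                       width = geom[[uid]]$width, height = geom[[uid]]$height)
    cx <- ux + geom[[uid]]$width
    for (cu in vis_children(uid, "in_context_of")) {
      boxes[[cu]] <<- c(x = cx + CTX_GAP, y = band_top[depth[[cu]]],
                        width = geom[[cu]]$width, height = geom[[cu]]$height)
      cx <- cx + CTX_GAP + geom[[cu]]$width
    }
    kids <- vis_children(uid, "supported_by")
    if (length(kids)) {
      kw <- sum(vapply(kids, subtree_width, numeric(1))) +
        H_GAP * (length(kids) - 1)
      x <- x0 + (w - kw) / 2
      for (kid in kids) {
        place(kid, x)
        x <- x + subtree_width(kid) + H_GAP
      }
    }
  }
  place(g$root, MARGIN)

  df <- data.frame(
    uid = names(boxes),
    x = vapply(boxes, `[[`, numeric(1), "x"),
    y = vapply(boxes, `[[`, numeric(1), "y"),
    width = vapply(boxes, `[[`, numeric(1), "width"),
    height = vapply(boxes, `[[`, numeric(1), "height"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    boxes = df,
    width = max(df$x + df$width) + MARGIN,
    height = max(df$y + df$height) + MARGIN
  ), class = "gsn_layout")
}

fmt <- function(x) sprintf("%.1f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

svg_diamond <- function(cx, cy, r, filled) {
  sprintf('<polygon points="%s,%s %s,%s %s,%s %s,%s" fill="%s" stroke="black" stroke-width="1"/>',
          fmt(cx), fmt(cy - r), fmt(cx + r), fmt(cy), fmt(cx), fmt(cy + r),
          fmt(cx - r), fmt(cy), if (filled) "black" else "white")
}

svg_node_shape <- function(n, b) {
  x <- b["x"]; y <- b["y"]; w <- b["width"]; h <- b["height"]
  common <- 'fill="white" stroke="black" stroke-width="1.5"'
  switch(n$kind,
    goal = sprintf('<rect x="%s" y="%s" width="%s" height="%s" %s/>',
                   fmt(x), fmt(y), fmt(w), fmt(h), common),
    strategy = {
      s <- 14
      sprintf('<polygon points="%s,%s %s,%s %s,%s %s,%s" %s/>',
              fmt(x + s), fmt(y), fmt(x + w), fmt(y),
              fmt(x + w - s), fmt(y + h), fmt(x), fmt(y + h), common)
    },
    context = sprintf('<rect x="%s" y="%s" width="%s" height="%s" rx="12" ry="12" %s/>',
                      fmt(x), fmt(y), fmt(w), fmt(h), common),
    assumption = ,
    justification = sprintf('<ellipse cx="%s" cy="%s" rx="%s" ry="%s" %s/>',
                            fmt(x + w / 2), fmt(y + h / 2),
                            fmt(w / 2), fmt(h / 2), common),
    evidence = sprintf('<circle cx="%s" cy="%s" r="%s" %s/>',
                       fmt(x + w / 2), fmt(y + h / 2), fmt(w / 2), common)
  )
}

svg_node_text <- function(n, b, geom) {
  lines <- geom$lines
  if (geom$has_label) lines <- c(n$label, lines)
  n_lines <- length(lines)
  cx <- b["x"] + b["width"] / 2
  top <- b["y"] + b["height"] / 2 - (n_lines - 1) * LINE_H / 2
  spans <- vapply(seq_along(lines), function(i) {
    style <- if (geom$has_label && i == 1) ' font-weight="bold"' else ""
    sprintf('<tspan x="%s" y="%s"%s>%s</tspan>', fmt(cx),
            fmt(top + (i - 1) * LINE_H + 4), style, xml_escape(lines[i]))
  }, character(1))
  sprintf('<text text-anchor="middle" font-family="Helvetica" font-size="11">%s</text>',
          paste(spans, collapse = ""))
}

#' Render an argument diagram as SVG
#'
#' Glyph conventions: goal = rectangle, strategy = parallelogram, context =
#' rounded rectangle, assumption/justification = ellipse tagged `[A]`/`[J]`,
#' evidence = circle; `supported_by` edges end in a solid (filled)
#' arrowhead, `in_context_of` edges in an open (white) arrowhead; an
#' undeveloped goal carries a small open diamond below it and a collapsed
#' node a small filled diamond. Node labels are shown in bold above the
#' statement; evidence hyperlinks are emitted as SVG links wrapping the
#' node group. Output is byte-identical for equal inputs.
#'
#' @param g A well-formed `gsn_graph`.
#' @param layout A `gsn_layout`, by default computed from `g`.
#' @param path Optional file to write the SVG to.
#' @return SVG text, invisibly when `path` is given.
#' @export
gsn_render_svg <- function(g, layout = gsn_layout(g), path = NULL) {
  stopifnot(inherits(g, "gsn_graph"), inherits(layout, "gsn_layout"))
  hidden <- hidden_uids(g)
  visible <- setdiff(names(g$nodes), hidden)
  missing <- setdiff(visible, layout$boxes$uid)
  if (length(missing)) {
    abort_invalid(sprintf("layout has no box for visible node(s): %s",
                          paste(missing, collapse = ", ")))
  }
  bx <- layout$boxes
  rownames(bx) <- bx$uid
  box <- function(uid) {
    r <- bx[uid, ]
    c(x = r$x, y = r$y, width = r$width, height = r$height)
  }

  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" xmlns:xlink="http://www.w3.org/1999/xlink" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt(layout$width), fmt(layout$height),
            fmt(layout$width), fmt(layout$height)),
    '<defs>',
    '<marker id="arrow-solid" markerWidth="10" markerHeight="8" refX="9" refY="4" orient="auto"><path d="M0,0 L10,4 L0,8 z" fill="black"/></marker>',
    '<marker id="arrow-open" markerWidth="10" markerHeight="8" refX="9" refY="4" orient="auto"><path d="M0,0 L10,4 L0,8 z" fill="white" stroke="black" stroke-width="1"/></marker>',
    '</defs>',
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="white"/>',
            fmt(layout$width), fmt(layout$height))
  )

  for (e in g$edges) {
    if (e$source %in% hidden || e$target %in% hidden) next
    if (!(e$source %in% visible) || !(e$target %in% visible)) next
    s <- box(e$source); t <- box(e$target)
    if (e$kind == "supported_by") {
      line <- sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1.2" marker-end="url(#arrow-solid)"/>',
                      fmt(s["x"] + s["width"] / 2), fmt(s["y"] + s["height"]),
                      fmt(t["x"] + t["width"] / 2), fmt(t["y"]))
    } else {
      line <- sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1.2" marker-end="url(#arrow-open)"/>',
                      fmt(s["x"] + s["width"]), fmt(s["y"] + s["height"] / 2),
                      fmt(t["x"]), fmt(t["y"] + t["height"] / 2))
    }
    out <- c(out, line)
  }

  for (uid in sort(visible, method = "radix")) {
    n <- g$nodes[[uid]]
    b <- box(uid)
    geom <- node_box_geom(n)
    grp <- c(sprintf('<g id="%s">', xml_escape(uid)),
             svg_node_shape(n, b),
             svg_node_text(n, b, geom))
    if (n$kind == "goal" && n$status == "undeveloped") {
      grp <- c(grp, svg_diamond(b["x"] + b["width"] / 2,
                                b["y"] + b["height"] + 8, 7, filled = FALSE))
    }
    if (isTRUE(n$collapsed)) {
      grp <- c(grp, svg_diamond(b["x"] + b["width"] / 2,
                                b["y"] + b["height"] + 8, 7, filled = TRUE))
    }
    grp <- c(grp, '</g>')
    if (length(n$links)) {
      grp <- c(sprintf('<a xlink:href="%s">', xml_escape(n$links[[1]])),
               grp, '</a>')
    }
    out <- c(out, grp)
  }

  txt <- paste0(paste(c(out, "</svg>"), collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(txt)), con)
    return(invisible(txt))
  }
  txt
}

draw_png_node <- function(n, b, geom) {
  x <- b["x"]; y <- b["y"]; w <- b["width"]; h <- b["height"]
  switch(n$kind,
    goal = graphics::rect(x, y, x + w, y + h),
    strategy = {
      s <- 14
      graphics::polygon(c(x + s, x + w, x + w - s, x),
                        c(y, y, y + h, y + h))
    },
    context = graphics::rect(x, y, x + w, y + h),   # rounded in SVG only
    assumption = ,
    justification = {
      th <- seq(0, 2 * pi, length.out = 60)
      graphics::polygon(x + w / 2 + w / 2 * cos(th),
                        y + h / 2 + h / 2 * sin(th))
    },
    evidence = {
      th <- seq(0, 2 * pi, length.out = 60)
      graphics::polygon(x + w / 2 + w / 2 * cos(th),
                        y + h / 2 + h / 2 * sin(th))
    })
  lines <- geom$lines
  if (geom$has_label) lines <- c(n$label, lines)
  n_lines <- length(lines)
  top <- y + h / 2 - (n_lines - 1) * LINE_H / 2
  for (i in seq_along(lines)) {
    graphics::text(x + w / 2, top + (i - 1) * LINE_H, lines[i], cex = 0.75)
  }
}

#' Render an argument diagram as a PNG image
#'
#' Rasterizes the same drawing as [gsn_render_svg()] at the requested
#' scale; the image is `ceiling(canvas width x scale)` by
#' `ceiling(canvas height x scale)` pixels. Output is pixel-identical
#' across runs on one platform.
#'
#' @param g A well-formed `gsn_graph`.
#' @param path Output PNG path.
#' @param scale Positive magnification factor (pixels per canvas unit).
#' @param layout A `gsn_layout`, by default computed from `g`.
#' @return `path`, invisibly.
#' @export
gsn_render_png <- function(g, path, scale = 1, layout = gsn_layout(g)) {
  stopifnot(inherits(g, "gsn_graph"), inherits(layout, "gsn_layout"))
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0) {
    abort_invalid("scale must be a single positive number")
  }
  hidden <- hidden_uids(g)
  visible <- setdiff(names(g$nodes), hidden)
  missing <- setdiff(visible, layout$boxes$uid)
  if (length(missing)) {
    abort_invalid(sprintf("layout has no box for visible node(s): %s",
                          paste(missing, collapse = ", ")))
  }
  w_px <- ceiling(layout$width * scale)
  h_px <- ceiling(layout$height * scale)
  grDevices::png(path, width = w_px, height = h_px, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  # y axis flipped: canvas y grows downward
  graphics::plot.window(xlim = c(0, w_px / scale),
                        ylim = c(h_px / scale, 0))

  bx <- layout$boxes
  rownames(bx) <- bx$uid
  box <- function(uid) {
    r <- bx[uid, ]
    c(x = r$x, y = r$y, width = r$width, height = r$height)
  }
  for (e in g$edges) {
    if (!(e$source %in% visible) || !(e$target %in% visible)) next
    s <- box(e$source); t <- box(e$target)
    if (e$kind == "supported_by") {
      graphics::segments(s["x"] + s["width"] / 2, s["y"] + s["height"],
                         t["x"] + t["width"] / 2, t["y"])
    } else {
      graphics::segments(s["x"] + s["width"], s["y"] + s["height"] / 2,
                         t["x"], t["y"] + t["height"] / 2)
    }
  }
  diamond <- function(cx, cy, r, filled) {
    graphics::polygon(c(cx, cx + r, cx, cx - r), c(cy - r, cy, cy + r, cy),
                      col = if (filled) "black" else "white")
  }
  for (uid in sort(visible, method = "radix")) {
    n <- g$nodes[[uid]]
    b <- box(uid)
    draw_png_node(n, b, node_box_geom(n))
    if (n$kind == "goal" && n$status == "undeveloped") {
      diamond(b["x"] + b["width"] / 2, b["y"] + b["height"] + 8, 7, FALSE)
    }
    if (isTRUE(n$collapsed)) {
      diamond(b["x"] + b["width"] / 2, b["y"] + b["height"] + 8, 7, TRUE)
    }
  }
  invisible(path)
}
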