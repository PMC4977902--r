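# Palette version string written into exports; bump when colors change
# so snapshot bytes stay test-stable across releases.
PALETTE_VERSION <- "cpmsim-palette-1"

#' Deterministic lattice palette
#'
#' Hex colors for ECM and every spin index. ECM is grey. With two cells
#' the dark cell is dark red and the light cell light blue. With more
#' cells, odd (dark) spins take red-to-purple tones and even (light)
#' spins blue-to-green tones, interpolated deterministically so renders
#' are byte-stable.
#'
#' @param max_sigma Number of cells.
#' @return Named character vector of hex colors: `"0"` (ECM) through
#'   `as.character(max_sigma)`, with attribute `"version"`.
#' @export
cpm_palette <- function(max_sigma) {
  max_sigma <- as.integer(max_sigma)
  cols <- character(max_sigma + 1L)
  names(cols) <- as.character(0L:max_sigma)
  cols["0"] <- "#BEBEBE" # grey ECM
  if (max_sigma >= 1L) {
    odd <- seq.int(1L, max_sigma, by = 2L)
    even <- if (max_sigma >= 2L) seq.int(2L, max_sigma, by = 2L) else integer(0)
    if (max_sigma <= 2L) {
      cols[as.character(odd)] <- "#8B0000"  # darkred
      if (length(even)) cols[as.character(even)] <- "#ADD8E6" # lightblue
    } else {
      dark_ramp <- grDevices::colorRampPalette(c("#8B0000", "#800080"))
      light_ramp <- grDevices::colorRampPalette(c("#ADD8E6", "#2E8B57"))
      cols[as.character(odd)] <- toupper(dark_ramp(length(odd)))
      if (length(even)) {
        cols[as.character(even)] <- toupper(light_ramp(length(even)))
      }
    }
  }
  attr(cols, "version") <- PALETTE_VERSION
  cols
}

#' Export a trajectory as CSV
#'
#' Writes the table of [as.data.frame.cpm_trajectory()] — header row then
#' one row per recorded step — as plain comma-separated values ("."
#' decimal mark, UTF-8). Undefined dark/light ratios are written as empty
#' fields.
#'
#' @param trajectory A `cpm_trajectory`.
#' @param destination Output file path.
#' @return `destination`, invisibly.
#' @export
export_csv <- function(trajectory, destination) {
  df <- as.data.frame(trajectory)
  utils::write.csv(df, destination, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(destination)
}

#' Read a trajectory CSV back into its table
#'
#' Round-trip companion to [export_csv()].
#'
#' @param path Path to a CSV written by [export_csv()].
#' @return The trajectory data frame.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
}

# Graph-elements document for a lattice state (shared by the JSON
# export and any renderer). Node ids are "x_y" with 0-based column (x)
# and row (y) indices; positions are pixel coordinates at a fixed pitch.
graph_doc <- function(state, params, pitch = 20L, edges = FALSE) {
  g <- state$grid
  ny <- nrow(g)
  nx <- ncol(g)
  pal <- cpm_palette(params$max_sigma)
  idx <- expand.grid(row = seq_len(ny), col = seq_len(nx))
  sigma <- g[cbind(idx$row, idx$col)]
  x0 <- idx$col - 1L
  y0 <- idx$row - 1L
  nodes <- lapply(seq_along(sigma), function(i) {
    s <- sigma[i]
    list(
      data = list(
        id = paste0(x0[i], "_", y0[i]),
        sigma = s,
        tau_class = sigma_class(s),
        color = unname(pal[as.character(s)]),
        parent = if (s == 0L) "ecm" else paste0("cell_", s)
      ),
      position = list(x = x0[i] * pitch, y = y0[i] * pitch)
    )
  })
  edge_list <- list()
  if (edges) {
    np <- neighbour_pairs(state)
    same <- np[np$same_cell == 1L & np$sigma_a > 0L, , drop = FALSE]
    edge_list <- lapply(seq_len(nrow(same)), function(i) {
      list(data = list(source = same$site_a[i], target = same$site_b[i]))
    })
  }
  list(
    format = "cpm-graph-elements",
    layout = list(name = "grid", rows = ny, cols = nx, pitch = pitch),
    style = list(palette = PALETTE_VERSION),
    elements = list(nodes = nodes, edges = edge_list)
  )
}

#' Export a lattice state as a graph-elements JSON document
#'
#' One node per lattice site with id (`"x_y"`, 0-based column/row),
#' pixel position on a fixed-pitch grid, hex color from [cpm_palette()],
#' spin, cell class and parent cell key — the structure a grid-layout
#' graph renderer (e.g. Cytoscape.js) consumes. Optionally includes edges
#' between adjacent same-cell bricks (off by default).
#'
#' @param state A `cpm_state`.
#' @param params A [sim_params()] object.
#' @param destination Output file path.
#' @param pitch Pixel distance between adjacent node centres.
#' @param edges Include same-cell adjacency edges.
#' @return `destination`, invisibly.
#' @export
export_graph_json <- function(state, params, destination, pitch = 20L,
                              edges = FALSE) {
  doc <- graph_doc(state, params, pitch = pitch, edges = edges)
  jsonlite::write_json(doc, destination, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(destination)
}

#' Render a lattice snapshot as PNG
#'
#' One square block of `scale` x `scale` pixels per lattice site, colored
#' with [cpm_palette()] (grey ECM, dark-red/purple dark cells,
#' light-blue/green light cells). Output bytes are a deterministic
#' function of the state and palette version.
#'
#' @param state A `cpm_state`.
#' @param params A [sim_params()] object.
#' @param destination Output PNG path.
#' @param scale Pixels per lattice site (default 8).
#' @return `destination`, invisibly.
#' @export
render_snapshot <- function(state, params, destination, scale = 8L) {
  scale <- as.integer(scale)
  if (scale < 1L) stop("scale must be >= 1", call. = FALSE)
  pal <- cpm_palette(params$max_sigma)
  rgb <- grDevices::col2rgb(pal) / 255
  g <- state$grid
  big <- g[rep(seq_len(nrow(g)), each = scale),
           rep(seq_len(ncol(g)), each = scale), drop = FALSE]
  img <- array(0, dim = c(nrow(big), ncol(big), 3L))
  for (ch in 1:3) {
    img[, , ch] <- matrix(rgb[ch, big + 1L], nrow(big), ncol(big))
  }
  png::writePNG(img, destination)
  invisible(destination)
}
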