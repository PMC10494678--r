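#' Build the displacement graph for one biennium
#'
#' Directed, simple graph: one node per municipality appearing in the OD
#' table (positioned at its seat coordinates), one weighted edge per distinct
#' origin -> destination pair (weight = flow). Node colour encodes the
#' municipality's macroregion, edge colour the origin's macroregion, per the
#' fixed palette [MACROREGION_COLORS]. Each node carries its in-degree (the
#' number of distinct municipalities it serves) and inflow (admissions of
#' non-residents it received).
#'
#' @param od OD table ([aggregate_od()]); must contain a single biennium,
#'   or use `biennium` to select one.
#' @param registry Municipality registry.
#' @param biennium Optional biennium label (e.g. `"2018-2019"`) to filter
#'   `od` by before building.
#' @return An `igraph` object with vertex attributes `name` (code as
#'   character), `label` (municipality name), `lat`, `lon`, `macroregion`,
#'   `color`, `in_degree`, `inflow`, `is_destination`, edge attributes
#'   `weight` and `color`, and graph attribute `biennium`.
#' @examples
#' reg <- generate_registry(synth_params(n_regions = 2, munis_per_region = 3))
#' od <- tibble::tibble(origin_code = reg$code[2:3],
#'                      destination_code = reg$code[1],
#'                      biennium_label = "2008-2009", biennium_index = 1L,
#'                      flow = c(3L, 1L))
#' g <- build_graph(od, reg)
#' inflow(g, reg$code[1])
#' @export
build_graph <- function(od, registry, biennium = NULL) {
  stop_if_not_df_with(od, c("origin_code", "destination_code",
                            "biennium_label", "flow"), "od")
  check_registry(registry)
  if (!is.null(biennium)) {
    od <- od[od$biennium_label == biennium, , drop = FALSE]
  }
  labels <- unique(od$biennium_label)
  if (length(labels) > 1L) {
    stop("OD table spans several biennia; pass `biennium` to select one",
         call. = FALSE)
  }
  bad <- setdiff(c(od$origin_code, od$destination_code), registry$code)
  if (length(bad)) {
    stop("OD endpoints absent from the registry: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(od$origin_code == od$destination_code)) {
    stop("self-loops are not displacements", call. = FALSE)
  }

  codes <- sort(unique(c(od$origin_code, od$destination_code)))
  verts <- registry[match(codes, registry$code), ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(od$origin_code),
               to = as.character(od$destination_code),
               weight = od$flow),
    directed = TRUE,
    vertices = data.frame(
      name = as.character(codes),
      label = verts$name,
      lat = verts$seat_lat,
      lon = verts$seat_lon,
      macroregion = verts$macroregion,
      color = unname(MACROREGION_COLORS[verts$macroregion])
    )
  )
  igraph::E(g)$color <- unname(
    MACROREGION_COLORS[verts$macroregion[match(od$origin_code, codes)]]
  )
  igraph::V(g)$in_degree <- igraph::degree(g, mode = "in")
  igraph::V(g)$inflow <- igraph::strength(g, mode = "in")
  igraph::V(g)$is_destination <- igraph::V(g)$in_degree > 0L
  g <- igraph::set_graph_attr(g, "biennium",
                              if (length(labels)) labels else NA_character_)
  g
}

lookup_vertex <- function(graph, municipality) {
  i <- match(as.character(municipality), igraph::V(graph)$name)
  if (anyNA(i)) {
    stop("municipality ", paste(municipality[is.na(i)], collapse = ", "),
         " is not a node of the graph", call. = FALSE)
  }
  i
}

#' In-degree of a destination municipality
#'
#' Number of distinct municipalities whose residents were hospitalized at
#' `municipality` (one per incoming edge, regardless of flow size).
#'
#' @param graph A displacement graph from [build_graph()].
#' @param municipality Municipality code(s); must be nodes of the graph.
#' @return Integer vector.
#' @export
in_degree <- function(graph, municipality) {
  unname(igraph::V(graph)$in_degree[lookup_vertex(graph, municipality)])
}

#' Inflow of a destination municipality
#'
#' Total admissions at `municipality` of residents of other municipalities
#' (sum of incoming edge flows).
#'
#' @inheritParams in_degree
#' @return Numeric vector.
#' @export
inflow <- function(graph, municipality) {
  unname(igraph::V(graph)$inflow[lookup_vertex(graph, municipality)])
}

# all-node metric table for one graph
graph_metrics <- function(graph) {
  tibble::tibble(
    code = as.integer(igraph::V(graph)$name),
    in_degree = igraph::V(graph)$in_degree,
    inflow = as.numeric(igraph::V(graph)$inflow)
  )
}

#' Compare the most frequent destinations of two biennia
#'
#' Selects the destinations to report — all region seats plus any
#' municipality whose inflow reaches `inflow_threshold` in either biennium —
#' and tabulates in-degree and inflow in each biennium together with their
#' percent variation ([percent_variation()]). A destination absent from a
#' biennium's graph counts 0 there, and its percent variation from a zero
#' baseline is reported missing.
#'
#' @param graph_a,graph_b Displacement graphs of the earlier (A) and later
#'   (B) biennium, over the same registry.
#' @param registry Municipality registry.
#' @param inflow_threshold Minimum inflow, in either biennium, for a
#'   non-seat municipality to be listed (default 100).
#' @return A tibble sorted by macroregion, region and descending later-
#'   biennium inflow, with columns `code`, `name`, `region_id`,
#'   `macroregion`, `is_region_seat`, `in_degree_a`, `in_degree_b`,
#'   `vp_in_degree`, `inflow_a`, `inflow_b`, `vp_inflow`.
#' @export
rank_destinations <- function(graph_a, graph_b, registry,
                              inflow_threshold = 100) {
  check_registry(registry)
  ma <- graph_metrics(graph_a)
  mb <- graph_metrics(graph_b)
  m <- dplyr::full_join(ma, mb, by = "code", suffix = c("_a", "_b"))
  for (cl in c("in_degree_a", "in_degree_b", "inflow_a", "inflow_b")) {
    m[[cl]][is.na(m[[cl]])] <- 0
  }
  sel <- registry$code[registry$is_region_seat]
  sel <- union(sel, m$code[m$inflow_a >= inflow_threshold |
                             m$inflow_b >= inflow_threshold])
  out <- tibble::tibble(code = sel)
  out <- dplyr::left_join(out, m, by = "code")
  for (cl in c("in_degree_a", "in_degree_b", "inflow_a", "inflow_b")) {
    out[[cl]][is.na(out[[cl]])] <- 0
  }
  out <- dplyr::left_join(
    out,
    registry[, c("code", "name", "region_id", "macroregion", "is_region_seat")],
    by = "code"
  )
  out$vp_in_degree <- suppressWarnings(
    percent_variation(out$in_degree_a, out$in_degree_b)
  )
  out$vp_inflow <- suppressWarnings(
    percent_variation(out$inflow_a, out$inflow_b)
  )
  out <- out[order(out$macroregion, out$region_id, -out$inflow_b), ]
  out[, c("code", "name", "region_id", "macroregion", "is_region_seat",
          "in_degree_a", "in_degree_b", "vp_in_degree",
          "inflow_a", "inflow_b", "vp_inflow")]
}

# GEXF ----------------------------------------------------------------------

gexf_num <- function(x) sprintf("%.17g", x)

gexf_node_attrs <- c(lat = "double", lon = "double", macroregion = "string",
                     color = "string", in_degree = "integer",
                     inflow = "double", is_destination = "boolean")

#' Export / import a displacement graph
#'
#' `export_graph()` writes a graph losslessly in one of three formats:
#' `"gexf"` (GEXF 1.2, with node positions, colours, in-degree and inflow as
#' declared attributes — openable in Gephi), `"graphml"` (via igraph) or
#' `"csv"` (flat edge list `origin,destination,biennium,flow`).
#' `import_graph()` reads the GEXF and GraphML files back into an igraph
#' object with the same node and edge attributes; for `"csv"` it returns the
#' edge-list tibble.
#'
#' @param graph A graph from [build_graph()].
#' @param path Output file path.
#' @param format One of `"gexf"`, `"graphml"`, `"csv"`.
#' @return `export_graph()`: `path`, invisibly. `import_graph()`: an igraph
#'   object (or a tibble for `"csv"`).
#' @export
export_graph <- function(graph, path, format = c("gexf", "graphml", "csv")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop("unsupported graph format: ", format[1], call. = FALSE)
  })
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  if (format == "csv") {
    el <- igraph::as_data_frame(graph, what = "edges")
    readr::write_csv(tibble::tibble(
      origin = as.integer(el$from),
      destination = as.integer(el$to),
      biennium = igraph::graph_attr(graph, "biennium"),
      flow = el$weight
    ), path)
    return(invisible(path))
  }

  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2"
  )
  gr <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed")
  bi <- igraph::graph_attr(graph, "biennium")
  if (!is.null(bi) && !is.na(bi)) xml2::xml_set_attr(gr, "label", bi)

  natts <- xml2::xml_add_child(gr, "attributes", class = "node")
  for (i in seq_along(gexf_node_attrs)) {
    xml2::xml_add_child(natts, "attribute", id = names(gexf_node_attrs)[i],
                        title = names(gexf_node_attrs)[i],
                        type = gexf_node_attrs[[i]])
  }
  eatts <- xml2::xml_add_child(gr, "attributes", class = "edge")
  xml2::xml_add_child(eatts, "attribute", id = "color", title = "color",
                      type = "string")

  nodes <- xml2::xml_add_child(gr, "nodes")
  v <- igraph::as_data_frame(graph, what = "vertices")
  for (i in seq_len(nrow(v))) {
    nd <- xml2::xml_add_child(nodes, "node", id = v$name[i],
                              label = v$label[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    vals <- c(lat = gexf_num(v$lat[i]), lon = gexf_num(v$lon[i]),
              macroregion = v$macroregion[i], color = v$color[i],
              in_degree = as.character(v$in_degree[i]),
              inflow = gexf_num(v$inflow[i]),
              is_destination = tolower(as.character(v$is_destination[i])))
    for (nm in names(vals)) {
      xml2::xml_add_child(av, "attvalue", "for" = nm, value = vals[[nm]])
    }
  }

  edges <- xml2::xml_add_child(gr, "edges")
  e <- igraph::as_data_frame(graph, what = "edges")
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                              source = e$from[i], target = e$to[i],
                              weight = gexf_num(e$weight[i]))
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "color", value = e$color[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("gexf", "graphml", "csv")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop("unsupported graph format: ", format[1], call. = FALSE)
  })
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  if (format == "csv") {
    return(readr::read_csv(path, col_types = readr::cols(
      origin = readr::col_integer(), destination = readr::col_integer(),
      biennium = readr::col_character(), flow = readr::col_double()
    )))
  }

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//nodes/node")
  get_att <- function(node_set, key) {
    vapply(node_set, function(nd) {
      av <- xml2::xml_find_first(nd, sprintf(".//attvalue[@for='%s']", key))
      xml2::xml_attr(av, "value")
    }, character(1))
  }
  vd <- data.frame(
    name = xml2::xml_attr(nodes, "id"),
    label = xml2::xml_attr(nodes, "label"),
    lat = as.numeric(get_att(nodes, "lat")),
    lon = as.numeric(get_att(nodes, "lon")),
    macroregion = get_att(nodes, "macroregion"),
    color = get_att(nodes, "color"),
    in_degree = as.integer(get_att(nodes, "in_degree")),
    inflow = as.numeric(get_att(nodes, "inflow")),
    is_destination = get_att(nodes, "is_destination") == "true",
    stringsAsFactors = FALSE
  )
  edges <- xml2::xml_find_all(doc, ".//edges/edge")
  ed <- data.frame(
    from = xml2::xml_attr(edges, "source"),
    to = xml2::xml_attr(edges, "target"),
    weight = as.numeric(xml2::xml_attr(edges, "weight")),
    color = get_att(edges, "color"),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    if (nrow(ed)) ed else data.frame(from = character(), to = character(),
                                     weight = numeric(), color = character()),
    directed = TRUE, vertices = vd
  )
  lab <- xml2::xml_attr(xml2::xml_find_first(doc, ".//graph"), "label")
  igraph::set_graph_attr(g, "biennium",
                         if (is.na(lab)) NA_character_ else lab)
}
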