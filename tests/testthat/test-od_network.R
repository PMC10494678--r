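make_two_region_graph <- function() {
  reg <- manual_registry(
    codes = c(11, 12, 21, 22),
    region = c(1, 1, 2, 2),
    lat = c(0, 0.1, 0.5, 0.6), lon = c(0, 0.1, 0.5, 0.6)
  )
  od <- tibble::tibble(
    origin_code = c(12L, 21L, 22L),
    destination_code = c(11L, 11L, 21L),
    biennium_label = "2008-2009", biennium_index = 1L,
    flow = c(3L, 1L, 2L)
  )
  list(reg = reg, od = od, graph = build_graph(od, reg))
}

test_that("graph nodes carry in-degree, inflow, position and macroregion colors", {
  x <- make_two_region_graph()
  g <- x$graph
  expect_equal(in_degree(g, 11), 2L)
  expect_equal(inflow(g, 11), 4)
  expect_equal(in_degree(g, 22), 0L)
  expect_equal(inflow(g, 22), 0)
  expect_false(any(igraph::which_loop(g)))

  v <- igraph::as_data_frame(g, what = "vertices")
  expect_equal(v$lat[v$name == "11"], x$reg$seat_lat[x$reg$code == 11])
  expect_equal(v$color[v$name == "11"], unname(MACROREGION_COLORS["leste"]))
  expect_equal(v$color[v$name == "21"], unname(MACROREGION_COLORS["oeste"]))
  e <- igraph::as_data_frame(g, what = "edges")
  # edge color follows the origin municipality's macroregion
  expect_equal(e$color[e$from == "21"], unname(MACROREGION_COLORS["oeste"]))
  expect_equal(e$color[e$from == "12"], unname(MACROREGION_COLORS["leste"]))
  expect_equal(igraph::graph_attr(g, "biennium"), "2008-2009")

  expect_error(in_degree(g, 999), "not a node")
  expect_error(build_graph(x$od, x$reg[-4, ]), "absent from the registry")
  expect_error(build_graph(dplyr::mutate(x$od, destination_code = origin_code),
                           x$reg), "self-loops")
})

test_that("an empty pair set yields a valid empty graph", {
  x <- make_two_region_graph()
  g <- build_graph(x$od[0, ], x$reg)
  expect_equal(igraph::vcount(g), 0L)
  expect_equal(igraph::ecount(g), 0L)
})

test_that("flow is conserved and the build is a pure function of its inputs", {
  reg <- generate_registry(small_params())
  od <- random_od(reg, 120, seed = 5L, n_biennia = 1L)
  g <- build_graph(od, reg)
  expect_equal(igraph::ecount(g), nrow(od))
  expect_equal(sum(igraph::V(g)$inflow), sum(od$flow))
  expect_equal(sum(igraph::strength(g, mode = "out")), sum(od$flow))
  expect_true(all(igraph::V(g)$in_degree <= nrow(reg) - 1L))
  # brute-force in-degree/inflow recount
  for (code in sample(unique(od$destination_code), 5)) {
    sel <- od$destination_code == code
    expect_equal(in_degree(g, code), length(unique(od$origin_code[sel])))
    expect_equal(inflow(g, code), sum(od$flow[sel]))
  }
  expect_true(igraph::identical_graphs(g, build_graph(od, reg)))

  expect_error(build_graph(random_od(reg, 40, seed = 6L, n_biennia = 2L), reg),
               "several biennia")
})

test_that("destination ranking reports both biennia with percent variations", {
  reg <- manual_registry(
    codes = c(11, 12, 13, 21, 22),
    region = c(1, 1, 1, 2, 2),
    lat = c(0, 0.1, 0.2, 0.5, 0.6), lon = c(0, 0.1, 0.2, 0.5, 0.6)
  )
  od_a <- tibble::tibble(
    origin_code =      c(12L, 13L, 21L, 13L),
    destination_code = c(11L, 11L, 11L, 12L),
    biennium_label = "2008-2009", biennium_index = 1L,
    flow = c(200L, 100L, 80L, 40L)
  )
  od_b <- tibble::tibble(
    origin_code =      c(12L, 13L, 21L, 22L, 11L, 13L),
    destination_code = c(11L, 11L, 11L, 11L, 12L, 12L),
    biennium_label = "2018-2019", biennium_index = 6L,
    flow = c(1000L, 800L, 500L, 271L, 300L, 312L)
  )
  rk <- rank_destinations(build_graph(od_a, reg), build_graph(od_b, reg), reg,
                          inflow_threshold = 100)
  # seats always listed; 12 crosses the threshold in B
  expect_setequal(rk$code, c(11L, 21L, 12L))
  r11 <- rk[rk$code == 11L, ]
  expect_equal(r11$inflow_a, 380)
  expect_equal(r11$inflow_b, 2571)
  expect_equal(r11$vp_inflow, 576.58, tolerance = 1e-4)
  r12 <- rk[rk$code == 12L, ]
  expect_equal(r12$in_degree_a, 1)
  expect_equal(r12$in_degree_b, 2)
  expect_equal(r12$vp_in_degree, 100)
  # seat 21 receives nothing in either biennium: zero baseline, missing VP
  r21 <- rk[rk$code == 21L, ]
  expect_equal(r21$inflow_a, 0)
  expect_equal(r21$inflow_b, 0)
  expect_true(is.na(r21$vp_inflow))
})

test_that("GEXF and GraphML exports round-trip attributes and total flow", {
  reg <- generate_registry(small_params())
  od <- random_od(reg, 100, seed = 9L, n_biennia = 1L)
  g <- build_graph(od, reg)

  for (fmt in c("gexf", "graphml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(g, path, fmt)
    g2 <- import_graph(path, fmt)
    expect_equal(igraph::vcount(g2), igraph::vcount(g))
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
    expect_equal(sum(igraph::E(g2)$weight), sum(igraph::E(g)$weight))
    v1 <- igraph::as_data_frame(g, what = "vertices")
    v2 <- igraph::as_data_frame(g2, what = "vertices")
    v2 <- v2[match(v1$name, v2$name), ]
    for (att in c("lat", "lon", "macroregion", "color", "in_degree",
                  "inflow", "is_destination")) {
      expect_equal(unname(v2[[att]]), unname(v1[[att]]), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
    e1 <- igraph::as_data_frame(g, what = "edges")
    e2 <- igraph::as_data_frame(g2, what = "edges")
    e2 <- e2[match(paste(e1$from, e1$to), paste(e2$from, e2$to)), ]
    expect_equal(e2$weight, e1$weight)
    if (fmt == "gexf") {
      expect_equal(e2$color, e1$color)
      expect_equal(igraph::graph_attr(g2, "biennium"),
                   igraph::graph_attr(g, "biennium"))
    }
  }
})

test_that("edge-list CSV export carries origin, destination, biennium and flow", {
  x <- make_two_region_graph()
  path <- withr::local_tempfile(fileext = ".csv")
  export_graph(x$graph, path, "csv")
  el <- import_graph(path, "csv")
  expect_equal(nrow(el), 3L)
  expect_equal(sum(el$flow), sum(x$od$flow))
  expect_equal(unique(el$biennium), "2008-2009")
})

test_that("empty graphs export to valid documents and bad formats error", {
  x <- make_two_region_graph()
  empty <- build_graph(x$od[0, ], x$reg)
  path <- withr::local_tempfile(fileext = ".gexf")
  export_graph(empty, path, "gexf")
  g2 <- import_graph(path, "gexf")
  expect_equal(igraph::vcount(g2), 0L)
  expect_error(export_graph(x$graph, path, "dot"), "unsupported")
  expect_error(import_graph(path, "pajek"), "unsupported")
})
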