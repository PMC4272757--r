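mock_stats <- function(left, right, mean_delta, endpoint = "act",
                       kind = "continuous") {
  n <- length(left)
  data.frame(transformation = paste0("T", seq_len(n)), endpoint = endpoint,
             left = left, right = right, n_cuts = 1L, N = 10L,
             n_pos = 10L, n_neg = 0L, npos_after = NA_integer_,
             mean_delta = mean_delta, p_value = 1e-4,
             significance_level = 4, holm_significant = TRUE,
             significant = TRUE, provenance_class = "experimental",
             kind = kind)
}

test_that("the transformation graph points toward increasing property", {
  st <- mock_stats(left = c("[*:1]Cl", "[*:1]Cl", "[*:1]Cl"),
                   right = c("[*:1]Br", "[*:1]O", "[*:1]N"),
                   mean_delta = c(0.8, -1.2, 0.3))
  g <- build_graph(st)
  expect_equal(igraph::ecount(g), 3L)       # one edge per transformation
  expect_equal(igraph::vcount(g), 4L)
  deg <- igraph::degree(g, mode = "all")
  expect_equal(unname(deg[names(deg) == "[*:1]Cl"]), 3)
  # the negative-delta edge is reversed: it runs toward the chloro fragment
  ends <- igraph::as_edgelist(g)
  rev_edge <- ends[igraph::E(g)$transformation == "T2", ]
  expect_equal(rev_edge[1], "[*:1]O")
  expect_equal(rev_edge[2], "[*:1]Cl")
  expect_true(all(igraph::E(g)$effect >= 0))
})

test_that("graph building validates input and handles emptiness", {
  st <- mock_stats("[*:1]C", "[*:1]O", 1.0)
  st2 <- st; st2$endpoint <- "other"
  expect_error(build_graph(rbind(st, st2)), "mix endpoints")
  empty <- st[st$mean_delta > 99, ]
  expect_equal(igraph::ecount(build_graph(empty)), 0L)
  # exports are written and re-readable
  g <- build_graph(st)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  dot <- withr::local_tempfile(fileext = ".dot")
  export_graph(g, dot, "dot")
  expect_true(any(grepl("->", readLines(dot))))
})

test_that("binary graphs orient toward the higher active fraction", {
  st <- mock_stats("[*:1]C", "[*:1]O", NA_real_, kind = "binary")
  st$n_pos <- 8L; st$npos_after <- 1L; st$N <- 10L
  g <- build_graph(st)
  ends <- igraph::as_edgelist(g)
  expect_equal(ends[1], "[*:1]O")  # deactivating: edge runs right -> left
  expect_equal(ends[2], "[*:1]C")
})

delta_fixture <- function(de, dp) {
  n <- length(de)
  pairs <- data.frame(mol_a = paste0("a", 1:n), mol_b = paste0("b", 1:n),
                      pair_group = paste0("g", 1:n), sign = 1L)
  ep <- normalize_endpoints(rbind(
    data.frame(id = pairs$mol_a, endpoint = "act", kind = "continuous",
               value = "0", source = "experimental", uncertainty = 0,
               in_domain = TRUE),
    data.frame(id = pairs$mol_b, endpoint = "act", kind = "continuous",
               value = as.character(de), source = "experimental",
               uncertainty = 0, in_domain = TRUE),
    data.frame(id = pairs$mol_a, endpoint = "act", kind = "continuous",
               value = "0", source = "predicted", uncertainty = 0.1,
               in_domain = TRUE),
    data.frame(id = pairs$mol_b, endpoint = "act", kind = "continuous",
               value = as.character(dp), source = "predicted",
               uncertainty = 0.1, in_domain = TRUE)))
  list(pairs = pairs, endpoints = ep)
}

test_that("delta-pair rows land in the documented quadrants", {
  fx <- delta_fixture(de = c(1.5, 1.5, 0.1, -2.0, -0.4),
                      dp = c(1.4, -1.2, -0.1, -1.1, 0.9))
  rows <- delta_pair_table(fx$pairs, fx$endpoints, "act",
                           cliff_threshold = 1.0)
  rows <- rows[order(rows$pair_group), ]
  expect_equal(rows$quadrant, c(1L, 4L, 4L, 3L, 2L))
  expect_equal(rows$is_mispredicted_cliff, c(FALSE, TRUE, FALSE, FALSE,
                                             FALSE))
  # ordering is by decreasing absolute experimental effect
  rows2 <- delta_pair_table(fx$pairs, fx$endpoints, "act")
  expect_true(all(diff(abs(rows2$experimental_delta)) <= 0))
})

test_that("zero deltas sit on an axis in the lower adjacent quadrant", {
  fx <- delta_fixture(de = c(0, 0, 2, -2), dp = c(1.5, -1.5, 0, 0))
  rows <- delta_pair_table(fx$pairs, fx$endpoints, "act")
  rows <- rows[order(rows$pair_group), ]
  expect_equal(rows$quadrant, c(1L, 3L, 1L, 2L))
  expect_true(all(rows$on_axis))
})

test_that("flipping every pair maps quadrants 1<->3 and 2<->4 row-for-row", {
  fx <- delta_fixture(de = c(1.5, -1.2, 0.7, -0.3, 2.2),
                      dp = c(1.1, 1.3, -0.8, -0.9, 2.0))
  rows <- delta_pair_table(fx$pairs, fx$endpoints, "act")
  flipped_pairs <- fx$pairs
  flipped_pairs$sign <- -1L
  flipped <- delta_pair_table(flipped_pairs, fx$endpoints, "act")
  m <- match(rows$pair_group, flipped$pair_group)
  remap <- c(`1` = 3L, `2` = 4L, `3` = 1L, `4` = 2L)
  expect_equal(unname(remap[as.character(rows$quadrant)]),
               flipped$quadrant[m])
  expect_equal(rows$experimental_delta, -flipped$experimental_delta[m])
})

test_that("pairs missing either delta are skipped and counted", {
  fx <- delta_fixture(de = c(1, 2), dp = c(1, 2))
  ep <- fx$endpoints
  ep <- ep[!(ep$id == "b2" & ep$source == "predicted"), ]
  rows <- delta_pair_table(fx$pairs, ep, "act")
  expect_equal(nrow(rows), 1L)
  expect_equal(attr(rows, "n_skipped"), 1L)
})
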