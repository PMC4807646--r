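test_that("graph invariants are enforced and violations are named", {
  ord <- block_ordering(list(
    list(variable_spec("y1", 0, "response"), variable_spec("y2", 0, "response")),
    list(variable_spec("x1", 0, "response"), variable_spec("x2", 0, "response"))),
    c("response", "response"))

  empty <- regression_graph(ord)
  expect_length(validate_graph(empty, ord), 0)

  bad_dir <- regression_graph(ord, arrows = rbind(c("y1", "x1")),
                              validate = FALSE)
  v <- validate_graph(bad_dir, ord)
  expect_length(v, 1)
  expect_equal(v[[1]]$rule, "arrow direction")

  bad_dash <- regression_graph(ord, dashed = rbind(c("y1", "x1")),
                               validate = FALSE)
  v <- validate_graph(bad_dash, ord)
  expect_length(v, 1)
  expect_equal(v[[1]]$rule, "dashed cross-box")

  expect_error(regression_graph(ord, arrows = rbind(c("y1", "x1"))),
               "arrow")
  expect_error(anterior_set(empty, "nope"), "unknown node")
})

test_that("anterior sets close under ancestry and full lines", {
  g <- chain_graph()
  expect_setequal(anterior_set(g, "A"), c("A", "B", "Cc"))
  expect_setequal(anterior_set(g, "Cc"), "Cc")
  # idempotence
  expect_setequal(anterior_set(g, anterior_set(g, "A")),
                  anterior_set(g, "A"))

  set.seed(421)
  for (i in 1:25) {
    g <- random_block_graph(8)
    seeds <- sample(g$nodes, sample(1:3, 1))
    a <- anterior_set(g, seeds)
    expect_setequal(a, bf_anterior(g, seeds))
    expect_setequal(anterior_set(g, a), a)               # idempotent
    bigger <- union(seeds, sample(g$nodes, 1))
    expect_true(all(a %in% anterior_set(g, bigger)))     # monotone
  }
})

test_that("m-separation handles chains, colliders and argument errors", {
  g <- chain_graph()
  expect_true(m_separated(g, "A", "Cc", "B"))
  expect_false(m_separated(g, "A", "Cc", character(0)))

  ord <- block_ordering(list(
    list(variable_spec("Z", 0, "response")),
    list(variable_spec("A", 0, "response"), variable_spec("B", 0, "response"))),
    c("response", "response"))
  coll <- regression_graph(ord, arrows = rbind(c("A", "Z"), c("B", "Z")))
  expect_true(m_separated(coll, "A", "B", character(0)))
  expect_false(m_separated(coll, "A", "B", "Z"))

  expect_error(m_separated(g, "A", "A", character(0)), "differ")
  expect_error(m_separated(g, "A", "B", "A"), "conditioning")
})

test_that("m-separation agrees with path-enumeration on random graphs and is symmetric", {
  set.seed(1234)
  for (i in 1:30) {
    g <- random_block_graph(sample(5:8, 1))
    for (q in 1:20) {
      xy <- sample(g$nodes, 2)
      rest <- setdiff(g$nodes, xy)
      C <- if (length(rest)) sample(rest, sample(0:min(2, length(rest)), 1))
           else character(0)
      s <- m_separated(g, xy[1], xy[2], C)
      expect_identical(s, bf_m_separated(g, xy[1], xy[2], C))
      expect_identical(s, m_separated(g, xy[2], xy[1], C))
    }
  }
})

test_that("adding an edge never creates a new separation", {
  set.seed(77)
  tried <- 0
  for (i in 1:40) {
    g <- random_block_graph(6, p_edge = 0.3)
    # candidate extra arrow between boxes
    bx <- g$box
    cand <- NULL
    for (a in g$nodes) for (b in g$nodes) {
      if (bx[[a]] > bx[[b]] &&
          !any(g$arrows[, 1] == a & g$arrows[, 2] == b))
        cand <- rbind(cand, c(a, b))
    }
    if (is.null(cand)) next
    tried <- tried + 1
    extra <- cand[sample(nrow(cand), 1), , drop = FALSE]
    g2 <- g
    g2$arrows <- rbind(g$arrows, extra)
    ind_before <- implied_independencies(g, max_cond = 1)
    ind_after <- implied_independencies(g2, max_cond = 1)
    key <- function(l) vapply(l, function(e)
      paste(e$x, e$y, paste(e$given, collapse = ","), sep = "|"), "")
    expect_true(all(key(ind_after) %in% key(ind_before)))
  }
  expect_gt(tried, 20)
})

test_that("implied independencies enumerate exactly the separated triples", {
  # complete dashed one-box graph: nothing is separated
  ord1 <- block_ordering(list(lapply(paste0("r", 1:3), function(nm)
    variable_spec(nm, 0, "response"))), "response")
  gfull <- regression_graph(ord1, dashed = t(utils::combn(paste0("r", 1:3), 2)))
  expect_length(implied_independencies(gfull, 1), 0)

  # an isolated node is separated from everything unconditionally
  ord2 <- block_ordering(list(
    list(variable_spec("iso", 0, "response"), variable_spec("y", 0, "response")),
    list(variable_spec("x", 0, "response"))), c("response", "response"))
  giso <- regression_graph(ord2, arrows = rbind(c("x", "y")))
  ind <- implied_independencies(giso, 0)
  keys <- vapply(ind, function(e) paste(sort(c(e$x, e$y)), collapse = "-"), "")
  expect_true(all(c("iso-y", "iso-x") %in% keys))

  # deterministic, matches exhaustive m_separated enumeration
  set.seed(99)
  g <- random_block_graph(6)
  got <- implied_independencies(g, 2)
  nodes <- sort(g$nodes)
  want <- list()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    rest <- sort(setdiff(nodes, nodes[c(i, j)]))
    for (k in 0:min(2, length(rest))) {
      sets <- if (k == 0) list(character(0)) else
        utils::combn(rest, k, simplify = FALSE)
      for (C in sets)
        if (bf_m_separated(g, nodes[i], nodes[j], C))
          want[[length(want) + 1]] <- list(x = nodes[i], y = nodes[j], given = C)
    }
  }
  expect_equal(got, want)
})

test_that("DOT export carries clusters, labels and round-trips its edges", {
  ord <- default_ordering()
  g0 <- regression_graph(ord)
  dot <- to_dot(g0)
  expect_match(dot, "cluster_box0")
  expect_match(dot, "cluster_box3")
  expect_length(parse_dot_edges(dot)$arrows, 0)

  g <- regression_graph(ord,
                        arrows = rbind(c("lean_mass", "csa_dis"),
                                       c("leptin", "fat_mass_pct")),
                        dashed = rbind(c("csa_dis", "vbmd_tot_dis")))
  dot <- to_dot(g, fit_annotations = list(
    "lean_mass->csa_dis" = "0.46 (0.17, 0.76)"))
  expect_match(dot, "0.46 (0.17, 0.76)", fixed = TRUE)
  back <- parse_dot_edges(dot)
  expect_setequal(paste(back$arrows[, 1], back$arrows[, 2]),
                  paste(g$arrows[, 1], g$arrows[, 2]))
  expect_equal(back$dashed, g$dashed, ignore_attr = TRUE)

  path <- tempfile(fileext = ".graphml")
  to_graphml(g, path)
  xml <- paste(readLines(path), collapse = "\n")
  expect_match(xml, "<node id=\"csa_dis\">")
  expect_match(xml, "<data key=\"ekind\">dashed</data>")
})
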