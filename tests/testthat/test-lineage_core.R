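tm4 <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")

test_that("parsing builds validated lineages and rejects bad input", {
  lin <- parse_lineage("((A1,A2),(B1,B2));", tm4)
  expect_s3_class(lin, "cell_lineage")
  expect_equal(lin$L, 4L)
  expect_equal(nrow(lin$children), 3L)

  two <- parse_lineage("(A1,B1);", c(A1 = "A", B1 = "B"))
  expect_equal(two$L, 2L)
  expect_equal(two$root, 3L)

  expect_error(parse_lineage("((A1,A2,A3));",
                             c(A1 = "A", A2 = "A", A3 = "A")),
               "binary|structure")
  expect_error(parse_lineage("((A1,A2),(B1,B2));", tm4[-3]), "mapping")
  expect_error(parse_lineage("((A1,A2", tm4), "malformed")
})

test_that("internal node count is L - 1 for parsed and generated lineages", {
  for (seed in 1:5) {
    lin <- random_toy_lineage(L = 10 + seed, n_types = 3, seed = seed)
    expect_equal(nrow(lin$children), lin$L - 1L)
    expect_equal(lin$n_nodes, 2L * lin$L - 1L)
  }
})

test_that("depths follow the division-count convention", {
  lin <- parse_lineage("((A1,A2),(B1,B2));", tm4)
  d <- node_depths(lin)
  expect_equal(unname(d$depth[lin$root]), 0L)
  expect_equal(unname(d$tip_depth), rep(2L, 4))
  expect_equal(d$max_depth, 2L)

  bal8 <- parse_lineage(
    "(((a1,a2),(a3,a4)),((a5,a6),(a7,a8)));",
    setNames(rep("a", 8), paste0("a", 1:8)))
  d8 <- node_depths(bal8)
  expect_equal(d8$max_depth, 3L)
  expect_equal(d8$mean_depth, 3)
})

test_that("theoretical minimum of the maximum depth is ceiling(log2(L))", {
  expect_identical(theoretical_min_max_depth(c(671, 638, 110)),
                   c(10L, 10L, 7L))
  expect_identical(theoretical_min_max_depth(4), 2L)
  expect_identical(theoretical_min_max_depth(1), 0L)
  expect_error(theoretical_min_max_depth(0), ">= 1")
  # never above the realized max depth; equality on balanced power-of-two
  for (seed in 1:5) {
    lin <- random_toy_lineage(L = 17 + seed, n_types = 2, seed = 30 + seed)
    expect_lte(theoretical_min_max_depth(lin$L),
               node_depths(lin)$max_depth)
  }
})

test_that("lineal distance counts edges and satisfies the triangle inequality", {
  lin <- parse_lineage("((A1,A2),(B1,B2));", tm4)
  expect_equal(lineal_distance(lin, "A1", "A1"), 0L)
  expect_equal(lineal_distance(lin, "A1", "A2"), 2L)
  expect_equal(lineal_distance(lin, "A1", "B1"), 4L)
  expect_equal(lineal_distance(lin, "B1", "A1"), 4L)
  expect_error(lineal_distance(lin, "A1", "nope"), "lookup")

  lin2 <- random_toy_lineage(L = 12, n_types = 3, seed = 9)
  set.seed(42)
  for (q in 1:25) {
    abc <- sample(lin2$n_nodes, 3)
    expect_lte(lineal_distance(lin2, abc[1], abc[3]),
               lineal_distance(lin2, abc[1], abc[2]) +
                 lineal_distance(lin2, abc[2], abc[3]))
  }
})

test_that("program inference canonicalizes daughter fates unordered", {
  lin1 <- parse_lineage("((A1,A2),(B1,B2));", tm4)
  lin2 <- parse_lineage("((A1,B1),(A2,B2));", tm4)
  lin3 <- parse_lineage("(A1,B1);", c(A1 = "A", B1 = "B"))
  expect_equal(infer_programs(lin1)$n_programs, 3L)
  expect_equal(infer_programs(lin2)$n_programs, 2L)
  expect_equal(infer_programs(lin3)$n_programs, 1L)
  expect_lte(infer_programs(lin1)$n_programs,
             infer_programs(lin1)$n_internal)

  # swapping the two children of any internal node never changes programs
  lin <- random_toy_lineage(L = 14, n_types = 3, seed = 4)
  base <- sort(table(infer_programs(lin)$key[infer_programs(lin)$program]))
  for (i in seq_len(lin$L - 1L)) {
    sw <- lin
    sw$children[i, ] <- rev(sw$children[i, ])
    sw <- validate_cell_lineage(sw)
    expect_equal(infer_programs(sw)$n_programs,
                 infer_programs(lin)$n_programs)
    expect_setequal(infer_programs(sw)$key, infer_programs(lin)$key)
  }
})

test_that("census accounting separates excluded types", {
  lin <- parse_lineage("((A1,A2),(B1,D1));",
                       c(A1 = "A", A2 = "A", B1 = "B", D1 = "death"))
  cen <- lineage_census(lin, excluded = "death")
  expect_equal(sum(cen$counts), lin$L)
  expect_equal(cen$T_included, 2L)
  expect_error(cell_type_census(c(A = 0)), "positive")
})

test_that("Newick and JSON round trips preserve the lineage", {
  lin <- random_toy_lineage(L = 9, n_types = 3, seed = 2)
  back <- parse_lineage(as_newick(lin), setNames(lin$tip_type,
                                                 lin$tip_label))
  expect_setequal(back$tip_label, lin$tip_label)
  expect_equal(sort(node_depths(back)$tip_depth[lin$tip_label]),
               sort(node_depths(lin)$tip_depth[lin$tip_label]))

  path <- tempfile(fileext = ".json")
  write_lineage_json(lin, path)
  rt <- read_lineage_json(path)
  expect_equal(setNames(rt$lineage$tip_type, rt$lineage$tip_label)[lin$tip_label],
               setNames(lin$tip_type, lin$tip_label))
})
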