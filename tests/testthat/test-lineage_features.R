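tm4 <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
tl1 <- parse_lineage("((A1,A2),(B1,B2));", tm4)
tl2 <- parse_lineage("((A1,B1),(A2,B2));", tm4)

test_that("clonality matches hand enumeration and the brute-force oracle", {
  expect_equal(clonality(tl1)$C, 5 / 3)
  expect_equal(clonality(tl2)$C, 5 / 6)
  mono <- parse_lineage("((x1,x2),(x3,x4));",
                        setNames(rep("x", 4), paste0("x", 1:4)))
  expect_equal(clonality(mono)$C, 1)
  for (seed in 1:5) {
    lin <- random_toy_lineage(L = 11, n_types = 3, seed = 110 + seed)
    expect_equal(clonality(lin)$C, oracle_clonality(lin))
  }
  singles <- parse_lineage("((a,b),(c,d));",
                           c(a = "w", b = "x", c = "y", d = "z"))
  expect_error(clonality(singles), "undefined")
})

test_that("the all-pairs distance sum is a topology invariant", {
  lin <- random_toy_lineage(L = 16, n_types = 4, seed = 120)
  s0 <- clonality(lin)$sum_all
  for (seed in 1:5) {
    r <- randomize_lineage(lin, "relabel-all", seed = seed)
    expect_equal(clonality(r)$sum_all, s0)
  }
  # and invariant under child swaps (re-rooting-preserving isomorphism)
  sw <- lin
  sw$children[3, ] <- rev(sw$children[3, ])
  expect_equal(clonality(validate_cell_lineage(sw))$C, clonality(lin)$C)
})

test_that("rare-early correlation has the forced signs on tiny fixtures", {
  shallow_rare <- parse_lineage("((B1,B2),A1);",
                                c(B1 = "B", B2 = "B", A1 = "A"))
  expect_equal(rare_early_correlation(shallow_rare)$rho, 1)
  deep_rare <- parse_lineage("((B1,B2),(B3,A1));",
                             c(B1 = "B", B2 = "B", B3 = "B", A1 = "A"))
  expect_equal(rare_early_correlation(deep_rare)$rho, NA_real_)  # equal depths
  deep_rare2 <- parse_lineage("(B1,(B2,(B3,A1)));",
                              c(B1 = "B", B2 = "B", B3 = "B", A1 = "A"))
  expect_lt(rare_early_correlation(deep_rare2)$rho, 0)
  one_type <- parse_lineage("(x1,(x2,x3));",
                            setNames(rep("x", 3), paste0("x", 1:3)))
  expect_true(rare_early_correlation(one_type)$undefined)
})

test_that("relabel-all null of the rare-early correlation centers near zero", {
  lin <- random_toy_lineage(L = 24, n_types = 4, seed = 130)
  nd <- null_distribution(lin,
                          function(l) linrob:::rho_rare_early(l)$rho,
                          mode = "relabel-all", n = 300, seed = 3)
  expect_lt(abs(mean(nd$samples)), 0.1)
})

test_that("twin counting finds same-type sibling pairs only", {
  expect_equal(count_twins(tl1)$n_twins, 2L)
  expect_equal(count_twins(tl2)$n_twins, 0L)
  expect_equal(count_twins(parse_lineage("(A1,B1);",
                                         c(A1 = "A", B1 = "B")))$n_twins, 0L)
  expect_equal(sort(as.vector(count_twins(tl1)$pairs)),
               c("A1", "A2", "B1", "B2"))
})

test_that("physical-lineal correlation responds to planted structure", {
  lin <- random_toy_lineage(L = 20, n_types = 2, seed = 140)
  # coordinates as a monotone function of lineal position: embed each tip
  # at x = its distance to tip 1
  d1 <- sapply(seq_len(lin$L), function(v) lineal_distance(lin, 1L, v))
  co <- data.frame(cell = lin$tip_label, x = d1, y = 0, z = 0)
  rho <- physical_lineal_correlation(lin, co)$rho
  expect_gt(rho, 0)
  const <- data.frame(cell = lin$tip_label, x = 1, y = 1, z = 1)
  expect_true(physical_lineal_correlation(lin, const)$undefined)
  expect_error(physical_lineal_correlation(
    lin, data.frame(cell = "nope", x = 1, y = 1, z = 1)), "no same-type")
})

test_that("twin spatial Z is strongly negative for coincident twins", {
  cen <- cell_type_census(c(A = 8, B = 8))
  lin <- synth_lineage(cen, twin_enrichment = 3, seed = 150)
  co <- synth_coords(lin, clustering_strength = 0, twin_adjacency = 1000,
                     seed = 151)
  z <- twin_spatial_zscore(lin, co, reps = 100, seed = 152)
  expect_lt(z$Z, -1)
  expect_identical(twin_spatial_zscore(lin, co, reps = 50, seed = 7)$Z,
                   twin_spatial_zscore(lin, co, reps = 50, seed = 7)$Z)
  same <- data.frame(cell = lin$tip_label, x = 0, y = 0, z = 0)
  expect_true(twin_spatial_zscore(lin, same, reps = 20,
                                  seed = 1)$zero_variance)
})

test_that("the hill climb never lowers the correlation and can improve it", {
  cen <- cell_type_census(c(A = 16, B = 16))
  lin <- synth_lineage(cen, seed = 160)
  co <- synth_coords(lin, clustering_strength = 3, seed = 161)
  # random start: shuffle labels within depth to break the planted link
  start <- randomize_lineage(lin, "relabel-within-depth", seed = 162)
  hc <- hill_climb_rho(start, co, rounds = 30, candidates = 30, seed = 163)
  expect_gte(hc$rho_final, hc$rho_start)
  expect_gt(hc$rho_final, hc$rho_start)  # strict improvement from random
  expect_true(all(diff(hc$trace) >= -1e-12))
  id <- hill_climb_rho(start, co, rounds = 0, candidates = 10, seed = 1)
  expect_identical(id$lineage$tip_label, start$tip_label)
  expect_equal(id$rho_final, id$rho_start)
})
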