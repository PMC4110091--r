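tm4 <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
tl1 <- parse_lineage("((A1,A2),(B1,B2));", tm4)
tl2 <- parse_lineage("((A1,B1),(A2,B2));", tm4)

test_that("f is the product of weighted survival fractions", {
  cen <- cell_type_census(c(A = 2, B = 2))
  expect_equal(compute_f(cen, c(A = 2, B = 2)), 1)
  expect_equal(compute_f(cen, c(A = 1, B = 2)), 0.5)
  expect_equal(compute_f(cen, c(A = 1, B = 2), a = c(A = 2)), 0.25)
  expect_equal(compute_f(cen, c(A = 0, B = 2)), 0)
  expect_error(compute_f(cen, c(A = 3, B = 2)), "consistency")
  expect_error(compute_f(cen, c(A = 1, Z = 1)), "mapping")
  expect_error(compute_f(cen, c(A = 1), a = 0.5), ">= 1")
  # excluded types do not enter f
  cend <- cell_type_census(c(A = 2, death = 3), excluded = "death")
  expect_equal(compute_f(cend, c(A = 2, death = 0)), 1)
})

test_that("f is monotone: extra survivors never lower it", {
  cen <- cell_type_census(c(A = 5, B = 4, C = 3))
  set.seed(1)
  for (q in 1:20) {
    n1 <- c(A = sample(0:4, 1), B = sample(0:3, 1), C = sample(0:2, 1))
    bump <- sample(names(n1), 1)
    n2 <- n1
    n2[bump] <- n1[bump] + 1
    expect_gte(compute_f(cen, n2), compute_f(cen, n1))
  }
})

test_that("subtree removal yields the survivor census", {
  surv <- remove_subtree(tl1, "A1")
  expect_equal(surv, c(A = 1L, B = 2L))
  # the parent of A1, A2 is an internal node; find it via the tip ids
  pa <- tl1$parent[match("A1", tl1$tip_label)]
  expect_equal(remove_subtree(tl1, pa), c(A = 0L, B = 2L))
  expect_equal(remove_subtree(tl1, tl1$root), c(A = 0L, B = 0L))
  expect_error(remove_subtree(tl1, "nope"), "lookup")
})

test_that("necrosis robustness equals exhaustive single-removal enumeration", {
  expect_equal(necrosis_robustness(tl1), 1 / 3)
  expect_equal(necrosis_robustness(tl2), 2.5 / 6)
  # four singleton types: every removal extinguishes a type
  lin4 <- parse_lineage("((a,b),(c,d));",
                        c(a = "ta", b = "tb", c = "tc", d = "td"))
  expect_equal(necrosis_robustness(lin4), 0)
  # excluded-type terminals count as removal targets but leave f = 1
  lind <- parse_lineage("((A1,A2),(B1,D1));",
                        c(A1 = "A", A2 = "A", B1 = "B", D1 = "death"))
  specd <- robustness_spec(excluded = "death")
  expect_equal(necrosis_robustness(lind, specd), oracle_fn(lind, "death"))
  for (seed in 1:6) {
    lin <- random_toy_lineage(L = 8 + seed, n_types = 3, seed = 50 + seed)
    expect_equal(necrosis_robustness(lin), oracle_fn(lin))
  }
  # deterministic: identical on repeated calls
  expect_identical(necrosis_robustness(tl1), necrosis_robustness(tl1))
})

test_that("exact program-failure expectation matches subset enumeration", {
  spec13 <- robustness_spec(p = 1 / 3)
  expect_equal(exact_program_failure_expectation(tl1, spec13), 8 / 27)
  expect_equal(exact_program_failure_expectation(tl2, spec13), 4 / 9)
  expect_equal(exact_program_failure_expectation(tl1, robustness_spec(p = 0)), 1)
  lin2 <- parse_lineage("(A1,B1);", c(A1 = "A", B1 = "B"))
  expect_equal(exact_program_failure_expectation(lin2, robustness_spec(p = 1)), 0)
  for (seed in 1:4) {
    lin <- random_toy_lineage(L = 7 + seed, n_types = 3, seed = 70 + seed)
    p <- 1 / (lin$L - 1)
    expect_equal(exact_program_failure_expectation(lin, robustness_spec(p = p)),
                 oracle_fp(lin, p))
  }
})

test_that("Monte Carlo f_p converges to the exact expectation", {
  spec13 <- robustness_spec(p = 1 / 3)
  fp <- program_failure_robustness(tl1, spec13, replicates = 20000, seed = 5)
  expect_lt(abs(as.numeric(fp) - 8 / 27), 3 * attr(fp, "se"))
  fp2 <- program_failure_robustness(tl2, spec13, replicates = 20000, seed = 5)
  expect_lt(abs(as.numeric(fp2) - 4 / 9), 3 * attr(fp2, "se"))
  expect_equal(as.numeric(program_failure_robustness(
    tl1, robustness_spec(p = 0), replicates = 10, seed = 1)), 1)
  # seeded reproducibility and the 10 * N_all default
  a <- program_failure_robustness(tl1, seed = 9)
  b <- program_failure_robustness(tl1, seed = 9)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_equal(attr(a, "replicates"), 10L * tl1$n_nodes)
})

test_that("the default p makes one expected internal-cell failure", {
  lins <- list(tl1, tl2)
  for (seed in 1:5) {
    lins <- c(lins, list(random_toy_lineage(12, 3, 90 + seed)))
  }
  for (lin in lins) {
    pa <- infer_programs(lin)
    p <- 1 / pa$n_internal
    expect_equal(sum(pa$usage) * p, 1)
  }
})

test_that("loss concentrated in one type never beats distributed loss", {
  for (T in 2:3) for (N in 2:4) {
    cen <- cell_type_census(setNames(rep(N, T), paste0("t", 1:T)))
    for (h in 2:N) {
      conc <- setNames(rep(N, T), paste0("t", 1:T))
      conc[1] <- N - h
      f_conc <- compute_f(cen, conc)
      allocs <- expand.grid(rep(list(0:min(h, N)), T))
      allocs <- allocs[rowSums(allocs) == h, , drop = FALSE]
      for (r in seq_len(nrow(allocs))) {
        surv <- setNames(N - as.numeric(allocs[r, ]), paste0("t", 1:T))
        expect_lte(f_conc, compute_f(cen, surv) + 1e-12)
      }
    }
  }
})

test_that("variable-rate robustness reduces to constant rates in the limit", {
  # single draw with rates all equal would be the constant case; with many
  # draws the mean approaches the constant-rate value
  vr <- variable_rate_robustness(tl1, draws = 4000, seed = 8)
  fnc <- necrosis_robustness(tl1)
  # weighted-average estimator is unbiased for f_n... only approximately:
  # compare against its own Monte Carlo spread instead of exact equality
  expect_lt(abs(vr$f_n_variable - fnc), 0.05)
  expect_true(vr$f_p_variable >= 0 && vr$f_p_variable <= 1)
  expect_identical(variable_rate_robustness(tl1, draws = 50, seed = 3),
                   variable_rate_robustness(tl1, draws = 50, seed = 3))
  expect_error(variable_rate_robustness(tl1, draws = 0), "draws")
})

test_that("stochastic f distributions behave at the edges and the mean", {
  spec13 <- robustness_spec(p = 1 / 3)
  sp <- stochastic_f_distribution(tl1, spec13, ndraws = 8000,
                                  mode = "program", seed = 4)
  se <- sd(sp$samples) / sqrt(length(sp$samples))
  expect_lt(abs(sp$mean - 8 / 27), 3 * se)
  s0 <- stochastic_f_distribution(tl1, robustness_spec(p = 0), ndraws = 50,
                                  mode = "program", seed = 1)
  expect_equal(s0$sd, 0)
  expect_equal(s0$mean, 1)
  sn <- stochastic_f_distribution(tl1, ndraws = 6000, mode = "necrosis",
                                  seed = 2)
  # necrosis mode at one expected death per lineage: mean f must sit
  # between f_n (one guaranteed death) and 1 (no death occurs sometimes)
  expect_gt(sn$mean, necrosis_robustness(tl1))
  expect_lt(sn$mean, 1)
  expect_identical(
    stochastic_f_distribution(tl1, ndraws = 100, seed = 7)$samples,
    stochastic_f_distribution(tl1, ndraws = 100, seed = 7)$samples)
})
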