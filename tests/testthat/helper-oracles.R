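# Brute-force oracles, written independently of the package's vectorized
# implementations: plain recursion over the tree and direct products over
# the census. They stay deliberately slow and simple.

# terminal descendants of a node by naive recursion
oracle_desc_tips <- function(lin, v) {
  if (v <= lin$L) return(v)
  kids <- lin$children[v - lin$L, ]
  c(oracle_desc_tips(lin, kids[1]), oracle_desc_tips(lin, kids[2]))
}

# f from a full survivor table, direct product
oracle_f <- function(N, n, a, excluded) {
  keep <- setdiff(names(N), excluded)
  prod((n[keep] / N[keep])^a[keep])
}

# f_n by exhaustive enumeration of all single non-root removals
oracle_fn <- function(lin, excluded = character(), a = 1) {
  N <- table(lin$tip_type)
  N <- setNames(as.numeric(N), names(N))
  av <- setNames(rep(a, length(N)), names(N))
  vals <- sapply(setdiff(seq_len(lin$n_nodes), lin$root), function(v) {
    dead <- oracle_desc_tips(lin, v)
    n <- N - table(factor(lin$tip_type[dead], levels = names(N)))
    oracle_f(N, setNames(as.numeric(n), names(N)), av, excluded)
  })
  mean(vals)
}

# exact f_p by enumerating every subset of failing programs and walking
# the tree from the root (arrest propagates downward)
oracle_fp <- function(lin, p, excluded = character(), a = 1) {
  pa <- infer_programs(lin)
  P <- pa$n_programs
  N <- table(lin$tip_type)
  N <- setNames(as.numeric(N), names(N))
  av <- setNames(rep(a, length(N)), names(N))
  total <- 0
  for (s in 0:(2^P - 1)) {
    failed <- which(bitwAnd(s, 2^(0:(P - 1))) > 0)
    w <- p^length(failed) * (1 - p)^(P - length(failed))
    alive <- character(0)
    walk <- function(v) {
      if (v > lin$L && pa$program[[v - lin$L]] %in% failed) return()
      if (v <= lin$L) {
        alive <<- c(alive, lin$tip_label[v])
      } else {
        walk(lin$children[v - lin$L, 1])
        walk(lin$children[v - lin$L, 2])
      }
    }
    walk(lin$root)
    n <- table(factor(lin$tip_type[match(alive, lin$tip_label)],
                      levels = names(N)))
    total <- total + w * oracle_f(N, setNames(as.numeric(n), names(N)),
                                  av, excluded)
  }
  total
}

# clonality by explicit enumeration of every terminal pair
oracle_clonality <- function(lin) {
  pairs <- combn(seq_len(lin$L), 2)
  d <- apply(pairs, 2, function(q) lineal_distance(lin, q[1], q[2]))
  mean_all <- mean(d)
  types <- names(which(table(lin$tip_type) >= 2))
  ratios <- sapply(types, function(ty) {
    within <- lin$tip_type[pairs[1, ]] == ty & lin$tip_type[pairs[2, ]] == ty
    mean_all / mean(d[within])
  })
  mean(ratios)
}

# small typed lineages for property loops
random_toy_lineage <- function(L, n_types, seed) {
  types <- paste0("ty", seq_len(n_types))
  set.seed(seed)
  tt <- c(types, sample(types, L - n_types, replace = TRUE))
  proto <- linrob:::cell_lineage_from_cells(paste0("c", seq_len(L)), tt)
  randomize_lineage(proto, "coalescent", seed = seed + 1)
}
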