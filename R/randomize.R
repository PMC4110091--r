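#' Constrained lineage randomization (null models)
#'
#' Generates a random lineage that conserves the terminal-cell census of the
#' input exactly, under one of eight progressively stricter constraints:
#'
#' * `"coalescent"` — repeatedly coalesce two uniformly chosen remaining
#'   cells until a single root remains.
#' * `"coalescent-fixed-maxdepth"` — constrained coalescence whose realized
#'   maximum terminal depth equals `max_depth` exactly (merges that would
#'   make a depth-`max_depth` tree infeasible are forbidden; completed trees
#'   with a smaller maximum depth are rejected and redrawn).
#' * `"coalescent-bootstrap-depths"` — terminal depths are a bootstrap
#'   resample of the real depth multiset with the maximum depth held at the
#'   real value; the topology is rebuilt by random pairing per depth.
#' * `"from-depth-multiset"` — terminal depths are exactly the real
#'   multiset, randomly reassigned to cells; topology rebuilt by pairing
#'   the cells at the deepest level and recursing upward.
#' * `"relabel-all"` — identical unlabeled topology, terminal cells
#'   permuted uniformly over all leaf positions.
#' * `"relabel-within-depth"` — terminal cells permuted only among leaf
#'   positions of their own depth.
#' * `"relabel-within-depth-twins"` — as above, but twin terminal cells
#'   (same-type siblings) stay twins.
#' * `"clonality-gradient"` — within every depth, a fraction `g` of the
#'   cells of every type is sorted by a predefined random type order and
#'   the rest inserted at random positions; cells are then assigned to the
#'   depth's leaf positions from left to right, so clonality grows with
#'   `g`.
#'
#' @param lineage a [cell_lineage()].
#' @param mode one of the eight mode tags above.
#' @param max_depth target maximum depth for
#'   `"coalescent-fixed-maxdepth"`.
#' @param g sorted fraction in `[0, 1]` for `"clonality-gradient"`.
#' @param seed RNG seed.
#' @param max_tries retry cap for the rejection steps.
#' @return A new [cell_lineage()] with the same terminal cells.
#' @export
randomize_lineage <- function(lineage,
                              mode = c("coalescent",
                                       "coalescent-fixed-maxdepth",
                                       "coalescent-bootstrap-depths",
                                       "from-depth-multiset",
                                       "relabel-all",
                                       "relabel-within-depth",
                                       "relabel-within-depth-twins",
                                       "clonality-gradient"),
                              max_depth = NULL, g = NULL, seed = NULL,
                              max_tries = 10000L) {
  mode <- match.arg(mode)
  if (lineage$L < 2L) stop("randomization needs at least two terminal cells")
  with_seed(seed, switch(
    mode,
    "coalescent" = rand_coalescent(lineage),
    "coalescent-fixed-maxdepth" = {
      if (is.null(max_depth)) stop("max_depth is required for this mode")
      rand_coalescent_fixed(lineage, as.integer(max_depth), max_tries)
    },
    "coalescent-bootstrap-depths" = rand_bootstrap_depths(lineage, max_tries),
    "from-depth-multiset" = rand_from_multiset(lineage, max_tries),
    "relabel-all" = relabel(lineage, within_depth = FALSE),
    "relabel-within-depth" = relabel(lineage, within_depth = TRUE),
    "relabel-within-depth-twins" = relabel_twins(lineage),
    "clonality-gradient" = {
      if (is.null(g) || g < 0 || g > 1) stop("g in [0, 1] is required")
      clonality_gradient(lineage, g)
    }))
}

# ---- coalescent builders ----------------------------------------------

# assemble a cell_lineage from merge bookkeeping produced by the builders
assemble_lineage <- function(L, children, root, tip_label, tip_type) {
  n <- 2L * L - 1L
  parent <- integer(n)
  for (i in seq_len(L - 1L)) parent[children[i, ]] <- L + i
  cell_lineage(parent, children, tip_label, tip_type, root)
}

rand_coalescent <- function(lineage) {
  L <- lineage$L
  active <- seq_len(L)
  children <- matrix(0L, nrow = L - 1L, ncol = 2L)
  for (i in seq_len(L - 1L)) {
    pick <- sample.int(length(active), 2L)
    children[i, ] <- active[pick]
    active <- c(active[-pick], L + i)
  }
  assemble_lineage(L, children, 2L * L - 1L, lineage$tip_label,
                   lineage$tip_type)
}

# coalescence under a hard height cap D, keeping completion feasible:
# merging heights (h1, h2) is allowed when the resulting height multiset
# can still close into one tree of height <= D (Kraft sum <= 2^D in units
# of 2^-D). Completed trees of height < D are rejected and redrawn.
rand_coalescent_fixed <- function(lineage, D, max_tries) {
  L <- lineage$L
  if (D < theoretical_min_max_depth(L)) {
    stop("constraint error: max_depth below the theoretical minimum")
  }
  for (try in seq_len(max_tries)) {
    active <- seq_len(L)
    height <- integer(L)
    children <- matrix(0L, nrow = L - 1L, ncol = 2L)
    ok <- TRUE
    for (i in seq_len(L - 1L)) {
      S <- sum(2^height)
      # enumerate feasible unordered height-class pairs
      hc <- table(height)
      hv <- as.integer(names(hc))
      cnt <- as.integer(hc)
      cand_h1 <- integer(0); cand_h2 <- integer(0); cand_n <- numeric(0)
      for (ii in seq_along(hv)) for (jj in ii:length(hv)) {
        h1 <- hv[ii]; h2 <- hv[jj]
        npair <- if (ii == jj) cnt[ii] * (cnt[ii] - 1) / 2 else cnt[ii] * cnt[jj]
        if (npair <= 0) next
        hnew <- max(h1, h2) + 1L
        if (hnew > D) next
        if (S - 2^h1 - 2^h2 + 2^hnew > 2^D) next
        cand_h1 <- c(cand_h1, h1); cand_h2 <- c(cand_h2, h2)
        cand_n <- c(cand_n, npair)
      }
      if (!length(cand_n)) { ok <- FALSE; break }
      k <- sample.int(length(cand_n), 1L, prob = cand_n)
      h1 <- cand_h1[k]; h2 <- cand_h2[k]
      if (h1 == h2) {
        pick <- resample(which(height == h1), 2L)
      } else {
        pick <- c(resample(which(height == h1), 1L),
                  resample(which(height == h2), 1L))
      }
      children[i, ] <- active[pick]
      newh <- max(h1, h2) + 1L
      active <- c(active[-pick], L + i)
      height <- c(height[-pick], newh)
    }
    if (ok && height[1L] == D) {
      return(assemble_lineage(L, children, 2L * L - 1L,
                              lineage$tip_label, lineage$tip_type))
    }
  }
  stop("constraint error: no lineage with max depth ", D, " in ",
       max_tries, " tries")
}

# ---- depth-multiset builders ------------------------------------------

# build a topology realizing (approximately, via the odd-count carry rule)
# a target depth per terminal cell; returns NULL when the levels cannot
# close into a single root
build_from_depths <- function(L, tip_depth) {
  maxd <- max(tip_depth)
  pool <- vector("list", maxd + 1L)        # pool[[d + 1]] = nodes at depth d
  for (d in 0:maxd) pool[[d + 1L]] <- which(tip_depth == d)
  children <- matrix(0L, nrow = L - 1L, ncol = 2L)
  nxt <- L + 1L
  for (d in maxd:1) {
    nodes <- pool[[d + 1L]]
    if (length(nodes) %% 2L == 1L) {
      carry <- sample.int(length(nodes), 1L)
      pool[[d]] <- c(pool[[d]], nodes[carry])
      nodes <- nodes[-carry]
    }
    if (length(nodes)) {
      ord <- resample(nodes)
      for (k in seq_len(length(ord) / 2L)) {
        children[nxt - L, ] <- ord[c(2L * k - 1L, 2L * k)]
        pool[[d]] <- c(pool[[d]], nxt)
        nxt <- nxt + 1L
      }
    }
  }
  root_pool <- pool[[1L]]
  if (length(root_pool) != 1L || root_pool[1L] <= L) return(NULL)
  list(children = children, root = root_pool[1L])
}

rand_from_multiset <- function(lineage, max_tries) {
  L <- lineage$L
  depths <- node_depths(lineage)$tip_depth
  for (try in seq_len(max_tries)) {
    asg <- sample(as.integer(depths))       # random cell <-> depth pairing
    built <- build_from_depths(L, asg)
    if (is.null(built)) next
    lin <- assemble_lineage(L, built$children, built$root,
                            lineage$tip_label, lineage$tip_type)
    if (identical(sort(as.integer(node_depths(lin)$tip_depth)),
                  sort(as.integer(depths)))) {
      return(lin)
    }
  }
  stop("constraint error: could not realize the depth multiset in ",
       max_tries, " tries")
}

rand_bootstrap_depths <- function(lineage, max_tries) {
  L <- lineage$L
  depths <- as.integer(node_depths(lineage)$tip_depth)
  D <- max(depths)
  for (try in seq_len(max_tries)) {
    bs <- sample(depths, L, replace = TRUE)
    if (max(bs) != D) next
    built <- build_from_depths(L, bs)
    if (is.null(built)) next
    lin <- assemble_lineage(L, built$children, built$root,
                            lineage$tip_label, lineage$tip_type)
    if (node_depths(lin)$max_depth == D) return(lin)
  }
  stop("constraint error: no bootstrap depth set closed to a root in ",
       max_tries, " tries")
}

# ---- relabeling modes --------------------------------------------------

relabel <- function(lineage, within_depth) {
  lin <- lineage
  L <- lin$L
  if (within_depth) {
    depth <- node_depths(lin)$tip_depth
    perm <- seq_len(L)
    for (d in unique(depth)) {
      idx <- which(depth == d)
      perm[idx] <- idx[sample.int(length(idx))]
    }
  } else {
    perm <- sample.int(L)
  }
  lin$tip_label <- lineage$tip_label[perm]
  lin$tip_type <- lineage$tip_type[perm]
  validate_cell_lineage(lin)
}

# within-depth relabeling that keeps twin terminal cells (same-type
# siblings) on sibling leaf positions of their depth
relabel_twins <- function(lineage) {
  L <- lineage$L
  depth <- node_depths(lineage)$tip_depth
  tw <- twin_pairs(lineage)                 # matrix of tip id pairs
  new_label <- character(L)
  new_type <- character(L)
  placed <- logical(L)                      # slot filled
  used <- logical(L)                        # cell assigned
  for (d in unique(depth)) {
    slots <- which(depth == d)
    # sibling slot pairs fully inside this depth
    sib <- sibling_tip_pairs(lineage)
    sib <- sib[depth[sib[, 1L]] == d & depth[sib[, 2L]] == d, , drop = FALSE]
    twd <- tw[depth[tw[, 1L]] == d, , drop = FALSE]
    if (nrow(twd) > 0L) {
      pickp <- sample.int(nrow(sib), nrow(twd))
      for (q in seq_len(nrow(twd))) {
        pairslot <- sib[pickp[q], ]
        cells <- twd[q, ][sample.int(2L)]
        pairslot <- pairslot[sample.int(2L)]
        new_label[pairslot] <- lineage$tip_label[cells]
        new_type[pairslot] <- lineage$tip_type[cells]
        placed[pairslot] <- TRUE
        used[cells] <- TRUE
      }
    }
    free_slots <- slots[!placed[slots]]
    free_cells <- intersect(which(depth == d), which(!used))
    stopifnot(length(free_slots) == length(free_cells))
    if (length(free_slots)) {
      ord <- resample(free_cells)
      new_label[free_slots] <- lineage$tip_label[ord]
      new_type[free_slots] <- lineage$tip_type[ord]
      placed[free_slots] <- TRUE
      used[ord] <- TRUE
    }
  }
  lin <- lineage
  lin$tip_label <- new_label
  lin$tip_type <- new_type
  validate_cell_lineage(lin)
}

# tip id pairs that are siblings (both children of one internal cell)
sibling_tip_pairs <- function(lineage) {
  L <- lineage$L
  ch <- lineage$children
  both <- ch[, 1L] <= L & ch[, 2L] <= L
  ch[both, , drop = FALSE]
}

# sibling tip pairs of identical type ("twins")
twin_pairs <- function(lineage) {
  sib <- sibling_tip_pairs(lineage)
  same <- lineage$tip_type[sib[, 1L]] == lineage$tip_type[sib[, 2L]]
  sib[same, , drop = FALSE]
}

# ---- clonality gradient ------------------------------------------------

clonality_gradient <- function(lineage, g) {
  L <- lineage$L
  depth <- node_depths(lineage)$tip_depth
  type_order <- resample(unique(lineage$tip_type)) # one order per lineage
  pre <- preorder_nodes(lineage)
  tip_seq <- pre[pre <= L]                         # left-to-right leaf order
  new_label <- character(L)
  new_type <- character(L)
  for (d in unique(depth)) {
    slots <- tip_seq[depth[tip_seq] == d]          # left to right at depth d
    cells <- which(depth == d)
    picked <- integer(0)
    for (ty in type_order) {
      cty <- cells[lineage$tip_type[cells] == ty]
      npick <- round(g * length(cty))
      if (npick > 0L) picked <- c(picked, resample(cty, npick))
    }
    rest <- setdiff(cells, picked)
    # sorted block in type order, remainder inserted at random positions
    ordered <- picked[order(match(lineage$tip_type[picked], type_order))]
    for (cell in resample(rest)) {
      pos <- sample.int(length(ordered) + 1L, 1L)
      ordered <- append(ordered, cell, after = pos - 1L)
    }
    new_label[slots] <- lineage$tip_label[ordered]
    new_type[slots] <- lineage$tip_type[ordered]
  }
  lin <- lineage
  lin$tip_label <- new_label
  lin$tip_type <- new_type
  validate_cell_lineage(lin)
}

# ---- empirical null testing -------------------------------------------

#' Empirical null distribution of a lineage statistic
#'
#' Draws `n` randomized lineages under a given constraint, evaluates a
#' statistic on each, and reports the empirical P-value (fraction of null
#' samples at least as extreme as the observation, ties counting as
#' extreme) and the Z-score (observation minus null mean, in null standard
#' deviations).
#'
#' @param lineage a [cell_lineage()].
#' @param statistic a function mapping a lineage to a single number.
#' @param mode randomization mode tag (see [randomize_lineage()]).
#' @param n number of null samples.
#' @param direction `"greater"` if large values are extreme, `"less"`
#'   otherwise.
#' @param seed RNG seed.
#' @param statistic_name label stored in the result.
#' @param ... further arguments (`max_depth`, `g`, ...) for
#'   [randomize_lineage()].
#' @return An object of class `null_distribution`: list with `statistic`,
#'   `observed`, `samples`, `P`, `Z`, `n`, `mode`, `direction`.
#' @export
null_distribution <- function(lineage, statistic, mode, n = 1000L,
                              direction = c("greater", "less"), seed = NULL,
                              statistic_name = deparse(substitute(statistic)),
                              ...) {
  direction <- match.arg(direction)
  if (n < 1) stop("n must be >= 1")
  # observed is evaluated inside the seeded context so that Monte Carlo
  # statistics are reproducible under the same seed
  run <- with_seed(seed, {
    observed <- statistic(lineage)
    samples <- vapply(seq_len(n),
                      function(i) statistic(randomize_lineage(lineage,
                                                              mode, ...)),
                      numeric(1L))
    list(observed = observed, samples = samples)
  })
  observed <- run$observed
  samples <- run$samples
  P <- if (direction == "greater") mean(samples >= observed)
       else mean(samples <= observed)
  sdn <- stats::sd(samples)
  Z <- if (sdn > 0) (observed - mean(samples)) / sdn else NA_real_
  structure(list(statistic = statistic_name, observed = observed,
                 samples = samples, P = P, Z = Z, n = as.integer(n),
                 mode = mode, direction = direction,
                 zero_variance = !(sdn > 0)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$statistic, " under ", x$mode,
      " (n = ", x$n, ")\n", sep = "")
  cat("  observed = ", signif(x$observed, 6),
      ", null mean = ", signif(mean(x$samples), 6),
      ", sd = ", signif(stats::sd(x$samples), 6), "\n", sep = "")
  cat("  empirical P (", x$direction, ") = ", x$P,
      ", Z = ", signif(x$Z, 6), "\n", sep = "")
  invisible(x)
}
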