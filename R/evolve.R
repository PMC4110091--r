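#' Macroevolution simulation settings
#'
#' Controls the stepwise expansion of a lineage under truncation selection:
#' per round of bifurcation, `candidates` random bifurcations are examined,
#' ranked by fitness, and the winner is drawn uniformly from the top `k`
#' (selection intensity `k/candidates`; `k = candidates` removes
#' selection). Fitness is one of `"fn"` (robustness to necrosis, R),
#' `"fp"` (robustness to program failure), `"S"` (simplicity,
#' 1/complexity) or `"RxS"` (`R^x * S` with exponent `x`). Necrosis is
#' evaluated at one expected death per lineage and program failure at
#' `1/N_internal` per program, recomputed as the lineage grows; f_p uses
#' exact enumeration up to `fp_exact_max` programs and Monte Carlo with
#' `fp_replicates` replicates beyond that.
#'
#' @param candidates bifurcations examined per round.
#' @param k truncation threshold, `1 <= k <= candidates`.
#' @param fitness fitness definition.
#' @param x exponent on R in the `"RxS"` fitness.
#' @param a,excluded robustness index settings (see [robustness_spec()]).
#' @param fp_exact_max,fp_replicates f_p evaluation policy.
#' @param mirror evolve one half-lineage but evaluate fitness on the
#'   mirrored whole (for fully symmetric lineages).
#' @return An `evolution_config` object.
#' @export
evolution_config <- function(candidates = 100L, k = 5L,
                             fitness = c("fn", "fp", "S", "RxS"), x = 1,
                             a = 1, excluded = character(),
                             fp_exact_max = 12L, fp_replicates = 200L,
                             mirror = FALSE) {
  fitness <- match.arg(fitness)
  if (k < 1L || k > candidates) stop("k must lie in [1, candidates]")
  if (x < 0) stop("x must be >= 0")
  structure(list(candidates = as.integer(candidates), k = as.integer(k),
                 fitness = fitness, x = x, a = a,
                 excluded = as.character(excluded),
                 fp_exact_max = as.integer(fp_exact_max),
                 fp_replicates = as.integer(fp_replicates),
                 mirror = isTRUE(mirror)),
            class = "evolution_config")
}

#' Shuffle a census into a terminal-cell sequence
#'
#' Expands a census into one labelled cell per count and shuffles the
#' result uniformly. Sharing one sequence across runs with different
#' selection intensities makes the runs paired.
#'
#' @param census a [cell_type_census()].
#' @param seed RNG seed.
#' @return Data frame with columns `label` and `type`, in arrival order.
#' @export
shuffle_census_cells <- function(census, seed = NULL) {
  types <- rep(names(census$counts), census$counts)
  labels <- paste0(types, "_", unlist(lapply(census$counts, seq_len)))
  ord <- with_seed(seed, sample.int(length(types)))
  data.frame(label = labels[ord], type = types[ord],
             stringsAsFactors = FALSE)
}

#' Evaluate the configured fitness of a lineage
#'
#' @param lineage a [cell_lineage()].
#' @param config an [evolution_config()].
#' @param seed RNG seed for Monte Carlo f_p (only used for `"fp"` fitness
#'   beyond the exact-enumeration limit).
#' @return Fitness value.
#' @export
lineage_fitness <- function(lineage, config = evolution_config(),
                            seed = NULL) {
  if (lineage$L < 2L) stop("fitness undefined for a single-cell lineage")
  spec <- robustness_spec(a = config$a, excluded = config$excluded)
  switch(config$fitness,
    fn = necrosis_robustness(lineage, spec),
    fp = eval_fp(lineage, spec, config, seed),
    S = 1 / infer_programs(lineage)$n_programs,
    RxS = necrosis_robustness(lineage, spec)^config$x /
      infer_programs(lineage)$n_programs)
}

eval_fp <- function(lineage, spec, config, seed = NULL) {
  P <- infer_programs(lineage)$n_programs
  if (P <= config$fp_exact_max) {
    exact_program_failure_expectation(lineage, spec,
                                      max_programs = config$fp_exact_max)
  } else {
    as.numeric(program_failure_robustness(
      lineage, spec, replicates = config$fp_replicates, seed = seed))
  }
}

#' Simulate the evolutionary expansion of a cell lineage
#'
#' Grows a lineage whose final terminal census equals `target_census`
#' exactly. The census cells are shuffled once into an arrival sequence;
#' starting from the first cell as the founder, each of the `m - 1` rounds
#' picks candidate bifurcations of uniformly chosen current terminals, one
#' daughter inheriting the parental type and the other taking the next
#' type in the sequence; candidates are ranked by fitness (ties broken by
#' generation order) and the next lineage is drawn uniformly from the top
#' `k`.
#'
#' @param target_census a [cell_type_census()].
#' @param config an [evolution_config()].
#' @param seed RNG seed.
#' @param sequence optional precomputed arrival sequence from
#'   [shuffle_census_cells()] (for paired runs).
#' @param trajectory record per-round statistics (`FALSE` skips the
#'   bookkeeping, which dominates the run time of batch experiments that
#'   only need the final lineage).
#' @return List with `lineage` (the final [cell_lineage()]) and
#'   `trajectory` (one row per round: terminal count, fitness, f_n, f_p,
#'   complexity, max/mean depth, rare-early correlation; `NULL` when not
#'   recorded).
#' @export
evolve_lineage <- function(target_census, config = evolution_config(),
                           seed = NULL, sequence = NULL, trajectory = TRUE) {
  m <- sum(target_census$counts)
  if (m < 2L) stop("target census must contain at least two cells")
  if (is.null(sequence)) sequence <- shuffle_census_cells(target_census, seed)
  stopifnot(nrow(sequence) == m)
  with_seed(seed, evolve_run(sequence, config, target_census, trajectory))
}

# growing-array state: type/label NA on internal nodes
evolve_run <- function(sequence, config, census, record = TRUE) {
  m <- nrow(sequence)
  nmax <- 2L * m - 1L
  parent <- integer(nmax)
  type <- rep(NA_character_, nmax)
  label <- rep(NA_character_, nmax)
  type[1L] <- sequence$type[1L]
  label[1L] <- sequence$label[1L]
  n <- 1L
  tips <- 1L
  traj <- vector("list", m - 1L)
  spec <- robustness_spec(a = config$a, excluded = config$excluded)
  for (r in seq_len(m - 1L)) {
    newtype <- sequence$type[r + 1L]
    newlabel <- sequence$label[r + 1L]
    cand_tip <- resample(tips, config$candidates, replace = TRUE)
    utips <- unique(cand_tip)
    fit_cache <- vapply(utips, function(t) {
      st <- bifurcate(parent, type, label, n, t, newtype, newlabel)
      lin <- arrays_to_lineage(st$parent, st$type, st$label, st$n,
                               mirror = config$mirror)
      lineage_fitness(lin, config)
    }, numeric(1L))
    fit <- fit_cache[match(cand_tip, utips)]
    ord <- order(-fit)                  # stable: ties keep generation order
    winner <- cand_tip[ord[sample.int(min(config$k, length(ord)), 1L)]]
    st <- bifurcate(parent, type, label, n, winner, newtype, newlabel)
    parent <- st$parent; type <- st$type; label <- st$label; n <- st$n
    tips <- c(setdiff(tips, winner), n - 1L, n)
    if (!record) next
    lin <- arrays_to_lineage(parent, type, label, n, mirror = config$mirror)
    dd <- node_depths(lin)
    traj[[r]] <- data.frame(
      round = r, n_terminals = lin$L,
      fitness = lineage_fitness(lin, config),
      f_n = necrosis_robustness(lin, spec),
      f_p = eval_fp(lin, spec, config),
      complexity = infer_programs(lin)$n_programs,
      max_depth = dd$max_depth, mean_depth = dd$mean_depth,
      rho_rare_early = rho_rare_early(lin, spec$excluded)$rho)
  }
  final <- arrays_to_lineage(parent, type, label, n, mirror = config$mirror)
  if (!config$mirror) {
    stopifnot(identical(lineage_census(final)$counts, census$counts))
  }
  list(lineage = final,
       trajectory = if (record) do.call(rbind, traj) else NULL)
}

# split tip t into (n+1) inheriting its type/label and (n+2) taking the
# next cell in the sequence
bifurcate <- function(parent, type, label, n, t, newtype, newlabel) {
  parent[n + 1L] <- t
  parent[n + 2L] <- t
  type[n + 1L] <- type[t]
  label[n + 1L] <- label[t]
  type[n + 2L] <- newtype
  label[n + 2L] <- newlabel
  type[t] <- NA_character_
  label[t] <- NA_character_
  list(parent = parent, type = type, label = label, n = n + 2L)
}

# renumber a growing-array state into a cell_lineage (optionally mirrored)
arrays_to_lineage <- function(parent, type, label, n, mirror = FALSE) {
  tip_nodes <- which(!is.na(type[seq_len(n)]))
  L <- length(tip_nodes)
  if (L == 1L) {
    lin <- cell_lineage(0L, matrix(integer(0), ncol = 2L),
                        label[tip_nodes], type[tip_nodes], 1L)
    return(if (mirror) mirror_lineage(lin) else lin)
  }
  int_nodes <- setdiff(seq_len(n), tip_nodes)
  map <- integer(n)
  map[tip_nodes] <- seq_len(L)
  map[int_nodes] <- L + seq_along(int_nodes)
  children <- matrix(0L, nrow = L - 1L, ncol = 2L)
  slot <- integer(L - 1L)
  newparent <- integer(2L * L - 1L)
  root <- 0L
  for (v in seq_len(n)) {
    pv <- parent[v]
    if (pv == 0L) { root <- map[v]; next }
    newparent[map[v]] <- map[pv]
    i <- map[pv] - L
    slot[i] <- slot[i] + 1L
    children[i, slot[i]] <- map[v]
  }
  lin <- cell_lineage(newparent, children, label[tip_nodes],
                      type[tip_nodes], root)
  if (mirror) mirror_lineage(lin) else lin
}

#' Mirror a half-lineage into a symmetric whole
#'
#' Joins two copies of a lineage under a new root; copy labels get a
#' `.m` suffix, types are unchanged, and every type count doubles.
#'
#' @param lineage a [cell_lineage()] (the half).
#' @return The mirrored [cell_lineage()] with `2 L` terminal cells.
#' @export
mirror_lineage <- function(lineage) {
  half <- sub(";$", "", as_newick(lineage))
  mirror <- half
  for (lb in lineage$tip_label) {
    # leaf names are comma/paren-delimited, so anchored replacement is safe
    mirror <- gsub(paste0("(^|[(,])", lb, "([),])"),
                   paste0("\\1", lb, ".m\\2"), mirror)
  }
  if (lineage$L == 1L) mirror <- paste0(lineage$tip_label, ".m")
  tm <- stats::setNames(c(lineage$tip_type, lineage$tip_type),
                        c(lineage$tip_label,
                          paste0(lineage$tip_label, ".m")))
  parse_lineage(paste0("(", half, ",", mirror, ");"), tm)
}

#' Evolve a mirrored (fully symmetric) lineage
#'
#' Bifurcations are applied to one half-lineage; fitness and trajectory
#' statistics are evaluated on the mirrored whole.
#'
#' @param target_half_census census of the half-lineage.
#' @param config an [evolution_config()] (the mirror flag is forced on).
#' @param seed RNG seed.
#' @param sequence optional precomputed half-census arrival sequence.
#' @return As [evolve_lineage()]; `lineage` is the mirrored whole.
#' @export
mirror_evolve <- function(target_half_census, config = evolution_config(),
                          seed = NULL, sequence = NULL) {
  config$mirror <- TRUE
  evolve_lineage(target_half_census, config, seed, sequence)
}
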