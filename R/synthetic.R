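#' Built-in terminal-cell censuses
#'
#' Per-type terminal-cell counts of the published determinative lineages:
#' the 671-cell embryonic and 937-cell post-embryonic hermaphrodite
#' *Caenorhabditis elegans* censuses (with a neuron-subtype variant), the
#' 638-cell *Pellioditis marina* census and the 110-cell *Halocynthia
#' roretzi* census. Only the counts are packaged; no tree structure is
#' claimed as real data. Apoptotic ("death") types are pre-marked as
#' excluded from the robustness index.
#'
#' @param name census identifier.
#' @return A [cell_type_census()].
#' @examples
#' sum(builtin_census("celegans_embryonic")$counts)  # 671
#' @export
builtin_census <- function(name = c("celegans_embryonic",
                                    "celegans_postembryonic",
                                    "celegans_neuron_subtypes",
                                    "pmarina", "hroretzi")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("census_", name, ".tsv"),
                      package = "linrob", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  cell_type_census(stats::setNames(df$count, df$type),
                   excluded = df$type[df$excluded])
}

#' Canonical toy lineages with analytic reference values
#'
#' Small fixtures whose robustness statistics have closed-form values:
#' `TL1` and `TL2` are four-cell, two-type lineages differing only in how
#' the types are arranged (clonal vs interleaved); `mixed16` is a 16-cell,
#' four-type lineage with mixed clonality; `rare_early` is a three-cell
#' lineage whose rare type sits shallow. Each entry carries its `lineage`
#' and an `oracle` list (exhaustive-enumeration values; f_p at
#' `p = 1/N_internal`).
#'
#' @return Named list of fixtures.
#' @export
toy_lineages <- function() {
  tl1 <- parse_lineage("((A1,A2),(B1,B2));",
                       c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  tl2 <- parse_lineage("((A1,B1),(A2,B2));",
                       c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  mixed16_nwk <- paste0("(((T1a,T1b),(T1c,T2a)),(((T2b,T2d),(T3a,T3b)),",
                     "((T1d,T1e),((T4a,T4b),((T1f,T3c),(T2c,T3d))))));")
  mixed16_types <- c(T1a = "T1", T1b = "T1", T1c = "T1", T2a = "T2",
                  T2b = "T2", T2d = "T2", T3a = "T3", T3b = "T3",
                  T1d = "T1", T1e = "T1", T4a = "T4", T4b = "T4",
                  T1f = "T1", T3c = "T3", T2c = "T2", T3d = "T3")
  mixed16 <- parse_lineage(mixed16_nwk, mixed16_types)
  re <- parse_lineage("((B1,B2),A1);", c(B1 = "B", B2 = "B", A1 = "A"))
  list(
    TL1 = list(lineage = tl1,
               oracle = list(f_n = 1 / 3, f_p = 8 / 27, p = 1 / 3,
                             complexity = 3L, clonality = 5 / 3,
                             n_twins = 2L)),
    TL2 = list(lineage = tl2,
               oracle = list(f_n = 2.5 / 6, f_p = 4 / 9, p = 1 / 3,
                             complexity = 2L, clonality = 5 / 6,
                             n_twins = 0L)),
    mixed16 = list(lineage = mixed16, oracle = list()),
    rare_early = list(lineage = re,
                      oracle = list(rho_rare_early = 1))
  )
}

#' Synthesize a typed cell lineage from a census
#'
#' Builds a random lineage whose terminal census equals `census` exactly.
#' The topology comes from random coalescence; `rare_early` in `[0, 1]`
#' biases rare types toward shallow leaf positions (at strength 1, cells
#' sorted by type size occupy depth-sorted positions exactly), and
#' `twin_enrichment >= 1` multiplies the count of same-type sibling pairs
#' relative to the unenriched draw by greedy label swaps.
#'
#' @param census a [cell_type_census()].
#' @param rare_early rare-early placement strength in `[0, 1]`.
#' @param twin_enrichment target multiple of the baseline twin count.
#' @param seed RNG seed.
#' @return A [cell_lineage()].
#' @export
synth_lineage <- function(census, rare_early = 0, twin_enrichment = 1,
                          seed = NULL) {
  if (rare_early < 0 || rare_early > 1) stop("rare_early must be in [0, 1]")
  if (twin_enrichment < 1) stop("twin_enrichment must be >= 1")
  L <- sum(census$counts)
  if (L < 2L) stop("census must contain at least two cells")
  with_seed(seed, {
    cells <- shuffle_census_cells(census)
    proto <- cell_lineage_from_cells(cells$label, cells$type)
    lin <- rand_coalescent(proto)
    lin <- place_rare_early(lin, rare_early)
    if (twin_enrichment > 1) lin <- enrich_twins(lin, twin_enrichment)
    lin
  })
}

# a star-free placeholder lineage carrying the cells; only its tip
# labels/types matter to rand_coalescent
cell_lineage_from_cells <- function(labels, types) {
  L <- length(labels)
  # arbitrary caterpillar topology
  children <- cbind(c(1L, (L + 1L):(2L * L - 2L)), 2:L)
  parent <- integer(2L * L - 1L)
  for (i in seq_len(L - 1L)) parent[children[i, ]] <- L + i
  cell_lineage(parent, children, labels, types, 2L * L - 1L)
}

# reassign cells to leaf positions: with probability `strength` a cell
# keeps its rank in the (type size, type, cell) order and lands on the
# correspondingly ranked depth slot; the rest are shuffled
place_rare_early <- function(lineage, strength) {
  if (strength == 0) return(lineage)
  L <- lineage$L
  depth <- node_depths(lineage)$tip_depth
  slot_order <- order(depth, stats::runif(L))        # shallow first
  size <- as.vector(table(lineage$tip_type)[lineage$tip_type])
  cell_order <- order(size, lineage$tip_type, stats::runif(L)) # rare first
  keep <- stats::runif(L) < strength
  final <- integer(L)
  final[keep] <- cell_order[keep]
  if (any(!keep)) final[!keep] <- resample(cell_order[!keep])
  lin <- lineage
  lin$tip_label[slot_order] <- lineage$tip_label[final]
  lin$tip_type[slot_order] <- lineage$tip_type[final]
  validate_cell_lineage(lin)
}

# raise the twin count toward factor * baseline by swapping a matching
# cell into one slot of a non-twin sibling pair
enrich_twins <- function(lineage, factor) {
  lin <- lineage
  baseline <- nrow(twin_pairs(lin))
  target <- min(nrow(sibling_tip_pairs(lin)),
                max(baseline + 1L, round(factor * max(baseline, 1L))))
  guard <- 0L
  while (nrow(twin_pairs(lin)) < target && guard < 10000L) {
    guard <- guard + 1L
    sib <- sibling_tip_pairs(lin)
    tt <- lin$tip_type
    open <- sib[tt[sib[, 1L]] != tt[sib[, 2L]], , drop = FALSE]
    if (!nrow(open)) break
    pairq <- open[resample(seq_len(nrow(open)), 1L), ]
    # find a cell elsewhere matching the first member's type and swap it
    # into the second slot; prefer donors that are not twins themselves
    tw <- twin_pairs(lin)
    donor <- setdiff(which(tt == tt[pairq[1L]]), pairq)
    free_donor <- setdiff(donor, as.vector(tw))
    if (length(free_donor)) donor <- free_donor
    if (!length(donor)) next
    d <- resample(donor, 1L)
    s <- pairq[2L]
    lin$tip_label[c(s, d)] <- lin$tip_label[c(d, s)]
    lin$tip_type[c(s, d)] <- lin$tip_type[c(d, s)]
  }
  validate_cell_lineage(lin)
}

#' Synthesize an expression matrix with planted cluster structure
#'
#' Every cluster receives a mean vector; within-cluster noise has unit
#' standard deviation and sister clusters sit `separation` within-cluster
#' SD units apart per gene-block. Cluster centers are not independent:
#' they are laid out on a balanced hierarchy over the clusters ordered by
#' size (Haar-style offsets that double toward the root), emulating the
#' nested transcriptome similarity of real cell types, where subtypes of a
#' broad class resemble each other and share abundance profiles. Cutting
#' the recovered dendrogram coarser than the planted `k` therefore merges
#' size-adjacent clusters rather than arbitrary ones, and cutting finer
#' splits clusters into balanced planted sub-blobs rather than noise
#' outliers.
#'
#' @param partition planted partition: named cluster labels per cell.
#' @param separation between-sister-cluster mean gap in within-cluster SD
#'   units; 0 plants no signal.
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @return Numeric matrix, cells in rows (named), genes in columns.
#' @export
synth_expression <- function(partition, separation, n_genes = 20L,
                             seed = NULL) {
  if (separation < 0) stop("separation must be >= 0")
  cells <- names(partition)
  if (is.null(cells)) stop("partition must be named by cell")
  labs <- as.character(unclass(partition))
  sizes <- sort(table(labs))           # rare types first
  ul <- names(sizes)
  with_seed(seed, {
    means <- matrix(0, nrow = length(cells), ncol = n_genes)
    # recursive Haar layout over cell groups: each split pushes the two
    # halves apart by an offset whose scale halves with depth, so the
    # closest type pairs are size-adjacent sisters and, below the type
    # level, every type carries balanced subtype blobs
    splitrec <- function(groups, scale) {
      if (length(groups) == 1L) {
        cells_in <- groups[[1L]]
        if (length(cells_in) < 2L || scale < 1) return()
        cut <- seq_len(ceiling(length(cells_in) / 2L))
        groups <- list(cells_in[cut], cells_in[-cut])
      }
      half <- seq_len(ceiling(length(groups) / 2L))
      a <- unlist(groups[half])
      b <- unlist(groups[-half])
      offset <- stats::rnorm(n_genes) * scale / 2
      means[a, ] <<- sweep(means[a, , drop = FALSE], 2L, offset, "+")
      means[b, ] <<- sweep(means[b, , drop = FALSE], 2L, offset, "-")
      splitrec(groups[half], scale / 2)
      splitrec(groups[-half], scale / 2)
    }
    if (separation > 0) {
      groups <- lapply(ul, function(u) resample(which(labs == u)))
      depth <- ceiling(log2(max(length(ul), 2L)))
      splitrec(groups, separation * 2^(depth - 1L))
    }
    m <- means + matrix(stats::rnorm(length(cells) * n_genes),
                        nrow = length(cells))
    dimnames(m) <- list(cells, paste0("gene_", seq_len(n_genes)))
    m
  })
}

#' Synthesize 3D terminal-cell coordinates with planted structure
#'
#' Each cell type receives a random spatial center; a cell's position adds
#' a lineage-Brownian component (independent displacements summed along
#' its root path, weighted by `clustering_strength`) plus unit isotropic
#' noise, so that, within a type, lineally close cells are physically
#' close exactly when `clustering_strength > 0`. `twin_adjacency` pulls
#' twin terminal cells toward their midpoint by a factor
#' `1/(1 + twin_adjacency)`.
#'
#' @param lineage a [cell_lineage()].
#' @param clustering_strength weight of the lineage-Brownian component.
#' @param twin_adjacency twin contraction strength.
#' @param seed RNG seed.
#' @return Coordinate data frame (`cell`, `x`, `y`, `z`).
#' @export
synth_coords <- function(lineage, clustering_strength = 0,
                         twin_adjacency = 0, seed = NULL) {
  if (clustering_strength < 0 || twin_adjacency < 0) {
    stop("strengths must be >= 0")
  }
  L <- lineage$L
  types <- sort(unique(lineage$tip_type))
  with_seed(seed, {
    centers <- matrix(stats::runif(length(types) * 3L, 0, 100),
                      nrow = length(types), dimnames = list(types, NULL))
    n <- lineage$n_nodes
    step <- matrix(stats::rnorm(n * 3L), nrow = n)  # per-node displacement
    walk <- matrix(0, nrow = n, ncol = 3L)
    ord <- preorder_nodes(lineage)
    par <- lineage$parent
    for (v in ord) {
      walk[v, ] <- step[v, ] + if (v == lineage$root) 0 else walk[par[v], ]
    }
    pos <- centers[lineage$tip_type, , drop = FALSE] +
      clustering_strength * walk[seq_len(L), , drop = FALSE] +
      matrix(stats::rnorm(L * 3L), nrow = L)
    if (twin_adjacency > 0) {
      tw <- twin_pairs(lineage)
      shrink <- 1 / (1 + twin_adjacency)
      for (q in seq_len(nrow(tw))) {
        mid <- colMeans(pos[tw[q, ], , drop = FALSE])
        pos[tw[q, ], ] <- matrix(mid, 2L, 3L, byrow = TRUE) +
          shrink * sweep(pos[tw[q, ], , drop = FALSE], 2L, mid)
      }
    }
    data.frame(cell = lineage$tip_label, x = pos[, 1L], y = pos[, 2L],
               z = pos[, 3L], stringsAsFactors = FALSE)
  })
}

#' Write a synthetic data bundle
#'
#' Generates and writes a matched set of inputs (Newick tree, type map
#' TSV, coordinates TSV, expression CSV and a JSON manifest recording the
#' seed and settings) under one directory.
#'
#' @param out_dir output directory (created if missing).
#' @param census a [cell_type_census()].
#' @param rare_early,twin_enrichment lineage settings
#'   (see [synth_lineage()]).
#' @param clustering_strength,twin_adjacency coordinate settings
#'   (see [synth_coords()]).
#' @param expression_separation cluster separation (see
#'   [synth_expression()]); the planted partition is the type map.
#' @param n_genes genes in the expression matrix.
#' @param seed RNG seed (fanned out per stage).
#' @return Invisibly, the list of written paths.
#' @export
simulate_data_bundle <- function(out_dir, census,
                                 rare_early = 0.5, twin_enrichment = 1,
                                 clustering_strength = 1,
                                 twin_adjacency = 0,
                                 expression_separation = 5,
                                 n_genes = 20L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lin <- synth_lineage(census, rare_early, twin_enrichment,
                       seed = child_seed(seed, "lineage"))
  coords <- synth_coords(lin, clustering_strength, twin_adjacency,
                         seed = child_seed(seed, "coords"))
  part <- stats::setNames(lin$tip_type, lin$tip_label)
  class(part) <- "partition"
  expr <- synth_expression(part, expression_separation, n_genes,
                           seed = child_seed(seed, "expression"))
  paths <- list(
    newick = file.path(out_dir, "lineage.nwk"),
    types = file.path(out_dir, "types.tsv"),
    coords = file.path(out_dir, "coords.tsv"),
    expression = file.path(out_dir, "expression.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  writeLines(as_newick(lin), paths$newick)
  utils::write.table(data.frame(lin$tip_label, lin$tip_type),
                     paths$types, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(coords, paths$coords, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(cell = rownames(expr), expr),
                     paths$expression, sep = ",", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, census = as.list(census$counts),
         excluded = census$excluded, rare_early = rare_early,
         twin_enrichment = twin_enrichment,
         clustering_strength = clustering_strength,
         twin_adjacency = twin_adjacency,
         expression_separation = expression_separation,
         n_genes = n_genes),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
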