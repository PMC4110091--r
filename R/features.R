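#' Clonality index C of a cell lineage
#'
#' Measures how strongly terminal cells of the same type cluster lineally.
#' For each included type i with at least two cells, the mean lineal
#' distance over all terminal pairs (which is fixed by the tree structure)
#' is divided by the mean lineal distance over the within-type pairs; C is
#' the average of these ratios over the contributing types. Tight
#' within-type clusters shrink the denominator, so larger C means stronger
#' clonality. The alternative `"sum"` form uses raw distance sums instead
#' of means.
#'
#' @param lineage a [cell_lineage()].
#' @param form `"ratio-of-means"` (default) or `"sum"`.
#' @return An object of class `clonality_result`: list with `C`, `form`,
#'   `T` (contributing types), `sum_all` (sum of lineal distances over all
#'   pairs), `mean_all`, and per-type `within` table.
#' @examples
#' lin <- parse_lineage("((A1,A2),(B1,B2));",
#'                      c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
#' clonality(lin)$C  # 5/3
#' @export
clonality <- function(lineage, form = c("ratio-of-means", "sum")) {
  form <- match.arg(form)
  L <- lineage$L
  if (L < 2L) stop("clonality needs at least two terminal cells")
  types <- sort(unique(lineage$tip_type))
  counts <- desc_type_counts(lineage, types)   # per-node tips below, by type
  N <- colSums(counts[seq_len(L), , drop = FALSE])
  # sum of pairwise tip distances = sum over edges of n_below * (n - n_below);
  # one edge sits above every non-root node
  nonroot <- setdiff(seq_len(lineage$n_nodes), lineage$root)
  below_all <- rowSums(counts)[nonroot]
  sum_all <- sum(below_all * (L - below_all))
  pairs_all <- L * (L - 1) / 2
  contributing <- names(N)[N >= 2]
  if (!length(contributing)) {
    stop("clonality undefined: no cell type has two or more terminal cells")
  }
  within <- data.frame(type = contributing, n = as.integer(N[contributing]),
                       sum_d = NA_real_, mean_d = NA_real_,
                       stringsAsFactors = FALSE)
  ratios <- numeric(length(contributing))
  for (k in seq_along(contributing)) {
    ty <- contributing[k]
    bt <- counts[nonroot, ty]
    sum_ty <- sum(bt * (N[ty] - bt))
    pairs_ty <- N[ty] * (N[ty] - 1) / 2
    within$sum_d[k] <- sum_ty
    within$mean_d[k] <- sum_ty / pairs_ty
    ratios[k] <- if (form == "ratio-of-means") {
      (sum_all / pairs_all) / (sum_ty / pairs_ty)
    } else {
      sum_all / sum_ty
    }
  }
  structure(list(C = mean(ratios), form = form, T = length(contributing),
                 sum_all = sum_all, mean_all = sum_all / pairs_all,
                 within = within),
            class = "clonality_result")
}

#' @export
print.clonality_result <- function(x, ...) {
  cat("<clonality_result> C = ", signif(x$C, 6), " (", x$form, ", ",
      x$T, " contributing types)\n", sep = "")
  invisible(x)
}

#' Rare-early correlation
#'
#' Spearman's rank correlation, across terminal cells, between the depth of
#' a cell and the size of its cell type (number of terminal cells of that
#' type). A positive value means rare cell types appear shallow (early) in
#' the lineage. Cells of excluded types (e.g. apoptotic) are left out.
#'
#' @param lineage a [cell_lineage()].
#' @param excluded cell types to drop before correlating.
#' @param null_n if positive, an empirical null via `"relabel-all"`
#'   randomization with this many samples.
#' @param seed RNG seed for the null.
#' @return An object of class `correlation_result`: list with `rho`,
#'   `n_points`, `undefined` flag and optionally `P`/`Z` from the null.
#' @export
rare_early_correlation <- function(lineage, excluded = character(),
                                   null_n = 0L, seed = NULL) {
  res <- rho_rare_early(lineage, excluded)
  out <- structure(list(rho = res$rho, n_points = res$n,
                        undefined = is.na(res$rho), P = NULL, Z = NULL),
                   class = "correlation_result")
  if (!is.na(res$rho) && null_n > 0L) {
    nd <- null_distribution(
      lineage, function(l) rho_rare_early(l, excluded)$rho,
      mode = "relabel-all", n = null_n, direction = "greater", seed = seed,
      statistic_name = "rho_rare_early")
    out$P <- nd$P
    out$Z <- nd$Z
  }
  out
}

# bare statistic used inside nulls and trajectories
rho_rare_early <- function(lineage, excluded = character()) {
  keep <- !(lineage$tip_type %in% excluded)
  depth <- node_depths(lineage)$tip_depth[keep]
  size <- as.vector(table(lineage$tip_type)[lineage$tip_type])[keep]
  if (length(depth) < 2L || length(unique(depth)) < 2L ||
        length(unique(size)) < 2L) {
    return(list(rho = NA_real_, n = length(depth)))
  }
  list(rho = stats::cor(depth, size, method = "spearman"), n = length(depth))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> rho = ", signif(x$rho, 6),
      " over ", x$n_points, " points", sep = "")
  if (!is.null(x$P)) cat(", empirical P = ", x$P, ", Z = ", signif(x$Z, 4),
                         sep = "")
  cat(if (isTRUE(x$undefined)) " [undefined]\n" else "\n")
  invisible(x)
}

#' Read a terminal-cell coordinate table
#'
#' Loads nucleus-center coordinates from a TSV with header columns
#' `cell`, `x`, `y`, `z`. Cells without coordinates are simply absent and
#' are excluded from spatial statistics.
#'
#' @param path TSV path.
#' @return A data frame with columns `cell`, `x`, `y`, `z`.
#' @export
read_coords <- function(path) {
  co <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("cell", "x", "y", "z")
  if (!all(need %in% names(co))) {
    stop("coordinates file must have header columns cell, x, y, z")
  }
  if (!all(is.finite(as.matrix(co[, c("x", "y", "z")])))) {
    stop("coordinates must be finite")
  }
  co[, need]
}

# same-type terminal pairs having coordinates, with physical and lineal
# distances; excluded types dropped
same_type_pair_distances <- function(lineage, coords,
                                     excluded = character()) {
  idx <- match(coords$cell, lineage$tip_label)
  coords <- coords[!is.na(idx), , drop = FALSE]
  tips <- idx[!is.na(idx)]
  keep <- !(lineage$tip_type[tips] %in% excluded)
  tips <- tips[keep]
  coords <- coords[keep, , drop = FALSE]
  depth <- node_depths(lineage)$depth
  par <- lineage$parent
  # ancestor paths once per tip, LCA depth by path comparison
  paths <- lapply(tips, function(v) {
    out <- v
    while (par[v] != 0L) { v <- par[v]; out <- c(out, v) }
    out
  })
  res <- list()
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  for (ty in unique(lineage$tip_type[tips])) {
    members <- which(lineage$tip_type[tips] == ty)
    if (length(members) < 2L) next
    cmb <- utils::combn(members, 2L)
    phys <- sqrt(colSums((t(xyz[cmb[1L, ], , drop = FALSE]) -
                            t(xyz[cmb[2L, ], , drop = FALSE]))^2))
    lin_d <- vapply(seq_len(ncol(cmb)), function(q) {
      a <- cmb[1L, q]; b <- cmb[2L, q]
      anc <- max(depth[intersect(paths[[a]], paths[[b]])])
      depth[tips[a]] + depth[tips[b]] - 2L * anc
    }, numeric(1L))
    res[[ty]] <- data.frame(type = ty, physical = phys, lineal = lin_d)
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

#' Physical-versus-lineal distance correlation
#'
#' Spearman's rank correlation, over all same-type terminal-cell pairs with
#' coordinates, between the Euclidean distance of their nucleus centers and
#' their lineal distance.
#'
#' @param lineage a [cell_lineage()].
#' @param coords coordinate table (see [read_coords()]).
#' @param excluded cell types to drop.
#' @return A `correlation_result` with `rho` and the pair count.
#' @export
physical_lineal_correlation <- function(lineage, coords,
                                        excluded = character()) {
  pd <- same_type_pair_distances(lineage, coords, excluded)
  if (is.null(pd)) stop("no same-type terminal pair with coordinates")
  undef <- stats::sd(pd$physical) == 0 || stats::sd(pd$lineal) == 0
  rho <- if (undef) NA_real_ else
    stats::cor(pd$physical, pd$lineal, method = "spearman")
  structure(list(rho = rho, n_points = nrow(pd), undefined = undef,
                 P = NULL, Z = NULL),
            class = "correlation_result")
}

#' Twin terminal cells
#'
#' Twin terminal cells share their immediate progenitor as well as their
#' cell type.
#'
#' @param lineage a [cell_lineage()].
#' @return List with `n_twins` (number of twin pairs) and `pairs`
#'   (two-column matrix of terminal-cell labels).
#' @export
count_twins <- function(lineage) {
  tw <- twin_pairs(lineage)
  pairs <- matrix(lineage$tip_label[tw], ncol = 2L)
  colnames(pairs) <- c("cell_1", "cell_2")
  list(n_twins = nrow(tw), pairs = pairs)
}

#' Are twin cells physically closer than random same-type pairs?
#'
#' Compares the mean physical distance between twin terminal cells to the
#' distribution of means obtained by repeatedly drawing, for each twin
#' pair, a random pair of distinct terminal cells of the same type.
#' Negative Z means twins sit closer together than expected.
#'
#' @param lineage a [cell_lineage()].
#' @param coords coordinate table (see [read_coords()]).
#' @param reps random-pair replicate count.
#' @param seed RNG seed.
#' @return List with `Z`, `observed` mean twin distance, `null_mean`,
#'   `null_sd`, `n_twins` used, and a `zero_variance` flag.
#' @export
twin_spatial_zscore <- function(lineage, coords, reps = 100L, seed = NULL) {
  tw <- twin_pairs(lineage)
  if (nrow(tw) == 0L) stop("no twin terminal cells in lineage")
  idx <- match(lineage$tip_label, coords$cell)
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  has <- !is.na(idx)
  usable <- tw[has[tw[, 1L]] & has[tw[, 2L]], , drop = FALSE]
  if (nrow(usable) == 0L) stop("no twin pair has coordinates")
  pdist <- function(a, b) {
    sqrt(rowSums((xyz[idx[a], , drop = FALSE] -
                    xyz[idx[b], , drop = FALSE])^2))
  }
  observed <- mean(pdist(usable[, 1L], usable[, 2L]))
  # candidate pools: same-type cells with coordinates, per twin type
  types <- lineage$tip_type[usable[, 1L]]
  pools <- lapply(types, function(ty) {
    which(lineage$tip_type == ty & has)
  })
  if (any(vapply(pools, length, 1L) < 2L)) {
    stop("a twin type has fewer than two cells with coordinates")
  }
  means <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      a <- integer(nrow(usable)); b <- integer(nrow(usable))
      for (q in seq_len(nrow(usable))) {
        pick <- resample(pools[[q]], 2L)
        a[q] <- pick[1L]; b[q] <- pick[2L]
      }
      mean(pdist(a, b))
    }, numeric(1L))
  })
  sdn <- stats::sd(means)
  list(Z = if (sdn > 0) (observed - mean(means)) / sdn else NA_real_,
       observed = observed, null_mean = mean(means), null_sd = sdn,
       n_twins = nrow(usable), zero_variance = !(sdn > 0))
}

#' Greedy hill climb on the physical-lineal correlation
#'
#' Searches for a lineage with a higher physical-versus-lineal distance
#' correlation than the input by repeated one-swap moves: per round,
#' `candidates` neighbors are generated, each differing from the current
#' lineage by one swap between two terminal cells of the same depth and
#' type, and the best is kept if it does not lower the correlation.
#'
#' @param lineage a [cell_lineage()].
#' @param coords coordinate table.
#' @param rounds number of hill-climb rounds.
#' @param candidates one-swap neighbors examined per round.
#' @param excluded cell types ignored in the correlation.
#' @param seed RNG seed.
#' @return List with `lineage` (the improved lineage), `rho_start`,
#'   `rho_final` and the per-round `trace`.
#' @export
hill_climb_rho <- function(lineage, coords, rounds = 100L,
                           candidates = 100L, excluded = character(),
                           seed = NULL) {
  depth <- node_depths(lineage)$tip_depth
  key <- paste(depth, lineage$tip_type)
  swappable <- names(which(table(key) >= 2L))
  rho_of <- function(lin) physical_lineal_correlation(lin, coords,
                                                      excluded)$rho
  current <- lineage
  rho_cur <- rho_of(current)
  rho_start <- rho_cur
  trace <- numeric(rounds)
  if (!length(swappable) || rounds < 1L) {
    return(list(lineage = current, rho_start = rho_start,
                rho_final = rho_cur, trace = numeric(0)))
  }
  with_seed(seed, {
    for (r in seq_len(rounds)) {
      best <- NULL
      best_rho <- -Inf
      for (cc in seq_len(candidates)) {
        grp <- resample(swappable, 1L)
        members <- which(key == grp)
        sw <- resample(members, 2L)
        cand <- current
        cand$tip_label[sw] <- cand$tip_label[rev(sw)]
        # same type by construction; coordinates follow the label
        rho_c <- rho_of(cand)
        if (!is.na(rho_c) && rho_c > best_rho) {
          best <- cand
          best_rho <- rho_c
        }
      }
      if (!is.null(best) && best_rho >= rho_cur) {
        current <- best
        rho_cur <- best_rho
        # swapped labels moved, so the depth/type key must be rebuilt
        key <- paste(node_depths(current)$tip_depth, current$tip_type)
      }
      trace[r] <- rho_cur
    }
  })
  list(lineage = current, rho_start = rho_start, rho_final = rho_cur,
       trace = trace)
}
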