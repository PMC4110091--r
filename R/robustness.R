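#' Robustness calculation settings
#'
#' Bundles the tunable quantities of the robustness index and its two
#' perturbation models: per-type importance exponents `a_i >= 1`, the set of
#' cell types excluded from f (apoptotic/"death" cells), the per-program
#' failure probability `p` (default `1/N_internal`, which makes the expected
#' number of internal cells with failed programs exactly 1), the Monte Carlo
#' replicate count for f_p (default `10 * N_all` where `N_all` is the total
#' number of cells), and the rate model (`"constant"` or `"exponential"`
#' for cell- or program-specific rates drawn from an exponential
#' distribution with the same mean).
#'
#' @param a importance exponents: a scalar, a full vector, or a named
#'   vector (unnamed types default to 1).
#' @param excluded character vector of cell types excluded from f.
#' @param p per-program failure probability; `NULL` means `1/N_internal`.
#' @param replicates Monte Carlo replicates for f_p; `NULL` means
#'   `10 * N_all`.
#' @param rate_model `"constant"` or `"exponential"`.
#' @param seed optional integer RNG seed.
#' @return An object of class `robustness_spec`.
#' @export
robustness_spec <- function(a = 1, excluded = character(), p = NULL,
                            replicates = NULL,
                            rate_model = c("constant", "exponential"),
                            seed = NULL) {
  if (!is.null(p) && (p < 0 || p > 1)) stop("p must lie in [0, 1]")
  if (!is.null(replicates) && replicates < 1) stop("replicates must be >= 1")
  structure(list(a = a, excluded = as.character(excluded), p = p,
                 replicates = replicates,
                 rate_model = match.arg(rate_model), seed = seed),
            class = "robustness_spec")
}

# ---- core: f from per-type losses -------------------------------------

# loss: K x T matrix of lost-cell counts (columns ordered as names(N));
# returns f for each of the K perturbation outcomes
f_from_loss <- function(loss, N, a, included) {
  li <- loss[, included, drop = FALSE]
  Ni <- N[included]
  ai <- a[included]
  if (length(Ni) == 0L) stop("no included cell types in census")
  lg <- log1p(-sweep(li, 2L, Ni, "/"))  # log(n_i / N_i); -Inf when n_i = 0
  as.vector(exp(lg %*% ai))
}

# per-node descendant terminal counts by type: (2L-1) x T matrix
desc_type_counts <- function(lineage, types) {
  L <- lineage$L
  idx <- match(lineage$tip_type, types)
  if (anyNA(idx)) stop("lineage contains a type missing from the census")
  n <- lineage$n_nodes
  counts <- matrix(0, nrow = n, ncol = length(types))
  counts[cbind(seq_len(L), idx)] <- 1
  ord <- rev(preorder_nodes(lineage))
  par <- lineage$parent
  for (v in ord) {
    if (v != lineage$root) counts[par[v], ] <- counts[par[v], ] + counts[v, ]
  }
  colnames(counts) <- types
  counts
}

# census + exponent bookkeeping shared by the robustness functions
rob_prep <- function(lineage, spec) {
  census <- lineage_census(lineage, excluded = spec$excluded)
  N <- census$counts
  a <- a_vector(census, spec$a)
  included <- !names(N) %in% census$excluded
  list(census = census, N = N, a = a, included = included)
}

#' The multiplicative cell-type survival index f
#'
#' f is the product over included cell types of `(n_i / N_i)^{a_i}`, where
#' `N_i` is the unperturbed number of terminal cells of type i, `n_i` the
#' number surviving a perturbation, and `a_i >= 1` its importance exponent.
#' f equals 1 when all included types are fully alive and 0 when any
#' included type is extinguished.
#'
#' @param census a [cell_type_census()].
#' @param survivors named vector of surviving terminal-cell counts per type;
#'   excluded types may be omitted.
#' @param a importance exponents (see [robustness_spec()]).
#' @return f in `[0, 1]`.
#' @export
compute_f <- function(census, survivors, a = 1) {
  N <- census$counts
  unknown <- setdiff(names(survivors), names(N))
  if (length(unknown)) {
    stop("mapping error: unknown type(s) in survivors: ",
         paste(unknown, collapse = ", "))
  }
  full <- N
  full[names(survivors)] <- survivors
  if (any(full > N)) stop("consistency error: survivors exceed census counts")
  if (any(full < 0)) stop("consistency error: negative survivor counts")
  av <- a_vector(census, a)
  included <- !names(N) %in% census$excluded
  f_from_loss(matrix(N - full, nrow = 1L), N, av, included)
}

#' Surviving terminal counts after removing a cell and its descendants
#'
#' Removing any cell (terminal or internal) discards the cell together with
#' all of its direct and indirect descendants; a terminal cell is its own
#' descendant.
#'
#' @param lineage a [cell_lineage()].
#' @param cell terminal-cell label or integer node id.
#' @return Named vector of surviving terminal-cell counts over all types.
#' @export
remove_subtree <- function(lineage, cell) {
  v <- resolve_node(lineage, cell)
  types <- sort(unique(lineage$tip_type))
  counts <- desc_type_counts(lineage, types)
  N <- table(factor(lineage$tip_type, levels = types))
  stats::setNames(as.integer(N) - as.integer(counts[v, ]), types)
}

#' Robustness to necrosis (f_n)
#'
#' The expected f when one uniformly chosen non-root cell dies by necrosis:
#' the single-removal f is computed for every non-root cell (internal and
#' terminal, including excluded-type terminals, whose removal leaves f = 1)
#' and averaged. Fully deterministic.
#'
#' @param lineage a [cell_lineage()].
#' @param spec a [robustness_spec()].
#' @param details if `TRUE`, attach the per-cell f values as attribute `f`.
#' @return f_n in `[0, 1]`.
#' @examples
#' lin <- parse_lineage("((A1,A2),(B1,B2));",
#'                      c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
#' necrosis_robustness(lin)  # 1/3
#' @export
necrosis_robustness <- function(lineage, spec = robustness_spec(),
                                details = FALSE) {
  if (lineage$L == 1L) stop("degenerate input: lineage has no non-root cell")
  pr <- rob_prep(lineage, spec)
  loss <- desc_type_counts(lineage, names(pr$N))
  nonroot <- setdiff(seq_len(lineage$n_nodes), lineage$root)
  f <- f_from_loss(loss[nonroot, , drop = FALSE], pr$N, pr$a, pr$included)
  fn <- mean(f)
  if (details) attr(fn, "f") <- stats::setNames(f, nonroot)
  fn
}

# per-terminal incidence of division programs on the root path:
# returns list(M = L x P logical incidence, programs = program_assignment)
program_incidence <- function(lineage, programs = infer_programs(lineage)) {
  L <- lineage$L
  P <- programs$n_programs
  M <- matrix(FALSE, nrow = L, ncol = P)
  par <- lineage$parent
  for (tip in seq_len(L)) {
    v <- par[tip]
    while (v != 0L) {
      M[tip, programs$program[[v - L]]] <- TRUE
      v <- par[v]
    }
  }
  list(M = M, programs = programs)
}

#' Robustness to division-program failure (f_p), Monte Carlo
#'
#' Per replicate, the number of failing programs is drawn as
#' `b ~ Binomial(N_program, p)` and `b` distinct programs are picked
#' uniformly without replacement; every internal cell using a failed
#' program is arrested and all its descendants are lost. f is computed on
#' the survivors and averaged over replicates (default `10 * N_all`).
#'
#' @inheritParams necrosis_robustness
#' @param replicates overrides `spec$replicates`.
#' @param seed overrides `spec$seed`.
#' @return f_p estimate with attributes `se` (Monte Carlo standard error),
#'   `replicates`, `p` and `n_programs`.
#' @export
program_failure_robustness <- function(lineage, spec = robustness_spec(),
                                       replicates = NULL, seed = NULL) {
  if (lineage$L == 1L) stop("degenerate input: lineage has no division")
  pr <- rob_prep(lineage, spec)
  inc <- program_incidence(lineage)
  P <- inc$programs$n_programs
  p <- if (is.null(spec$p)) 1 / inc$programs$n_internal else spec$p
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  R <- replicates %||% spec$replicates %||% (10L * lineage$n_nodes)
  R <- as.integer(R)
  seed <- seed %||% spec$seed
  typef <- factor(lineage$tip_type, levels = names(pr$N))
  Mnum <- inc$M * 1
  f_all <- with_seed(seed, {
    out <- numeric(R)
    done <- 0L
    while (done < R) {
      chunk <- min(2000L, R - done)
      b <- stats::rbinom(chunk, P, p)
      Fm <- matrix(0, nrow = P, ncol = chunk)
      for (j in seq_len(chunk)) {
        if (b[j] > 0L) Fm[sample.int(P, b[j]), j] <- 1
      }
      dead <- (Mnum %*% Fm) > 0          # L x chunk
      loss <- rowsum(dead * 1, typef)    # T x chunk (levels all present)
      out[done + seq_len(chunk)] <-
        f_from_loss(t(loss), pr$N, pr$a, pr$included)
      done <- done + chunk
    }
    out
  })
  fp <- mean(f_all)
  attr(fp, "se") <- stats::sd(f_all) / sqrt(R)
  attr(fp, "replicates") <- R
  attr(fp, "p") <- p
  attr(fp, "n_programs") <- P
  fp
}

# exact expectation of f under independent/heterogeneous program failure;
# probs is a vector of per-program failure probabilities
exact_fp_probs <- function(lineage, probs, pr, inc) {
  P <- length(probs)
  if (P > 25L) stop("size error: too many programs for exact enumeration")
  L <- lineage$L
  bit <- 2^(seq_len(P) - 1L)
  tipmask <- as.integer(inc$M %*% bit)
  typeidx <- match(lineage$tip_type, names(pr$N))
  Tn <- length(pr$N)
  total <- 0
  for (s in 0:(2^P - 1)) {
    fail <- bitwAnd(s, bit) > 0
    w <- prod(ifelse(fail, probs, 1 - probs))
    if (w == 0) next
    dead <- bitwAnd(tipmask, s) != 0L
    lost <- tabulate(typeidx[dead], nbins = Tn)
    total <- total + w * f_from_loss(matrix(lost, nrow = 1L),
                                     pr$N, pr$a, pr$included)
  }
  total
}

#' Exact expectation of f under program failure
#'
#' Sums `f * probability` over all subsets of failing programs, serving as
#' an exact oracle for [program_failure_robustness()] on lineages with few
#' programs.
#'
#' @inheritParams necrosis_robustness
#' @param max_programs refuse enumeration beyond this many programs.
#' @return Exact f_p.
#' @export
exact_program_failure_expectation <- function(lineage,
                                              spec = robustness_spec(),
                                              max_programs = 18L) {
  if (lineage$L == 1L) stop("degenerate input: lineage has no division")
  pr <- rob_prep(lineage, spec)
  inc <- program_incidence(lineage)
  P <- inc$programs$n_programs
  if (P > max_programs) {
    stop("size error: ", P, " programs exceed max_programs = ", max_programs)
  }
  p <- if (is.null(spec$p)) 1 / inc$programs$n_internal else spec$p
  exact_fp_probs(lineage, rep(p, P), pr, inc)
}

#' Robustness under cell- and program-specific perturbation rates
#'
#' Relaxes the equal-rates assumption: per draw, every non-root cell
#' receives a necrosis rate and every program a failure probability drawn
#' from an exponential distribution whose mean equals the constant rate
#' (`1/n_nonroot` per cell; `p` per program, truncated at 1). f_n becomes
#' the rate-weighted mean of the single-removal f values; f_p is the
#' expectation under the drawn per-program probabilities (exact enumeration
#' when feasible, Monte Carlo otherwise). Both are averaged over draws.
#'
#' @inheritParams necrosis_robustness
#' @param draws number of rate draws.
#' @param seed RNG seed.
#' @param max_exact exact f_p enumeration limit (programs).
#' @param mc_replicates Monte Carlo replicates used above `max_exact`.
#' @return `list(f_n_variable, f_p_variable, draws)`.
#' @export
variable_rate_robustness <- function(lineage, spec = robustness_spec(),
                                     draws = 100L, seed = NULL,
                                     max_exact = 12L, mc_replicates = 1000L) {
  if (draws < 1) stop("draws must be >= 1")
  pr <- rob_prep(lineage, spec)
  loss <- desc_type_counts(lineage, names(pr$N))
  nonroot <- setdiff(seq_len(lineage$n_nodes), lineage$root)
  f_single <- f_from_loss(loss[nonroot, , drop = FALSE],
                          pr$N, pr$a, pr$included)
  inc <- program_incidence(lineage)
  P <- inc$programs$n_programs
  p <- if (is.null(spec$p)) 1 / inc$programs$n_internal else spec$p
  nn <- length(nonroot)
  with_seed(seed %||% spec$seed, {
    fn_draws <- numeric(draws)
    fp_draws <- numeric(draws)
    for (d in seq_len(draws)) {
      r <- stats::rexp(nn, rate = nn)          # mean 1/nn per cell
      fn_draws[d] <- sum(r * f_single) / sum(r)
      pj <- pmin(stats::rexp(P, rate = 1 / p), 1)
      if (P <= max_exact) {
        fp_draws[d] <- exact_fp_probs(lineage, pj, pr, inc)
      } else {
        fp_draws[d] <- mc_fp_probs(lineage, pj, pr, inc, mc_replicates)
      }
    }
    list(f_n_variable = mean(fn_draws), f_p_variable = mean(fp_draws),
         draws = draws)
  })
}

# Monte Carlo f_p under heterogeneous per-program failure probabilities
mc_fp_probs <- function(lineage, probs, pr, inc, replicates) {
  P <- length(probs)
  typef <- factor(lineage$tip_type, levels = names(pr$N))
  Fm <- matrix(stats::runif(P * replicates) < probs, nrow = P)
  dead <- ((inc$M * 1) %*% Fm) > 0
  loss <- rowsum(dead * 1, typef)
  mean(f_from_loss(t(loss), pr$N, pr$a, pr$included))
}

#' Distribution of individual f values under stochastic perturbation
#'
#' Individuals sharing one expected lineage still differ in realized f
#' because necrosis and program failure are stochastic. Per draw, in
#' necrosis mode every non-root cell dies independently with probability
#' `1/n_nonroot` (one expected necrosis per lineage); in program mode every
#' program fails independently with probability `p`.
#'
#' @inheritParams necrosis_robustness
#' @param ndraws number of simulated individuals (>= 2).
#' @param mode `"necrosis"` or `"program"`.
#' @param seed RNG seed.
#' @return `list(samples, mean, sd)`.
#' @export
stochastic_f_distribution <- function(lineage, spec = robustness_spec(),
                                      ndraws = 1000L,
                                      mode = c("necrosis", "program"),
                                      seed = NULL) {
  mode <- match.arg(mode)
  if (ndraws < 2) stop("ndraws must be >= 2")
  pr <- rob_prep(lineage, spec)
  samples <- with_seed(seed %||% spec$seed, {
    if (mode == "necrosis") {
      loss <- desc_type_counts(lineage, names(pr$N))
      nonroot <- setdiff(seq_len(lineage$n_nodes), lineage$root)
      nn <- length(nonroot)
      pdie <- 1 / nn
      typeidx <- match(lineage$tip_type, names(pr$N))
      # descendant tip lists per node, for cheap unions of the few deaths
      tips_below <- descendant_tip_list(lineage)
      out <- numeric(ndraws)
      for (d in seq_len(ndraws)) {
        k <- stats::rbinom(1L, nn, pdie)
        if (k == 0L) { out[d] <- 1; next }
        dead_nodes <- nonroot[sample.int(nn, k)]
        dead_tips <- unique(unlist(tips_below[dead_nodes]))
        lost <- tabulate(typeidx[dead_tips], nbins = length(pr$N))
        out[d] <- f_from_loss(matrix(lost, nrow = 1L),
                              pr$N, pr$a, pr$included)
      }
      out
    } else {
      inc <- program_incidence(lineage)
      P <- inc$programs$n_programs
      p <- if (is.null(spec$p)) 1 / inc$programs$n_internal else spec$p
      out <- numeric(ndraws)
      done <- 0L
      typef <- factor(lineage$tip_type, levels = names(pr$N))
      while (done < ndraws) {
        chunk <- min(2000L, ndraws - done)
        Fm <- matrix(stats::runif(P * chunk) < p, nrow = P)
        dead <- ((inc$M * 1) %*% Fm) > 0
        loss <- rowsum(dead * 1, typef)
        out[done + seq_len(chunk)] <-
          f_from_loss(t(loss), pr$N, pr$a, pr$included)
        done <- done + chunk
      }
      out
    }
  })
  list(samples = samples, mean = mean(samples), sd = stats::sd(samples))
}

# list of descendant terminal ids for every node (a tip lists itself)
descendant_tip_list <- function(lineage) {
  L <- lineage$L
  out <- vector("list", lineage$n_nodes)
  for (tip in seq_len(L)) out[[tip]] <- tip
  for (v in rev(preorder_nodes(lineage))) {
    if (v > L) {
      kids <- lineage$children[v - L, ]
      out[[v]] <- c(out[[kids[1L]]], out[[kids[2L]]])
    }
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
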