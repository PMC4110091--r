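#' Validate an analysis input bundle
#'
#' Checks that the tree parses as a rooted binary lineage, that every
#' terminal cell has a type, and (when given) how many terminal cells have
#' coordinates; spatial statistics are restricted to those that do.
#'
#' @param newick_file Newick tree path.
#' @param type_map_file two-column headerless TSV (cell, type).
#' @param coords_file optional coordinates TSV (cell, x, y, z header).
#' @return List with `errors` and `warnings` (character vectors) and, on
#'   success, the parsed `lineage` and `coords`.
#' @export
validate_inputs <- function(newick_file, type_map_file,
                            coords_file = NULL) {
  errors <- character(0)
  warnings <- character(0)
  lineage <- NULL
  coords <- NULL
  for (p in c(newick_file, type_map_file, coords_file)) {
    if (!is.null(p) && !file.exists(p)) {
      errors <- c(errors, paste0("missing file: ", p))
    }
  }
  if (!length(errors)) {
    lineage <- tryCatch(read_lineage(newick_file, type_map_file),
                        error = function(e) {
                          errors <<- c(errors, conditionMessage(e))
                          NULL
                        })
  }
  if (!is.null(lineage) && !is.null(coords_file)) {
    coords <- tryCatch(read_coords(coords_file),
                       error = function(e) {
                         errors <<- c(errors, conditionMessage(e))
                         NULL
                       })
    if (!is.null(coords)) {
      n_missing <- sum(!(lineage$tip_label %in% coords$cell))
      if (n_missing > 0L) {
        warnings <- c(warnings, paste0(
          n_missing, " of ", lineage$L, " terminal cells lack coordinates;",
          " spatial statistics are restricted to the rest"))
      }
    }
  }
  list(errors = errors, warnings = warnings, lineage = lineage,
       coords = coords)
}

#' Run the full lineage-robustness analysis
#'
#' Computes the per-lineage report (f_n, f_p, depths, complexity,
#' clonality, rare-early correlation, twin count), an optional table of
#' empirical null tests, optional spatial statistics, and writes
#' everything as TSV/JSON under `out_dir`. Fully deterministic under a
#' fixed `seed`: one global seed fans out to fixed per-stage child seeds.
#'
#' @param lineage a [cell_lineage()] (or use `newick_file`/`type_map_file`).
#' @param newick_file,type_map_file,coords_file input paths, used when
#'   `lineage` is `NULL`.
#' @param coords optional coordinate data frame (overrides `coords_file`).
#' @param spec a [robustness_spec()].
#' @param nulls list of null analyses, each a list with elements
#'   `statistic` (`"f_n"`, `"f_p"` or `"rho_rare_early"`), `mode`
#'   (see [randomize_lineage()]), `n`, and optional `max_depth`/`g`;
#'   f_p inside nulls uses `fp_replicates` Monte Carlo replicates.
#' @param fp_replicates replicate count for f_p (`NULL`: the
#'   `10 * N_all` default for the observed lineage; nulls use 1000).
#' @param out_dir output directory; `NULL` skips writing.
#' @param seed global seed.
#' @return List with `report` (one-row data frame), `null_tests` (data
#'   frame or `NULL`), `spatial` (list or `NULL`), and `paths`.
#' @export
run_analysis <- function(lineage = NULL, newick_file = NULL,
                         type_map_file = NULL, coords_file = NULL,
                         coords = NULL, spec = robustness_spec(),
                         nulls = list(), fp_replicates = NULL,
                         out_dir = NULL, seed = 1L) {
  if (is.null(lineage)) {
    diag <- validate_inputs(newick_file, type_map_file, coords_file)
    if (length(diag$errors)) {
      stop("invalid inputs:\n  ", paste(diag$errors, collapse = "\n  "))
    }
    lineage <- diag$lineage
    if (is.null(coords)) coords <- diag$coords
  }
  fn <- necrosis_robustness(lineage, spec)
  fp <- program_failure_robustness(lineage, spec,
                                   replicates = fp_replicates,
                                   seed = child_seed(seed, "fp"))
  dd <- node_depths(lineage)
  progs <- infer_programs(lineage)
  cl <- clonality(lineage)
  re <- rho_rare_early(lineage, spec$excluded)
  report <- data.frame(
    L = lineage$L, n_internal = progs$n_internal,
    f_n = fn, f_p = as.numeric(fp), fp_se = attr(fp, "se"),
    fp_replicates = attr(fp, "replicates"), p = attr(fp, "p"),
    complexity = progs$n_programs,
    max_depth = dd$max_depth, mean_depth = dd$mean_depth,
    min_max_depth = theoretical_min_max_depth(lineage$L),
    clonality = cl$C, rho_rare_early = re$rho,
    n_twins = count_twins(lineage)$n_twins,
    seed = seed)
  null_tests <- NULL
  if (length(nulls)) {
    rows <- lapply(seq_along(nulls), function(i) {
      nl <- nulls[[i]]
      stat_fun <- switch(
        nl$statistic,
        f_n = function(l) necrosis_robustness(l, spec),
        f_p = function(l) as.numeric(program_failure_robustness(
          l, spec, replicates = nl$fp_replicates %||% 1000L)),
        rho_rare_early = function(l) rho_rare_early(l, spec$excluded)$rho,
        stop("unknown null statistic: ", nl$statistic))
      nd <- null_distribution(
        lineage, stat_fun, mode = nl$mode, n = nl$n %||% 1000L,
        direction = nl$direction %||% "greater",
        seed = child_seed(seed, paste0("null", i)),
        statistic_name = nl$statistic,
        max_depth = nl$max_depth, g = nl$g)
      data.frame(statistic = nl$statistic, mode = nl$mode, n = nd$n,
                 observed = nd$observed, null_mean = mean(nd$samples),
                 null_sd = stats::sd(nd$samples), P = nd$P, Z = nd$Z)
    })
    null_tests <- do.call(rbind, rows)
  }
  spatial <- NULL
  if (!is.null(coords)) {
    spatial <- list(
      rho_p_l = physical_lineal_correlation(lineage, coords,
                                            spec$excluded)$rho,
      twin_z = tryCatch(
        twin_spatial_zscore(lineage, coords,
                            seed = child_seed(seed, "twinz"))$Z,
        error = function(e) NA_real_))
  }
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(report = file.path(out_dir, "report.tsv"),
                  null_tests = file.path(out_dir, "null_tests.tsv"),
                  spatial = file.path(out_dir, "spatial.json"))
    utils::write.table(report, paths$report, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(null_tests)) {
      utils::write.table(null_tests, paths$null_tests, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(spatial)) {
      jsonlite::write_json(spatial, paths$spatial, auto_unbox = TRUE,
                           digits = NA)
    }
  }
  list(report = report, null_tests = null_tests, spatial = spatial,
       paths = paths)
}
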