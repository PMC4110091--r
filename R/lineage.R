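#' Rooted binary cell-lineage trees
#'
#' A `cell_lineage` represents a determinative developmental cell lineage as
#' a rooted binary tree: every internal node is a progenitor cell that
#' divides into exactly two daughters, and every terminal node (leaf) is a
#' terminal cell carrying a cell-type label. Branch lengths play no role;
#' lineage "time" is counted in cell divisions (depth).
#'
#' Node numbering follows the ape convention: terminal cells are `1..L`,
#' internal cells are `L+1 .. 2L-1`. The root is an internal cell (or, for
#' the degenerate single-cell lineage, the sole terminal cell).
#'
#' @param parent integer vector, `parent[v]` is the parent node of `v`
#'   (0 for the root).
#' @param children integer matrix with one row per internal cell (row `i`
#'   corresponds to node `L + i`) holding its two daughters in left/right
#'   order.
#' @param tip_label character vector of terminal-cell names.
#' @param tip_type character vector of terminal-cell type labels, parallel
#'   to `tip_label`.
#' @param root integer id of the root node.
#' @return An object of class `cell_lineage` with fields `parent`,
#'   `children`, `tip_label`, `tip_type`, `root`, `L` (number of terminal
#'   cells) and `n_nodes` (`2L - 1`).
#' @seealso [parse_lineage()] to build one from Newick text,
#'   [node_depths()], [infer_programs()], [lineage_census()].
#' @export
cell_lineage <- function(parent, children, tip_label, tip_type, root) {
  L <- length(tip_label)
  obj <- structure(
    list(
      parent = as.integer(parent),
      children = matrix(as.integer(children), ncol = 2),
      tip_label = as.character(tip_label),
      tip_type = as.character(tip_type),
      root = as.integer(root),
      L = L,
      n_nodes = if (L == 1L) 1L else 2L * L - 1L
    ),
    class = "cell_lineage"
  )
  validate_cell_lineage(obj)
}

#' @rdname cell_lineage
#' @param x object to validate.
#' @export
validate_cell_lineage <- function(x) {
  stopifnot(inherits(x, "cell_lineage"))
  L <- x$L
  if (L < 1L) stop("a cell lineage needs at least one terminal cell")
  if (length(x$tip_type) != L) stop("tip_type and tip_label lengths differ")
  if (anyNA(x$tip_type) || any(x$tip_type == "")) {
    stop("every terminal cell must carry a type label")
  }
  if (anyDuplicated(x$tip_label)) stop("terminal cell names must be unique")
  if (L == 1L) {
    if (x$root != 1L || nrow(x$children) != 0L) {
      stop("single-cell lineage must consist of the root terminal only")
    }
    return(x)
  }
  n <- 2L * L - 1L
  if (length(x$parent) != n) stop("parent vector has wrong length")
  if (nrow(x$children) != L - 1L) {
    stop("number of internal cells must be L - 1")
  }
  if (x$root <= L || x$root > n) stop("root must be an internal node")
  if (x$parent[x$root] != 0L) stop("root must have parent 0")
  if (sum(x$parent == 0L) != 1L) stop("exactly one root is required")
  kid <- as.vector(x$children)
  if (anyNA(kid) || any(kid < 1L) || any(kid > n)) {
    stop("children matrix refers to unknown nodes")
  }
  if (anyDuplicated(kid) || length(kid) != n - 1L) {
    stop("every non-root node must be the child of exactly one internal node")
  }
  for (i in seq_len(L - 1L)) {
    if (any(x$parent[x$children[i, ]] != L + i)) {
      stop("parent and children maps disagree")
    }
  }
  # reachability from the root guards against disconnected cycles
  seen <- logical(n)
  stack <- x$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) stop("cycle detected in lineage")
    seen[v] <- TRUE
    if (v > L) stack <- c(stack, x$children[v - L, ])
  }
  if (!all(seen)) stop("lineage is not connected")
  x
}

#' Parse a cell lineage from Newick text and a cell-to-type map
#'
#' Reads a rooted, strictly binary tree in Newick format (branch lengths and
#' internal-node labels, if present, are ignored) and attaches a cell-type
#' label to every terminal cell.
#'
#' @param newick_text a Newick string (or a length-1 path is *not*
#'   accepted here; see [read_lineage()] for files).
#' @param type_map either a named character vector (`cell -> type`) or a
#'   two-column data frame with cell ids in column 1 and type names in
#'   column 2.
#' @return A [cell_lineage()].
#' @examples
#' lin <- parse_lineage("((A1,A2),(B1,B2));",
#'                      c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
#' lin$L
#' @export
parse_lineage <- function(newick_text, type_map) {
  type_map <- as_type_map(type_map)
  phy <- tryCatch(
    ape::read.tree(text = newick_text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e)),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w))
  )
  if (is.null(phy)) stop("malformed Newick: could not parse tree text")
  as_cell_lineage_phylo(phy, type_map)
}

# accepts named character vector or 2-column table
as_type_map <- function(type_map) {
  if (is.data.frame(type_map)) {
    tm <- as.character(type_map[[2L]])
    names(tm) <- as.character(type_map[[1L]])
    type_map <- tm
  }
  if (is.null(names(type_map)) || anyNA(names(type_map))) {
    stop("type_map must carry cell ids as names (or as its first column)")
  }
  type_map
}

# convert an ape phylo (rooted, binary, >= 2 tips) to cell_lineage
as_cell_lineage_phylo <- function(phy, type_map) {
  L <- length(phy$tip.label)
  if (L < 2L) stop("a parsed lineage needs at least two terminal cells")
  if (phy$Nnode != L - 1L) {
    stop("structure error: tree is not strictly binary (",
         phy$Nnode, " internal nodes for ", L, " terminals)")
  }
  n <- 2L * L - 1L
  parent <- integer(n)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  deg <- tabulate(phy$edge[, 1L], nbins = n)
  if (any(deg[(L + 1L):n] != 2L)) {
    stop("structure error: non-binary internal node in tree")
  }
  children <- matrix(0L, nrow = L - 1L, ncol = 2L)
  slot <- integer(L - 1L)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L] - L
    slot[p] <- slot[p] + 1L
    children[p, slot[p]] <- phy$edge[e, 2L]
  }
  missing <- setdiff(phy$tip.label, names(type_map))
  if (length(missing)) {
    stop("mapping error: no cell type for terminal cell(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  root <- which(parent[(L + 1L):n] == 0L) + L
  cell_lineage(parent, children, phy$tip.label,
               unname(type_map[phy$tip.label]), root)
}

#' @export
print.cell_lineage <- function(x, ...) {
  cat("<cell_lineage> ", x$L, " terminal cells, ",
      max(0L, x$L - 1L), " internal cells\n", sep = "")
  tab <- sort(table(x$tip_type), decreasing = TRUE)
  cat("  types: ",
      paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "),
      "\n", sep = "")
  d <- node_depths(x)
  cat("  max terminal depth ", d$max_depth,
      ", mean terminal depth ", round(d$mean_depth, 3), "\n", sep = "")
  invisible(x)
}

# preorder node sequence (root first, children after parents)
preorder_nodes <- function(lin) {
  if (lin$L == 1L) return(1L)
  n <- lin$n_nodes
  out <- integer(n)
  stack <- integer(n)
  stack[1L] <- lin$root
  sp <- 1L
  k <- 0L
  L <- lin$L
  ch <- lin$children
  while (sp > 0L) {
    v <- stack[sp]
    sp <- sp - 1L
    k <- k + 1L
    out[k] <- v
    if (v > L) {
      stack[sp + 1L] <- ch[v - L, 2L]
      stack[sp + 2L] <- ch[v - L, 1L]
      sp <- sp + 2L
    }
  }
  out
}

#' Cell depths (division counts from the zygote)
#'
#' The depth of a cell is the number of cell divisions required to generate
#' it from the root (the zygote), so the root sits at depth 0 and each
#' daughter is one deeper than its parent.
#'
#' @param lineage a [cell_lineage()].
#' @return A list with `depth` (integer vector indexed by node id over all
#'   `2L - 1` cells), `tip_depth` (named by terminal-cell label),
#'   `max_depth` and `mean_depth` (maximum and mean depth over terminal
#'   cells).
#' @export
node_depths <- function(lineage) {
  L <- lineage$L
  if (L == 1L) {
    td <- 0L
    names(td) <- lineage$tip_label
    return(list(depth = 0L, tip_depth = td, max_depth = 0L, mean_depth = 0))
  }
  depth <- integer(lineage$n_nodes)
  ord <- preorder_nodes(lineage)
  par <- lineage$parent
  for (v in ord[-1L]) depth[v] <- depth[par[v]] + 1L
  td <- depth[seq_len(L)]
  names(td) <- lineage$tip_label
  list(depth = depth, tip_depth = td,
       max_depth = max(td), mean_depth = mean(td))
}

#' Theoretical minimum of the maximum depth
#'
#' A binary lineage producing `L` terminal cells cannot have a maximum
#' terminal depth below `ceiling(log2(L))`: that bound is attained by a
#' perfectly balanced tree.
#'
#' @param L number of terminal cells (vectorised).
#' @return Integer vector of depth lower bounds.
#' @examples
#' theoretical_min_max_depth(c(671, 638, 110))  # 10 10 7
#' @export
theoretical_min_max_depth <- function(L) {
  if (any(L < 1)) stop("L must be >= 1")
  # guard against log2(2^k) landing just above k in floating point
  as.integer(ceiling(log2(L) - 1e-9))
}

#' Lineal distance between two cells
#'
#' The lineal distance is the number of tree edges on the shortest path
#' connecting two cells.
#'
#' @param lineage a [cell_lineage()].
#' @param cell_a,cell_b terminal-cell labels or integer node ids.
#' @return Non-negative integer path length.
#' @export
lineal_distance <- function(lineage, cell_a, cell_b) {
  a <- resolve_node(lineage, cell_a)
  b <- resolve_node(lineage, cell_b)
  if (a == b) return(0L)
  depth <- node_depths(lineage)$depth
  par <- lineage$parent
  d <- 0L
  while (depth[a] > depth[b]) { a <- par[a]; d <- d + 1L }
  while (depth[b] > depth[a]) { b <- par[b]; d <- d + 1L }
  while (a != b) { a <- par[a]; b <- par[b]; d <- d + 2L }
  d
}

resolve_node <- function(lineage, cell) {
  if (is.character(cell)) {
    i <- match(cell, lineage$tip_label)
    if (is.na(i)) stop("lookup error: unknown cell '", cell, "'")
    return(i)
  }
  cell <- as.integer(cell)
  if (is.na(cell) || cell < 1L || cell > lineage$n_nodes) {
    stop("lookup error: node id out of range")
  }
  cell
}

#' Infer division programs by recursive fate canonicalization
#'
#' The division program of an internal cell is defined entirely by the fates
#' of its two daughters, where the fate of a terminal daughter is its cell
#' type and the fate of an internal daughter is its own division program.
#' Fates are combined as an unordered pair, so swapping left and right
#' daughters never changes a program. The number of distinct programs is the
#' lineage complexity.
#'
#' @param lineage a [cell_lineage()].
#' @return An object of class `program_assignment`: list with `program`
#'   (integer program id per internal node, named by node id), `key`
#'   (canonical string key per program id), `usage` (number of internal
#'   cells per program), `n_internal` and `n_programs` (lineage complexity).
#' @examples
#' lin <- parse_lineage("((A1,A2),(B1,B2));",
#'                      c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
#' infer_programs(lin)$n_programs  # 3
#' @export
infer_programs <- function(lineage) {
  L <- lineage$L
  if (L == 1L) {
    return(structure(list(program = integer(0), key = character(0),
                          usage = integer(0), n_internal = 0L,
                          n_programs = 0L),
                     class = "program_assignment"))
  }
  ord <- rev(preorder_nodes(lineage))  # postorder: children before parents
  fate <- character(lineage$n_nodes)
  fate[seq_len(L)] <- lineage$tip_type
  keys <- character(L - 1L)
  for (v in ord) {
    if (v <= L) next
    kids <- lineage$children[v - L, ]
    pair <- sort(c(fate[kids[1L]], fate[kids[2L]]))
    key <- paste0("(", pair[1L], "|", pair[2L], ")")
    keys[v - L] <- key
    fate[v] <- key
  }
  uk <- unique(keys)
  prog <- match(keys, uk)
  names(prog) <- as.character((L + 1L):lineage$n_nodes)
  structure(list(program = prog, key = uk,
                 usage = tabulate(prog, nbins = length(uk)),
                 n_internal = L - 1L, n_programs = length(uk)),
            class = "program_assignment")
}

#' @export
print.program_assignment <- function(x, ...) {
  cat("<program_assignment> ", x$n_programs, " distinct programs over ",
      x$n_internal, " internal cells\n", sep = "")
  invisible(x)
}

#' Terminal cell-type census of a lineage
#'
#' Counts terminal cells per type. Types in `excluded` (typically
#' programmed-cell-death / apoptotic types) keep their counts but are
#' excluded from the robustness index f; `T_included` counts the remaining
#' types.
#'
#' @param lineage a [cell_lineage()].
#' @param excluded character vector of type names excluded from f.
#' @return A `cell_type_census`: list with `counts` (named integer vector),
#'   `excluded` and `T_included`.
#' @export
lineage_census <- function(lineage, excluded = character()) {
  counts <- table(lineage$tip_type)
  cell_type_census(stats::setNames(as.integer(counts), names(counts)),
                   excluded = excluded)
}

#' @rdname lineage_census
#' @param counts named integer vector of per-type terminal-cell counts.
#' @export
cell_type_census <- function(counts, excluded = character()) {
  if (is.null(names(counts)) || anyNA(names(counts))) {
    stop("census counts must be named by cell type")
  }
  if (any(counts < 1L)) stop("census counts must be positive")
  unknown <- setdiff(excluded, names(counts))
  # silently allow excluding a type absent from this lineage (e.g. a
  # death type when no apoptotic cell exists)
  excluded <- setdiff(excluded, unknown)
  counts <- counts[sort(names(counts))]  # canonical type order
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 excluded = as.character(excluded),
                 T_included = sum(!names(counts) %in% excluded)),
            class = "cell_type_census")
}

#' @export
print.cell_type_census <- function(x, ...) {
  cat("<cell_type_census> ", sum(x$counts), " terminal cells, ",
      x$T_included, " included types",
      if (length(x$excluded)) paste0(" (excluded: ",
                                     paste(x$excluded, collapse = ", "), ")"),
      "\n", sep = "")
  print(x$counts)
  invisible(x)
}

# ---- file I/O ----------------------------------------------------------

#' Read and write cell lineages
#'
#' `read_lineage()` loads a lineage from a Newick tree file plus a
#' two-column headerless TSV type map (cell id, type name).
#' `read_lineage_json()`/`write_lineage_json()` round-trip a single JSON
#' container holding the tree, the type map and optional 3D coordinates.
#'
#' @param newick_file path to a Newick file.
#' @param type_map_file path to a two-column headerless TSV (cell, type).
#' @return A [cell_lineage()]; the JSON reader returns
#'   `list(lineage, coords)` where `coords` may be `NULL`.
#' @export
read_lineage <- function(newick_file, type_map_file) {
  tm <- utils::read.table(type_map_file, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          col.names = c("cell", "type"))
  parse_lineage(paste(readLines(newick_file), collapse = ""), tm)
}

#' @rdname read_lineage
#' @param lineage a [cell_lineage()].
#' @param coords optional coordinate table as returned by [read_coords()].
#' @param path output / input JSON path.
#' @export
write_lineage_json <- function(lineage, path, coords = NULL) {
  obj <- list(newick = as_newick(lineage),
              types = as.list(stats::setNames(lineage$tip_type,
                                              lineage$tip_label)))
  if (!is.null(coords)) obj$coords <- coords
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_lineage
#' @export
read_lineage_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lin <- parse_lineage(obj$newick, unlist(obj$types))
  coords <- NULL
  if (!is.null(obj$coords)) {
    coords <- as.data.frame(obj$coords)
    coords$cell <- as.character(coords$cell)
  }
  list(lineage = lin, coords = coords)
}

#' Serialize a lineage to Newick text
#'
#' @param lineage a [cell_lineage()].
#' @return A Newick string (no branch lengths).
#' @export
as_newick <- function(lineage) {
  L <- lineage$L
  if (L == 1L) return(paste0(lineage$tip_label, ";"))
  build <- function(v) {
    if (v <= L) return(lineage$tip_label[v])
    kids <- lineage$children[v - L, ]
    paste0("(", build(kids[1L]), ",", build(kids[2L]), ")")
  }
  paste0(build(lineage$root), ";")
}

#' Convert to an ape phylo object
#'
#' @param lineage a [cell_lineage()].
#' @return An object of class `phylo` (unit branch lengths omitted).
#' @export
as_phylo <- function(lineage) {
  ape::read.tree(text = as_newick(lineage))
}
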