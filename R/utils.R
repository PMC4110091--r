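# internal helpers shared across modules

# evaluate expr with a temporarily fixed RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a bounded child seed from a global seed and a stage label, so
# pipeline stages are independently reproducible
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

# sample() that never falls into the 1:n trap on length-1 vectors
resample <- function(x, size = length(x), ...) {
  x[sample.int(length(x), size, ...)]
}

# expand a scalar or partially-named exponent spec into a full named vector
# over the census types; a_i >= 1 is required by the robustness index
a_vector <- function(census, a) {
  types <- names(census$counts)
  if (is.null(names(a))) {
    if (length(a) == 1L) {
      av <- stats::setNames(rep(as.numeric(a), length(types)), types)
    } else if (length(a) == length(types)) {
      av <- stats::setNames(as.numeric(a), types)
    } else {
      stop("a must be scalar, named, or one value per census type")
    }
  } else {
    unknown <- setdiff(names(a), types)
    if (length(unknown)) {
      stop("exponent given for unknown type(s): ",
           paste(unknown, collapse = ", "))
    }
    av <- stats::setNames(rep(1, length(types)), types)
    av[names(a)] <- as.numeric(a)
  }
  if (any(av < 1)) stop("exponents a_i must be >= 1")
  av
}
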