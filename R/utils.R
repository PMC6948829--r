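# internal helpers shared across stages

#' Round half away from zero
#'
#' Edge-count rounding for binarized networks uses round-half-up, so that
#' 25% of the 210 measure pairs gives 53 edges (base `round()` would give 52).
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, halves rounded up.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Evaluate an expression with a temporary RNG state
#'
#' Seeds the RNG, runs `expr`, and restores the caller's RNG state, so that
#' seeded operations do not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic sub-seeds below 2^31 derived from one root seed
derive_seeds <- function(root_seed, n) {
  with_seed(root_seed, sample.int(.Machine$integer.max - 1L, n))
}

# polynomial rolling hash of a character scalar; fingerprints configs in run logs
fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

pn_log <- function(..., file = NULL) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(..., collapse = ""))
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE, sep = "")
  invisible(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# matrix <-> plain-list representation that survives a JSON round trip
mat_to_list <- function(m) {
  list(rows = rownames(m), cols = colnames(m), values = unname(as.matrix(m)))
}

list_to_mat <- function(l) {
  v <- l$values
  if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
  m <- as.matrix(v)
  rn <- unlist(l$rows); cn <- unlist(l$cols)
  if (length(rn)) rownames(m) <- rn
  if (length(cn)) colnames(m) <- cn
  m
}
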