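# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state so
#' package functions never clobber the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derivation from one top-level seed.  Offsets
# keep the streams of the generator stages and of each per-gene classifier
# distinct while everything remains a pure function of the top-level seed.
derive_seed <- function(seed, offset = 0L) {
  s <- (as.numeric(seed) + as.numeric(offset)) %% 2147483647
  as.integer(s)
}

# Small stable hash of a string onto 0..99999, used to give each gene its own
# reproducible RNG stream in the per-gene classifier stage.
string_offset <- function(x) {
  v <- utf8ToInt(x)
  as.integer(sum(v * seq_along(v)) %% 100000L)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
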