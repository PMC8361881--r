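# Internal helpers shared across modules.

# Complement/reverse-complement on plain character strings. Biostrings is used
# for FASTA I/O; these avoid XString construction in hot loops.
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so that seeded sampling inside the package
#' never perturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# logit with the pseudocount convention used for PSI values.
logit_psi <- function(psi, eps = 0.01) {
  log((psi + eps) / (1 - psi + eps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
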