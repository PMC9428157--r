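# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All seeded operations in the package go
# through this so that user-level RNG state is never clobbered.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Draw one Dirichlet vector via independent gammas; alpha entries equal to
# zero yield structural zeros (the taxon is absent from the template).
rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  g <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  # guard against all-zero gamma draws at very small shapes
  if (sum(g) <= 0) g[which.max(alpha[pos])] <- 1
  x[pos] <- g / sum(g)
  x
}

geometric_mean <- function(x, na.rm = TRUE) {
  x <- x[if (na.rm) !is.na(x) else TRUE]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) return(NA_real_)
  exp(mean(log(x)))
}

# Polynomial rolling hash of a character representation; used only to stamp
# output files with a short config fingerprint for provenance.
fnv1a_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_values <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
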