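# Internal helpers shared across modules.

# Replicate-pad a matrix by the given margins (edge-value padding).
pad_replicate <- function(m, top, bottom, left, right) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rep(1L, top), seq_len(h), rep(h, bottom))
  ci <- c(rep(1L, left), seq_len(w), rep(w, right))
  m[ri, ci, drop = FALSE]
}

# Block boundaries for splitting an extent of n pixels into k blocks:
# b_i = floor(i * n / k), i = 0..k.  Block i (1-based) holds 0-based
# coordinates v with b_{i-1} <= v < b_i; trailing blocks absorb remainders.
block_bounds <- function(n, k) floor((0:k) * n / k)

# Map 0-based coordinates to 1-based block indices given block_bounds().
block_index <- function(v, bounds) {
  findInterval(v, bounds[-length(bounds)])
}

# Deterministic 31-bit seed derived from a stream of integer components.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() accepts it.
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  s <- 11
  for (p in parts) s <- (s * 48271 + p * 16807 + 1) %% 2147483647
  as.integer(s %% 2147483645) + 1L
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (any(!is.finite(img)))
    stop(sprintf("`%s` contains non-finite intensities", arg), call. = FALSE)
  invisible(img)
}

check_video <- function(video, arg = "video") {
  if (!is.array(video) || length(dim(video)) != 3L || !is.numeric(video))
    stop(sprintf("`%s` must be a numeric 3-D array (height x width x length)", arg),
         call. = FALSE)
  if (any(!is.finite(video)))
    stop(sprintf("`%s` contains non-finite intensities", arg), call. = FALSE)
  invisible(video)
}
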