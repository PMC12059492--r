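# Internal numeric and plumbing helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable logistic function
#' @param x numeric vector or matrix
#' @return values in (0, 1)
#' @keywords internal
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# Row-wise softmax with -Inf masking support; rows with all -Inf are invalid.
softmax_rows <- function(e) {
  mx <- apply(e, 1L, max)
  z <- exp(e - mx)
  z[is.nan(z)] <- 0 # -Inf - -Inf
  z / rowSums(z)
}

# Clamp probabilities away from 0/1 before taking logs.
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Derive a module seed from a global seed
#'
#' One global seed deterministically spawns per-stage seeds so that pipeline
#' stages remain reproducible independently of execution order. Results are
#' kept below 2^31 - 1.
#'
#' @param seed integer global seed
#' @param stage character stage label
#' @return integer seed
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- fnv1a(paste0(stage, ":", format(seed, scientific = FALSE)))
  as.integer(h %% 2147483647)
}

# Polynomial rolling hash of a string over the Mersenne prime 2^31 - 1.
# Used for seed derivation and config fingerprinting, not cryptography.
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  h
}

# Largest-remainder apportionment of n into parts proportional to `ratios`.
largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Stable stratified mode with recency tie-break: among values tied for the
# highest count, the one observed most recently wins. `times` breaks ties.
mode_recency <- function(values, times) {
  key <- as.character(values)
  tab <- table(key)
  top <- names(tab)[tab == max(tab)]
  cand <- key %in% top
  values[cand][which.max(times[cand])]
}
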