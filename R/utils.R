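# Internal helpers shared across modules.

#' @import data.table
#' @importFrom methods as is
#' @importFrom stats median pchisq pnorm pt rbinom rlnorm rnbinom rnorm rpois runif
#' @importFrom utils read.csv write.csv head
NULL

# data.table NSE column symbols
utils::globalVariables(c(
  ".N", ".SD", "pct", "n", "count", "chain_key", "rate", "n_mac", "n_trog",
  "cdr3", "cdr3_aa", "tcr_pos", "cd4", "cd8", "share", "clonotype_key"))

# Deterministic 31-ary polynomial string hash, kept below 2^31 - 1 so it can
# seed R's RNG. Arithmetic stays within double precision (< 2^53).
hash_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% m
  h
}

# Splitting rule for per-sample / per-purpose RNG streams: combine a master
# seed with a string label through a multiplicative congruential step.
derive_seed <- function(seed, label) {
  m <- 2147483647
  as.integer((((seed %% m) * 48271) %% m + hash_string(label)) %% m)
}

with_stream <- function(seed, label, code) {
  withr::with_seed(derive_seed(seed, label), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

# Counts -> counts-per-10k -> log1p, the conventional normalization for
# marker scoring and signature scoring. Returns a dgCMatrix.
lognormalize <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::colSums(counts)
  totals[totals == 0] <- 1  # all-zero cells stay all-zero
  x <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  x@x <- log1p(x@x)
  dimnames(x) <- dimnames(counts)
  methods::as(x, "CsparseMatrix")
}
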