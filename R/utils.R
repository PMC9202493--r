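# Internal numeric and string helpers shared across modules.

# Zero-truncated Poisson -----------------------------------------------------

#' Rate of a zero-truncated Poisson with a given mean
#'
#' Solves lambda / (1 - exp(-lambda)) = m for lambda. The zero-truncated
#' Poisson mean is always > 1, so `m` must exceed 1.
#' @param m target mean, must be > 1
#' @return the Poisson rate lambda
#' @keywords internal
#' @noRd
ztp_rate <- function(m) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m))
  if (m <= 1) {
    stop("a zero-truncated Poisson cannot have mean <= 1 (got ", m, ")")
  }
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 interval = c(1e-10, m * 10), tol = 1e-12)$root
}

# Inverse-CDF sampler: u is uniform on (P(K=0), 1), so qpois(u) >= 1.
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  p0 <- stats::dpois(0, lambda)
  u <- stats::runif(n, min = p0, max = 1)
  as.integer(stats::qpois(u, lambda))
}

ztp_pmf <- function(k, lambda) {
  stats::dpois(k, lambda) / (1 - exp(-lambda))
}


# Poisson-binomial pmf (independent Bernoulli probs p) by direct convolution.
poisbinom_pmf <- function(p) {
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf  # pmf[s + 1] = P(S = s)
}

# Zipf ------------------------------------------------------------------------

zipf_weights <- function(n, exponent = 1) {
  if (n <= 0L) return(numeric(0))
  w <- 1 / seq_len(n)^exponent
  w / sum(w)
}

# Misc ------------------------------------------------------------------------

# Round half away from zero (Table-style percentage rounding), vectorized.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Case-fold + trim: the canonicalization applied to raw strings and map keys.
normalize_key <- function(x) tolower(trimws(x))

# Canonical single-string key for an itemset (order-free).
itemset_key <- function(items) paste(sort(items), collapse = "\x1f")

key_to_items <- function(key) strsplit(key, "\x1f", fixed = TRUE)

# Join/split for human-readable outputs.
join_terms <- function(items) paste(sort(items), collapse = ";")

split_terms <- function(x) strsplit(x, ";", fixed = TRUE)

# Deterministic polynomial hash of a string, for config fingerprints in run
# manifests (not cryptographic; collisions are inconsequential here).
string_fingerprint <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
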