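# internal helpers: argument checking and seed derivation

stop_domain <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("`%s` must be a single finite number", name))
  if (strict_lower) {
    if (x <= lower) stop_domain(sprintf("`%s` must be > %g", name, lower))
  } else if (x < lower) {
    stop_domain(sprintf("`%s` must be >= %g", name, lower))
  }
  if (x > upper) stop_domain(sprintf("`%s` must be <= %g", name, upper))
  if (integerish && abs(x - round(x)) > 1e-8)
    stop_domain(sprintf("`%s` must be an integer", name))
  x
}

# Deterministic 31-bit sub-stream seed from a master seed and a label, so
# that per-droplet randomness does not depend on render order or subsetting.
# Simple polynomial string hash mod the Mersenne prime 2^31 - 1.
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

# run-length encode a logical vector; returns data.frame(start, length, value)
rle_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1L, length = r$lengths, value = r$values)
}
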