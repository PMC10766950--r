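#' @keywords internal
"_PACKAGE"

# Polynomial rolling content hash (mod the Mersenne prime 2^31 - 1), used to
# stamp pipeline output tables so reruns can be checked for byte-identity
# without external digest packages. Double arithmetic stays exact: values
# never exceed 2^31 * 131 + 255 < 2^53.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# BH step-up, exposed internally so tests can compare against stats::p.adjust
# and a brute-force oracle.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fd <- function(...) stop(..., call. = FALSE)

check_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop_fd("'seed' must be a single number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
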