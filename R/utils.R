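#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx ar.yw binom.test chisq.test fft filter median
#'   mvfft na.omit pbinom qbeta qnorm quantile rbinom rnorm rpois runif sd
#'   t.test var predict
#' @importFrom utils head read.csv write.csv
NULL

MOD31 <- 2147483647

#' Derive a reproducible child seed from a master seed and a key
#'
#' Stable arithmetic hash (multiplicative congruential over 2^31 - 1) used to
#' fan a single master seed out to per-stage, per-run and per-fold seeds so
#' that every source of randomness in a run is determined by one integer.
#'
#' @param master integer master seed.
#' @param key character or integer tag identifying the consumer (e.g. a run
#'   index or an infant id).
#' @return an integer in `[1, 2^31 - 2]` suitable for `set.seed()`.
#' @export
derive_seed <- function(master, key) {
  h <- as.numeric(master) %% MOD31
  for (ch in utf8ToInt(paste0("#", as.character(key)))) {
    # keep products below 2^53: 2^31 * 127 * 31 < 2^44
    h <- (h * 31 + ch) %% MOD31
  }
  h <- (h * 48271) %% MOD31
  as.integer(h %% (MOD31 - 2) + 1)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_invalid("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_invalid("'%s' must be positive and finite", name)
  invisible(x)
}

# dB with a hard floor, used for all energy reporting
db_floor <- function(p, floor_db = -120) {
  out <- rep(floor_db, length(p))
  pos <- is.finite(p) & p > 0
  out[pos] <- pmax(10 * log10(p[pos]), floor_db)
  out
}

# FNV-1a over a raw vector; cheap content checksum for run manifests
fnv1a <- function(raw_bytes) {
  h <- 2166136261
  for (b in as.integer(raw_bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

file_checksum <- function(path) {
  fnv1a(readBin(path, "raw", n = file.info(path)$size))
}
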