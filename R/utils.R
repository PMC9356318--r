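# Internal helpers shared across modules.

# Coerce a 2-vector of dates (or ISO strings) into a validated window.
as_window <- function(window) {
  if (is.null(window)) return(NULL)
  if (length(window) != 2L) {
    stop("`window` must be a length-2 vector c(start, end)", call. = FALSE)
  }
  w <- as.Date(window)
  if (anyNA(w)) stop("`window` contains unparseable dates", call. = FALSE)
  if (w[1] > w[2]) stop("`window` start is after its end", call. = FALSE)
  w
}

# Deterministic substream seed: mixes a base seed with an index, staying
# within the 32-bit integer range set.seed() accepts.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

# Canonical unordered pair ordering for admission ids.
canonical_pair <- function(a, b) {
  swap <- a > b
  tibble::tibble(
    admission_a = ifelse(swap, b, a),
    admission_b = ifelse(swap, a, b)
  )
}

assert_bundle <- function(bundle) {
  if (!inherits(bundle, "encounter_bundle")) {
    stop("expected an `encounter_bundle` (see `encounter_bundle()`)", call. = FALSE)
  }
  invisible(bundle)
}
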