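# Internal helpers shared across modules.

# Deterministic sub-seed so each generator draws from its own named
# substream of the single user seed; adding a generator never perturbs
# the draws of another. Result stays below 2^31 - 1.
substream_seed <- function(seed, name) {
  chars <- utf8ToInt(name)
  h <- sum(chars * seq_along(chars)) %% 104729L
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(h)
}

abort_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

abort_input <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse band labels like "15-19" / "90+" into numeric bounds.
# Open-ended final bands are capped at age 99 for sampling purposes.
band_bounds <- function(bands) {
  lo <- numeric(length(bands))
  hi <- numeric(length(bands))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    if (grepl("^\\d+\\+$", b)) {
      lo[i] <- as.numeric(sub("\\+$", "", b))
      hi[i] <- 99
    } else if (grepl("^\\d+-\\d+$", b)) {
      parts <- as.numeric(strsplit(b, "-", fixed = TRUE)[[1]])
      lo[i] <- parts[1]
      hi[i] <- parts[2]
    } else {
      abort_input("unparseable age band label '%s'", b)
    }
  }
  tibble::tibble(age_band = bands, lo = lo, hi = hi, mid = (lo + hi) / 2)
}

# Assign ages to configured bands; ages above the last closed band fall
# into the open-ended band.
age_to_band <- function(age, bands) {
  bb <- band_bounds(bands)
  idx <- findInterval(age, bb$lo)
  idx[idx < 1L] <- NA_integer_
  bands[idx]
}
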