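# Shared internal helpers.

# Case-fold a word for lexicon lookup while preserving accents
# (Spanish norms are accent-sensitive: 'papa' != 'papá').
fold_word <- function(x) tolower(x)

abort_schema <- function(msg) stop(structure(
  class = c("pltmarkers_schema_error", "error", "condition"),
  list(message = msg, call = NULL)
))

abort_validation <- function(msg) stop(structure(
  class = c("pltmarkers_validation_error", "error", "condition"),
  list(message = msg, call = NULL)
))

# Sample variance with configurable denominator; NA when fewer than 2 values.
# Short sequences yield an undefined value rather than a fabricated zero.
seq_variance <- function(x, var_type = c("sample", "population")) {
  var_type <- match.arg(var_type)
  n <- length(x)
  if (n < 2L) return(NA_real_)
  if (var_type == "sample") var(x) else var(x) * (n - 1) / n
}

# Mean that treats NA as "undefined for that unit": NA only if all missing.
mean_defined <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}

# Derive a 32-bit sub-seed from a master seed and a stream label.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 69069 + h * 1013 + 1) %% 2147483647)
}
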