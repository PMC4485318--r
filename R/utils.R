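# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

abort <- function(..., class = "plastisig_error") {
  stop(errorCondition(paste0(...), class = c(class, "plastisig_error", "error")))
}

validation_error <- function(...) abort(..., class = "plastisig_validation_error")
parse_error <- function(...) abort(..., class = "plastisig_parse_error")

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Format numbers for TSV output so that a write/read round trip preserves
# values to well below 1e-12 relative error.
format_num <- function(x) formatC(x, digits = 17, format = "g")
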