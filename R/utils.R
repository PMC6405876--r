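# internal helpers

# evaluate `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# derive a stream-specific 31-bit sub-seed from a master seed
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(stream) * 97) %% 2147483562) + 1L
}

stop_mrr <- function(msg, class) {
  rlang::abort(msg, class = paste0("mrrkit_", class))
}

sex_levels <- c("male", "female")

normalize_sex <- function(x) {
  out <- dplyr::case_when(
    x %in% c("M", "m", "male") ~ "male",
    x %in% c("F", "f", "female") ~ "female",
    TRUE ~ NA_character_
  )
  out
}

# fold a coordinate into [0, w] by reflection at the boundaries
reflect_into <- function(x, w) {
  y <- x %% (2 * w)
  ifelse(y > w, 2 * w - y, y)
}
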