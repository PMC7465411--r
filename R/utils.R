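#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# round half away from zero at `digits` decimals; base round() is half-to-even
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# cosine similarity of two numeric vectors; errors carry the offending label
cosine_sim <- function(a, b, label_a = "a", label_b = "b") {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0) abort(paste0("zero vector for heading '", label_a, "'"))
  if (nb == 0) abort(paste0("zero vector for heading '", label_b, "'"))
  sum(a * b) / (na * nb)
}

# row-wise softmax with max-shift for numerical stability
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
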