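`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_mitopop <- function(..., class = "mitopop_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Derive a child RNG seed from a user seed; keeps results < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483587)
}

ALLELES <- c("A", "C", "G", "T", "-")
BASES <- c("A", "C", "G", "T")

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop_mitopop(name, " must be a non-negative integer")
  as.integer(x)
}
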