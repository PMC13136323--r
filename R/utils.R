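# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_named <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# clamp to an interval, preserving NA
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= 0
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

# Fisher z transform guarded against |rho| = 1
fisher_z <- function(r, eps = 1e-12) atanh(clamp(r, -1 + eps, 1 - eps))
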