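# Internal helpers shared across modules.

# Uppercase + strip surrounding whitespace; the only symbol normalisation
# performed anywhere (no alias resolution).
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

stop_dg <- function(msg, class, ...) {
  abort(msg, class = c(class, "dualgene_error"), ...)
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    stop_dg(sprintf("`%s` must be positive and finite.", name),
            "dualgene_domain_error")
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}
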