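# Internal helpers shared across modules.

# Band masks on discrete frequency grids must be robust to the floating-point
# noise of seq(); endpoints are inclusive by convention (7.0 and 13.0 count).
in_band <- function(freqs, band, tol = 1e-8) {
  freqs >= band[1] - tol & freqs <= band[2] + tol
}

stop_alphapaf <- function(message, class, ...) {
  stop(structure(
    class = c(class, "alphapaf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
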