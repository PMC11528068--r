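# Internal helpers shared across modules.

# Clamp to [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Squared-correlation clamp used by the Gaussian MI closed form; bounds MI at
# -log(MI_RHO2_EPS)/2 ~= 13.8 nats so duplicated rows stay finite.
MI_RHO2_EPS <- 1e-12

# Soft diagnostic channel: degenerate-input conventions (constant vectors,
# all-zero rows) are flagged without aborting vectorized paths.
flag_note <- function(...) message("spotfuse note: ", ...)

stop_sf <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of a file, or NA if absent.
file_hash <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}
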