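#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-item sub-seeds derived from a master seed (< 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Compartment label dictionary used throughout (atlas integer codes).
COMPARTMENT_LABELS <- c(LFC = 1L, LT = 2L, MFC = 3L, MT = 4L, TRO = 5L, PAT = 6L)

# Broad anatomical groupings used for thickness adjustment.
COMPARTMENT_GROUPS <- list(
  femoral  = c("MFC", "LFC", "TRO"),
  tibial   = c("MT", "LT"),
  patellar = "PAT"
)

compartment_names <- function() names(COMPARTMENT_LABELS)
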