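# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# evaluate expr with a locally seeded RNG, restoring global RNG state after
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# atomic number for the elements that occur in protein models
.atomic_numbers <- c(
  H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34, FE = 26,
  MG = 12, ZN = 30, CA = 20, "NA" = 11, K = 19, CL = 17, MN = 25
)

atomic_number <- function(element) {
  z <- .atomic_numbers[toupper(element)]
  z[is.na(z)] <- 6  # unknown elements scatter roughly like carbon
  unname(z)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stopf("cannot normalize a zero-length vector")
  v / n
}
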