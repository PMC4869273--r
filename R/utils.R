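#' Reverse-complement nucleotide sequences
#'
#' Vectorised reverse complement over `{A,C,G,T,N}`; any other character
#' becomes `N`.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length (names preserved).
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Maximal runs where `low` (logical vector) is TRUE, as a 0-based half-open
# interval matrix with columns start/end; zero-row matrix when none.
runs_true <- function(low) {
  if (!any(low)) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  m <- cbind(start = starts[r$values], end = ends[r$values])
  storage.mode(m) <- "integer"
  m
}

# uppercase, U -> T
normalise_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
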