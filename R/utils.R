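# internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
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
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Normalize a span string before bagging
#'
#' Lowercases, trims leading/trailing whitespace, and collapses internal
#' whitespace runs to a single space. Used before any entropy computation so
#' trivial casing/spacing variants of the same surface form do not inflate
#' span diversity.
#'
#' @param x character vector of raw span strings.
#' @return character vector of normalized strings.
#' @export
#' @examples
#' normalize_span(c("Stable ", "  stable", "no  change"))
normalize_span <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Shannon entropy (base 2) of a vector of non-negative counts
#'
#' @param counts numeric vector of counts or weights; zeros are dropped.
#' @return entropy in bits; 0 for a single positive count.
#' @export
#' @examples
#' entropy_bits(c(15, 1, 1, 2, 1))
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("entropy of an empty bag is undefined", call. = FALSE)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# pairwise interval overlap between two annotation frames restricted to the
# same document; returns a data.frame of row indices into a and b plus the
# overlap length in characters (only pairs with overlap >= 1 are returned)
overlap_pairs <- function(a, b) {
  out <- list()
  docs <- intersect(unique(a$doc_id), unique(b$doc_id))
  for (d in docs) {
    ia <- which(a$doc_id == d)
    ib <- which(b$doc_id == d)
    if (!length(ia) || !length(ib)) next
    lo <- outer(a$start[ia], b$start[ib], pmax)
    hi <- outer(a$end[ia], b$end[ib], pmin)
    len <- hi - lo
    hit <- which(len > 0, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        i = ia[hit[, 1L]],
        j = ib[hit[, 2L]],
        overlap = len[hit],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(), overlap = integer()))
  }
  do.call(rbind, out)
}

# sum `x` by `by` and return a named numeric vector (names = group labels)
sum_by <- function(x, by) {
  v <- tapply(x, by, sum)
  out <- as.numeric(v)
  names(out) <- names(v)
  out
}

# uniform draw from an inclusive integer range c(lo, hi); immune to the
# sample(x, 1) scalar surprise when lo == hi
sample_range <- function(r) {
  v <- seq.int(r[1L], r[2L])
  v[sample.int(length(v), 1L)]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
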