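#' Length of genomic intervals
#'
#' Intervals are 1-based and inclusive at both ends, matching the coordinate
#' convention in which published aCGH calls are printed, so a single-base
#' interval has length 1.
#'
#' @param x A data frame with integer columns `start` and `end`
#'   (1-based inclusive), or a numeric vector of starts if `end` is given.
#' @param end Optional numeric vector of end positions when `x` is a vector
#'   of starts.
#' @return Integer vector of lengths, `end - start + 1`.
#' @examples
#' interval_length(tibble::tibble(chrom = "chr16",
#'                                start = 73290945, end = 73626825))
#' @export
interval_length <- function(x, end = NULL) {
  if (is.data.frame(x)) {
    start <- x$start
    end <- x$end
  } else {
    start <- x
  }
  if (is.null(end)) rlang::abort("`end` positions are required.")
  check_intervals(start, end)
  as.integer(round(end - start + 1))
}

# shared validation for 1-based inclusive intervals
check_intervals <- function(start, end, what = "interval") {
  if (length(start) != length(end)) {
    rlang::abort(sprintf("%s start/end lengths differ.", what))
  }
  if (length(start) == 0) return(invisible(TRUE))
  if (anyNA(start) || anyNA(end) || any(!is.finite(start)) || any(!is.finite(end))) {
    rlang::abort(sprintf("%s coordinates must be finite and non-missing.", what))
  }
  if (any(start < 1)) rlang::abort(sprintf("%s start must be >= 1.", what))
  if (any(end < start)) rlang::abort(sprintf("%s end must be >= start.", what))
  invisible(TRUE)
}

#' Normalize chromosome names
#'
#' Accepts both `"chr1"` and `"1"` dialects and returns names with the
#' `"chr"` prefix, so files from either convention join cleanly.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector with a `"chr"` prefix on every name.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Reciprocal overlap between interval pairs
#'
#' The field-standard match criterion for CNV events: the overlap must cover
#' at least a fraction `f` of *each* interval. Returns the minimum of the two
#' coverage fractions (0 when the intervals are disjoint), which callers
#' compare against their threshold.
#'
#' @param start1,end1,start2,end2 Numeric vectors of 1-based inclusive
#'   coordinates; recycled to a common length.
#' @return Numeric vector in \[0, 1\]: `min(overlap/len1, overlap/len2)`.
#' @export
reciprocal_overlap <- function(start1, end1, start2, end2) {
  n <- max(length(start1), length(start2))
  start1 <- rep_len(start1, n); end1 <- rep_len(end1, n)
  start2 <- rep_len(start2, n); end2 <- rep_len(end2, n)
  ov <- pmin(end1, end2) - pmax(start1, start2) + 1
  ov <- pmax(ov, 0)
  pmin(ov / (end1 - start1 + 1), ov / (end2 - start2 + 1))
}

# run a block with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  }
  force(code)
}
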