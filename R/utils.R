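# Small shared helpers. Sequences are plain uppercase character scalars over
# {A,C,G,T,N}; Biostrings objects appear only at the IO / alignment boundary.

.check_sequence <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    abort(sprintf("`%s` must be a single non-empty string", arg))
  }
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    abort(sprintf("`%s` contains characters outside {A,C,G,T,N}", arg))
  }
  x
}

#' Reverse complement of a nucleotide string
#'
#' @param x A single nucleotide string over `A,C,G,T,N`.
#' @return The reverse complement, as a string.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  x <- .check_sequence(x)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

.subseq <- function(x, start, end) substr(x, start, end)

# Run code with a temporary RNG state derived from `seed`, restoring the
# caller's state afterwards. All generator randomness funnels through this.
.with_seed <- function(seed, code) {
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
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)

# locate all (possibly overlapping) occurrences of a fixed pattern
.find_all <- function(subject, pattern) {
  out <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(pattern, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (hit == -1L) break
    out <- c(out, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)
  }
  out
}
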