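# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over plain character strings (A/C/G/T,
#' case-insensitive; IUPAC ambiguity codes are not accepted).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  x <- toupper(as.character(x))
  comp <- chartr("ACGT", "TGCA", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
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
    set.seed(seed)
  }
  force(expr)
}

# stopifnot with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

read_tsv_checked <- function(path, required, what) {
  abort_if(!file.exists(path), "%s file not found: %s", what, path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  missing <- setdiff(required, names(df))
  abort_if(length(missing) > 0, "%s file %s lacks column(s): %s",
           what, path, paste(missing, collapse = ", "))
  df
}

write_tsv_plain <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

# Random DNA of length n with a given GC fraction; optionally a per-position
# GC probability vector.
random_dna <- function(n, gc = 0.5) {
  if (length(gc) == 1) gc <- rep(gc, n)
  is_gc <- stats::runif(n) < gc
  base <- character(n)
  base[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
  base[!is_gc] <- sample(c("A", "T"), sum(!is_gc), replace = TRUE)
  paste(base, collapse = "")
}
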