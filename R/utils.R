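# internal helpers shared across modules

# standard amino-acid alphabet; everything else is coerced to X
.qs_standard_aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.qs_msg <- function(...) message("[qstate] ", sprintf(...))

#' Replace non-standard residues by X
#'
#' Sequences are uppercased; residues outside the 20 standard letters
#' (for example B, Z, U, O, J) are mapped to `X` with a warning.  Empty
#' sequences are rejected.
#'
#' @param sequences character vector of amino-acid sequences.
#' @return character vector of cleaned sequences.
#' @export
clean_sequences <- function(sequences) {
  stopifnot(is.character(sequences))
  if (any(is.na(sequences) | !nzchar(sequences))) {
    stop("empty sequence encountered; every record needs a non-empty sequence")
  }
  up <- toupper(sequences)
  ok <- c(.qs_standard_aa, "X")
  bad <- lapply(strsplit(up, ""), function(ch) setdiff(unique(ch), ok))
  n_bad <- sum(lengths(bad) > 0)
  if (n_bad > 0) {
    letters_seen <- sort(unique(unlist(bad)))
    warning(sprintf(
      "%d sequence(s) contain non-standard residues (%s); mapped to X",
      n_bad, paste(letters_seen, collapse = ",")), call. = FALSE)
    up <- vapply(up, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[!(ch %in% ok)] <- "X"
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  up
}

# run expr with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards
.qs_with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# largest-remainder apportionment of n into shares `p` (sums to n)
.qs_apportion <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-8)
  raw <- n * p
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
    cnt[extra] <- cnt[extra] + 1
  }
  as.integer(cnt)
}
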