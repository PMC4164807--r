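# Global pairwise alignment and identity filtering.

#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment under linear gap scoring. Tie-breaking during
#' traceback is deterministic: diagonal is preferred over a gap in the
#' second sequence ("up"), which is preferred over a gap in the first
#' ("left"). `X` scores as a mismatch against everything, including `X`.
#'
#' @param a,b Character scalars or `seq_record`s; ungapped sequences.
#' @param match Score for an identical pair (default 1).
#' @param mismatch Score for a differing pair (default -1).
#' @param gap Score per gapped position (default -2, linear).
#' @return A list of class `pairwise_alignment` with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings) and `score`.
#' @export
needleman_wunsch <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- if (inherits(a, "seq_record")) a$residues else toupper(as.character(a))
  b <- if (inherits(b, "seq_record")) b$residues else toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  # F: (n+1) x (m+1) score matrix; P: traceback pointer (1 diag, 2 up, 3 left)
  F <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)
  F[, 1L] <- gap * (0:n); F[1L, ] <- gap * (0:m)
  P[, 1L] <- 2L; P[1L, ] <- 3L; P[1L, 1L] <- 0L
  subst <- ifelse(outer(av, bv, "=="), match, mismatch)
  subst[av == "X", ] <- mismatch
  subst[, bv == "X"] <- mismatch
  for (i in 1:n) {
    diag_row <- F[i, 1:m] + subst[i, ]
    prev <- F[i + 1L, 1L]
    fi <- numeric(m); pi_ <- integer(m)
    up_col <- F[i, 2:(m + 1L)] + gap
    for (j in 1:m) {
      d <- diag_row[j]; u <- up_col[j]; l <- prev + gap
      if (d >= u && d >= l) { prev <- d; pi_[j] <- 1L }
      else if (u >= l)      { prev <- u; pi_[j] <- 2L }
      else                  { prev <- l; pi_[j] <- 3L }
      fi[j] <- prev
    }
    F[i + 1L, 2:(m + 1L)] <- fi
    P[i + 1L, 2:(m + 1L)] <- pi_
  }
  # traceback
  ra <- character(0); rb <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    move <- P[i, j]
    if (move == 1L) {
      ra <- c(av[i - 1L], ra); rb <- c(bv[j - 1L], rb)
      i <- i - 1L; j <- j - 1L
    } else if (move == 2L) {
      ra <- c(av[i - 1L], ra); rb <- c("-", rb)
      i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j - 1L], rb)
      j <- j - 1L
    }
  }
  structure(list(aligned_a = paste(ra, collapse = ""),
                 aligned_b = paste(rb, collapse = ""),
                 score = F[n + 1L, m + 1L]),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment, score ", x$score, "\n", x$aligned_a, "\n",
      x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity between two sequences
#'
#' Globally aligns the two sequences with [needleman_wunsch()] and returns
#' `100 * identical pairs / aligned columns where neither row is a gap`.
#'
#' @param a,b Sequences (character or `seq_record`).
#' @param ... Scoring parameters passed to [needleman_wunsch()].
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b, ...) {
  aln <- needleman_wunsch(a, b, ...)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) return(0)
  100 * sum(ca[keep] == cb[keep]) / sum(keep)
}

#' Select sequences above an identity threshold to a query
#'
#' Retains candidates whose global percent identity to the query is
#' strictly greater than `threshold` ("more than" semantics); the query
#' itself, if present among the candidates, is always retained. Input
#' order is preserved.
#'
#' @param candidates List of `seq_record`s (or character vector).
#' @param query A `seq_record` or character scalar.
#' @param threshold Identity threshold in `(0, 100]`; default 80.
#' @return The retained subset of `candidates`, same type as input.
#' @export
filter_by_identity <- function(candidates, query, threshold = 80) {
  stopifnot(threshold > 0, threshold <= 100)
  if (!length(candidates)) return(candidates)
  qres <- if (inherits(query, "seq_record")) query$residues else toupper(query)
  keep <- vapply(candidates, function(cand) {
    cres <- if (inherits(cand, "seq_record")) cand$residues else toupper(cand)
    identical(cres, qres) || percent_identity(cand, query) > threshold
  }, logical(1))
  candidates[keep]
}
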