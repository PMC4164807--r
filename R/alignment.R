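# Aligned-sequence container and readers/writers.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")
AA_ALLOWED <- c(AA_LETTERS, "X")
GAP_CHAR <- "-"

#' Create an amino-acid sequence record
#'
#' A minimal record holding an identifier and an ungapped amino-acid
#' sequence over the 20 standard residues plus `X` (unknown). Input is
#' case-normalised to upper case.
#'
#' @param id Character scalar; accession or label.
#' @param residues Character scalar; amino-acid sequence (no gaps).
#' @param species Optional character scalar.
#' @return An object of class `seq_record` with elements `id`, `residues`
#'   and `species`.
#' @export
seq_record <- function(id, residues, species = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("empty sequence for record '", id, "'")
  bad <- which(!strsplit(residues, "")[[1]] %in% AA_ALLOWED)
  if (length(bad)) {
    stop("unknown character '", substr(residues, bad[1], bad[1]),
         "' at position ", bad[1], " in record '", id, "'")
  }
  structure(list(id = id, residues = residues, species = species),
            class = "seq_record")
}

#' Construct a multiple alignment object
#'
#' Holds aligned sequences of identical length, with optional per-record
#' group labels. `.` gap characters are normalised to `-`; residues are
#' upper-cased and validated against the amino-acid alphabet plus `X`.
#'
#' @param ids Character vector of unique record identifiers.
#' @param seqs Character vector of aligned (gapped) sequences, one per id.
#' @param groups Optional vector of group labels, one per record.
#' @return An object of class `et_alignment`: a list with `ids`, `seqs`
#'   (named character) and `groups` (or `NULL`).
#' @export
et_alignment <- function(ids, seqs, groups = NULL) {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) < 2L) stop("an alignment needs at least 2 records")
  if (anyDuplicated(ids)) stop("duplicated record ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- gsub(".", "-", toupper(as.character(seqs)), fixed = TRUE)
  L <- nchar(seqs)
  if (length(unique(L)) != 1L) {
    off <- ids[which(L != L[1])[1]]
    stop("unaligned input: record '", off, "' has length ",
         nchar(seqs[which(ids == off)]), " but '", ids[1], "' has length ", L[1])
  }
  if (L[1] < 1L) stop("alignment length must be >= 1")
  allowed <- c(AA_ALLOWED, GAP_CHAR)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    bad <- which(!ch %in% allowed)
    if (length(bad)) {
      stop("unknown character '", ch[bad[1]], "' at position ", bad[1],
           " in record '", ids[i], "'")
    }
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  if (any(colSums(m != GAP_CHAR) == 0L)) {
    warning("alignment contains all-gap column(s): ",
            paste(which(colSums(m != GAP_CHAR) == 0L), collapse = ", "))
  }
  names(seqs) <- ids
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(ids))
    groups <- as.character(groups)
    names(groups) <- ids
  }
  structure(list(ids = ids, seqs = seqs, groups = groups),
            class = "et_alignment")
}

#' @export
print.et_alignment <- function(x, ...) {
  cat("Multiple alignment: ", length(x$ids), " sequences, length ",
      alignment_length(x), "\n", sep = "")
  invisible(x)
}

#' Number of aligned columns
#' @param aln An `et_alignment`.
#' @return Integer alignment length.
#' @export
alignment_length <- function(aln) nchar(aln$seqs[[1]])

#' Alignment as a character matrix
#' @param x An `et_alignment`.
#' @param ... Unused.
#' @return Character matrix, one row per record, one column per position.
#' @export
as.matrix.et_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$seqs), ""))
  rownames(m) <- x$ids
  m
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA or Clustal (ALN) alignments. Record ids are the header token
#' up to the first whitespace. Ragged inputs raise an "unaligned input"
#' error naming the offending record; characters outside the amino-acid
#' alphabet (plus `X`, `-`, `.`) raise an error with the position.
#'
#' @param path File path.
#' @param format `"fasta"` or `"clustal"`.
#' @return An `et_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE, whole.header = TRUE)
    if (!length(recs)) stop("no records in ", path)
    ids <- vapply(names(recs), function(h) strsplit(trimws(h), "\\s+")[[1]][1], "")
    seqs <- vapply(recs, function(r) as.character(r)[1], "")
  } else {
    m <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(m)
    ids <- vapply(names(seqs), function(h) strsplit(trimws(h), "\\s+")[[1]][1], "")
  }
  et_alignment(unname(ids), unname(seqs))
}

#' Write a multiple sequence alignment
#'
#' FASTA output wraps sequences at 60 columns; Clustal output writes a
#' `CLUSTAL` header and interleaved blocks of 60 with a conservation line.
#' Writing refuses alignments with all-gap columns.
#'
#' @param aln An `et_alignment`.
#' @param path Output file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  m <- as.matrix(aln)
  if (any(colSums(m != GAP_CHAR) == 0L)) {
    stop("refusing to write alignment with all-gap column(s)")
  }
  if (format == "fasta") {
    seqinr::write.fasta(strsplit(unname(aln$seqs), ""), names = aln$ids,
                        file.out = path, nbchar = 60)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("CLUSTAL W multiple sequence alignment", "", ""), con)
    L <- alignment_length(aln)
    wid <- max(nchar(aln$ids)) + 4L
    cons_row <- apply(m, 2, function(col) {
      r <- col[col != GAP_CHAR]
      if (length(r) == nrow(m) && length(unique(r)) == 1L) "*" else " "
    })
    for (start in seq(1L, L, by = 60L)) {
      end <- min(start + 59L, L)
      for (i in seq_along(aln$ids)) {
        writeLines(sprintf("%-*s%s", wid, aln$ids[i],
                           substr(aln$seqs[i], start, end)), con)
      }
      writeLines(c(sprintf("%-*s%s", wid, "",
                           paste(cons_row[start:end], collapse = "")), ""), con)
    }
  }
  invisible(path)
}

#' Extract one record of an alignment, ungapped
#' @param aln An `et_alignment`.
#' @param id Record identifier.
#' @return A `seq_record` with gaps removed.
#' @export
ungapped_record <- function(aln, id) {
  if (!id %in% aln$ids) stop("unknown record id '", id, "'")
  seq_record(id, gsub(GAP_CHAR, "", aln$seqs[[id]], fixed = TRUE))
}
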