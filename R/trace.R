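# Evolutionary trace classification: per-group consensus, column status,
# ET sequence rendering and mapping onto a query's residue numbering.

CONSENSUS_VARIABLE <- "VARIABLE"
CONSENSUS_ALL_GAP <- "ALL_GAP"
STATUS_LEVELS <- c("CONSERVED", "GROUP_SPECIFIC", "NEUTRAL")

#' Per-group consensus of an alignment
#'
#' For each column, restricted to the group's sequences: if all non-gap
#' residues are one letter, that letter; if two or more distinct letters
#' occur, the marker `"VARIABLE"`; if the column is all gaps within the
#' group, the marker `"ALL_GAP"`. Gaps are ignored, not counted as a
#' residue state.
#'
#' @param msa An `et_alignment`.
#' @param partition An `et_partition` assigning every record to a group.
#' @param group Group id to summarise.
#' @return Character vector of length `L` (class `et_consensus`) holding
#'   single letters or the two markers; attribute `group` records the id.
#' @export
group_consensus <- function(msa, partition, group) {
  miss <- setdiff(msa$ids, names(partition$groups))
  if (length(miss)) {
    stop("record(s) without group assignment: ", paste(miss, collapse = ", "))
  }
  members <- msa$ids[partition$groups[msa$ids] == group]
  if (!length(members)) stop("group '", group, "' has no members")
  m <- as.matrix(msa)[members, , drop = FALSE]
  cons <- apply(m, 2, function(col) {
    r <- unique(col[col != GAP_CHAR])
    if (!length(r)) CONSENSUS_ALL_GAP
    else if (length(r) == 1L) r
    else CONSENSUS_VARIABLE
  })
  structure(cons, group = group, class = "et_consensus")
}

#' Classify alignment columns from group consensuses
#'
#' Per column: `CONSERVED` when every group resolves to the same single
#' residue; `GROUP_SPECIFIC` when every group resolves to a single residue
#' but the residues differ between groups; `NEUTRAL` otherwise (some group
#' is variable or all-gap at that column). The three classes partition the
#' columns.
#'
#' @param consensuses List of two or more `et_consensus` vectors of equal
#'   length.
#' @return An `et_trace`: list with `status` (character vector over
#'   `CONSERVED`/`GROUP_SPECIFIC`/`NEUTRAL`), `letters` (groups x L matrix
#'   of consensus entries) and `rendering` (the ET sequence string).
#' @export
classify_columns <- function(consensuses) {
  if (length(consensuses) < 2L) stop("need at least 2 group consensuses")
  L <- unique(lengths(consensuses))
  if (length(L) != 1L) stop("consensus length mismatch: ",
                            paste(lengths(consensuses), collapse = " vs "))
  letters <- do.call(rbind, lapply(consensuses, as.character))
  rownames(letters) <- vapply(consensuses, function(x) {
    g <- attr(x, "group"); if (is.null(g)) NA_character_ else as.character(g)
  }, "")
  single <- !(letters %in% c(CONSENSUS_VARIABLE, CONSENSUS_ALL_GAP))
  dim(single) <- dim(letters)
  status <- vapply(seq_len(L), function(j) {
    if (!all(single[, j])) return("NEUTRAL")
    if (length(unique(letters[, j])) == 1L) "CONSERVED" else "GROUP_SPECIFIC"
  }, "")
  trace <- structure(list(status = status, letters = letters,
                          rendering = NULL), class = "et_trace")
  trace$rendering <- render_et_sequence(trace)
  trace
}

#' Render the ET sequence
#'
#' One character per column: the shared residue letter for `CONSERVED`
#' columns, `X` for `GROUP_SPECIFIC`, `-` for `NEUTRAL`.
#'
#' @param trace An `et_trace`.
#' @return Character scalar of length `L`.
#' @export
render_et_sequence <- function(trace) {
  ch <- ifelse(trace$status == "CONSERVED", trace$letters[1, ],
               ifelse(trace$status == "GROUP_SPECIFIC", "X", "-"))
  paste(ch, collapse = "")
}

#' Parse an ET sequence string back to column statuses
#'
#' Inverse of [render_et_sequence()]: letters map to `CONSERVED`, `X` to
#' `GROUP_SPECIFIC`, `-` to `NEUTRAL`. (A conserved column whose residue
#' is the unknown code `X` is not distinguishable from a group-specific
#' column in this rendering.)
#'
#' @param et Character scalar.
#' @return Character vector of statuses.
#' @export
parse_et_sequence <- function(et) {
  ch <- strsplit(toupper(et), "")[[1]]
  ifelse(ch == "-", "NEUTRAL", ifelse(ch == "X", "GROUP_SPECIFIC", "CONSERVED"))
}

#' Map column statuses onto a query sequence's residue numbering
#'
#' Walks the query's row of the alignment, skipping its gap columns; each
#' query residue receives the status of its alignment column. Residue
#' numbers start at `numbering_offset` (e.g. the first residue number of
#' the crystal structure) and increase by one per query residue.
#'
#' @param trace An `et_trace` for the alignment.
#' @param msa The `et_alignment` the trace was computed from.
#' @param query_id Record id of the query sequence.
#' @param numbering_offset First residue number (default 1).
#' @return An `et_status_map`: data frame with columns `resnum`, `residue`
#'   and `status`; attribute `query_id`.
#' @export
map_to_query <- function(trace, msa, query_id, numbering_offset = 1L) {
  if (!query_id %in% msa$ids) stop("unknown query id '", query_id, "'")
  row <- strsplit(msa$seqs[[query_id]], "")[[1]]
  if (length(row) != length(trace$status)) {
    stop("trace length ", length(trace$status),
         " does not match alignment length ", length(row))
  }
  cols <- which(row != GAP_CHAR)
  map <- data.frame(resnum = numbering_offset + seq_along(cols) - 1L,
                    residue = row[cols],
                    status = trace$status[cols],
                    stringsAsFactors = FALSE)
  structure(map, query_id = query_id, class = c("et_status_map", "data.frame"))
}

#' Status counts and percentages of a residue status map
#'
#' Counts residues per trace status and the percentage of the query's
#' residues in each, rounded to one decimal for reporting (189 conserved
#' residues of a 501-residue query report as 37.7).
#'
#' @param map An `et_status_map` (or data frame with a `status` column).
#' @return Data frame with columns `status`, `count`, `percent`.
#' @export
status_fractions <- function(map) {
  if (!nrow(map)) stop("empty status map")
  total <- nrow(map)
  counts <- vapply(STATUS_LEVELS, function(s) sum(map$status == s), 0L)
  data.frame(status = STATUS_LEVELS,
             count = unname(counts),
             percent = round(100 * unname(counts) / total, 1),
             stringsAsFactors = FALSE)
}

#' Write the ET sequence as FASTA
#' @param trace An `et_trace`.
#' @param path Output path.
#' @param id FASTA record id (default `"ET"`).
#' @return Invisibly, `path`.
#' @export
write_et_sequence <- function(trace, path, id = "ET") {
  seqinr::write.fasta(strsplit(trace$rendering, ""), names = id,
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Write a residue status map as TSV
#' @param map An `et_status_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_status_map <- function(map, path) {
  df <- data.frame(query_id = attr(map, "query_id"),
                   resnum = map$resnum, residue = map$residue,
                   status = map$status)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
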