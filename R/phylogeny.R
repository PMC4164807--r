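# Distance matrix, neighbor-joining and tree partitioning.
#
# Trees are ape "phylo" objects throughout; edges are addressed by their
# row index in tree$edge.

#' Uncorrected p-distance matrix from an alignment
#'
#' For each pair of records, the fraction of mismatched columns among the
#' columns where neither row is a gap. Pairs with no comparable columns
#' are an error (the distance is undefined).
#'
#' @param msa An `et_alignment` with at least 3 records.
#' @return A symmetric numeric matrix with zero diagonal; dimnames are the
#'   record ids.
#' @export
p_distance_matrix <- function(msa) {
  m <- as.matrix(msa)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 records for a distance matrix")
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  gap <- m == GAP_CHAR
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    comp <- !gap[i, ] & !gap[j, ]
    if (!any(comp)) {
      stop("no comparable columns between '", msa$ids[i], "' and '",
           msa$ids[j], "'")
    }
    d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
  }
  d
}

# Lexicographically smallest leaf label of each active node, used for
# deterministic tie-breaking in NJ.
.pair_key <- function(li, lj) {
  a <- sort(c(li, lj))
  paste(a[1], a[2], sep = "\r")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j` is joined, with branch lengths from
#' the usual NJ formulas. Negative branch lengths are clamped to zero with
#' the deficit transferred to the sister branch, so path lengths through
#' the join are preserved. Ties in Q are broken by the lexicographically
#' smallest pair of clade labels (a clade is labelled by its smallest leaf
#' label), making the result independent of input order.
#'
#' @param dm Symmetric numeric matrix with zero diagonal, unique dimnames,
#'   no negative entries; at least 3 taxa.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  labs <- rownames(dm)
  if (is.null(labs) || anyDuplicated(labs)) stop("distance matrix needs unique labels")
  if (any(dm < 0)) stop("negative distances are not allowed")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")

  # Newick fragments per active node; key labels for tie-breaking.
  frag <- labs
  key <- labs
  D <- dm
  fmt <- function(x) sprintf("%.12g", max(x, 0))

  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) .pair_key(key[ij[1]], key[ij[2]]))
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    newkey <- min(key[i], key[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    D <- D2
  }

  # terminal 3-star: closed-form branch lengths
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ord <- order(key)
  parts <- paste0(frag[ord], ":", vapply(c(a, b, c3)[ord], fmt, ""))
  nwk <- paste0("(", paste(parts, collapse = ","), ");")
  ape::read.tree(text = nwk)
}

# Tip indices on the child side of an edge (row of tree$edge).
.edge_tips <- function(tree, edge) {
  nt <- length(tree$tip.label)
  child <- tree$edge[edge, 2]
  if (child <= nt) return(child)
  stack <- child
  tips <- integer(0)
  while (length(stack)) {
    node <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    tips <- c(tips, kids[kids <= nt])
    stack <- c(stack, kids[kids > nt])
  }
  sort(tips)
}

#' Partition tree leaves by cutting one edge
#'
#' Removing the edge splits the tree into two connected components; the
#' leaves of each component form the two groups. Group 1 is the side
#' containing the lexicographically smallest leaf label.
#'
#' @param tree An `ape::phylo` tree.
#' @param edge Edge id: row index into `tree$edge`.
#' @return An `et_partition`: a list with `groups` (named integer vector,
#'   leaf label to group id) and `k` (number of groups).
#' @export
partition_at_edge <- function(tree, edge) {
  ne <- nrow(tree$edge)
  if (!is.numeric(edge) || length(edge) != 1L || edge < 1 || edge > ne) {
    stop("invalid edge id (tree has ", ne, " edges)")
  }
  labs <- tree$tip.label
  side <- .edge_tips(tree, as.integer(edge))
  g <- rep(2L, length(labs))
  g[side] <- 1L
  if (!any(g == 2L)) stop("edge cut leaves one side empty")
  # canonical orientation: group 1 holds the smallest label
  if (labs[order(labs)[1]] %in% labs[g == 2L]) g <- 3L - g
  names(g) <- labs
  structure(list(groups = g, k = 2L), class = "et_partition")
}

#' @export
print.et_partition <- function(x, ...) {
  for (gid in sort(unique(x$groups))) {
    cat("group ", gid, ": ",
        paste(sort(names(x$groups)[x$groups == gid]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Automatic two-group partition of a tree
#'
#' Selects the edge whose removal maximises the minimum inter-group
#' leaf-to-leaf path length (the deepest split). Ties are broken by the
#' most balanced split, then by leaf-label order, so the choice is
#' deterministic.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param k Number of groups; only `k = 2` is supported.
#' @return An `et_partition` (see [partition_at_edge()]).
#' @export
auto_partition <- function(tree, k = 2) {
  if (k != 2) stop("unsupported: only k = 2 partitions are implemented")
  nt <- length(tree$tip.label)
  if (nt < 2L) stop("need at least 2 leaves")
  D <- ape::cophenetic.phylo(tree)
  ord <- tree$tip.label
  best <- NULL
  for (e in seq_len(nrow(tree$edge))) {
    side <- tree$tip.label[.edge_tips(tree, e)]
    other <- setdiff(ord, side)
    if (!length(side) || !length(other)) next
    minsep <- min(D[side, other])
    imbal <- abs(length(side) - length(other))
    kside <- paste(sort(side), collapse = "\r")
    cand <- list(edge = e, minsep = minsep, imbal = imbal, key = kside)
    if (is.null(best) ||
        cand$minsep > best$minsep + 1e-12 ||
        (abs(cand$minsep - best$minsep) <= 1e-12 &&
         (cand$imbal < best$imbal ||
          (cand$imbal == best$imbal && cand$key < best$key)))) {
      best <- cand
    }
  }
  partition_at_edge(tree, best$edge)
}

#' Write a leaf partition as a two-column TSV
#' @param partition An `et_partition`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(leaf_id = names(partition$groups),
                   group = unname(partition$groups))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a leaf partition from a two-column TSV
#' @param path Path to a TSV with columns `leaf_id`, `group`.
#' @return An `et_partition`.
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- as.integer(df$group)
  names(g) <- df$leaf_id
  structure(list(groups = g, k = length(unique(g))), class = "et_partition")
}
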