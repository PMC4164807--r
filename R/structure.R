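# Structure handling: PDB I/O (via bio3d), chain selection, ligand
# binding-site extraction by distance cutoff, C-alpha matching and Kabsch
# superposition, and trace-status annotation.

WATER_RESIDUES <- c("HOH", "WAT", "DOD")

#' Read a PDB structure
#'
#' Thin wrapper around [bio3d::read.pdb()] that additionally validates
#' coordinate fields line by line (a malformed coordinate raises an error
#' naming the line), keeps only the first alternate location of each atom,
#' and ignores models after the first with a warning.
#'
#' @param path Path to a PDB-format file.
#' @return A `bio3d` `pdb` object.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  coord <- grep("^(ATOM  |HETATM)", lines)
  for (i in coord) {
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(lines[i], fld[1], fld[2])))
      if (is.na(v) || !is.finite(v)) {
        stop("malformed coordinate field at line ", i, ": ", lines[i])
      }
    }
  }
  if (sum(grepl("^MODEL ", lines)) > 1L) {
    warning("multiple MODEL records; only the first model is used")
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  # first altloc only: keep atoms whose alt code is blank or the first
  # code seen for that (chain, resno, insert, elety)
  alt <- pdb$atom$alt
  if (any(!is.na(alt) & alt != "")) {
    keyres <- paste(pdb$atom$type, pdb$atom$chain, pdb$atom$resno,
                    pdb$atom$insert, pdb$atom$elety)
    pdb <- bio3d::trim.pdb(pdb,
                           inds = bio3d::as.select(which(!duplicated(keyres))))
  }
  pdb
}

#' Select a single chain of a structure
#'
#' @param s A `pdb` object.
#' @param chain Chain identifier.
#' @return A `pdb` object restricted to that chain.
#' @export
select_chain <- function(s, chain) {
  avail <- unique(s$atom$chain)
  if (!chain %in% avail) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(avail, collapse = ", "))
  }
  bio3d::trim.pdb(s, bio3d::atom.select(s, chain = chain, verbose = FALSE))
}

#' Define the ligand atom set of a structure
#'
#' By default all HETATM residues except water are treated as the ligand.
#' Peptidomimetic inhibitors deposited as a separate polymer chain can be
#' selected with `chain`; specific residue names with `resnames`.
#'
#' @param s A `pdb` object containing the ligand.
#' @param chain Optional chain id: every atom of this chain is the ligand.
#' @param resnames Optional character vector of residue names.
#' @return An `et_ligand`: list with `atoms` (data frame of ligand atoms),
#'   `xyz` (n x 3 matrix, Angstrom) and `residues` (chain/resno/insert keys).
#' @export
ligand_selection <- function(s, chain = NULL, resnames = NULL) {
  at <- s$atom
  if (!is.null(chain)) {
    sel <- at$chain %in% chain
  } else if (!is.null(resnames)) {
    sel <- at$resid %in% toupper(resnames)
  } else {
    sel <- at$type == "HETATM" & !(at$resid %in% WATER_RESIDUES)
  }
  if (!any(sel)) stop("empty ligand selection")
  atoms <- at[sel, , drop = FALSE]
  structure(list(atoms = atoms,
                 xyz = as.matrix(atoms[, c("x", "y", "z")]),
                 residues = unique(paste(atoms$chain, atoms$resno,
                                         ifelse(is.na(atoms$insert), "",
                                                atoms$insert)))),
            class = "et_ligand")
}

# Protein (non-water, non-ligand) atom table of a structure.
.protein_atoms <- function(s, ligand) {
  at <- s$atom
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  sel <- at$type == "ATOM" & !(at$resid %in% WATER_RESIDUES) &
    !(key %in% ligand$residues)
  at[sel, , drop = FALSE]
}

#' Ligand-binding residues within a distance cutoff
#'
#' A protein residue belongs to the binding site iff the minimum Euclidean
#' distance over all its atom-ligand atom pairs is less than or equal to
#' `cutoff` (inclusive). Waters never count as protein; ligand residues
#' are excluded from the protein side. All atoms present in the file are
#' used (crystal structures typically lack hydrogens).
#'
#' @param protein A `pdb` object (may contain the ligand; it is excluded).
#' @param ligand An `et_ligand` from [ligand_selection()].
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @return An `et_bindsite`: data frame with columns `chain`, `resnum`,
#'   `resname` and `min_dist`, sorted by residue number, no duplicates.
#' @export
binding_site <- function(protein, ligand, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  if (!inherits(ligand, "et_ligand") || !nrow(ligand$atoms)) {
    stop("empty ligand selection")
  }
  at <- .protein_atoms(protein, ligand)
  if (!nrow(at)) {
    warning("no protein atoms in structure")
    return(.empty_bindsite(cutoff))
  }
  px <- as.matrix(at[, c("x", "y", "z")])
  lx <- ligand$xyz
  # squared distances protein-atoms x ligand-atoms
  d2 <- outer(rowSums(px^2), rowSums(lx^2), "+") - 2 * px %*% t(lx)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  res_min <- tapply(mind, key, min)
  first <- !duplicated(key)
  info <- at[first, c("chain", "resno", "resid")]
  info$min_dist <- as.numeric(res_min[paste(at$chain, at$resno,
                                            ifelse(is.na(at$insert), "",
                                                   at$insert))[first]])
  hit <- info[info$min_dist <= cutoff, , drop = FALSE]
  hit <- hit[order(hit$chain, hit$resno), , drop = FALSE]
  out <- data.frame(chain = hit$chain, resnum = hit$resno,
                    resname = hit$resid, min_dist = hit$min_dist,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, cutoff = cutoff, class = c("et_bindsite", "data.frame"))
}

.empty_bindsite <- function(cutoff) {
  structure(data.frame(chain = character(0), resnum = integer(0),
                       resname = character(0), min_dist = numeric(0)),
            cutoff = cutoff, class = c("et_bindsite", "data.frame"))
}

#' Pair C-alpha atoms of two chains by sequence alignment
#'
#' Derives one-letter sequences from the residues of each chain
#' (non-standard residues become `X`), aligns them globally with
#' [needleman_wunsch()], and pairs residues aligned to one another where
#' both have a C-alpha atom.
#'
#' @param a,b Single-chain `pdb` objects with at least 3 C-alpha residues.
#' @param ... Scoring parameters passed to [needleman_wunsch()].
#' @return List with `xyz_a`, `xyz_b` (n x 3 coordinate matrices) and
#'   `pairs` (data frame of paired residue numbers and letters).
#' @export
match_calphas <- function(a, b, ...) {
  ca_a <- .calpha_table(a)
  ca_b <- .calpha_table(b)
  if (nrow(ca_a) < 3L || nrow(ca_b) < 3L) {
    stop("insufficient pairs: need at least 3 C-alpha residues per chain")
  }
  aln <- needleman_wunsch(paste(ca_a$aa, collapse = ""),
                          paste(ca_b$aa, collapse = ""), ...)
  ra <- strsplit(aln$aligned_a, "")[[1]]
  rb <- strsplit(aln$aligned_b, "")[[1]]
  ia <- cumsum(ra != "-")
  ib <- cumsum(rb != "-")
  both <- ra != "-" & rb != "-"
  pa <- ia[both]; pb <- ib[both]
  if (length(pa) < 3L) stop("insufficient pairs: fewer than 3 aligned C-alphas")
  pairs <- data.frame(resnum_a = ca_a$resno[pa], aa_a = ca_a$aa[pa],
                      resnum_b = ca_b$resno[pb], aa_b = ca_b$aa[pb],
                      stringsAsFactors = FALSE)
  list(xyz_a = as.matrix(ca_a[pa, c("x", "y", "z")]),
       xyz_b = as.matrix(ca_b[pb, c("x", "y", "z")]),
       pairs = pairs)
}

.calpha_table <- function(s) {
  at <- s$atom
  sel <- at$type == "ATOM" & at$elety == "CA" & !(at$resid %in% WATER_RESIDUES)
  ca <- at[sel, , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert)), , drop = FALSE]
  aa <- bio3d::aa321(ca$resid)
  aa[is.na(aa) | !aa %in% AA_LETTERS] <- "X"
  data.frame(resno = ca$resno, aa = aa, x = ca$x, y = ca$y, z = ca$z,
             stringsAsFactors = FALSE)
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body superposition of two equal-length coordinate sets by
#' singular value decomposition, with reflection correction so the
#' rotation is proper (`det(R) = +1`). The transform maps `p` onto `q`:
#' `p %*% R + t`. Inputs are not modified.
#'
#' @param p,q Numeric n x 3 matrices, n >= 1, finite coordinates.
#' @return A `superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom) and `n_pairs`.
#' @export
kabsch_superpose <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!nrow(p) || !nrow(q)) stop("zero-length coordinate set")
  stopifnot(nrow(p) == nrow(q), ncol(p) == 3, ncol(q) == 3,
            all(is.finite(p)), all(is.finite(q)))
  cp <- colMeans(p); cq <- colMeans(q)
  p0 <- sweep(p, 2, cp); q0 <- sweep(q, 2, cq)
  H <- crossprod(p0, q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  moved <- p0 %*% R
  rmsd <- sqrt(mean(rowSums((moved - q0)^2)))
  translation <- as.numeric(cq - cp %*% R)
  structure(list(rotation = R, translation = translation,
                 rmsd = rmsd, n_pairs = nrow(p)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: RMSD %.3f A over %d pairs\n", x$rmsd, x$n_pairs))
  invisible(x)
}

#' Superpose two chains over matched C-alpha atoms
#'
#' Convenience wrapper: [match_calphas()] then [kabsch_superpose()].
#'
#' @param a,b Single-chain `pdb` objects.
#' @return A `superposition` with an additional `pairs` element.
#' @export
superpose_chains <- function(a, b) {
  m <- match_calphas(a, b)
  res <- kabsch_superpose(m$xyz_a, m$xyz_b)
  res$pairs <- m$pairs
  res
}

#' Annotate binding-site residues with trace statuses
#'
#' Joins a binding site with a residue status map on residue number.
#' Residues absent from the map are reported as `UNMAPPED`.
#'
#' @param site An `et_bindsite`.
#' @param statuses An `et_status_map`.
#' @return Data frame `resnum`, `resname`, `status`, `min_dist` with a
#'   `counts` attribute (named status counts, including `UNMAPPED`).
#' @export
annotate_binding_site <- function(site, statuses) {
  idx <- match(site$resnum, statuses$resnum)
  status <- ifelse(is.na(idx), "UNMAPPED", statuses$status[idx])
  out <- data.frame(resnum = site$resnum, resname = site$resname,
                    status = status, min_dist = site$min_dist,
                    stringsAsFactors = FALSE)
  lv <- c(STATUS_LEVELS, "UNMAPPED")
  counts <- vapply(lv, function(s) sum(status == s), 0L)
  attr(out, "counts") <- counts
  out
}

#' Binding-site residues inside a flap region
#'
#' Returns the binding-site residue numbers falling in the closed interval
#' `[flap_start, flap_end]` (e.g. the BACE1 flap, residues 67-77).
#'
#' @param site An `et_bindsite`, annotated site table, or numeric vector
#'   of residue numbers.
#' @param flap_start,flap_end Residue numbers bounding the flap
#'   (inclusive); `flap_start <= flap_end`.
#' @return Sorted numeric vector of residue numbers.
#' @export
flap_intersection <- function(site, flap_start, flap_end) {
  stopifnot(flap_start <= flap_end)
  resnums <- if (is.numeric(site)) site else site$resnum
  sort(unique(resnums[resnums >= flap_start & resnums <= flap_end]))
}

#' Write a structure with trace statuses encoded in the B-factor column
#'
#' Sets the B-factor of every atom by its residue's status: 0.00 NEUTRAL,
#' 25.00 UNMAPPED, 50.00 GROUP_SPECIFIC, 99.99 CONSERVED — a convention
#' any molecular viewer can colour by.
#'
#' @param s A `pdb` object.
#' @param statuses An `et_status_map` covering (part of) the structure.
#' @param path Output PDB path.
#' @return Invisibly, `path`.
#' @export
write_annotated_pdb <- function(s, statuses, path) {
  codes <- c(NEUTRAL = 0, UNMAPPED = 25, GROUP_SPECIFIC = 50, CONSERVED = 99.99)
  idx <- match(s$atom$resno, statuses$resnum)
  status <- ifelse(is.na(idx), "UNMAPPED", statuses$status[idx])
  b <- unname(codes[status])
  bio3d::write.pdb(s, file = path, b = b)
  invisible(path)
}

#' Decode trace statuses from an annotated PDB's B-factors
#'
#' Inverse of [write_annotated_pdb()], for round-trip checking.
#'
#' @param s A `pdb` object read from an annotated file.
#' @return Data frame `resnum`, `status` (one row per residue).
#' @export
read_annotated_statuses <- function(s) {
  at <- s$atom[s$atom$type == "ATOM", , drop = FALSE]
  first <- !duplicated(paste(at$chain, at$resno, at$insert))
  code <- round(at$b[first])
  status <- c(`0` = "NEUTRAL", `25` = "UNMAPPED", `50` = "GROUP_SPECIFIC",
              `100` = "CONSERVED")[as.character(code)]
  data.frame(resnum = at$resno[first], status = unname(status),
             stringsAsFactors = FALSE)
}
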