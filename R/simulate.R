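# Synthetic data: ortholog families with planted column statuses, and toy
# protein-ligand complexes with a binding site known by construction.

#' Specification of a synthetic two-group ortholog family
#'
#' The defaults emulate a pair of paralog groups of mammalian orthologs in
#' the regime of the beta-secretase family: seven sequences per group
#' (human plus six other mammals), a query-length alignment of 501
#' columns, and status fractions close to the observed conserved (~38%)
#' and group-specific (~25%) shares.
#'
#' @param seqs_per_group Sequences in each of the two groups (default 7).
#' @param length Alignment length L (default 501).
#' @param fraction_conserved,fraction_group_specific,fraction_neutral
#'   Column status fractions; must sum to 1 (defaults 0.38 / 0.25 / 0.37).
#' @param neutral_alphabet_size Number of residue letters a neutral column
#'   draws from, at least 2 (default 4).
#' @param within_group_noise Extra per-sequence substitution probability
#'   applied at neutral columns only (default 0.1). Planted conserved and
#'   group-specific columns are never perturbed, so planted statuses are
#'   recovered exactly at any noise level.
#' @param seed Integer seed fixing all randomness.
#' @return A validated `family_spec` list.
#' @export
family_spec <- function(seqs_per_group = 7L, length = 501L,
                        fraction_conserved = 0.38,
                        fraction_group_specific = 0.25,
                        fraction_neutral = 0.37,
                        neutral_alphabet_size = 4L,
                        within_group_noise = 0.1,
                        seed = 1L) {
  f <- c(fraction_conserved, fraction_group_specific, fraction_neutral)
  if (any(f < 0)) stop("fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) stop("status fractions must sum to 1 (got ",
                                   sum(f), ")")
  if (neutral_alphabet_size < 2L) stop("neutral_alphabet_size must be >= 2")
  if (seqs_per_group < 2L) stop("need at least 2 sequences per group")
  if (length < 1L) stop("alignment length must be >= 1")
  if (within_group_noise < 0 || within_group_noise > 1) {
    stop("within_group_noise must be in [0, 1]")
  }
  structure(list(n_groups = 2L, seqs_per_group = as.integer(seqs_per_group),
                 length = as.integer(length),
                 fraction_conserved = fraction_conserved,
                 fraction_group_specific = fraction_group_specific,
                 fraction_neutral = fraction_neutral,
                 neutral_alphabet_size = as.integer(neutral_alphabet_size),
                 within_group_noise = within_group_noise,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# Largest-remainder apportionment of L columns to the three statuses.
.apportion <- function(L, fractions) {
  raw <- L * fractions
  base <- floor(raw)
  rem <- L - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a two-group ortholog family with planted column statuses
#'
#' Columns are assigned planted statuses according to the spec fractions.
#' Conserved columns carry one residue in every sequence; group-specific
#' columns carry one residue per group, differing between the groups;
#' neutral columns draw residues per sequence from a small alphabet, with
#' at least two distinct residues forced within each group so the column
#' is genuinely variable. All randomness is fixed by `spec$seed`.
#'
#' @param spec A [family_spec()].
#' @return List with `msa` (an `et_alignment` with group labels),
#'   `partition` (an `et_partition`) and `truth` (list: `status` per
#'   column, `group_letters` 2 x L matrix, `identity` per sequence to the
#'   first sequence of its group).
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  L <- spec$length
  npg <- spec$seqs_per_group
  counts <- .apportion(L, c(spec$fraction_conserved,
                            spec$fraction_group_specific,
                            spec$fraction_neutral))
  status <- rep(c("CONSERVED", "GROUP_SPECIFIC", "NEUTRAL"), counts)
  status <- sample(status)

  m <- matrix("", nrow = 2L * npg, ncol = L)
  grp <- rep(1:2, each = npg)
  group_letters <- matrix(NA_character_, 2L, L)
  for (j in seq_len(L)) {
    if (status[j] == "CONSERVED") {
      a <- sample(AA_LETTERS, 1L)
      m[, j] <- a
      group_letters[, j] <- a
    } else if (status[j] == "GROUP_SPECIFIC") {
      ab <- sample(AA_LETTERS, 2L)
      m[grp == 1L, j] <- ab[1]
      m[grp == 2L, j] <- ab[2]
      group_letters[, j] <- ab
    } else {
      alpha <- sample(AA_LETTERS, spec$neutral_alphabet_size)
      col <- sample(alpha, 2L * npg, replace = TRUE)
      noise <- stats::runif(2L * npg) < spec$within_group_noise
      col[noise] <- sample(alpha, sum(noise), replace = TRUE)
      # force within-group variability so the column is truly neutral
      for (g in 1:2) {
        idx <- which(grp == g)
        if (length(unique(col[idx])) == 1L) {
          col[idx[2]] <- setdiff(alpha, col[idx[1]])[1]
        }
      }
      m[, j] <- col
    }
  }
  ids <- paste0("G", grp, "_SEQ", rep(seq_len(npg), times = 2))
  seqs <- apply(m, 1, paste, collapse = "")
  msa <- et_alignment(ids, seqs, groups = grp)
  part <- structure(list(groups = stats::setNames(grp, ids), k = 2L),
                    class = "et_partition")
  identity <- vapply(seq_along(ids), function(i) {
    ref <- which(grp == grp[i])[1]
    100 * mean(m[i, ] == m[ref, ])
  }, 0)
  list(msa = msa, partition = part,
       truth = list(status = status, group_letters = group_letters,
                    identity = stats::setNames(identity, ids)))
}

#' Specification of a toy protein-ligand complex
#'
#' A single-chain backbone (ideal alpha-helix: 1.5 A rise, 100 degree
#' twist, 2.3 A radius; or a straight chain at 3.8 A C-alpha spacing) with
#' ligand atoms placed at stated distances from chosen residues.
#'
#' @param n_residues Number of residues in the chain.
#' @param geometry `"helix"` (default) or `"straight"`.
#' @param placements Data frame with columns `residue` (target residue
#'   number) and `distance` (Angstrom from that residue's C-alpha, along
#'   the outward radial direction); each row becomes one ligand atom.
#' @param sequence Optional one-letter amino-acid string of length
#'   `n_residues` naming the residues; default poly-alanine.
#' @param seed Integer seed (reserved; generation is deterministic).
#' @return A validated `complex_spec` list.
#' @export
complex_spec <- function(n_residues, geometry = c("helix", "straight"),
                         placements, sequence = NULL, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(is.data.frame(placements),
            all(c("residue", "distance") %in% names(placements)))
  if (any(placements$distance < 1)) stop("ligand distances must be >= 1 A")
  if (any(placements$residue < 1 | placements$residue > n_residues)) {
    stop("placement residue outside the chain")
  }
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != n_residues) {
      stop("sequence length must equal n_residues")
    }
  }
  structure(list(n_residues = as.integer(n_residues), geometry = geometry,
                 placements = placements, sequence = sequence,
                 seed = as.integer(seed)),
            class = "complex_spec")
}

# Backbone coordinates: list of per-atom vectors for N, CA, C, O.
.toy_backbone <- function(n, geometry) {
  t <- seq_len(n)
  if (geometry == "helix") {
    ang <- (t - 1) * 100 * pi / 180
    ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (t - 1))
  } else {
    ca <- cbind(3.8 * (t - 1), 0, 0)
  }
  # crude but valid peptide geometry around each C-alpha
  nxt <- rbind(ca[-1, , drop = FALSE], ca[n, ] + c(1, 0, 0))
  prv <- rbind(ca[1, ] - c(1, 0, 0), ca[-n, , drop = FALSE])
  unit <- function(v) v / sqrt(rowSums(v^2))
  Npos <- ca + 1.46 * unit(prv - ca)
  Cpos <- ca + 1.52 * unit(nxt - ca)
  Opos <- Cpos + 1.23 * unit(Cpos - ca)
  list(N = Npos, CA = ca, C = Cpos, O = Opos)
}

#' Write a toy protein-ligand complex and return its true binding site
#'
#' Generates the backbone from the spec, places one HETATM ligand atom per
#' placement at exactly the requested distance from the target residue's
#' C-alpha (radially outward, so in-memory distances match the request to
#' machine precision; on disk, PDB's three decimals), writes a PDB file,
#' and computes the true binding site at `cutoff` directly from the
#' coordinates as written.
#'
#' @param spec A [complex_spec()].
#' @param path Output PDB path.
#' @param cutoff Cutoff used for the returned truth (default 5.0 A).
#' @return List with `path`, `site` (data frame `resnum`, `min_dist` of
#'   residues within `cutoff` of any ligand atom, from on-disk coordinates)
#'   and `ligand_xyz`.
#' @export
simulate_complex <- function(spec, path, cutoff = 5.0) {
  stopifnot(inherits(spec, "complex_spec"))
  bb <- .toy_backbone(spec$n_residues, spec$geometry)
  lig <- t(vapply(seq_len(nrow(spec$placements)), function(i) {
    res <- spec$placements$residue[i]
    d <- spec$placements$distance[i]
    ca <- bb$CA[res, ]
    u <- if (spec$geometry == "helix") {
      v <- c(ca[1], ca[2], 0); v / sqrt(sum(v^2))
    } else c(0, 1, 0)
    ca + d * u
  }, numeric(3)))

  n <- spec$n_residues
  elety <- rep(c("N", "CA", "C", "O"), n)
  resno <- rep(seq_len(n), each = 4L)
  res3 <- if (is.null(spec$sequence)) rep("ALA", n) else
    bio3d::aa123(strsplit(spec$sequence, "")[[1]])
  xyz <- matrix(NA_real_, 4L * n, 3L)
  for (k in seq_len(n)) {
    xyz[4 * k - 3, ] <- bb$N[k, ]; xyz[4 * k - 2, ] <- bb$CA[k, ]
    xyz[4 * k - 1, ] <- bb$C[k, ]; xyz[4 * k, ] <- bb$O[k, ]
  }
  all_xyz <- rbind(xyz, lig)
  nl <- nrow(lig)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(all_xyz)),
                   type = c(rep("ATOM", 4L * n), rep("HETATM", nl)),
                   resno = c(resno, 900L + seq_len(nl)),
                   resid = c(rep(res3, each = 4L), rep("LIG", nl)),
                   chain = c(rep("A", 4L * n), rep("L", nl)),
                   elety = c(elety, paste0("C", seq_len(nl))))

  # truth from the file's 3-decimal coordinates, by direct distance scan
  rxyz <- round(all_xyz, 3)
  prot <- rxyz[seq_len(4L * n), , drop = FALSE]
  ligr <- rxyz[4L * n + seq_len(nl), , drop = FALSE]
  mind <- vapply(seq_len(n), function(res) {
    rows <- 4L * res - 3:0
    min(vapply(seq_len(nl), function(j) {
      min(sqrt(colSums((t(prot[rows, , drop = FALSE]) - ligr[j, ])^2)))
    }, 0))
  }, 0)
  site <- data.frame(resnum = which(mind <= cutoff),
                     min_dist = mind[mind <= cutoff])
  list(path = path, site = site, ligand_xyz = lig)
}

#' Packaged binding-site table of the BACE1/BACE2 worked example
#'
#' Returns the paired ligand-binding-site residues of BACE1 (PDB 1FKN,
#' chain A; 28 residues) and BACE2 (PDB 2EWY, chain A; 24 residues) with
#' their evolutionary trace statuses, as shipped in `inst/extdata`.
#' Rows pair structurally corresponding residues; an `NA` residue number
#' means the site was identified in only one of the two structures.
#'
#' @return Data frame with columns `bace1_resnum`, `bace1_resname`,
#'   `bace1_status`, `bace2_resnum`, `bace2_resname`, `bace2_status`
#'   (statuses are `CONSERVED`/`GROUP_SPECIFIC`).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "bace_binding_sites.tsv", package = "etrace")
  if (!nzchar(path)) stop("packaged fixture not found")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
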