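# Independent oracles used across the test files. These deliberately take
# the slow, obviously-correct route (recursion, double loops, grid search)
# so they share no code with the implementation they check.

# Optimal global alignment score by exhaustive recursion (linear gaps).
brute_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (av[i] == bv[j] && av[i] != "X") match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(av), length(bv))
}

# Binding-site residues by an all-pairs double loop over atoms.
brute_binding_site <- function(pdb, ligand_xyz, cutoff) {
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  res <- sort(unique(at$resno))
  hit <- integer(0)
  for (r in res) {
    rows <- which(at$resno == r)
    found <- FALSE
    for (i in rows) {
      for (j in seq_len(nrow(ligand_xyz))) {
        d <- sqrt((at$x[i] - ligand_xyz[j, 1])^2 +
                  (at$y[i] - ligand_xyz[j, 2])^2 +
                  (at$z[i] - ligand_xyz[j, 3])^2)
        if (d <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hit <- c(hit, r)
  }
  hit
}

# Minimum RMSD over rotations on a quaternion grid (no SVD). Centres both
# clouds, scans unit quaternions, returns the best RMSD found.
grid_rmsd <- function(p, q, n_axis = 14, n_angle = 240) {
  p <- sweep(p, 2, colMeans(p))
  q <- sweep(q, 2, colMeans(q))
  best <- Inf
  u <- seq(0, 1, length.out = n_axis)
  for (a1 in u) for (a2 in u) {
    theta <- acos(2 * a1 - 1); phi <- 2 * pi * a2
    ax <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    for (ang in seq(0, 2 * pi, length.out = n_angle)) {
      qt <- c(cos(ang / 2), sin(ang / 2) * ax)
      w <- qt[1]; x <- qt[2]; y <- qt[3]; z <- qt[4]
      R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                  3, 3, byrow = TRUE)
      r <- sqrt(mean(rowSums((p %*% t(R) - q)^2)))
      if (r < best) best <- r
    }
  }
  best
}

random_rotation <- function() {
  qt <- rnorm(4); qt <- qt / sqrt(sum(qt^2))
  w <- qt[1]; x <- qt[2]; y <- qt[3]; z <- qt[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Small alignment straight from strings.
aln_from <- function(..., groups = NULL) {
  seqs <- c(...)
  et_alignment(paste0("s", seq_along(seqs)), seqs, groups = groups)
}

partition_from <- function(aln, groups) {
  g <- as.integer(groups)
  names(g) <- aln$ids
  structure(list(groups = g, k = length(unique(g))), class = "et_partition")
}
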