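# Structure-level operations, checked against toy complexes whose
# geometry is known by construction.

make_complex <- function(n = 20, placements = data.frame(residue = 2,
                                                         distance = 4.9),
                         geometry = "helix", sequence = NULL) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  simulate_complex(complex_spec(n, geometry, placements,
                                sequence = sequence), path)
}

test_that("toy PDB files round-trip through the reader", {
  cx <- make_complex(3)
  s <- read_pdb(cx$path)
  at <- s$atom[s$atom$type == "ATOM", ]
  expect_equal(length(unique(at$resno)), 3L)
  expect_equal(nrow(at), 12L)  # N, CA, C, O per residue
  expect_equal(sum(s$atom$type == "HETATM"), 1L)
})

test_that("malformed coordinates are rejected with the line number", {
  cx <- make_complex(3)
  lines <- readLines(cx$path)
  tgt <- grep("^ATOM", lines)[2]
  substr(lines[tgt], 31, 38) <- "  abc   "
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, bad)
  expect_error(read_pdb(bad), paste("line", tgt))
})

test_that("chain selection keeps exactly the requested chain", {
  cx <- make_complex(6)
  s <- read_pdb(cx$path)
  a <- select_chain(s, "A")
  expect_setequal(unique(a$atom$chain), "A")
  expect_equal(sum(a$atom$type == "HETATM"), 0L)
  expect_error(select_chain(s, "Z"), "available chains")
})

test_that("water-only HETATM gives an empty protein selection downstream", {
  f <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = f, xyz = c(0, 0, 0, 3, 0, 0),
                   type = c("HETATM", "HETATM"), resno = c(1, 2),
                   resid = c("HOH", "LIG"), chain = c("W", "L"),
                   elety = c("O", "C1"))
  s <- read_pdb(f)
  lig <- ligand_selection(s)
  expect_equal(lig$atoms$resid, "LIG")
  expect_warning(site <- binding_site(s, lig, 5), "no protein atoms")
  expect_equal(nrow(site), 0L)
  expect_error(ligand_selection(s, resnames = "XYZ"), "empty ligand")
})

test_that("binding site honours the inclusive cutoff by construction", {
  # straight-chain geometry keeps coordinates exact in PDB's 3 decimals
  cx <- make_complex(12, data.frame(residue = c(4, 9), distance = c(4.9, 5.0)),
                     geometry = "straight")
  s <- read_pdb(cx$path)
  site <- binding_site(select_chain(s, "A"), ligand_selection(s), 5.0)
  expect_setequal(site$resnum, c(4, 9))   # 5.0 A exactly is included
  expect_equal(site$min_dist[site$resnum == 9], 5.0, tolerance = 1e-9)
  expect_setequal(site$resnum, cx$site$resnum)
})

test_that("binding site equals the all-pairs brute-force oracle", {
  set.seed(17)
  for (rep in 1:4) {
    pl <- data.frame(residue = sample(5:45, 3), distance = runif(3, 3, 7))
    cx <- make_complex(50, pl)
    s <- read_pdb(cx$path)
    lig <- ligand_selection(s)
    site <- binding_site(select_chain(s, "A"), lig, 5.0)
    expect_equal(site$resnum, brute_binding_site(s, lig$xyz, 5.0))
  }
})

test_that("binding site is monotone in the cutoff", {
  cx <- make_complex(40, data.frame(residue = c(8, 20, 33),
                                    distance = c(3.5, 5.5, 8)))
  s <- read_pdb(cx$path)
  lig <- ligand_selection(s)
  prev <- integer(0)
  for (cutoff in c(2, 4, 5, 7, 10)) {
    cur <- binding_site(select_chain(s, "A"), lig, cutoff)$resnum
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("C-alpha matching pairs a chain with itself and tolerates deletions", {
  set.seed(6)
  seq25 <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                        25, TRUE), collapse = "")
  cx <- make_complex(25, sequence = seq25)
  s <- select_chain(read_pdb(cx$path), "A")
  m <- match_calphas(s, s)
  expect_equal(nrow(m$pairs), 25L)
  expect_equal(m$pairs$resnum_a, m$pairs$resnum_b)
  # delete 5 interior residues from the second copy
  keep <- !(s$atom$resno %in% 10:14)
  s2 <- bio3d::trim.pdb(s, inds = bio3d::as.select(which(keep)))
  m2 <- match_calphas(s, s2)
  expect_equal(nrow(m2$pairs), 20L)
  sp <- kabsch_superpose(m2$xyz_a, m2$xyz_b)
  expect_lt(sp$rmsd, 1e-6)
})

test_that("Kabsch superposition is exact on rigidly moved copies", {
  set.seed(4)
  p <- matrix(rnorm(30), 10, 3)
  self <- kabsch_superpose(p, p)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  for (rep in 1:10) {
    R <- random_rotation()
    t <- rnorm(3, sd = 20)
    q <- sweep(p %*% t(R), 2, t, "+")
    sp <- kabsch_superpose(p, q)
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    # applying the reported transform reproduces q
    expect_equal(sweep(p %*% sp$rotation, 2, sp$translation, "+"), q,
                 tolerance = 1e-9)
    # symmetry of the residual
    expect_equal(kabsch_superpose(q, p)$rmsd, sp$rmsd, tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(p[0, ], p[0, ]), "zero-length")
})

test_that("Kabsch RMSD matches a quaternion-grid minimisation", {
  set.seed(11)
  for (rep in 1:2) {
    p <- matrix(rnorm(30), 10, 3)
    q <- matrix(rnorm(30), 10, 3)
    ours <- kabsch_superpose(p, q)$rmsd
    grid <- grid_rmsd(p, q)
    expect_lte(ours, grid + 1e-9)       # SVD optimum can't be worse
    expect_equal(ours, grid, tolerance = 0.05)  # grid gets close
  }
})

test_that("degenerate collinear input still yields a proper rotation", {
  p <- cbind(0:4, 0, 0)
  q <- cbind(0, 0:4, 0)
  sp <- kabsch_superpose(p, q)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_lt(sp$rmsd, 1e-9)
})

test_that("binding-site annotation joins statuses and counts them", {
  site <- structure(data.frame(chain = "A", resnum = c(32, 70, 99),
                               resname = c("ASP", "PRO", "GLY"),
                               min_dist = c(3.1, 4.2, 4.9)),
                    class = c("et_bindsite", "data.frame"))
  statuses <- data.frame(resnum = c(32, 70), residue = c("D", "P"),
                         status = c("CONSERVED", "GROUP_SPECIFIC"))
  ann <- annotate_binding_site(site, statuses)
  expect_equal(ann$status, c("CONSERVED", "GROUP_SPECIFIC", "UNMAPPED"))
  expect_equal(attr(ann, "counts")[["UNMAPPED"]], 1L)
  empty <- annotate_binding_site(site[0, ], statuses)
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(attr(empty, "counts")), 0L)
})

test_that("flap intersection uses closed bounds", {
  site <- c(60, 67, 69, 70, 77, 78, 110)
  expect_equal(flap_intersection(site, 67, 77), c(67, 69, 70, 77))
  expect_equal(flap_intersection(site, 200, 300), numeric(0))
  expect_equal(flap_intersection(site, 1, 9999), sort(site))
})

test_that("B-factor annotation round-trips statuses through a PDB file", {
  cx <- make_complex(9)
  s <- select_chain(read_pdb(cx$path), "A")
  statuses <- data.frame(resnum = 1:6, residue = "A",
                         status = rep(c("CONSERVED", "GROUP_SPECIFIC",
                                        "NEUTRAL"), 2))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_annotated_pdb(s, statuses, f)
  back <- read_annotated_statuses(read_pdb(f))
  expect_equal(back$status[match(1:6, back$resnum)], statuses$status)
  expect_equal(unique(back$status[back$resnum > 6]), "UNMAPPED")
  # all-conserved map sets every ATOM B-factor to 99.99
  all_cons <- data.frame(resnum = 1:9, residue = "A", status = "CONSERVED")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_annotated_pdb(s, all_cons, f2)
  s2 <- read_pdb(f2)
  expect_true(all(abs(s2$atom$b[s2$atom$type == "ATOM"] - 99.99) < 1e-6))
})
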