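test_that("group consensus resolves letters, variability and all-gap columns", {
  aln <- aln_from("PAA-", "PA--", "PT--", "KAAG", "KAAG", "KAAG")
  part <- partition_from(aln, c(1, 1, 1, 2, 2, 2))
  g1 <- group_consensus(aln, part, 1)
  expect_equal(as.character(g1), c("P", "VARIABLE", "A", "ALL_GAP"))
  g2 <- group_consensus(aln, part, 2)
  expect_equal(as.character(g2), c("K", "A", "A", "G"))
  # unassigned record is an error
  bad <- structure(list(groups = c(s1 = 1L), k = 1L), class = "et_partition")
  expect_error(group_consensus(aln, bad, 1), "without group assignment")
})

test_that("column classification implements the three-way ET rule", {
  aln <- aln_from("DPAG-", "DPA--", "DKAGT", "DKTGT")
  part <- partition_from(aln, c(1, 1, 2, 2))
  cons <- lapply(1:2, function(g) group_consensus(aln, part, g))
  tr <- classify_columns(cons)
  # col1 D/D conserved; col2 P/K group-specific; col3 A vs VARIABLE neutral;
  # col4 G vs G conserved (gap ignored); col5 ALL_GAP vs T neutral
  expect_equal(tr$status,
               c("CONSERVED", "GROUP_SPECIFIC", "NEUTRAL", "CONSERVED", "NEUTRAL"))
  expect_equal(tr$rendering, "DX-G-")
  expect_error(classify_columns(cons[1]), "at least 2")
})

test_that("ET rendering round-trips through parsing", {
  fam <- simulate_family(family_spec(length = 200, seed = 7))
  cons <- lapply(1:2, function(g) group_consensus(fam$msa, fam$partition, g))
  tr <- classify_columns(cons)
  expect_equal(nchar(tr$rendering), 200L)
  expect_equal(parse_et_sequence(tr$rendering), tr$status)
  # all-neutral renders as dashes
  expect_equal(render_et_sequence(list(status = rep("NEUTRAL", 4),
                                       letters = matrix("VARIABLE", 2, 4))),
               "----")
})

test_that("statuses partition the columns and are order/duplication invariant", {
  fam <- simulate_family(family_spec(length = 150, seqs_per_group = 4, seed = 5))
  cons <- lapply(1:2, function(g) group_consensus(fam$msa, fam$partition, g))
  tr <- classify_columns(cons)
  expect_equal(sum(table(tr$status)), 150L)
  # permuting sequences within groups changes nothing
  perm <- sample(fam$msa$ids)
  aln2 <- et_alignment(perm, fam$msa$seqs[perm])
  part2 <- structure(list(groups = fam$partition$groups[perm], k = 2L),
                     class = "et_partition")
  cons2 <- lapply(1:2, function(g) group_consensus(aln2, part2, g))
  expect_equal(classify_columns(cons2)$status, tr$status)
  # duplicating a sequence changes nothing
  aln3 <- et_alignment(c(fam$msa$ids, "dup"),
                       c(fam$msa$seqs, fam$msa$seqs[[1]]))
  part3 <- structure(list(groups = c(fam$partition$groups, dup = 1L), k = 2L),
                     class = "et_partition")
  cons3 <- lapply(1:2, function(g) group_consensus(aln3, part3, g))
  expect_equal(classify_columns(cons3)$status, tr$status)
})

test_that("a within-group variant can only move a column toward NEUTRAL", {
  fam <- simulate_family(family_spec(length = 80, seqs_per_group = 4,
                                     within_group_noise = 0, seed = 10))
  cons <- lapply(1:2, function(g) group_consensus(fam$msa, fam$partition, g))
  before <- classify_columns(cons)$status
  m <- as.matrix(fam$msa)
  set.seed(1)
  uniform_cols <- which(before != "NEUTRAL")
  for (rep in 1:25) {
    j <- sample(uniform_cols, 1)
    i <- sample(nrow(m), 1)
    m2 <- m
    m2[i, j] <- setdiff(c("A", "W"), m2[i, j])[1]
    aln2 <- et_alignment(rownames(m), apply(m2, 1, paste, collapse = ""))
    cons2 <- lapply(1:2, function(g) group_consensus(aln2, fam$partition, g))
    after <- classify_columns(cons2)$status
    changed <- which(after != before)
    expect_true(all(changed == j | length(changed) == 0))
    if (length(changed)) expect_equal(unique(after[changed]), "NEUTRAL")
  }
})

test_that("statuses map onto query numbering, skipping query gaps", {
  aln <- aln_from("DPAG", "DPAG", "DKAG", "DKAG")
  part <- partition_from(aln, c(1, 1, 2, 2))
  tr <- classify_columns(lapply(1:2, function(g) group_consensus(aln, part, g)))
  m1 <- map_to_query(tr, aln, "s1", 1)
  expect_equal(m1$resnum, 1:4)
  expect_equal(m1$status, tr$status)
  # gapped query: "A-CD" numbering 10,11,12 from columns 1,3,4
  aln2 <- aln_from("A-CD", "AGCD", "AGCD", "AGCD")
  part2 <- partition_from(aln2, c(1, 1, 2, 2))
  tr2 <- classify_columns(lapply(1:2, function(g) group_consensus(aln2, part2, g)))
  m2 <- map_to_query(tr2, aln2, "s1", 10)
  expect_equal(m2$resnum, 10:12)
  expect_equal(m2$residue, c("A", "C", "D"))
  expect_equal(m2$status, tr2$status[c(1, 3, 4)])
  expect_error(map_to_query(tr2, aln2, "nope"), "unknown query")
})

test_that("planted statuses are recovered at every query residue", {
  fam <- simulate_family(family_spec(length = 200, fraction_conserved = 0.4,
                                     fraction_group_specific = 0.25,
                                     fraction_neutral = 0.35, seed = 7))
  cons <- lapply(1:2, function(g) group_consensus(fam$msa, fam$partition, g))
  tr <- classify_columns(cons)
  expect_equal(tr$status, fam$truth$status)
  map <- map_to_query(tr, fam$msa, "G1_SEQ1", 14)
  expect_equal(map$status, fam$truth$status)  # no gaps in synthetic queries
  expect_equal(map$resnum, 14:213)
})

test_that("status fractions reproduce the reported percentages", {
  fake_map <- function(n_cons, n_gs, total) {
    data.frame(resnum = seq_len(total), residue = "A",
               status = c(rep("CONSERVED", n_cons), rep("GROUP_SPECIFIC", n_gs),
                          rep("NEUTRAL", total - n_cons - n_gs)))
  }
  f1 <- status_fractions(fake_map(189, 123, 501))
  expect_equal(f1$percent[f1$status == "CONSERVED"], 37.7)
  f2 <- status_fractions(fake_map(189, 123, 518))
  expect_equal(f2$percent[f2$status == "GROUP_SPECIFIC"], 23.7)
  fall <- status_fractions(fake_map(10, 0, 10))
  expect_equal(fall$percent, c(100, 0, 0))
  expect_equal(sum(f1$count), 501)
})
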