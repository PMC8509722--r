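test_that("unit segmentation extracts annotated units verbatim", {
  unit <- random_aa_string(40)
  protein <- strrep(unit, 4)
  b <- data.frame(start = c(1, 41, 81, 121), end = c(40, 80, 120, 160))
  rs <- segment_units(protein, b, "P1")
  expect_equal(nrow(rs$units), 4L)
  expect_true(all(rs$units$sequence == unit))
  expect_error(segment_units(protein, b[1, , drop = FALSE]), "at least 2")
})

test_that("invalid unit boundaries are always rejected", {
  set.seed(13)
  protein <- random_aa_string(100)
  expect_error(segment_units(protein,
                             data.frame(start = c(1, 20), end = c(25, 40))),
               "overlap")
  expect_error(segment_units(protein,
                             data.frame(start = c(50, 1), end = c(60, 10))),
               "sorted")
  expect_error(segment_units(protein,
                             data.frame(start = c(1, 90), end = c(10, 120))),
               "out of range")
  for (rep in 1:20) {
    s <- sort(sample(1:120, 2)); e <- s + sample(0:30, 2, replace = TRUE)
    b <- data.frame(start = s, end = e)
    valid <- all(e <= 100) && all(e >= s) && s[2] > e[1] && s[1] < s[2]
    if (valid) expect_silent(segment_units(protein, b))
    else expect_error(segment_units(protein, b))
  }
})

test_that("pairwise alignment handles identity and single-gap cases", {
  sub <- varodds:::submatrix_blosum62()
  a <- "PPASP"
  r <- pairwise_unit_align(a, a)
  expect_equal(r$a_gapped, a)
  expect_equal(r$b_gapped, a)
  av <- strsplit(a, "")[[1]]
  expect_equal(r$score, sum(diag(sub[av, av])))
  r <- pairwise_unit_align("ACDE", "ACE")
  expect_equal(nchar(r$a_gapped), 4)
  expect_equal(r$a_gapped, "ACDE")
  expect_equal(r$b_gapped, "AC-E")
})

test_that("self-alignment of AAAA is never beaten by another 4-mer", {
  set.seed(17)
  best <- pairwise_unit_align("AAAA", "AAAA")$score
  for (rep in 1:30) {
    x <- random_aa_string(4)
    expect_gte(best, pairwise_unit_align("AAAA", x)$score)
  }
})

test_that("alignment scores match the exhaustive oracle and gapped recount", {
  set.seed(19)
  seqs <- vapply(1:12, function(i)
    random_aa_string(sample(1:5, 1), alphabet = c("A", "R", "N", "D", "G", "W")),
    "")
  for (a in seqs) for (b in seqs) {
    r <- pairwise_unit_align(a, b)
    expect_equal(r$score, oracle_align_score(a, b),
                 info = paste(a, b))
    expect_equal(score_gapped_pair(r$a_gapped, r$b_gapped), r$score)
    expect_equal(gsub("-", "", r$a_gapped), a)
    expect_equal(gsub("-", "", r$b_gapped), b)
  }
})

test_that("identical units self-align without gaps and conserve fully", {
  unit <- random_aa_string(40)
  aln <- self_align(rep(unit, 4))
  expect_equal(length(aln$rows), 4L)
  expect_equal(aln$column_count, 40L)
  expect_false(any(grepl("-", aln$rows)))
  prof <- conservation_profile(aln)
  expect_true(all(prof$scores == 1))
  expect_equal(prof$consensus, unit)
})

test_that("a planted 2-residue insertion opens exactly one 2-column gap block", {
  set.seed(29)
  unit <- random_aa_string(30)
  with_ins <- paste0(substr(unit, 1, 15), "WW", substr(unit, 16, 30))
  aln <- self_align(c(unit, unit, with_ins))
  expect_equal(aln$column_count, 32L)
  for (k in 1:2) {
    gaps <- gregexpr("-+", aln$rows[k])[[1]]
    expect_equal(as.integer(attr(gaps, "match.length")), 2L)
  }
  expect_false(grepl("-", aln$rows[3]))
  # round trip: ungapping recovers each unit
  expect_equal(gsub("-", "", unname(aln$rows)),
               c(unit, unit, with_ins))
})

test_that("row count equals unit count and ungapping is lossless", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    units <- vapply(seq_len(n), function(i)
      random_aa_string(sample(20:30, 1)), "")
    aln <- self_align(units)
    expect_equal(length(aln$rows), n)
    expect_equal(gsub("-", "", unname(aln$rows)), units)
  }
})

test_that("conservation scores weight gaps and pick modal residues", {
  prof <- conservation_profile(c("AAV", "AAV", "AAV", "AVV"))
  expect_equal(prof$scores, c(1, 0.75, 1))
  expect_equal(prof$consensus, "AAV")
  # insertion column present in 1 of 4 rows scores low and shows a gap
  prof <- conservation_profile(c("A-C", "A-C", "A-C", "AWC"))
  expect_equal(prof$scores[2], 1 / 4)
  expect_equal(substr(prof$consensus, 2, 2), "-")
})

test_that("conservation is permutation-invariant for gap-free unit sets", {
  set.seed(37)
  rp <- gen_repeat_protein(sim_config(seed = 37, unit_length = 25,
                                      n_units = 4, unit_mut_rate = 0.2))
  base_aln <- self_align(rp$units)
  expect_false(any(grepl("-", base_aln$rows)))  # related units align gap-free
  base <- conservation_profile(base_aln)
  for (rep in 1:3) {
    perm <- sample(rp$units)
    prof <- conservation_profile(self_align(perm))
    expect_equal(prof$scores, base$scores)
  }
})

test_that("duplicating a unit shifts column scores exactly as the tally predicts", {
  # duplicating unit u raises a column score iff u carries the modal residue
  # there ((m+1)/(n+1) > m/n); elsewhere the modal frequency is diluted
  rp <- gen_repeat_protein(sim_config(seed = 39, unit_length = 30,
                                      n_units = 4, unit_mut_rate = 0.15))
  base <- conservation_profile(self_align(rp$units))
  for (dup in c(1L, 3L)) {
    more <- conservation_profile(self_align(c(rp$units, rp$units[dup])))
    expect_equal(length(more$scores), length(base$scores))
    cols <- do.call(rbind, strsplit(rp$units, ""))
    for (j in seq_along(base$scores)) {
      counts <- table(cols[, j])
      r <- cols[dup, j]
      expect_equal(more$scores[j], max(counts[[r]] + 1, max(counts)) / 5)
    }
  }
})

test_that("mean conservation tracks the planted substitution rate", {
  rp <- gen_repeat_protein(sim_config(seed = 47, unit_length = 60,
                                      n_units = 4, unit_mut_rate = 0.2))
  prof <- conservation_profile(self_align(rp$units))
  expect_gte(length(prof$scores), 50L)
  expect_lt(abs(mean(prof$scores) - 0.8), 0.05)
  # heavier mutation drags conservation down
  rp2 <- gen_repeat_protein(sim_config(seed = 47, unit_length = 60,
                                       n_units = 4, unit_mut_rate = 0.5))
  prof2 <- conservation_profile(self_align(rp2$units))
  expect_lt(mean(prof2$scores), 0.7)
})
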