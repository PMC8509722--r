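test_that("conservation score counts the modal non-gap residue", {
  expect_equal(conservation_descriptor(rep("R", 10)),
               list(score = 1.0, flag = 1L))
  expect_equal(conservation_descriptor(c("R", "R", "R", "K")),
               list(score = 0.75, flag = 0L))
  expect_equal(conservation_descriptor(rep("-", 4)),
               list(score = 0, flag = 0L))
  expect_error(conservation_descriptor(c("R", "B")), "unknown residue")
})

test_that("conservation matches an independent tally on random columns", {
  set.seed(41)
  for (rep in 1:20) {
    col <- sample(c(varodds:::AA20, "-"), 50, replace = TRUE)
    res <- conservation_descriptor(col)
    nongap <- col[col != "-"]
    counts <- vapply(unique(nongap),
                     function(a) sum(nongap == a), integer(1))
    expect_equal(res$score, max(counts) / length(nongap))
  }
})

test_that("conservation is monotone as identical residues are added", {
  col <- c("R", "K", "K", "A")
  prev <- conservation_descriptor(col)$score
  for (i in 1:6) {
    col <- c(col, "K")
    cur <- conservation_descriptor(col)$score
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("entropy hits the closed-form anchors and the summation oracle", {
  expect_equal(complexity_descriptor(strrep("A", 10)),
               list(entropy = 0, flag = 1L))
  sixteen <- paste(varodds:::AA20[1:16], collapse = "")
  expect_equal(complexity_descriptor(sixteen),
               list(entropy = 4, flag = 0L))
  expect_error(complexity_descriptor("AAA"), "at least 5")
  set.seed(42)
  for (rep in 1:20) {
    w <- random_aa_string(sample(5:40, 1))
    got <- complexity_descriptor(w)$entropy
    v <- strsplit(w, "")[[1]]
    exp_h <- 0
    for (a in unique(v)) {
      p <- sum(v == a) / length(v)
      exp_h <- exp_h - p * log2(p)
    }
    expect_equal(got, exp_h)
    expect_lte(got, log2(20) + 1e-12)
    # permutation invariance
    expect_equal(complexity_descriptor(
      paste(sample(v), collapse = ""))$entropy, got)
  }
})

test_that("motif proximity covers inside, flanking and far positions", {
  motifs <- data.frame(start = c(1573, 1590), end = c(1577, 1594))
  expect_equal(motif_descriptor(1585, motifs), 1L)   # between two motifs
  expect_equal(motif_descriptor(99, data.frame(start = 1520, end = 1600)), 0L)
  expect_equal(motif_descriptor(50, data.frame(start = integer(0),
                                               end = integer(0))), 0L)
  set.seed(43)
  for (rep in 1:20) {
    m <- sort(sample(1:500, 6))
    motifs <- data.frame(start = m[c(1, 3, 5)], end = m[c(2, 4, 6)])
    pos <- sample(1:500, 1)
    expected <- as.integer(any(vapply(1:3, function(k)
      pos >= motifs$start[k] - 5 && pos <= motifs$end[k] + 5, logical(1))))
    expect_equal(motif_descriptor(pos, motifs), expected)
  }
})

test_that("PPxSP scanning finds planted and random motifs", {
  expect_equal(find_ppxsp_motifs("AAPPASPAA"),
               data.frame(start = 3L, end = 7L))
  # five separated PPPSP copies on a synthetic tail
  tail_seq <- paste0(strrep("G", 10),
                     paste(rep(paste0("PPPSP", strrep("A", 7)), 5),
                           collapse = ""))
  hits <- find_ppxsp_motifs(tail_seq)
  expect_equal(nrow(hits), 5L)
  expect_equal(nrow(find_ppxsp_motifs("AAAA")), 0L)
  set.seed(44)
  for (rep in 1:30) {
    s <- random_aa_string(60, alphabet = c("P", "S", "A"))
    expect_equal(find_ppxsp_motifs(s), oracle_ppxsp(s))
  }
})

test_that("damage counts reproduce the case-study predictor rows", {
  p <- lrp5_predictor_calls()
  counts <- setNames(predictor_damage_count(p), p$variant)
  expect_equal(counts[["p.S1585L"]], 3L)  # damaging by all predictors
  expect_equal(counts[["p.V99L"]], 0L)
  expect_equal(counts[["p.R1036Q"]], 1L)
  expect_equal(counts[["p.R1135C"]], 2L)
  expect_error(predictor_damage_count(
    data.frame(polyphen = "bad", sift = "tolerated", pmut = "neutral")),
    "polyphen")
})

test_that("profile assembly equals its defining predicates on random contexts", {
  set.seed(45)
  for (rep in 1:100) {
    flags <- as.logical(sample(0:1, 8, replace = TRUE))
    # keep the literature/dbSNP exclusivity invariant satisfiable
    if (flags[1] && flags[2]) flags[2] <- FALSE
    e <- data.frame(variant = "p.X1Y",
                    literature_pathogenic = flags[1],
                    dbsnp_low_freq_no_functional = flags[2],
                    prior_annotation_in_db = flags[3],
                    in_functional_domain = flags[4],
                    in_structured_domain = flags[5],
                    on_linear_motif = flags[6],
                    conserved_position = flags[7],
                    low_complexity_context = flags[8])
    p <- data.frame(variant = "p.X1Y",
                    polyphen = sample(c("benign", "possibly_damaging",
                                        "probably_damaging"), 1),
                    sift = sample(c("tolerated", "not_tolerated"), 1),
                    pmut = sample(c("neutral", "disease"), 1))
    prof <- build_profile("p.X1Y", p, e)
    dmg <- (p$polyphen != "benign") + (p$sift == "not_tolerated") +
      (p$pmut == "disease")
    expect_equal(unlist(prof[, paste0("d", 1:8)], use.names = FALSE),
                 as.integer(c(flags[7], flags[4], flags[8], flags[5],
                              flags[6], dmg >= 2, flags[3], flags[1])))
    # purity: identical inputs give identical profiles
    expect_identical(prof, build_profile("p.X1Y", p, e))
  }
})

test_that("profile assembly names missing variants in its errors", {
  p <- lrp5_predictor_calls(); e <- lrp5_evidence_context()
  expect_error(build_profile("p.Z999Z", p, e), "p\\.Z999Z")
  expect_error(build_profile("p.V99L", p, e[-1, ]), "p\\.V99L")
})
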