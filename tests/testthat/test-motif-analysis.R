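test_that("the default box is a 17-bp self-reverse-complementary palindrome", {
  box <- palindrome_box()
  expect_equal(box$consensus, "AATTGGTnnnACCAATT")
  expect_equal(box$length, 17L)
  expect_equal(length(box$informative), 14L)
  # palindrome identity, checked through the Biostrings route
  expect_equal(oracle_revcomp(gsub("n", "N", box$consensus)),
               gsub("n", "N", toupper(box$consensus)))

  # the 15-bp variant is constructible by configuration
  box15 <- palindrome_box("ATTGGT", 3)
  expect_equal(box15$consensus, "ATTGGTnnnACCAAT")
  expect_equal(length(box15$informative), 12L)
})

test_that("conservation scores reproduce the published values", {
  cases <- list(
    list("AATTGGTAAGACCAATT", 14L),  # pdhR
    list("AATTGGTATAACCAATG", 13L),  # cyoA
    list("TCCTGGTCATAGCACCT", 8L),   # fadE/lpcA
    list("AATTGGTCCTACCTGTG", 11L),  # glcD
    list("CCCCCCCAAAGGGGGGG", 0L))
  for (cs in cases) {
    expect_equal(score_against_box(cs[[1]])$matches, cs[[2]])
    expect_equal(oracle_score(cs[[1]]), cs[[2]])
  }
  expect_equal(score_against_box("AATTGGTAAGACCAATT")$rendered, "14/14")
  expect_error(score_against_box("AATTGGT"), "length")
})

test_that("rendering uppercases matches and lowercases mismatches and spacer", {
  expect_equal(render_match("AATTGGTAAGACCAATT"), "AATTGGTaagACCAATT")
  expect_equal(render_match("AGTTGGTTATACCAAAG"), "AgTTGGTtatACCAAag")  # ppsA
  expect_equal(render_match("CCCCCCCAAAGGGGGGG"), "cccccccaaaggggggg")
  # round trip: uppercasing the rendering recovers the input
  set.seed(5)
  for (i in 1:50) {
    s <- random_dna(17)
    expect_equal(toupper(render_match(s)), s)
  }
})

test_that("scoring is strand-symmetric and responds to single mutations", {
  set.seed(9)
  box <- palindrome_box()
  bases <- c("A", "C", "G", "T")
  for (i in 1:300) {
    s <- random_dna(17)
    expect_equal(score_against_box(oracle_revcomp(s), box)$matches,
                 score_against_box(s, box)$matches)
    # mutate one informative matching position: score drops by exactly 1;
    # mutate a spacer base: score unchanged
    sc <- strsplit(s, "")[[1]]
    bc <- strsplit(box$consensus, "")[[1]]
    hits <- box$informative[sc[box$informative] == toupper(bc)[box$informative]]
    m0 <- score_against_box(s, box)$matches
    if (length(hits)) {
      p <- if (length(hits) == 1L) hits else sample(hits, 1)
      mut <- sc; mut[p] <- sample(setdiff(bases, mut[p]), 1)
      expect_equal(score_against_box(paste(mut, collapse = ""), box)$matches,
                   m0 - 1L)
    }
    sp <- sample(8:10, 1)
    mut <- sc; mut[sp] <- sample(setdiff(bases, mut[sp]), 1)
    expect_equal(score_against_box(paste(mut, collapse = ""), box)$matches, m0)
  }
})

test_that("ambiguity codes and n never match at informative positions", {
  expect_equal(score_against_box("NATTGGTAAGACCAATT")$matches, 13L)
  expect_equal(score_against_box("RATTGGTAAGACCAATT")$matches, 13L)
  # spacer content is irrelevant, whatever the letters
  expect_equal(score_against_box("AATTGGTNNRACCAATT")$matches, 14L)
})

test_that("scan_window finds planted sites and honours tie-breaks", {
  set.seed(33)
  bg <- random_dna(500)
  substr(bg, 201, 217) <- "AATTGGTAAGACCAATT"
  m <- scan_window(bg)
  expect_equal(m$offset, 201L)
  expect_equal(m$score$matches, 14L)
  expect_equal(m$genome_position, 201L)

  # window equal to the consensus itself
  m <- scan_window("AATTGGTAAGACCAATT")
  expect_equal(m$offset, 1L)
  expect_equal(m$strand, "+")
  expect_equal(m$score$matches, 14L)

  # the reverse complement of a 13/14 site scores identically
  site13 <- "AATTGGTATAACCAATG"
  expect_equal(scan_window(oracle_revcomp(site13))$score$matches,
               scan_window(site13)$score$matches)

  # origin offsets genome positions
  m <- scan_window(bg, origin = 1001L)
  expect_equal(m$genome_position, 1201L)

  expect_error(scan_window("ACGT"), "shorter")
})

test_that("scan_window equals the exhaustive oracle on random windows", {
  set.seed(17)
  for (i in 1:40) {
    w <- random_dna(sample(17:600, 1))
    got <- scan_window(w)
    want <- oracle_scan(w)
    expect_equal(got$score$matches, want$matches)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
  }
})

test_that("count matrices have the stated column sums and IC bounds", {
  m <- build_matrix(rep("AATTGGTAAAACCAATT", 10))
  expect_equal(unname(colSums(m$counts)), rep(10, 17))
  expect_equal(m$ic, rep(2, 17))

  m <- build_matrix(c(rep(strrep("A", 6), 5), rep(strrep("C", 6), 5)))
  expect_equal(m$ic, rep(1, 6))

  m <- build_matrix(c("ACGT", "TGCA"), pseudocount = 0.5)
  expect_equal(unname(colSums(m$counts)), rep(2 + 4 * 0.5, 4))
  expect_true(all(m$ic >= 0 & m$ic <= 2))

  expect_error(build_matrix(character(0)), "at least one")
  expect_error(build_matrix(c("ACGT", "ACG")), "unequal")
})

test_that("majority-rule consensus derivation handles modes, ties and thresholds", {
  m <- build_matrix(rep("AATTGGTAAAACCAATT", 10))
  expect_equal(derive_consensus(m, 0.8), "AATTGGTAAAACCAATT")

  m <- build_matrix(c("A", "A", "C", "C"))
  expect_equal(derive_consensus(m, 0.6), "n")   # 50/50 split below threshold
  expect_equal(derive_consensus(m, 0.5), "n")   # tie at the mode

  m <- build_matrix(c("A", "A", "A", "C"))
  expect_equal(derive_consensus(m, 0.75), "A")
  expect_equal(derive_consensus(m, 0.8), "n")
  expect_error(derive_consensus(m, 0.2), "majority_threshold")
})

test_that("the published sites recover the conserved GGTnnnACC core", {
  tbl <- pdhr_table1()
  printed <- tbl$site_sequence[tbl$site_sequence != "-"]
  # independent oracle: the printed casing marks informative-position matches,
  # so per-column match frequency is the uppercase fraction
  case_mat <- do.call(rbind, strsplit(printed, ""))
  upper_freq <- colMeans(matrix(case_mat %in% LETTERS, nrow = nrow(case_mat)))
  core <- c(5:7, 11:13)
  expect_true(all(upper_freq[core] >= 0.85))
  expect_true(min(upper_freq[core]) >= max(upper_freq[-core]))

  mat <- build_matrix(toupper(printed))
  cons <- derive_consensus(mat, 0.75)
  expect_equal(substr(cons, 5, 7), "GGT")
  expect_equal(substr(cons, 11, 13), "ACC")
  # the core also carries the highest information content outside the spacer
  expect_true(all(mat$ic[core] >= 0.8))

  f <- tempfile(fileext = ".tsv")
  write_motif_matrix(mat, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 17L)
  expect_equal(back$A + back$C + back$G + back$T, rep(length(printed), 17))
})
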