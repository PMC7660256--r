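divergent_ann <- function() genome_annotation(
  data.frame(id = c("aroP", "pdhR"), start = c(100L, 600L), end = c(400L, 900L),
             strand = c("-", "+")), 1000)

test_that("genomic contexts map to the four site types", {
  # divergent spacer: upstream of both flanks
  s <- classify_site(500, divergent_ann())
  expect_equal(s$site_type, "A")
  expect_setequal(s$regulated_genes$id, c("aroP", "pdhR"))

  # tandem spacer: upstream of exactly one flank
  tandem <- genome_annotation(
    data.frame(id = c("mngB", "cydA"), start = c(100L, 600L),
               end = c(400L, 900L), strand = c("+", "+")), 1000)
  s <- classify_site(500, tandem)
  expect_equal(s$site_type, "B")
  expect_equal(s$regulated_genes$id, "cydA")

  # convergent spacer: downstream of both
  convergent <- genome_annotation(
    data.frame(id = c("g1", "g2"), start = c(100L, 600L), end = c(400L, 900L),
               strand = c("+", "-")), 1000)
  s <- classify_site(500, convergent)
  expect_equal(s$site_type, "C")
  expect_equal(nrow(s$regulated_genes), 0L)

  # inside an ORF
  s <- classify_site(250, divergent_ann())
  expect_equal(s$site_type, "D")
  expect_equal(s$context$host_gene$id, "aroP")
  expect_equal(nrow(s$regulated_genes), 0L)
})

test_that("published divergent, tandem and intragenic rows type as printed", {
  ann <- fixture_annotation()
  expect_equal(classify_site(122052, ann)$site_type, "A")   # aroP <> pdhR spacer
  s <- classify_site(121966, ann)
  expect_setequal(s$regulated_genes$id, c("aroP", "pdhR"))
  expect_equal(classify_site(770852, ann)$site_type, "B")   # mngB >> cydA
  expect_equal(classify_site(770852, ann)$regulated_genes$id, "cydA")
  expect_equal(classify_site(92666, ann)$site_type, "D")    # inside ftsI
})

test_that("a missing flank on a linear genome warns and types from one side", {
  ann <- genome_annotation(
    data.frame(id = "g1", start = 500L, end = 800L, strand = "+"), 1000)
  expect_warning(s <- classify_site(100, ann), "left")
  expect_equal(s$site_type, "B")    # upstream of the only flank
  expect_warning(s <- classify_site(900, ann), "right")
  expect_equal(s$site_type, "C")    # downstream of the only flank
})

test_that("regulon bounds follow the counting rule", {
  e <- estimate_regulon_size(c(rep("A", 7), rep("B", 9), rep("D", 19)))
  expect_equal(e$min_targets, 16L)
  expect_equal(e$max_targets, 23L)

  e <- estimate_regulon_size(character(0))
  expect_equal(c(e$min_targets, e$max_targets), c(0L, 0L))

  e <- estimate_regulon_size(c("A", "A", "A", "B", "B"))
  expect_equal(c(e$min_targets, e$max_targets), c(5L, 8L))

  expect_error(estimate_regulon_size("E"), "A, B, C or D")

  # property: max - min equals the type-A count; types partition the input
  set.seed(13)
  for (i in 1:50) {
    types <- sample(c("A", "B", "C", "D"), sample(0:60, 1), replace = TRUE)
    e <- estimate_regulon_size(types)
    expect_equal(e$max_targets - e$min_targets, e$n_typeA)
    expect_equal(e$n_typeA + e$n_typeB + e$n_typeC + e$n_typeD, length(types))
    expect_lte(e$min_targets, e$max_targets)
  }
})

test_that("mirror-reflecting the genome leaves every site type unchanged", {
  set.seed(29)
  for (i in 1:10) {
    L <- 5000L
    ann <- random_annotation(n_genes = 10, genome_length = L)
    f <- ann$features
    mirror <- genome_annotation(
      data.frame(id = f$id, start = L + 1L - f$end, end = L + 1L - f$start,
                 strand = ifelse(f$strand == "+", "-", "+")), L)
    for (pos in sample.int(L, 40)) {
      # positions beyond the outermost genes warn about the missing flank;
      # that behaviour has its own test above
      expect_equal(suppressWarnings(classify_site(pos, ann)$site_type),
                   suppressWarnings(classify_site(L + 1L - pos,
                                                  mirror)$site_type))
    }
  }
})

test_that("the site report table mirrors the published layout", {
  tbl <- pdhr_table1()
  ann <- fixture_annotation(tbl)
  res <- run_pipeline(ann, peak_table = tbl)
  st <- res$site_table

  pdhr <- st[st$peak_position == 121966, ]
  expect_equal(pdhr$site_sequence, "AATTGGTaagACCAATT")
  expect_equal(pdhr$conservation, "14/14")
  expect_equal(pdhr$motif_position, 122052L)
  expect_equal(pdhr$left_gene, "aroP")
  expect_equal(pdhr$left_dir, "<")
  expect_equal(pdhr$right_gene, "pdhR")
  expect_equal(pdhr$right_dir, ">")

  # rows without a printed motif render '-'
  xtha <- st[st$peak_position == 1831272, ]
  expect_equal(xtha$site_sequence, "-")
  expect_equal(xtha$conservation, "-")

  # intragenic rows name their host ORF
  ftsi <- st[st$peak_position == 92666, ]
  expect_equal(ftsi$host_gene, "ftsI")
  expect_equal(ftsi$site_type, "D")
})

test_that("assemble_site_table rejects duplicates and handles empty input", {
  ann <- divergent_ann()
  peaks <- data.frame(position = c(500, 500),
                      intensity_no_effector = c(600, 700),
                      intensity_effector = c(NA, NA))
  sites <- classify_sites(peaks, ann)
  expect_error(assemble_site_table(sites, peaks), "duplicate")

  empty <- data.frame(position = numeric(),
                      intensity_no_effector = numeric(),
                      intensity_effector = numeric())
  out <- assemble_site_table(list(), empty)
  expect_equal(nrow(out), 0L)
})
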