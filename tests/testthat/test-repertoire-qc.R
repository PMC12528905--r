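test_that("CDR3 extraction round-trips a known cassette realization", {
  tm <- default_template()
  arms <- template_arms(tm, 12L)
  vl_real <- "TATGACCGTAAGCCTTGG"          # a realization of the VL cassette
  clone <- make_clone(vl_nt = vl_real)
  ex <- extract_cdr3(clone, arms$VL)
  expect_true(ex$found)
  expect_identical(ex$nt, vl_real)
  # one mismatch in the upstream anchor is tolerated
  iv <- tm$intervals[tm$intervals$region == "VL", ]
  mut <- flip_base(clone, iv$start - 3L)   # inside the 12-nt upstream anchor
  ex2 <- extract_cdr3(mut, arms$VL)
  expect_true(ex2$found)
  expect_identical(ex2$nt, vl_real)
  # scrambled framework is unanchored
  scr <- paste(rev(strsplit(clone, "")[[1]]), collapse = "")
  ex3 <- extract_cdr3(scr, arms$VL)
  expect_false(ex3$found)
  expect_identical(ex3$reason, "unanchored")
  # anchors must be at least 6 nt
  expect_error(extract_cdr3(clone, list(upstream = "ACGTA", downstream = "ACGTAC")),
               class = "scfvlib_configuration_error")
})

test_that("template detection triggers on exact match or depletion site", {
  tm <- default_template()
  clones <- data.frame(
    vl_nt = c(template_region(tm, "VL"),      # exact template VL
              "TATGAGCTCAAGCCTTGG",           # mutant that contains SacI
              "TATGACCGTAAGCCTTGG"),          # site-free mutant
    vh_nt = c(template_region(tm, "VH"),
              "CGTAAATTTGGGCCCTTTAAAGGGGAT",
              "CGTAAATTTGGGCCCTTTAAAGGGGAT"))
  det <- detect_template(clones, tm)
  expect_identical(det$is_template, c(TRUE, TRUE, FALSE))
  expect_match(det$evidence[1], "VL_exact")
  expect_match(det$evidence[1], "VH_exact")
  expect_identical(det$evidence[2], "VL_site")
  expect_identical(det$evidence[3], "")
})

test_that("an error-free synthetic repertoire is fully recovered", {
  design <- default_design()
  cfg <- generator_config(seed = 101, n_clones = 200)
  rep <- generate_repertoire(design, cfg)
  clones <- process_clones(rep$sequences, design$template)
  expect_true(all(clones$vl_found & clones$vh_found))      # 100% extraction
  expect_false(any(clones$vl_frameshift | clones$vh_frameshift))
  expect_identical(clones$vl_nt, rep$truth$vl_nt)
  expect_identical(clones$vh_nt, rep$truth$vh_nt)
  s <- summarize_repertoire(clones, design)
  expect_equal(s$n_total, 200L)
  expect_equal(s$template_count, 0L)
  # histogram equals the truth table's sampled lengths exactly
  # (the VH histogram conditions on VH-usable clones only)
  usable <- !grepl("*", rep$truth$vh_pep, fixed = TRUE)
  truth_hist <- table(rep$truth$vh_loop_length[usable])
  expect_equal(as.vector(s$length_histogram$VH),
               as.vector(truth_hist))
  expect_identical(names(s$length_histogram$VH), names(truth_hist))
})

test_that("per-position statistics: fixed positions have zero entropy", {
  design <- default_design()
  rep <- generate_repertoire(design, generator_config(seed = 7, n_clones = 150))
  s <- summarize_repertoire(rep$sequences, design)
  # VL 95 is fixed proline; VH 94/101 are fixed anchors
  expect_equal(unname(s$entropy_bits$VL[["95"]]), 0)
  expect_equal(s$aa_count_matrix$VL["P", "95"], sum(s$aa_count_matrix$VL[, "95"]))
  expect_equal(unname(s$entropy_bits$VH[["94"]]), 0)
  expect_equal(unname(s$entropy_bits$VH[["101"]]), 0)
  expect_true(all(unlist(s$entropy_bits) <= log2(21) + 1e-12))
  # each matrix column sums to the number of clones covering that position
  vh <- s$aa_count_matrix$VH
  expect_equal(unname(colSums(vh)[["94"]]), unname(s$n_usable[["VH"]]))
  lens <- as.integer(names(s$length_histogram$VH))
  cnts <- as.vector(s$length_histogram$VH)
  expect_equal(unname(colSums(vh)[["100a"]]), sum(cnts[lens >= 7L]))
})

test_that("summarize handles empty input", {
  design <- default_design()
  s <- summarize_repertoire(Biostrings::DNAStringSet(), design)
  expect_equal(s$n_total, 0L)
  expect_equal(unname(s$n_usable), c(0L, 0L))
})

test_that("Jensen-Shannon divergence: identical 0, disjoint 1, closed form", {
  p <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  expect_equal(js_divergence(p, p), 0)
  expect_equal(js_divergence(c(A = 1), c(B = 1)), 1)
  # hand-computed: p = {A:1}, q = {A:.5, B:.5}
  m <- c(0.75, 0.25)
  expected <- 0.5 * log2(1 / 0.75) +
    0.5 * (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25))
  expect_equal(js_divergence(c(A = 1), c(A = 0.5, B = 0.5)), expected)
  # reference vs theoretical NNK distribution at one position
  nnk <- aa_distribution("NNK")
  nnk <- nnk[names(nnk) != "*"]; nnk <- nnk / sum(nnk)
  unif <- stats::setNames(rep(1 / 20, 20), names(nnk))
  direct <- local({
    m <- (nnk + unif) / 2
    sum(nnk * log2(nnk / m)) / 2 + sum(unif * log2(unif / m)) / 2
  })
  expect_equal(js_divergence(nnk, unif), direct)
})

test_that("compare_to_reference is zero against the repertoire's own frequencies", {
  design <- default_design()
  rep <- generate_repertoire(design, generator_config(seed = 13, n_clones = 120))
  s <- summarize_repertoire(rep$sequences, design)
  ref <- export_logo_matrix(s, "VL")
  cmp <- compare_to_reference(s, ref, "VL")
  expect_true(all(abs(cmp$jsd_bits) < 1e-12))
  expect_equal(attr(cmp, "mean_jsd"), 0, tolerance = 1e-12)
})

test_that("logo matrices are row-normalized and export to TSV", {
  design <- default_design()
  rep <- generate_repertoire(design, generator_config(seed = 3, n_clones = 80))
  s <- summarize_repertoire(rep$sequences, design)
  freq <- export_logo_matrix(s, "VH")
  covered <- rowSums(freq) > 0
  expect_true(all(abs(rowSums(freq)[covered] - 1) < 1e-9))
  expect_equal(unname(freq["94", "R"]), 1)   # fixed Arg anchor row
  tsv <- tempfile(fileext = ".tsv")
  export_logo_matrix(s, "VL", tsv)
  back <- read_reference_tsv(tsv)
  expect_equal(unname(back), unname(export_logo_matrix(s, "VL")),
               tolerance = 1e-12)
})

test_that("library size estimation scales counts by dilution and plating", {
  est <- estimate_library_size(173, 1e8)
  expect_equal(est$estimate, 1.73e10)
  est3 <- estimate_library_size(c(100, 100, 100), 1e6)
  expect_equal(est3$estimate, 1e8)
  expect_equal(est3$sd, 0)
  frac <- estimate_library_size(100, 1e6, plated_fraction = 0.1)
  expect_equal(frac$estimate, 1e9)   # 10x the fully-plated estimate
  expect_error(estimate_library_size(c(1, 2), c(1e6, 1e6, 1e6)), "length")
})

test_that("clone FASTA/FASTQ readers accept both formats", {
  design <- default_design()
  rep <- generate_repertoire(design, generator_config(seed = 5, n_clones = 4))
  fa <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(rep$sequences, fa)
  expect_length(read_clones_fasta(fa), 4L)
  fq <- tempfile(fileext = ".fastq")
  Biostrings::writeXStringSet(rep$sequences, fq, format = "fastq")
  expect_length(read_clones_fasta(fq), 4L)
})
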