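test_that("VL cassettes follow the two-variant position plan", {
  vl <- build_vl_cassettes()
  expect_named(vl, c("A", "B"))
  codons <- function(cs) vapply(cs$positions, function(p)
    paste(p$codon$codes, collapse = ""), "")
  labels <- function(cs) vapply(cs$positions, `[[`, "", "kabat_label")
  expect_identical(labels(vl$A), as.character(91:96))
  expect_identical(codons(vl$A), c("TAT", "DRC", "RRY", "NNK", "CCT", "NNK"))
  expect_identical(codons(vl$B)[1], "NNK")      # variant B randomizes 91
  expect_identical(codons(vl$B)[-1], codons(vl$A)[-1])
  # fixed positions translate as designed
  expect_equal(c(unclass(aa_distribution(vl$A$positions[[5]]$codon))), c(P = 1))
  expect_identical(vl$A$positions[[1]]$fixed_aa, "Y")
})

test_that("VL variant A protein diversity is the per-position product", {
  vl <- build_vl_cassettes()$A
  randomized <- vl$positions[!vapply(vl$positions, scfvlib:::is_fixed_position, TRUE)]
  codons <- vapply(randomized, function(p) paste(p$codon$codes, collapse = ""), "")
  expect_identical(codons, c("DRC", "RRY", "NNK", "NNK"))
  expect_equal(as.numeric(cassette_protein_diversity(codons)),
               prod(vapply(codons, function(cs) {
                 aas <- oracle_aa_distribution(cs)
                 length(setdiff(names(aas), "*"))
               }, 1)))
})

test_that("VH cassettes put k NNK codons between Arg94 and Asp101", {
  for (k in c(1L, 5L, 28L)) {
    cs <- build_vh_cassettes("S", k)[[1]]
    expect_length(cs$positions, k + 2L)
    expect_equal(cassette_loop_length(cs), k)
    first <- cs$positions[[1]]; last <- cs$positions[[k + 2L]]
    expect_identical(first$kabat_label, "94")
    expect_identical(last$kabat_label, "101")
    code <- genetic_code("standard")
    expect_identical(unname(code[expand_codon(first$codon)]), "R")
    expect_identical(unname(code[expand_codon(last$codon)]), "D")
    mids <- vapply(cs$positions[2:(k + 1L)], function(p)
      paste(p$codon$codes, collapse = ""), "")
    expect_true(all(mids == "NNK"))
    labs <- vapply(cs$positions, `[[`, "", "kabat_label")
    expect_false(anyDuplicated(labs) > 0)
    expect_identical(labs, labs[order(scfvlib:::kabat_sort_key(labs))])
  }
  expect_error(build_vh_cassettes("S", 33L), class = "scfvlib_unsupported_length")
  expect_error(build_vh_cassettes("S", 0L), class = "scfvlib_unsupported_length")
})

test_that("Kabat insertion labels extend 100 with letters", {
  expect_identical(kabat_vh_labels(5), as.character(95:99))
  expect_identical(kabat_vh_labels(8), c(as.character(95:100), "100a", "100b"))
  expect_identical(kabat_vh_labels(28)[28], "100v")
})

test_that("the default design covers S 5-22 and L 9-28", {
  design <- default_design()
  s_len <- vapply(design$sublibraries$S$cassettes, cassette_loop_length, 1L)
  l_len <- vapply(design$sublibraries$L$cassettes, cassette_loop_length, 1L)
  expect_identical(unname(s_len), 5:22)
  expect_identical(unname(l_len), 9:28)
  expect_length(design$sublibraries$S$cassettes, 18L)
  expect_length(design$sublibraries$L$cassettes, 20L)
})

test_that("template carries unique SacI/NheI sites inside the CDR3 intervals", {
  report <- check_template_sites(default_template())
  expect_true(all(report$pass))
  expect_true(all(report$palindromic))
  # site missing
  broken <- default_template()
  broken$sequence <- sub("GAGCTC", "GAGGTC", broken$sequence)
  r2 <- check_template_sites(broken)
  expect_false(r2$pass[r2$enzyme == "SacI"])
  expect_equal(r2$n_in_region[r2$enzyme == "SacI"], 0L)
  # duplicated site outside the CDR3: uniqueness violated
  dup <- default_template()
  dup$sequence <- paste0(dup$sequence, "GCTAGC")
  r3 <- check_template_sites(dup)
  expect_false(r3$unique_in_template[r3$enzyme == "NheI"])
  expect_false(r3$pass[r3$enzyme == "NheI"])
  # unannotated template
  bare <- scfv_template(default_template()$sequence, intervals = NULL)
  expect_error(check_template_sites(bare),
               class = "scfvlib_annotation_required")
})

test_that("site-regeneration risk matches enumeration", {
  expect_equal(cassette_site_regeneration_risk(c("TAT", "CCT"), "GAGCTC"), 0)
  expect_equal(cassette_site_regeneration_risk(c("GAG", "CTC"), "GAGCTC"), 1)
  # single NNK window overlapping a fixed arm: enumerate the 32 realizations
  risk <- cassette_site_regeneration_risk("NNK", "GAGCTC",
                                          upstream_arm = "GAGCT",
                                          downstream_arm = "")
  hits <- mean(grepl("GAGCTC",
                     paste0("GAGCT", expand_codon("NNK")), fixed = TRUE))
  expect_equal(risk, hits)
  # NNK runs can never regenerate either depletion site without arm help
  expect_equal(cassette_site_regeneration_risk(rep("NNK", 10), "GAGCTC"), 0)
  expect_equal(cassette_site_regeneration_risk(rep("NNK", 10), "GCTAGC"), 0)
})

test_that("theoretical stats: totals are exact sums; k-NNK stop-free fraction is (31/32)^k", {
  design <- default_design()
  st <- theoretical_library_stats(design)
  pc <- st$per_cassette
  expect_equal(sum(pc$sublibrary == "S"), 18L)
  expect_equal(sum(pc$sublibrary == "L"), 20L)
  s_rows <- pc[pc$sublibrary == "S", ]
  expect_equal(s_rows$stop_free_fraction, (31 / 32)^s_rows$loop_length)
  manual <- Reduce(scfvlib:::bi_add,
                   lapply(s_rows$dna_diversity, big_integer), big_integer(0))
  expect_identical(format(manual), format(st$totals$S$dna_diversity))
  # every VH cassette's DNA diversity is 32^k
  expect_identical(pc$dna_diversity[pc$name == "VH-S-05"],
                   format(bi_prod(rep(32, 5))))
})

test_that("cassette constructor rejects ambiguous arms and enforces anchors", {
  pos <- list(position_spec("94", "CGT", "R"),
              position_spec("95", "NNK"),
              position_spec("101", "GAT", "D"))
  expect_error(cdr3_cassette("VH", pos, "ACGN", "ACGT", "x"),
               class = "scfvlib_invalid_arm")
  ok <- cdr3_cassette("VH", pos, "ACGT", "ACGT", "x")
  expect_s3_class(ok, "cdr3_cassette")
  # anchors out of order must fail
  bad <- list(position_spec("94", "NNK"), position_spec("101", "GAT", "D"))
  expect_error(cdr3_cassette("VH", bad, "ACGT", "ACGT", "x"))
})

test_that("cassette export round-trips through FASTA and manifest", {
  design <- default_design()
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  manifest <- export_cassettes(design, fa, tsv)
  oligos <- Biostrings::readDNAStringSet(fa)
  expect_length(oligos, 2L + 18L + 20L)
  expect_identical(nrow(utils::read.delim(tsv)), length(oligos))
  vlA <- as.character(oligos[["VL-A"]])
  core <- manifest$core_iupac[manifest$name == "VL-A"]
  expect_identical(vlA, paste0(design$vl_cassettes$A$upstream_arm, core,
                               design$vl_cassettes$A$downstream_arm))
})
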