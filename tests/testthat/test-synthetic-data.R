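test_that("generation is deterministic given the seed, to the byte", {
  design <- default_design()
  cfg <- generator_config(seed = 77, n_clones = 60, template_fraction = 0.1,
                          substitution_rate = 0.002, indel_rate = 0.001)
  r1 <- generate_repertoire(design, cfg)
  r2 <- generate_repertoire(design, cfg)
  f1 <- tempfile(fileext = ".fasta"); t1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fasta"); t2 <- tempfile(fileext = ".tsv")
  write_repertoire(r1, f1, t1)
  write_repertoire(r2, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
  # a different seed changes the output
  r3 <- generate_repertoire(design, generator_config(seed = 78, n_clones = 60,
                                                     template_fraction = 0.1))
  expect_false(identical(as.character(r1$sequences), as.character(r3$sequences)))
})

test_that("template_fraction = 1 emits only the unmutated template", {
  design <- default_design()
  rep <- generate_repertoire(design, generator_config(seed = 2, n_clones = 20,
                                                      template_fraction = 1))
  expect_true(all(rep$truth$is_template))
  expect_true(all(as.character(rep$sequences) == design$template$sequence))
})

test_that("error-free S-only clones stay within the designed length bounds", {
  design <- default_design()
  cfg <- generator_config(seed = 9, n_clones = 300,
                          sublibrary_mix = c(S = 1, L = 0))
  rep <- generate_repertoire(design, cfg)
  expect_true(all(rep$truth$source == "S"))
  expect_true(all(rep$truth$vh_loop_length >= 5 & rep$truth$vh_loop_length <= 22))
  # truth consistency: flags derived downstream match the truth table
  clones <- process_clones(rep$sequences, design$template)
  expect_true(all(clones$vl_found & clones$vh_found))
  expect_identical(clones$vh_nt, rep$truth$vh_nt)
  expect_identical(clones$vh_pep, rep$truth$vh_pep)
  expect_false(any(clones$template))
  has_stop <- grepl("*", rep$truth$vh_pep, fixed = TRUE) |
    grepl("*", rep$truth$vl_pep, fixed = TRUE)
  expect_identical(clones$vl_stop | clones$vh_stop, has_stop)
})

test_that("n_clones = 0 gives empty outputs", {
  rep <- generate_repertoire(default_design(), generator_config(n_clones = 0))
  expect_length(rep$sequences, 0L)
  expect_equal(nrow(rep$truth), 0L)
})

test_that("a spiked template fraction is recovered within the binomial CI", {
  design <- default_design()
  f <- 0.15
  rep <- generate_repertoire(design, generator_config(seed = 19, n_clones = 2000,
                                                      template_fraction = f))
  clones <- process_clones(rep$sequences, design$template)
  detected <- sum(clones$template)
  expect_identical(clones$template, rep$truth$is_template)
  ci <- stats::binom.test(detected, nrow(clones))$conf.int
  expect_gte(f, ci[1])
  expect_lte(f, ci[2])
})

test_that("sequencing errors are recorded and perturb the reads", {
  design <- default_design()
  cfg <- generator_config(seed = 4, n_clones = 50,
                          substitution_rate = 0.01, indel_rate = 0.004)
  rep <- generate_repertoire(design, cfg)
  expect_gt(sum(rep$truth$n_sub), 0)
  expect_gt(sum(rep$truth$n_ins) + sum(rep$truth$n_del), 0)
  # read lengths shift by the net indel count
  framework_len <- nchar(design$template$sequence) -
    sum(design$template$intervals$end - design$template$intervals$start)
  expect_equal(unname(nchar(as.character(rep$sequences))),
               framework_len + nchar(rep$truth$vl_nt) + nchar(rep$truth$vh_nt) +
                 rep$truth$n_ins - rep$truth$n_del)
})

test_that("sampled NNK positions match the theoretical distribution at n = 10,000", {
  design <- default_design()
  rep <- generate_repertoire(design, generator_config(seed = 31, n_clones = 10000))
  # VL Kabat 96 is NNK in both variants: 6th residue of the VL peptide
  aa <- substr(rep$truth$vl_pep, 6L, 6L)
  emp <- table(aa) / length(aa)
  theo <- aa_distribution("NNK")
  expect_lt(total_variation(stats::setNames(as.numeric(emp), names(emp)),
                            c(unclass(theo))), 0.05)
})

test_that("ELISA fixtures plant the configured binders", {
  fx0 <- generate_elisa_fixture(n_binders = 0, seed = 6)
  expect_length(call_hits(fx0$plate)$hits, 0L)
  expect_false(any(fx0$truth$is_binder))
  # recovery degrades monotonically as the high component sinks into the low
  recall_at <- function(high_meanlog) {
    hits <- vapply(1:8, function(s) {
      fx <- generate_elisa_fixture(
        seed = s, signal_params = list(low_meanlog = log(0.08), low_sdlog = 0.2,
                                       high_meanlog = high_meanlog,
                                       high_sdlog = 0.25))
      length(intersect(call_hits(fx$plate)$hits,
                       fx$truth$id[fx$truth$is_binder]))
    }, 1L)
    mean(hits) / 12
  }
  recalls <- vapply(log(c(1.0, 0.45, 0.25, 0.12)), recall_at, 1)
  expect_true(all(diff(recalls) <= 0))
  expect_equal(recalls[1], 1)
})

test_that("panning fixtures follow the configured enrichment factor", {
  tr <- enrichment_trajectory(generate_panning_fixture(
    n_rounds = 3, enrichment_factor = 10, initial_ratio = 1e-8,
    noise_sdlog = 0))
  expect_equal(tr$ratio, 1e-8 * c(1, 10, 100))
  flat <- enrichment_trajectory(generate_panning_fixture(
    n_rounds = 4, enrichment_factor = 1, noise_sdlog = 0))
  expect_true(all(flat$ratio == flat$ratio[1]))
  n1 <- generate_panning_fixture(noise_sdlog = 0.3, seed = 12)
  n2 <- generate_panning_fixture(noise_sdlog = 0.3, seed = 12)
  expect_identical(n1$output_titer, n2$output_titer)
})

test_that("configs round-trip through JSON", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 5, n_clones = 25, template_fraction = 0.2,
                            sublibrary_mix = list(S = 0.3, L = 0.7)),
                       path, auto_unbox = TRUE)
  cfg <- generator_config_from_json(path)
  expect_equal(cfg$n_clones, 25L)
  expect_equal(unname(cfg$sublibrary_mix[c("S", "L")]), c(0.3, 0.7))
  dpath <- tempfile(fileext = ".json")
  jsonlite::write_json(list(s_lengths = c(6, 10), l_lengths = c(12, 16),
                            vl_variant_b_91 = "NNC"), dpath, auto_unbox = TRUE)
  design <- design_from_json(dpath)
  expect_identical(design$sublibraries$S$loop_lengths, 6:10)
  expect_identical(
    paste(design$vl_cassettes$B$positions[[1]]$codon$codes, collapse = ""),
    "NNC")
})
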