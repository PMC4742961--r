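# A feature-rich community: 100 kb genomes carry the full complement of
# marker, pathway, defence and cas ORFs alongside planted arrays.
make_bundle <- function() {
  cfg <- community_config(n_genomes = 14L, genome_length_bp = 100000L,
                          n_viruses = 8L, circular_fraction = 0.75,
                          targeted_fraction = 0.25, symbiont_fraction = 0.35,
                          true_cas_rate = 0.45, rng_seed = 17L)
  generate_community(cfg)
}

test_that("the in-memory census is truthful and deterministic", {
  bundle <- make_bundle()
  res <- census_community(bundle)
  expect_s3_class(res, "census_result")
  expect_equal(nrow(res$per_genome), 14)

  truth <- bundle$truth
  # no genome is called positive unless it truly carries CRISPR-Cas
  expect_true(all(truth$cas_carrier[res$per_genome$cas_present]))
  # every intact planted array is found
  expect_true(all(res$per_genome$cas_present[truth$array_intact]))
  expect_true(all(res$per_genome$n_arrays[truth$array_intact] >= 1))

  # completeness estimates track the planted completeness closely
  expect_true(all(abs(res$per_genome$completeness - truth$completeness) < 0.1))

  # correction can only raise the rate, and rates stay probabilities
  expect_true(all(res$census$corrected_rate >= res$census$raw_rate - 1e-12))
  expect_true(all(res$census$corrected_rate <= 1))

  # deficit tail is a (log) probability over the bacterial subset
  expect_true(res$deficit$log10_tail <= 0)
  expect_equal(res$deficit$n, sum(truth$domain == "bacteria"))

  # defence inventory: symbionts carry no pathway KOs
  expect_equal(nrow(res$defence), 14)
  sym <- truth$genome[truth$lifestyle == "obligate_symbiont"]
  expect_true(all(res$defence$nucleotide_status[res$defence$genome %in% sym]
                  == "absent"))

  # genus-weighted association is fitted when both lifestyles are present
  expect_s3_class(res$association, "lifestyle_assoc")

  # determinism: the census is a pure function of the bundle
  res2 <- census_community(bundle)
  expect_equal(glance(res), glance(res2))
  expect_equal(res$census, res2$census)
})

test_that("census result prints, glances and plots", {
  bundle <- make_bundle()
  res <- census_community(bundle)
  expect_output(print(res), "Defence-system census")
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_genomes, 14)
  expect_true(gl$corrected_rate >= gl$raw_rate)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)

  hm <- plot_repeat_similarity(
    repeat_similarity_matrix(c(r1 = "ACGTACGTACGTACGTACGTACG",
                               r2 = "ACGTACGTACGAACGTACGTACG"))
  )
  expect_s3_class(hm, "ggplot")
})

test_that("run_census writes its outputs and reproduces the in-memory run", {
  bundle <- make_bundle()
  indir <- withr::local_tempdir()
  outdir <- file.path(withr::local_tempdir(), "out")
  write_community(bundle, indir)
  res <- run_census(list(input_dir = indir, outdir = outdir), verbose = FALSE)
  expect_true(file.exists(file.path(outdir, "census.tsv")))
  expect_true(file.exists(file.path(outdir, "defence.tsv")))
  expect_true(file.exists(file.path(outdir, "stats_report.json")))
  census_disk <- readr::read_tsv(file.path(outdir, "census.tsv"),
                                 show_col_types = FALSE)
  expect_equal(census_disk$n_present, res$census$n_present)
  report <- jsonlite::read_json(file.path(outdir, "stats_report.json"))
  expect_equal(report$deficit$k_observed, res$deficit$k_observed)
  expect_equal(report$thresholds$evalue, 1e-10)

  # disk round-trip gives the same census as the in-memory bundle
  res_mem <- census_community(bundle)
  expect_equal(res$census, res_mem$census)
  expect_equal(res$per_genome$cas_present, res_mem$per_genome$cas_present)
})

test_that("run_census validates thresholds before doing any work", {
  outdir <- file.path(tempdir(), "never-created-census-out")
  err <- expect_error(
    run_census(list(input_dir = tempdir(), outdir = outdir,
                    thresholds = list(min_spacer_identity = 1.5))),
    class = "crisprcensus_config_error"
  )
  expect_match(conditionMessage(err), "min_spacer_identity")
  expect_false(dir.exists(outdir))
  expect_error(
    run_census(list(thresholds = list(evalue = 0))),
    class = "crisprcensus_config_error"
  )
})

test_that("a stage failure names the stage and records the error", {
  outdir <- withr::local_tempdir()
  err <- expect_error(
    run_census(list(input_dir = file.path(tempdir(), "no-such-community"),
                    outdir = outdir), verbose = FALSE),
    class = "crisprcensus_stage_error"
  )
  expect_match(conditionMessage(err), "stage 'load'")
  expect_true(file.exists(file.path(outdir, "failed", "error.txt")))
  expect_match(readLines(file.path(outdir, "failed", "error.txt"))[1],
               "stage: load")
})

test_that("the command-line front end runs end to end", {
  cli <- system.file("cli", "crispr-census.R", package = "crisprcensus")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  outdir <- withr::local_tempdir()
  st <- system2(rscript, c(cli, "simulate", "--seed", "2", "--n-genomes", "3",
                           "--outdir", outdir),
                stdout = TRUE, stderr = TRUE)
  expect_equal(attr(st, "status") %||% 0L, 0L)
  expect_true(file.exists(file.path(outdir, "genomes.fasta")))

  arr_tsv <- file.path(outdir, "arrays.tsv")
  st2 <- system2(rscript, c(cli, "detect-arrays", "--fasta",
                            file.path(outdir, "genomes.fasta"),
                            "--out", arr_tsv),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(st2, "status") %||% 0L, 0L)
  arrays <- readr::read_tsv(arr_tsv, show_col_types = FALSE)
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
                               simplifyVector = TRUE)
  # every intact planted array is recovered, and arrays only ever sit on
  # scaffolds of true carrier genomes
  expect_gte(nrow(arrays), sum(truth$genomes$array_intact))
  carrier_ids <- truth$genomes$genome[truth$genomes$cas_carrier]
  array_genomes <- sub("\\|.*$", "", arrays$scaffold)
  expect_true(all(array_genomes %in% carrier_ids))

  # unknown subcommands exit non-zero (system2 warns about that status,
  # which is exactly what is being asserted)
  st3 <- suppressWarnings(
    system2(rscript, c(cli, "frobnicate"), stdout = TRUE, stderr = TRUE)
  )
  expect_equal(attr(st3, "status"), 1L)
})
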