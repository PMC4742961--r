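test_that("configuration fields are validated by name", {
  err <- expect_error(community_config(frac_bacteria = 1.2),
                      class = "crisprcensus_config_error")
  expect_match(conditionMessage(err), "frac_bacteria")
  expect_error(community_config(n_genomes = 0),
               class = "crisprcensus_config_error")
  expect_error(community_config(completeness_range = c(0.9, 0.5)),
               class = "crisprcensus_config_error")
  expect_error(community_config(cas_effect = -1),
               class = "crisprcensus_config_error")
  expect_s3_class(community_config(), "community_config")
})

test_that("planted array arithmetic is exact", {
  set.seed(801)
  bg <- oracle_random_dna(1000)
  arr <- plant_crispr_array(bg, n_units = 4L, repeat_len = 30L,
                            spacer_len = 35L, at = 600L)
  expect_equal(arr$end - arr$start, 4L * 30L + 3L * 35L)  # 225 bp
  expect_equal(nchar(arr$scaffold), 1000L + 225L)
  # the inserted region reconstructs from repeat and spacers
  region <- substring(arr$scaffold, arr$start + 1, arr$end)
  expect_identical(
    region,
    paste0(paste0(arr$repeat_seq, arr$spacers, collapse = ""), arr$repeat_seq)
  )
  # flanks are untouched
  expect_identical(substr(arr$scaffold, 1, 600), substr(bg, 1, 600))
  expect_identical(substring(arr$scaffold, arr$end + 1), substring(bg, 601))
})

test_that("degradation removes exactly one block of the right size", {
  set.seed(802)
  G <- 20000L
  g <- oracle_random_dna(G)
  deg <- degrade_genome(g, completeness = 0.8, gap_start = 5000L)
  expect_equal(deg$gap_len, 4000L)
  expect_equal(nchar(deg$scaffold), 16000L)
  expect_identical(substr(deg$scaffold, 1, 5000), substr(g, 1, 5000))
  expect_identical(substring(deg$scaffold, 5001), substring(g, 9001))
  # completeness 1 is a no-op
  intact <- degrade_genome(g, completeness = 1)
  expect_identical(intact$scaffold, g)
  expect_equal(intact$gap_len, 0L)
  expect_error(degrade_genome(g, 0), class = "crisprcensus_input_error")
})

test_that("features are dropped, truncated or remapped around the gap", {
  g <- strrep("ACGT", 5000)  # 20 kb
  feats <- tibble::tibble(
    fid = 1:4,
    start = c(1000L, 5500L, 4500L, 9000L),
    end = c(1900L, 6500L, 5500L, 9900L)
  )
  deg <- degrade_genome(g, completeness = 0.8, features = feats,
                        gap_start = 5000L)  # gap [5000, 9000)
  kept <- deg$features
  expect_setequal(kept$fid, c(1L, 3L, 4L))          # fid 2 wholly inside
  f1 <- kept[kept$fid == 1, ]                       # before the gap
  expect_equal(c(f1$start, f1$end), c(1000L, 1900L))
  expect_false(f1$truncated)
  f3 <- kept[kept$fid == 3, ]                       # straddles gap start
  expect_true(f3$truncated)
  expect_equal(c(f3$start, f3$end), c(4500L, 5000L))
  f4 <- kept[kept$fid == 4, ]                       # after the gap, shifted
  expect_equal(c(f4$start, f4$end), c(5000L, 5900L))
  expect_false(f4$truncated)
  # remapped features still address the same sequence content
  expect_identical(substring(deg$scaffold, f4$start + 1, f4$end),
                   substring(g, 9001, 9900))
})

test_that("gap placement loses a central segment at the modelled rate", {
  set.seed(803)
  G <- 20000L; L <- 775L; comp <- 0.7
  a <- (G - L) %/% 2
  g <- strrep("A", G)
  feats <- tibble::tibble(fid = 1L, start = a, end = a + L)
  lost <- vapply(1:400, function(i) {
    deg <- degrade_genome(g, comp, features = feats)
    nrow(deg$features) == 0
  }, logical(1))
  expected <- miss_probability(G, G - round((1 - comp) * G), L)
  # 400 Bernoulli draws: stay within ~3 standard errors
  expect_lt(abs(mean(lost) - expected), 0.08)
})

test_that("carrier draws respect the configured rate", {
  cfg <- community_config(n_genomes = 1000L, genome_length_bp = 5000L,
                          true_cas_rate = 0.40, symbiont_fraction = 0,
                          completeness_range = c(1, 1), n_viruses = 0L,
                          rng_seed = 7L)
  bundle <- generate_community(cfg)
  carriers <- sum(bundle$truth$cas_carrier)
  expect_gte(carriers, 340)
  expect_lte(carriers, 460)

  cfg_all <- community_config(n_genomes = 30L, genome_length_bp = 5000L,
                              true_cas_rate = 1, n_viruses = 0L, rng_seed = 3L)
  expect_true(all(generate_community(cfg_all)$truth$cas_carrier))
  cfg_none <- community_config(n_genomes = 30L, genome_length_bp = 5000L,
                               true_cas_rate = 0, n_viruses = 0L, rng_seed = 3L)
  expect_false(any(generate_community(cfg_none)$truth$cas_carrier))
})

test_that("cas_effect = 0 removes carriage from symbionts only", {
  cfg <- community_config(n_genomes = 300L, genome_length_bp = 5000L,
                          symbiont_fraction = 0.5, cas_effect = 0,
                          n_viruses = 0L, rng_seed = 5L)
  truth <- generate_community(cfg)$truth
  expect_true(any(truth$lifestyle == "obligate_symbiont"))
  expect_false(any(truth$cas_carrier[truth$lifestyle == "obligate_symbiont"]))
  expect_true(any(truth$cas_carrier[truth$lifestyle == "free_living"]))
})

test_that("generation is deterministic given the configuration", {
  cfg <- community_config(n_genomes = 6L, genome_length_bp = 20000L,
                          n_viruses = 4L, rng_seed = 99L)
  b1 <- generate_community(cfg)
  b2 <- generate_community(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$viruses, b2$viruses)
  expect_identical(b1$genomes[[1]]$scaffolds, b2$genomes[[1]]$scaffolds)
  expect_identical(b1$genomes[[3]]$orfs, b2$genomes[[3]]$orfs)
})

test_that("planted truth is faithful to the generated sequences", {
  cfg <- community_config(n_genomes = 8L, genome_length_bp = 100000L,
                          completeness_range = c(1, 1), n_viruses = 0L,
                          true_cas_rate = 0.5, rng_seed = 13L)
  bundle <- generate_community(cfg)
  for (i in seq_along(bundle$genomes)) {
    g <- bundle$genomes[[i]]
    t <- bundle$truth[i, ]
    if (t$cas_carrier) {
      # array coordinates index a repeat-spacer alternation
      region <- substring(g$scaffolds[[1]], t$array_start + 1, t$array_end)
      expect_equal(nchar(region), 4L * 30L + 3L * 35L)
      expect_true(t$array_intact)
      # cas hits planted in the ORF table
      expect_true(any(g$orfs$hit_family %in% "cas1"))
    } else {
      expect_false(any(g$orfs$hit_source %in% "cas"))
    }
    # single-copy markers planted; free-living genomes carry all KOs
    expect_gt(g$scg_expected, 0)
    expect_equal(g$scg_found, g$scg_expected)  # undegraded
    if (g$lifestyle == "free_living") {
      expect_setequal(g$kos, sprintf("K%05d", 1:19))
    } else {
      expect_length(g$kos, 0)
    }
  }
})

test_that("viral truth is faithful: links, circularity and protospacers", {
  set.seed(804)
  cfg <- community_config(n_genomes = 1L, n_viruses = 20L,
                          circular_fraction = 0.5, targeted_fraction = 0.2,
                          rng_seed = 21L)
  pool <- vapply(1:5, function(i) oracle_random_dna(35), character(1))
  vs <- generate_viral_set(cfg, spacer_pool = pool)
  expect_length(vs$viruses, 20)
  expect_equal(sum(vs$truth$is_circular), 10)
  # every circular virus has a >= 5-pair self link; no non-circular does
  self5 <- vs$link_table$scaffold_a[vs$link_table$n_pairs >= 5]
  expect_setequal(self5, vs$truth$virus[vs$truth$is_circular])
  # planted protospacers are recoverable at >= 90% identity
  planted <- vs$truth[!is.na(vs$truth$planted_spacer), ]
  expect_equal(nrow(planted), 4)
  for (j in seq_len(nrow(planted))) {
    m <- match_spacers(setNames(planted$planted_spacer[j], "sp"),
                       vs$viruses[planted$virus[j]])
    expect_gt(nrow(m), 0)
    expect_true(any(m$mismatches == planted$n_substitutions[j]))
  }
  # no spacer pool, no planting
  vs0 <- generate_viral_set(cfg, spacer_pool = character(0))
  expect_true(all(is.na(vs0$truth$planted_spacer)))
})

test_that("a community round-trips through disk", {
  cfg <- community_config(n_genomes = 5L, genome_length_bp = 20000L,
                          n_viruses = 4L, rng_seed = 31L)
  bundle <- generate_community(cfg)
  dir <- withr::local_tempdir()
  write_community(bundle, dir)
  back <- load_community(dir)
  expect_length(back$genomes, 5)
  for (i in 1:5) {
    expect_identical(back$genomes[[i]]$scaffolds,
                     bundle$genomes[[i]]$scaffolds)
    expect_equal(back$genomes[[i]]$orfs$annotation,
                 bundle$genomes[[i]]$orfs$annotation)
    expect_equal(back$genomes[[i]]$scg_found, bundle$genomes[[i]]$scg_found)
    expect_setequal(back$genomes[[i]]$kos, bundle$genomes[[i]]$kos)
  }
  expect_identical(back$viruses, bundle$viruses)
  expect_equal(back$link_table, bundle$link_table)
})
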