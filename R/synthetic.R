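#' Synthetic community configuration
#'
#' Defines the statistical structure of a generated genome collection:
#' hundreds of draft genomes of varying completeness, a minority carrying
#' CRISPR-Cas (reference carriage rate 40%), co-sampled viral scaffolds of
#' which some are circular and some spacer-targeted.
#'
#' @param n_genomes Number of genomes.
#' @param frac_bacteria Fraction of genomes labelled bacteria (rest
#'   archaea).
#' @param true_cas_rate Probability a genome carries CRISPR-Cas (the 40%
#'   reference rate for bacteria from cultivated-organism surveys).
#' @param completeness_range Low/high completeness fractions; per-genome
#'   completeness is uniform on this interval.
#' @param genome_length_bp Full genome length before degradation.
#' @param n_genera Number of genera to sample genomes from.
#' @param symbiont_fraction Fraction of genomes with an obligate-symbiont
#'   lifestyle.
#' @param cas_effect Odds multiplier applied to `true_cas_rate` for
#'   symbionts (below 1 depletes CRISPR-Cas in symbionts; 1 = no effect).
#' @param n_viruses,circular_fraction,targeted_fraction,viral_length_bp
#'   Viral set: count, fraction circular, fraction carrying a protospacer,
#'   and length range (pair).
#' @param rng_seed Integer seed; the generator is deterministic given the
#'   full configuration.
#' @return A `community_config` list.
#' @export
community_config <- function(n_genomes = 200L,
                             frac_bacteria = 0.9,
                             true_cas_rate = 0.40,
                             completeness_range = c(0.6, 1.0),
                             genome_length_bp = 100000L,
                             n_genera = 40L,
                             symbiont_fraction = 0.3,
                             cas_effect = 1.0,
                             n_viruses = 30L,
                             circular_fraction = 0.7,
                             targeted_fraction = 0.1,
                             viral_length_bp = c(6000L, 12000L),
                             rng_seed = 1L) {
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(paste0("invalid configuration field: ", nm),
            class = "crisprcensus_config_error")
    }
  }
  if (!is.numeric(n_genomes) || n_genomes < 1) {
    abort("invalid configuration field: n_genomes", class = "crisprcensus_config_error")
  }
  chk_frac(frac_bacteria, "frac_bacteria")
  chk_frac(true_cas_rate, "true_cas_rate")
  chk_frac(symbiont_fraction, "symbiont_fraction")
  chk_frac(circular_fraction, "circular_fraction")
  chk_frac(targeted_fraction, "targeted_fraction")
  if (length(completeness_range) != 2 ||
      completeness_range[1] > completeness_range[2] ||
      completeness_range[1] <= 0 || completeness_range[2] > 1) {
    abort("invalid configuration field: completeness_range",
          class = "crisprcensus_config_error")
  }
  if (cas_effect < 0) {
    abort("invalid configuration field: cas_effect", class = "crisprcensus_config_error")
  }
  structure(list(
    n_genomes = as.integer(n_genomes),
    frac_bacteria = frac_bacteria,
    true_cas_rate = true_cas_rate,
    completeness_range = as.numeric(completeness_range),
    genome_length_bp = as.integer(genome_length_bp),
    n_genera = as.integer(n_genera),
    symbiont_fraction = symbiont_fraction,
    cas_effect = cas_effect,
    n_viruses = as.integer(n_viruses),
    circular_fraction = circular_fraction,
    targeted_fraction = targeted_fraction,
    viral_length_bp = as.integer(viral_length_bp),
    rng_seed = as.integer(rng_seed)
  ), class = "community_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Built-in synthetic pathway module definitions
#'
#' Staged definitions mirroring the layout of KEGG modules M00048+M00051
#' (nucleotide biosynthesis, 12 combined stages) and M00082+M00083
#' (fatty-acid initiation + elongation, 7 combined stages). The KO
#' identifiers are synthetic placeholders emitted by the community
#' generator, not real KEGG orthologues.
#'
#' @return Module definition list as from [read_module_defs()].
#' @export
default_module_defs <- function() {
  list(
    nucleotide = list(
      modules = c("M00048", "M00051"),
      stages = lapply(1:12, function(i) sprintf("K%05d", i))
    ),
    fatty_acid = list(
      modules = c("M00082", "M00083"),
      stages = lapply(13:19, function(i) sprintf("K%05d", i))
    )
  )
}

#' Plant a CRISPR array into a scaffold
#'
#' Inserts a repeat-spacer alternation ending with a repeat (`n_units`
#' repeat copies, `n_units - 1` random spacers) at a random admissible
#' position, and returns the new scaffold plus exact coordinates.
#'
#' @param scaffold Nucleotide string.
#' @param n_units Number of repeat copies (>= 2).
#' @param repeat_len,spacer_len Unit lengths (bp).
#' @param at Insertion point (0-based); random if `NULL`.
#' @return List `scaffold`, `start`, `end` (0-based half-open on the new
#'   scaffold), `repeat_seq`, `spacers` (character vector).
#' @export
plant_crispr_array <- function(scaffold, n_units = 4L, repeat_len = 30L,
                               spacer_len = 35L, at = NULL) {
  stopifnot(n_units >= 2, repeat_len > 0, spacer_len > 0)
  n <- nchar(scaffold)
  ins_len <- n_units * repeat_len + (n_units - 1L) * spacer_len
  if (n < 2) {
    abort("scaffold too short to plant an array", class = "crisprcensus_plant_error")
  }
  rep_seq <- random_dna(repeat_len)
  spacers <- vapply(seq_len(n_units - 1L), function(i) random_dna(spacer_len),
                    character(1))
  insert <- paste0(paste0(rep_seq, spacers, collapse = ""), rep_seq)
  at <- at %||% sample.int(n - 1L, 1)
  list(
    scaffold = paste0(substr(scaffold, 1, at), insert,
                      substr(scaffold, at + 1L, n)),
    start = as.integer(at),
    end = as.integer(at + ins_len),
    repeat_seq = rep_seq,
    spacers = spacers
  )
}

#' Remove one contiguous block from a genome
#'
#' Implements the conservative contiguous-gap incompleteness model: a
#' block of `round((1 - completeness) * G)` bp is removed at a uniformly
#' random admissible start. Features (rows with `start`/`end`) wholly
#' inside the gap are dropped; features overlapping it are truncated and
#' flagged.
#'
#' @param scaffold Nucleotide string.
#' @param completeness Fraction in (0, 1].
#' @param features Optional tibble with `start`, `end` (0-based half-open)
#'   to remap onto the degraded scaffold.
#' @param gap_start Gap start (0-based); random if `NULL`.
#' @return List `scaffold`, `gap_start`, `gap_len`, `features` (remapped,
#'   with `truncated` flag; dropped rows removed).
#' @export
degrade_genome <- function(scaffold, completeness, features = NULL,
                           gap_start = NULL) {
  if (completeness <= 0 || completeness > 1) {
    abort("completeness must be in (0, 1]", class = "crisprcensus_input_error")
  }
  G <- nchar(scaffold)
  M <- round((1 - completeness) * G)
  if (M == 0) {
    if (!is.null(features)) features$truncated <- rep(FALSE, nrow(features))
    return(list(scaffold = scaffold, gap_start = NA_integer_, gap_len = 0L,
                features = features))
  }
  gs <- gap_start %||% (sample.int(G - M + 1L, 1) - 1L)  # 0-based
  ge <- gs + M
  new_scaffold <- paste0(substr(scaffold, 1, gs), substr(scaffold, ge + 1L, G))
  out_feats <- NULL
  if (!is.null(features) && nrow(features) > 0) {
    remap <- function(x) ifelse(x <= gs, x, pmax(gs, x - M))
    inside <- features$start >= gs & features$end <= ge
    features <- features[!inside, , drop = FALSE]
    if (nrow(features) > 0) {
      ns <- remap(pmin(features$start, G))
      ne <- remap(features$end)
      # positions inside the gap clamp to the junction
      s_in <- features$start > gs & features$start < ge
      e_in <- features$end > gs & features$end < ge
      ns[s_in] <- gs
      ne[e_in] <- gs
      features$truncated <- s_in | e_in |
        (features$start < gs & features$end > ge)
      features$start <- as.integer(ns)
      features$end <- as.integer(ne)
      features <- features[features$end > features$start, , drop = FALSE]
    }
    out_feats <- features
  }
  list(scaffold = new_scaffold, gap_start = as.integer(gs), gap_len = as.integer(M),
       features = out_feats)
}

#' Generate a synthetic viral set
#'
#' @param config A [community_config()].
#' @param spacer_pool Character vector of spacers available for
#'   protospacer planting (may be empty).
#' @return List `viruses` (named character vector), `link_table` (tibble),
#'   `truth` (tibble: `virus`, `is_circular`, `planted_spacer`,
#'   `n_substitutions`).
#' @export
generate_viral_set <- function(config, spacer_pool = character(0)) {
  nv <- config$n_viruses
  truth <- tibble(
    virus = sprintf("virus_%03d", seq_len(nv)),
    is_circular = logical(nv),
    planted_spacer = NA_character_,
    n_substitutions = NA_integer_
  )
  viruses <- character(nv)
  links <- list()
  if (nv == 0) {
    return(list(viruses = setNames(character(0), character(0)),
                link_table = empty_links(), truth = truth))
  }
  n_circ <- round(config$circular_fraction * nv)
  n_tgt <- round(config$targeted_fraction * nv)
  circ_idx <- if (n_circ > 0) seq_len(n_circ) else integer(0)
  tgt_idx <- if (n_tgt > 0 && length(spacer_pool) > 0) seq_len(n_tgt) else integer(0)
  for (i in seq_len(nv)) {
    len <- sample(config$viral_length_bp[1]:config$viral_length_bp[2], 1)
    seq <- random_dna(len)
    if (i %in% tgt_idx) {
      sp <- spacer_pool[[sample.int(length(spacer_pool), 1)]]
      # half exact, half diverged by <= 10% substitutions
      nsub <- if (i %% 2 == 0) 0L else
        sample.int(max(1L, floor(nchar(sp) * 0.1)), 1)
      proto <- mutate_substitutions(sp, nsub)
      at <- sample.int(len - nchar(proto), 1)
      seq <- paste0(substr(seq, 1, at), proto,
                    substr(seq, at + nchar(proto) + 1L, len))
      truth$planted_spacer[i] <- sp
      truth$n_substitutions[i] <- nsub
    }
    viruses[i] <- seq
    id <- truth$virus[i]
    if (i %in% circ_idx) {
      truth$is_circular[i] <- TRUE
      links[[length(links) + 1L]] <- tibble(
        scaffold_a = id, end_a = 5L, scaffold_b = id, end_b = 3L,
        n_pairs = sample(5:20, 1)
      )
    } else if (stats::runif(1) < 0.5) {
      # sub-threshold self-link noise
      links[[length(links) + 1L]] <- tibble(
        scaffold_a = id, end_a = 5L, scaffold_b = id, end_b = 3L,
        n_pairs = sample(1:4, 1)
      )
    }
  }
  names(viruses) <- truth$virus
  link_table <- if (length(links) > 0) bind_rows(links) else empty_links()
  list(viruses = viruses, link_table = link_table, truth = truth)
}

empty_links <- function() {
  tibble(scaffold_a = character(0), end_a = integer(0),
         scaffold_b = character(0), end_b = integer(0), n_pairs = integer(0))
}

mutate_substitutions <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome collection with planted truth
#'
#' Builds `n_genomes` single-scaffold draft genomes over i.i.d. uniform
#' ACGT background: CRISPR-Cas carriers (drawn Bernoulli at the configured
#' rate, odds-adjusted for symbionts) receive a planted cas operon (ORF
#' hits) and a planted CRISPR array (sequence); single-copy marker ORFs
#' are tiled uniformly so completeness can be re-estimated after
#' degradation; free-living genomes carry full biosynthesis KO inventories
#' while symbionts lack them; each genome then loses one contiguous block
#' sized by its target completeness. A co-sampled viral set and read-pair
#' link table are generated from the planted spacer pool.
#'
#' @param config A [community_config()].
#' @return A `community_bundle`: list with `genomes` (list of genome
#'   records: `genome_id`, `domain`, `lineage`, `genus`, `lifestyle`,
#'   `scaffolds`, `orfs`, `kos`, `scg_found`, `scg_expected`), `viruses`,
#'   `link_table`, `truth` (per-genome tibble) and `viral_truth`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$rng_seed)
  n <- config$n_genomes
  G <- config$genome_length_bp
  defs <- default_module_defs()
  nuc_kos <- unlist(defs$nucleotide$stages)
  fat_kos <- unlist(defs$fatty_acid$stages)

  genus <- sprintf("genus_%02d", sample.int(config$n_genera, n, replace = TRUE))
  lineage <- paste0("phylum_", toupper(substr(genus, 7, 8)))
  domain <- ifelse(stats::runif(n) < config$frac_bacteria, "bacteria", "archaea")
  lifestyle <- ifelse(stats::runif(n) < config$symbiont_fraction,
                      "obligate_symbiont", "free_living")
  q <- config$true_cas_rate
  odds <- q / max(1 - q, .Machine$double.eps) * config$cas_effect
  p_sym <- if (q == 1) 1 else odds / (1 + odds)
  p_carrier <- ifelse(lifestyle == "obligate_symbiont", p_sym, q)
  carrier <- stats::runif(n) < p_carrier
  completeness <- stats::runif(n, config$completeness_range[1],
                               config$completeness_range[2])

  genomes <- vector("list", n)
  truth_rows <- vector("list", n)
  all_spacers <- character(0)
  for (i in seq_len(n)) {
    gid <- sprintf("genome_%04d", i)
    scf_id <- paste0(gid, "|scaffold_1")
    seq <- random_dna(G)
    arr <- NULL
    if (carrier[i]) {
      arr <- plant_crispr_array(seq, n_units = 4L, repeat_len = 30L,
                                spacer_len = 35L)
      seq <- arr$scaffold
      all_spacers <- c(all_spacers, arr$spacers)
    }
    Gi <- nchar(seq)
    orfs <- tile_orfs(gid, scf_id, Gi, domain[i], lifestyle[i], carrier[i],
                      nuc_kos, fat_kos,
                      avoid = if (is.null(arr)) NULL else c(arr$start, arr$end))
    feats <- tibble(
      fid = c(if (!is.null(arr)) 0L, seq_len(nrow(orfs))),
      kind = c(if (!is.null(arr)) "array", rep("orf", nrow(orfs))),
      start = c(if (!is.null(arr)) arr$start, orfs$start),
      end = c(if (!is.null(arr)) arr$end, orfs$end)
    )
    deg <- degrade_genome(seq, completeness[i], features = feats)
    kept <- deg$features
    # rebuild the ORF table on the degraded scaffold; truncated ORFs drop
    ko <- kept[kept$kind == "orf" & !kept$truncated, , drop = FALSE]
    orfs_deg <- orfs[ko$fid, , drop = FALSE]
    orfs_deg$start <- ko$start
    orfs_deg$end <- ko$end
    orfs_deg <- arrange(orfs_deg, .data$start)
    orfs_deg$orf_index <- seq_len(nrow(orfs_deg)) - 1L
    arr_kept <- kept[kept$kind == "array", , drop = FALSE]
    array_intact <- !is.null(arr) && nrow(arr_kept) == 1 &&
      !arr_kept$truncated &&
      (arr_kept$end - arr_kept$start) == (arr$end - arr$start)

    scg_found <- sum(grepl("single copy marker", orfs_deg$annotation))
    scg_total <- sum(grepl("single copy marker", orfs$annotation))
    kos <- unique(orfs_deg$hit_family[orfs_deg$hit_source %in% "ko"])
    kos <- kos[!is.na(kos)]

    genomes[[i]] <- list(
      genome_id = gid,
      domain = domain[i],
      lineage = lineage[i],
      genus = genus[i],
      lifestyle = lifestyle[i],
      scaffolds = setNames(deg$scaffold, scf_id),
      orfs = orfs_deg,
      kos = kos,
      scg_found = scg_found,
      scg_expected = scg_total
    )
    truth_rows[[i]] <- tibble(
      genome = gid,
      domain = domain[i],
      lineage = lineage[i],
      genus = genus[i],
      lifestyle = lifestyle[i],
      cas_carrier = carrier[i],
      completeness = completeness[i],
      gap_start = deg$gap_start,
      gap_len = deg$gap_len,
      array_start = if (is.null(arr)) NA_integer_ else arr$start,
      array_end = if (is.null(arr)) NA_integer_ else arr$end,
      array_intact = array_intact,
      pathway_present = lifestyle[i] == "free_living"
    )
  }

  viral <- generate_viral_set(config, spacer_pool = all_spacers)
  structure(list(
    genomes = genomes,
    viruses = viral$viruses,
    link_table = viral$link_table,
    truth = bind_rows(truth_rows),
    viral_truth = viral$truth,
    config = config
  ), class = "community_bundle")
}

# tile background, marker, pathway, defence and (for carriers) cas ORFs
# along the scaffold; returns an ORF tibble in genomic order
tile_orfs <- function(gid, scf_id, G, domain, lifestyle, carrier,
                      nuc_kos, fat_kos, avoid = NULL) {
  step <- 1000L
  starts <- seq(0L, max(0L, G - 950L), by = step)
  if (!is.null(avoid)) {
    starts <- starts[starts + 900L <= avoid[1] | starts >= avoid[2]]
  }
  n_orf <- length(starts)
  ann <- rep("hypothetical protein", n_orf)
  src <- rep(NA_character_, n_orf)
  fam <- rep(NA_character_, n_orf)
  ev <- rep(NA_real_, n_orf)
  cov <- rep(NA_real_, n_orf)
  scg_n <- scg_expected_for(domain)
  scg_slots <- unique(round(seq(1, n_orf, length.out = min(scg_n, n_orf))))
  ann[scg_slots] <- paste0("single copy marker gene ", seq_along(scg_slots))
  free <- setdiff(seq_len(n_orf), scg_slots)
  # pathway KOs for free-living genomes
  if (lifestyle == "free_living") {
    kos <- c(nuc_kos, fat_kos)
    slots <- utils::head(free, length(kos))
    src[slots] <- "ko"
    fam[slots] <- kos[seq_along(slots)]
    ev[slots] <- 1e-6
    ann[slots] <- paste0("biosynthesis enzyme ", kos[seq_along(slots)])
    free <- setdiff(free, slots)
  }
  # defence annotations with fixed occurrence rates
  if (length(free) >= 4) {
    picks <- sample(free, 4)
    if (stats::runif(1) < 0.5) {
      ann[picks[1]] <- "type II restriction endonuclease"
    }
    if (stats::runif(1) < 0.2) {
      ann[picks[2]] <- "abortive infection protein AbiEii"
    }
    if (stats::runif(1) < 0.1) {
      ann[picks[3]] <- "alkaline phosphatase PglZ"
    }
    if (stats::runif(1) < 0.3) {
      ann[picks[4]] <- "vapB antitoxin"
    }
    free <- setdiff(free, picks)
  }
  if (carrier && length(free) >= 3) {
    run_start <- sample(seq_along(free), 1)
    cas_slots <- free[run_start:min(run_start + 2, length(free))]
    cas_fams <- c("cas1", "cas2", sample(c("cas3", "cas9", "cas10"), 1))
    for (j in seq_along(cas_slots)) {
      src[cas_slots[j]] <- "cas"
      fam[cas_slots[j]] <- cas_fams[j]
      ev[cas_slots[j]] <- 1e-30
      ann[cas_slots[j]] <- paste0("CRISPR-associated protein ", cas_fams[j])
    }
  }
  tibble(
    genome = gid,
    scaffold = scf_id,
    orf_index = seq_len(n_orf) - 1L,
    start = as.integer(starts),
    end = as.integer(starts + 900L),
    strand = sample(c("+", "-"), n_orf, replace = TRUE),
    annotation = ann,
    hit_source = src,
    hit_family = fam,
    hit_evalue = ev,
    hit_coverage = cov
  )
}

#' Write a community bundle to disk
#'
#' Scaffolds as FASTA (ids `<genome>|<scaffold>`), ORF tables and link
#' table as TSV, metadata as TSV, planted truth as JSON, configuration as
#' YAML.
#'
#' @param bundle A `community_bundle` from [generate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- unlist(lapply(bundle$genomes, function(g) g$scaffolds))
  write_fasta(seqs, file.path(dir, "genomes.fasta"))
  if (length(bundle$viruses) > 0) {
    write_fasta(bundle$viruses, file.path(dir, "viruses.fasta"))
  }
  orfs <- bind_rows(lapply(bundle$genomes, function(g) g$orfs))
  readr::write_tsv(orfs, file.path(dir, "orfs.tsv"))
  readr::write_tsv(bundle$link_table, file.path(dir, "links.tsv"))
  meta <- tibble(
    genome = map_chr(bundle$genomes, "genome_id"),
    domain = map_chr(bundle$genomes, "domain"),
    lineage = map_chr(bundle$genomes, "lineage"),
    genus = map_chr(bundle$genomes, "genus"),
    lifestyle = map_chr(bundle$genomes, "lifestyle"),
    scg_found = map_int(bundle$genomes, "scg_found"),
    scg_expected = map_int(bundle$genomes, "scg_expected")
  )
  readr::write_tsv(meta, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(
    list(genomes = bundle$truth, viruses = bundle$viral_truth),
    file.path(dir, "truth.json"),
    dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA
  )
  yaml::write_yaml(unclass(bundle$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
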