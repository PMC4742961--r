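#' Load a community from disk
#'
#' Reads the files written by [write_community()] back into genome records,
#' viruses and a link table.
#'
#' @param dir Directory written by [write_community()].
#' @return A list with `genomes`, `viruses`, `link_table`, `metadata`.
#' @export
load_community <- function(dir) {
  seqs <- read_fasta(file.path(dir, "genomes.fasta"))
  vir_path <- file.path(dir, "viruses.fasta")
  viruses <- if (file.exists(vir_path)) read_fasta(vir_path) else
    setNames(character(0), character(0))
  orfs <- read_orf_table(file.path(dir, "orfs.tsv"), dialect = "tsv")
  links <- read_link_table(file.path(dir, "links.tsv"))
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  genomes <- lapply(seq_len(nrow(meta)), function(i) {
    gid <- meta$genome[i]
    scf <- seqs[startsWith(names(seqs), paste0(gid, "|"))]
    g_orfs <- filter(orfs, .data$genome == gid)
    list(
      genome_id = gid,
      domain = meta$domain[i],
      lineage = meta$lineage[i],
      genus = meta$genus[i],
      lifestyle = if ("lifestyle" %in% names(meta)) meta$lifestyle[i] else NA,
      scaffolds = scf,
      orfs = g_orfs,
      kos = unique(stats::na.omit(
        g_orfs$hit_family[g_orfs$hit_source %in% "ko"]
      )),
      scg_found = if ("scg_found" %in% names(meta)) meta$scg_found[i] else NA,
      scg_expected = if ("scg_expected" %in% names(meta)) meta$scg_expected[i] else NA
    )
  })
  list(genomes = genomes, viruses = viruses, link_table = links, metadata = meta)
}

#' Run the defence-system census on a community
#'
#' Executes the full pipeline in memory: array detection, cas operon
#' calling, circular-virus identification and dereplication, spacer
#' targeting, defence-system inventory, completeness-corrected incidence
#' per lineage, the missing-segment deficit probability and the
#' genus-weighted lifestyle association.
#'
#' @param community A `community_bundle` from [generate_community()] or the
#'   list returned by [load_community()].
#' @param array_parameters From [array_params()].
#' @param cas_parameters From [cas_params()].
#' @param min_spacer_identity Spacer-protospacer identity threshold.
#' @param min_self_pairs,min_viral_len Circularity thresholds.
#' @param derep_identity,derep_coverage Population thresholds.
#' @param reference_rate Expected carriage rate for the deficit tail.
#' @param cas1_len Segment length for the miss-probability model (bp).
#' @param module_defs Pathway definitions; defaults to the bundled
#'   synthetic modules.
#' @param verbose Log per-stage counts with [message()].
#' @return A `census_result`: list of tibbles `per_genome`, `census`
#'   (per lineage), `targeting`, `defence`, plus `association`
#'   (a `lifestyle_assoc` or `NULL`) and `deficit` (list).
#' @export
census_community <- function(community,
                             array_parameters = array_params(),
                             cas_parameters = cas_params(),
                             min_spacer_identity = 0.90,
                             min_self_pairs = 5L,
                             min_viral_len = 5000L,
                             derep_identity = 0.99,
                             derep_coverage = 0.99,
                             reference_rate = 0.40,
                             cas1_len = 775L,
                             module_defs = default_module_defs(),
                             verbose = FALSE) {
  genomes <- community$genomes
  say <- function(...) if (verbose) message(sprintf(...))
  say("census: %d genomes, %d viral scaffolds", length(genomes),
      length(community$viruses))

  per_genome <- vector("list", length(genomes))
  all_arrays <- vector("list", length(genomes))
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    arrays <- detect_arrays_genome(g$scaffolds, array_parameters,
                                   genome_id = g$genome_id)
    hits <- filter_cas_hits(g$orfs, cas_parameters)
    operons <- call_cas_operons(hits, cas_parameters, genome_id = g$genome_id)
    scg_exp <- g$scg_expected
    if (is.null(scg_exp) || is.na(scg_exp)) scg_exp <- scg_expected_for(g$domain)
    completeness <- estimate_completeness(min(g$scg_found, scg_exp), scg_exp)
    recovered <- sum(nchar(g$scaffolds))
    G_est <- estimate_genome_length(recovered, completeness)
    types <- if (nrow(operons) > 0) operons$system_type else character(0)
    per_genome[[i]] <- tibble(
      genome = g$genome_id,
      domain = g$domain,
      lineage = g$lineage,
      genus = g$genus,
      lifestyle = g$lifestyle %||% NA_character_,
      completeness = completeness,
      recovered_bp = recovered,
      estimated_length = G_est,
      n_arrays = nrow(arrays),
      n_operons = nrow(operons),
      cas_present = crispr_cas_present(operons, arrays),
      type_I = sum(types == "I"),
      type_II = sum(types == "II"),
      type_III = sum(types == "III"),
      miss_prob = miss_probability(G_est, min(recovered, G_est), cas1_len)
    )
    all_arrays[[i]] <- arrays
  }
  per_genome <- bind_rows(per_genome)
  arrays <- bind_rows(all_arrays)
  say("census: %d arrays, %d genomes with cas operons",
      nrow(arrays), sum(per_genome$n_operons > 0))

  census <- per_genome |>
    group_by(.data$lineage) |>
    summarise(
      n = n(),
      n_present = sum(.data$cas_present),
      raw_rate = mean(.data$cas_present),
      corrected_rate = min(1, sum(.data$cas_present) / sum(.data$completeness)),
      type_I = sum(.data$type_I), type_II = sum(.data$type_II),
      type_III = sum(.data$type_III),
      .groups = "drop"
    )

  # viral stage
  targeting <- NULL
  viral <- NULL
  spacers <- unique_spacers(arrays)
  if (length(community$viruses) > 0) {
    viral <- viral_scaffold_table(
      community$viruses, community$link_table,
      min_self_pairs = min_self_pairs, min_len = min_viral_len,
      min_identity = derep_identity, min_coverage = derep_coverage
    )
    circ_pops <- unique(viral$population[viral$is_circular])
    say("census: %d circular of %d viral scaffolds (%d populations)",
        sum(viral$is_circular), nrow(viral), length(circ_pops))
    if (length(spacers) > 0 && length(circ_pops) > 0) {
      matches <- match_spacers(
        setNames(spacers, spacers), community$viruses,
        min_identity = min_spacer_identity
      )
      # lift matches from member scaffolds to their populations
      if (nrow(matches) > 0) {
        matches$target_id <- viral$population[
          match(matches$target_id, viral$scaffold)
        ]
      }
      targeting <- summarize_targeting(
        matches, setNames(spacers, spacers), circ_pops
      )
    }
  }

  defence <- bind_rows(lapply(genomes, function(g) {
    defence_inventory(g$orfs, genome_kos = g$kos, module_defs = module_defs,
                      genome_id = g$genome_id)
  }))

  # deficit probability for bacterial genomes
  bact <- per_genome[per_genome$domain == "bacteria", ]
  deficit <- NULL
  if (nrow(bact) > 0) {
    k_obs <- sum(bact$cas_present)
    lp <- deficit_tail(bact$miss_prob, q = reference_rate,
                       k_observed = k_obs, log_p = TRUE)
    deficit <- list(
      n = nrow(bact), k_observed = k_obs,
      reference_rate = reference_rate,
      log10_tail = lp / log(10), tail = exp(lp)
    )
  }

  association <- NULL
  ls <- per_genome$lifestyle
  if (!all(is.na(ls)) && length(unique(stats::na.omit(ls))) == 2) {
    ok <- !is.na(ls)
    sym <- ls[ok] == "obligate_symbiont"
    if (min(table(sym)) >= 2) {
      association <- lifestyle_association(
        per_genome$cas_present[ok], sym,
        domain_label = per_genome$domain[ok],
        weights = genus_weights(per_genome$genus[ok])
      )
    }
  }

  structure(list(
    per_genome = per_genome,
    arrays = arrays,
    spacers = spacers,
    census = census,
    viral = viral,
    targeting = targeting,
    defence = defence,
    deficit = deficit,
    association = association
  ), class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat("Defence-system census:", nrow(x$per_genome), "genomes,",
      nrow(x$census), "lineages\n")
  cat(sprintf("  CRISPR-Cas present: %d (raw %.1f%%, corrected %.1f%%)\n",
              sum(x$per_genome$cas_present),
              100 * mean(x$per_genome$cas_present),
              100 * min(1, sum(x$per_genome$cas_present) /
                          sum(x$per_genome$completeness))))
  if (!is.null(x$deficit)) {
    cat(sprintf("  deficit tail (q = %.2f): log10 p = %.1f\n",
                x$deficit$reference_rate, x$deficit$log10_tail))
  }
  if (!is.null(x$targeting)) {
    cat(sprintf("  spacers with target: %d/%d; circular populations targeted: %d/%d\n",
                x$targeting$n_spacers_matched, x$targeting$n_spacers,
                x$targeting$n_populations_targeted, x$targeting$n_populations))
  }
  invisible(x)
}

#' @method glance census_result
#' @export
glance.census_result <- function(x, ...) {
  tibble(
    n_genomes = nrow(x$per_genome),
    n_lineages = nrow(x$census),
    n_present = sum(x$per_genome$cas_present),
    raw_rate = mean(x$per_genome$cas_present),
    corrected_rate = min(1, sum(x$per_genome$cas_present) /
                           sum(x$per_genome$completeness)),
    log10_deficit_tail = if (is.null(x$deficit)) NA_real_ else x$deficit$log10_tail
  )
}

#' Plot per-lineage incidence
#'
#' Bar chart of raw and completeness-corrected CRISPR-Cas incidence per
#' lineage.
#'
#' @param object A `census_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot census_result
#' @export
autoplot.census_result <- function(object, ...) {
  d <- object$census |>
    tidyr::pivot_longer(c("raw_rate", "corrected_rate"),
                        names_to = "estimate", values_to = "rate")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lineage, y = .data$rate,
                                  fill = .data$estimate)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "CRISPR-Cas incidence", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a repeat similarity matrix
#'
#' @param m Matrix from [repeat_similarity_matrix()].
#' @return A ggplot heat map.
#' @export
plot_repeat_similarity <- function(m) {
  d <- as_tibble(as.data.frame(as.table(m)))
  names(d) <- c("repeat_a", "repeat_b", "similarity")
  ggplot2::ggplot(d, ggplot2::aes(.data$repeat_a, .data$repeat_b,
                                  fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Run the census from a configuration
#'
#' Reads a community from disk (or takes a bundle), runs
#' [census_community()] and writes the per-lineage census, targeting
#' summary, defence table and association report under `outdir`. All
#' thresholds are validated before any computation; a stage failure names
#' the stage and preserves partial outputs under a `failed/` prefix.
#'
#' @param config Named list (or path to a YAML file) with elements
#'   `input_dir`, `outdir`, optional `seed` and a `thresholds` block
#'   (`evalue`, `min_self_pairs`, `min_spacer_identity`, `derep_identity`,
#'   `pathway_present`, `pathway_absent`).
#' @param verbose Log stage counts.
#' @return The `census_result`, invisibly.
#' @export
run_census <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  th <- config$thresholds %||% list()
  thresholds <- list(
    evalue = th$evalue %||% 1e-10,
    min_self_pairs = th$min_self_pairs %||% 5L,
    min_spacer_identity = th$min_spacer_identity %||% 0.90,
    derep_identity = th$derep_identity %||% 0.99,
    derep_coverage = th$derep_coverage %||% 0.99,
    reference_rate = th$reference_rate %||% 0.40
  )
  for (nm in c("min_spacer_identity", "derep_identity", "derep_coverage",
               "reference_rate")) {
    v <- thresholds[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(paste0("invalid threshold: ", nm, " must be in [0, 1]"),
            class = "crisprcensus_config_error")
    }
  }
  if (thresholds$evalue <= 0) {
    abort("invalid threshold: evalue must be positive",
          class = "crisprcensus_config_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- "load"
  res <- tryCatch({
    community <- if (!is.null(config$input_dir)) {
      load_community(config$input_dir)
    } else {
      config$community
    }
    stage <- "census"
    census_community(
      community,
      cas_parameters = cas_params(evalue_threshold = thresholds$evalue),
      min_spacer_identity = thresholds$min_spacer_identity,
      min_self_pairs = thresholds$min_self_pairs,
      derep_identity = thresholds$derep_identity,
      derep_coverage = thresholds$derep_coverage,
      reference_rate = thresholds$reference_rate,
      verbose = verbose
    )
  }, error = function(e) {
    dir.create(file.path(outdir, "failed"), showWarnings = FALSE)
    writeLines(
      paste0("stage: ", stage, "\n", conditionMessage(e)),
      file.path(outdir, "failed", "error.txt")
    )
    abort(paste0("census failed at stage '", stage, "': ", conditionMessage(e)),
          class = "crisprcensus_stage_error")
  })

  stage <- "write"
  readr::write_tsv(res$census, file.path(outdir, "census.tsv"))
  readr::write_tsv(res$defence, file.path(outdir, "defence.tsv"))
  if (!is.null(res$targeting)) {
    readr::write_tsv(res$targeting, file.path(outdir, "targeting.tsv"))
  }
  report <- list(
    thresholds = thresholds,
    deficit = res$deficit,
    association = if (is.null(res$association)) NULL else list(
      coefficient = if (is.finite(res$association$coefficient)) {
        res$association$coefficient
      } else NA,
      p_value = res$association$p_value,
      separation = res$association$separation
    )
  )
  jsonlite::write_json(report, file.path(outdir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
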