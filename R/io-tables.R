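#' Read an ORF table
#'
#' Accepts either the package's tab-separated ORF format or GFF3. All
#' coordinates are normalised to 0-based half-open internally (GFF3's
#' 1-based closed intervals are converted on read) and records are sorted
#' by `(scaffold, start)`.
#'
#' The TSV dialect requires columns `scaffold`, `orf_index`, `start`, `end`,
#' `strand`, `annotation`; optional columns `genome`, `hit_source`,
#' `hit_family`, `hit_evalue`, `hit_coverage` carry homology-search results
#' (sources: `cas`, `ko`, `rebase`, `tadb`, `pglz`).
#'
#' @param path Input path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @return A tibble of ORF records, one row per (ORF, hit) pair; ORFs
#'   without hits have `NA` hit columns.
#' @export
read_orf_table <- function(path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    first <- readLines(path, n = 1)
    if (!grepl("^##gff-version", first)) {
      abort("GFF3 file lacks ##gff-version pragma", class = "crisprcensus_parse_error")
    }
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 requires the rtracklayer package")
    }
    g <- as.data.frame(rtracklayer::readGFF(path))
    ann <- if ("product" %in% names(g)) as.character(g$product) else
      if ("Name" %in% names(g)) as.character(g$Name) else rep("", nrow(g))
    orfs <- tibble(
      genome = NA_character_,
      scaffold = as.character(g$seqid),
      start = as.integer(g$start) - 1L,  # 1-based closed -> 0-based half-open
      end = as.integer(g$end),
      strand = as.character(g$strand),
      annotation = ann,
      hit_source = NA_character_,
      hit_family = NA_character_,
      hit_evalue = NA_real_,
      hit_coverage = NA_real_
    )
  } else {
    raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
    required <- c("scaffold", "orf_index", "start", "end", "strand", "annotation")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      abort(
        paste0("ORF table missing column(s): ", paste(missing_cols, collapse = ", ")),
        class = "crisprcensus_parse_error"
      )
    }
    orfs <- tibble(
      genome = if ("genome" %in% names(raw)) as.character(raw$genome) else NA_character_,
      scaffold = as.character(raw$scaffold),
      orf_index = as.integer(raw$orf_index),
      start = as.integer(raw$start),
      end = as.integer(raw$end),
      strand = as.character(raw$strand),
      annotation = as.character(raw$annotation),
      hit_source = if ("hit_source" %in% names(raw)) as.character(raw$hit_source) else NA_character_,
      hit_family = if ("hit_family" %in% names(raw)) as.character(raw$hit_family) else NA_character_,
      hit_evalue = if ("hit_evalue" %in% names(raw)) as.numeric(raw$hit_evalue) else NA_real_,
      hit_coverage = if ("hit_coverage" %in% names(raw)) as.numeric(raw$hit_coverage) else NA_real_
    )
  }
  bad <- which(orfs$start >= orfs$end)
  if (length(bad) > 0) {
    abort(
      paste0("ORF table row ", bad[1], ": start >= end"),
      class = "crisprcensus_parse_error"
    )
  }
  bad <- which(!orfs$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(
      paste0("ORF table row ", bad[1], ": unknown strand '", orfs$strand[bad[1]], "'"),
      class = "crisprcensus_parse_error"
    )
  }
  orfs <- arrange(orfs, .data$scaffold, .data$start)
  if (!"orf_index" %in% names(orfs) || all(is.na(orfs$orf_index))) {
    orfs <- orfs |>
      group_by(.data$scaffold) |>
      mutate(orf_index = seq_len(n()) - 1L) |>
      ungroup()
  }
  select(
    orfs, "genome", "scaffold", "orf_index", "start", "end", "strand",
    "annotation", "hit_source", "hit_family", "hit_evalue", "hit_coverage"
  )
}

#' Write an ORF table to TSV
#'
#' @param orfs ORF tibble as produced by [read_orf_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(orfs, path) {
  readr::write_tsv(orfs, path)
  invisible(path)
}

#' Read a paired-read end-link table
#'
#' Tab-separated with columns `scaffold_a`, `end_a`, `scaffold_b`, `end_b`,
#' `n_pairs`; ends are `5` or `3`. Each row records that `n_pairs` read
#' pairs connect the given scaffold ends.
#'
#' @param path Input path.
#' @return Tibble of link rows.
#' @export
read_link_table <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  required <- c("scaffold_a", "end_a", "scaffold_b", "end_b", "n_pairs")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("link table missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "crisprcensus_parse_error"
    )
  }
  links <- tibble(
    scaffold_a = as.character(raw$scaffold_a),
    end_a = as.integer(raw$end_a),
    scaffold_b = as.character(raw$scaffold_b),
    end_b = as.integer(raw$end_b),
    n_pairs = as.integer(raw$n_pairs)
  )
  bad <- which(!(links$end_a %in% c(3L, 5L)) | !(links$end_b %in% c(3L, 5L)))
  if (length(bad) > 0) {
    abort(
      paste0("link table row ", bad[1], ": ends must be 5 or 3"),
      class = "crisprcensus_parse_error"
    )
  }
  links
}

#' Read genome metadata
#'
#' Tab-separated with columns `genome`, `domain` (`bacteria`/`archaea`),
#' `lineage`, `genus`; optional `lifestyle` (`free_living`/
#' `obligate_symbiont`) and any further columns are preserved.
#'
#' @param path Input path.
#' @return Tibble of genome metadata.
#' @export
read_metadata <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  required <- c("genome", "domain", "lineage", "genus")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("metadata missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "crisprcensus_parse_error"
    )
  }
  bad <- which(!raw$domain %in% c("bacteria", "archaea"))
  if (length(bad) > 0) {
    abort(
      paste0("metadata row ", bad[1], ": domain must be 'bacteria' or 'archaea'"),
      class = "crisprcensus_parse_error"
    )
  }
  as_tibble(raw)
}

#' Read pathway module definitions
#'
#' Modules are KEGG-style staged definitions: an ordered list of stages,
#' each satisfied by any one of a set of orthologue (KO) identifiers.
#' JSON layout: `{"<pathway>": {"modules": [...], "stages": [["K..",..],
#' ...]}}`. TSV layout: columns `pathway`, `stage`, `ko` (one KO per row).
#'
#' @param path Input path (`.json` or `.tsv`).
#' @return Named list; each element a list with `modules` (character) and
#'   `stages` (list of character vectors of alternative KOs).
#' @export
read_module_defs <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    defs <- jsonlite::read_json(path, simplifyVector = FALSE)
    out <- lapply(defs, function(p) {
      list(
        modules = as.character(unlist(p$modules %||% character(0))),
        stages = lapply(p$stages, function(s) as.character(unlist(s)))
      )
    })
  } else {
    raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
    required <- c("pathway", "stage", "ko")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      abort(
        paste0("module definition missing column(s): ", paste(missing_cols, collapse = ", ")),
        class = "crisprcensus_parse_error"
      )
    }
    out <- lapply(split(raw, raw$pathway), function(p) {
      stages <- lapply(split(p$ko, p$stage), as.character)
      list(modules = character(0), stages = unname(stages))
    })
  }
  for (nm in names(out)) {
    if (length(out[[nm]]$stages) == 0) {
      abort(
        paste0("pathway '", nm, "' has no stages"),
        class = "crisprcensus_parse_error"
      )
    }
  }
  out
}
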