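#' Cas detection parameters
#'
#' @param evalue_threshold Hits must score strictly below this E-value.
#' @param adjacency_max_orfs Two Cas hits this many ORF ordinals apart (or
#'   fewer) on the same scaffold are merged into one operon.
#' @param cas1_alone_sufficient A lone Cas1 hit is itself an operon.
#' @param type_signatures Named vector mapping signature families to system
#'   types.
#' @return A list of parameters.
#' @export
cas_params <- function(evalue_threshold = 1e-10,
                       adjacency_max_orfs = 5L,
                       cas1_alone_sufficient = TRUE,
                       type_signatures = c(cas3 = "I", cas9 = "II", cas10 = "III")) {
  stopifnot(evalue_threshold > 0, adjacency_max_orfs >= 1)
  list(
    evalue_threshold = evalue_threshold,
    adjacency_max_orfs = as.integer(adjacency_max_orfs),
    cas1_alone_sufficient = isTRUE(cas1_alone_sufficient),
    type_signatures = type_signatures
  )
}

#' Filter Cas homology hits
#'
#' Keeps hits with E-value strictly below the threshold and reduces to one
#' best family per ORF (lowest E-value, ties broken by family name).
#'
#' @param orfs ORF tibble (see [read_orf_table()]); Cas hits are rows with
#'   `hit_source == "cas"`.
#' @param params Parameters from [cas_params()].
#' @return Tibble `scaffold`, `orf_index`, `family`, `evalue`, sorted by
#'   `(scaffold, orf_index)`.
#' @export
filter_cas_hits <- function(orfs, params = cas_params()) {
  hits <- orfs |>
    filter(!is.na(.data$hit_source), .data$hit_source == "cas",
           !is.na(.data$hit_evalue),
           .data$hit_evalue < params$evalue_threshold)
  if (nrow(hits) == 0) {
    return(tibble(scaffold = character(0), orf_index = integer(0),
                  family = character(0), evalue = numeric(0)))
  }
  hits |>
    arrange(.data$hit_evalue, .data$hit_family) |>
    group_by(.data$scaffold, .data$orf_index) |>
    dplyr::slice(1) |>
    ungroup() |>
    transmute_hits() |>
    arrange(.data$scaffold, .data$orf_index)
}

transmute_hits <- function(x) {
  tibble(
    scaffold = x$scaffold,
    orf_index = as.integer(x$orf_index),
    family = tolower(x$hit_family),
    evalue = x$hit_evalue
  )
}

#' Call cas operons from filtered hits
#'
#' An operon is any ORF hitting Cas1, or any two Cas-hit ORFs at most
#' `adjacency_max_orfs` ORF ordinals apart on the same scaffold. Qualifying
#' ORFs are merged by transitive closure of the adjacency relation. An
#' operon is flagged `partial` when cas1 or cas2 is absent from the merged
#' set.
#'
#' @param hits Output of [filter_cas_hits()].
#' @param params Parameters from [cas_params()].
#' @param genome_id Identifier copied into the result.
#' @return Tibble `genome`, `scaffold`, `first_orf`, `last_orf`,
#'   `families` (list column of family character vectors), `system_type`,
#'   `partial`, `has_cas1`.
#' @export
call_cas_operons <- function(hits, params = cas_params(), genome_id = NA_character_) {
  empty <- tibble(
    genome = character(0), scaffold = character(0),
    first_orf = integer(0), last_orf = integer(0), families = list(),
    system_type = character(0), partial = logical(0), has_cas1 = logical(0)
  )
  if (nrow(hits) == 0) return(empty)
  hits <- arrange(hits, .data$scaffold, .data$orf_index)
  out <- list()
  for (scf in unique(hits$scaffold)) {
    h <- hits[hits$scaffold == scf, ]
    # transitive closure of <= adjacency on sorted ordinals: split at gaps
    gaps <- which(diff(h$orf_index) > params$adjacency_max_orfs)
    grp <- cumsum(c(1L, seq_len(nrow(h) - 1) %in% gaps))
    for (g in unique(grp)) {
      hg <- h[grp == g, ]
      fams <- hg$family
      has_cas1 <- any(fams == "cas1")
      qualifies <- (params$cas1_alone_sufficient && has_cas1) || nrow(hg) >= 2
      if (!qualifies) next
      out[[length(out) + 1L]] <- tibble(
        genome = genome_id, scaffold = scf,
        first_orf = min(hg$orf_index), last_orf = max(hg$orf_index),
        families = list(fams),
        system_type = classify_system_type(fams, params),
        partial = !(has_cas1 && any(fams == "cas2")),
        has_cas1 = has_cas1
      )
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' Classify a cas operon's system type
#'
#' Type I is signalled by cas3, type II by cas9, type III by cas10; more
#' than one signature gives `mixed`, none gives `untyped`.
#'
#' @param families Character vector of Cas family names.
#' @param params Parameters from [cas_params()].
#' @return One of `"I"`, `"II"`, `"III"`, `"mixed"`, `"untyped"`.
#' @export
classify_system_type <- function(families, params = cas_params()) {
  sig <- params$type_signatures
  present <- names(sig)[names(sig) %in% tolower(families)]
  if (length(present) == 0) return("untyped")
  if (length(present) > 1) return("mixed")
  unname(sig[present])
}

#' Rescue scan over six-frame translations
#'
#' For genomes with no called operon, every scaffold is translated in all
#' six frames and scanned with a pluggable protein scorer; hits that do not
#' coincide with an existing Cas-hit ORF are returned so they can feed a
#' second [call_cas_operons()] pass.
#'
#' @param scaffolds Named character vector of scaffolds.
#' @param hit_scorer Function `(protein_string) -> tibble(family, evalue,
#'   aa_start)` (possibly zero rows); errors are propagated with the
#'   scaffold id.
#' @param existing_hits Output of [filter_cas_hits()] for this genome, used
#'   to suppress rediscoveries.
#' @param orfs ORF tibble used to locate existing hits on the sequence.
#' @param params Parameters from [cas_params()].
#' @return Tibble `scaffold`, `frame`, `family`, `evalue`, `start`, `end`
#'   (0-based half-open nucleotide coordinates of the scoring window).
#' @export
six_frame_rescan <- function(scaffolds, hit_scorer, existing_hits = NULL,
                             orfs = NULL, params = cas_params()) {
  res <- list()
  for (id in names(scaffolds)) {
    seq <- scaffolds[[id]]
    if (nchar(seq) < 3) next
    frames <- six_frame_translate(seq)
    for (fr in names(frames)) {
      prot <- frames[[fr]]
      if (!nzchar(prot)) next
      cand <- tryCatch(
        hit_scorer(prot),
        error = function(e) abort(
          paste0("hit scorer failed on scaffold '", id, "': ", conditionMessage(e)),
          class = "crisprcensus_scorer_error"
        )
      )
      if (is.null(cand) || nrow(cand) == 0) next
      if (!all(c("family", "evalue") %in% names(cand))) {
        abort("hit_scorer must return columns family and evalue")
      }
      cand <- filter(cand, .data$evalue < params$evalue_threshold)
      if (nrow(cand) == 0) next
      # report the frame's nucleotide window in forward coordinates
      n <- nchar(seq)
      off <- as.integer(substr(fr, 2, 2)) - 1L
      span <- 3L * nchar(prot)
      if (startsWith(fr, "F")) {
        nt_start <- off
        nt_end <- off + span
      } else {
        nt_end <- n - off
        nt_start <- nt_end - span
      }
      res[[length(res) + 1L]] <- tibble(
        scaffold = id, frame = fr,
        family = tolower(cand$family), evalue = cand$evalue,
        start = pmax(0L, as.integer(nt_start)),
        end = pmin(n, as.integer(nt_end))
      )
    }
  }
  found <- if (length(res) == 0) {
    tibble(scaffold = character(0), frame = character(0), family = character(0),
           evalue = numeric(0), start = integer(0), end = integer(0))
  } else {
    bind_rows(res)
  }
  if (!is.null(existing_hits) && !is.null(orfs) && nrow(found) > 0 &&
      nrow(existing_hits) > 0) {
    loc <- left_join(
      existing_hits,
      select(orfs, "scaffold", "orf_index", "start", "end"),
      by = c("scaffold", "orf_index")
    )
    overlap <- vapply(seq_len(nrow(found)), function(i) {
      any(loc$scaffold == found$scaffold[i] &
            loc$start < found$end[i] & loc$end > found$start[i], na.rm = TRUE)
    }, logical(1))
    found <- found[!overlap, ]
  }
  found
}

#' Genome-level CRISPR-Cas presence
#'
#' A genome is scored as carrying CRISPR-Cas if it has at least one called
#' cas operon or at least one detected CRISPR array.
#'
#' @param operons Operon tibble from [call_cas_operons()].
#' @param arrays Array tibble from [detect_arrays()].
#' @return Logical scalar.
#' @export
crispr_cas_present <- function(operons, arrays) {
  nrow(operons) > 0 || nrow(arrays) > 0
}
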