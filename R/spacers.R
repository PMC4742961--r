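#' Match spacers against target sequences
#'
#' Gapless (Hamming) scan of every spacer against both strands of every
#' target at every offset. Identity is matching positions divided by the
#' full spacer length; `N` matches nothing; matches at or above
#' `min_identity` are reported (inclusive threshold). Partial overlaps at
#' target ends are not considered.
#'
#' @param spacers Named character vector of spacer sequences (20-80 nt;
#'   out-of-bounds spacers are skipped with a warning).
#' @param targets Named character vector of target sequences.
#' @param min_identity Minimum identity fraction (default 0.90).
#' @return Tibble `spacer_id`, `target_id`, `target_start` (0-based),
#'   `strand`, `mismatches`, `identity`.
#' @export
match_spacers <- function(spacers, targets, min_identity = 0.90) {
  stopifnot(min_identity > 0, min_identity <= 1)
  ids <- names(spacers) %||% paste0("spacer_", seq_along(spacers))
  lens <- unname(nchar(spacers))
  bad <- lens < 20 | lens > 80
  if (any(bad)) {
    warn(paste0(sum(bad), " spacer(s) outside 20-80 nt skipped"))
    spacers <- spacers[!bad]; ids <- ids[!bad]; lens <- lens[!bad]
  }
  out <- list()
  tgt_objs <- lapply(targets, Biostrings::DNAString)
  for (k in seq_along(spacers)) {
    sp <- spacers[[k]]
    L <- lens[k]
    max_mm <- floor(L * (1 - min_identity) + 1e-9)
    pat_f <- Biostrings::DNAString(sp)
    pat_r <- Biostrings::reverseComplement(pat_f)
    for (t in seq_along(tgt_objs)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") pat_f else pat_r
        m <- Biostrings::matchPattern(pat, tgt_objs[[t]],
                                      max.mismatch = max_mm, fixed = TRUE)
        if (length(m) == 0) next
        mm <- vapply(seq_along(m), function(i) {
          Biostrings::neditAt(pat, tgt_objs[[t]], at = Biostrings::start(m)[i],
                              fixed = TRUE)
        }, integer(1))
        keep <- (L - mm) / L >= min_identity - 1e-12
        if (!any(keep)) next
        out[[length(out) + 1L]] <- tibble(
          spacer_id = ids[k],
          target_id = names(targets)[t],
          target_start = Biostrings::start(m)[keep] - 1L,
          strand = strand,
          mismatches = as.integer(mm[keep]),
          identity = (L - mm[keep]) / L
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(
      spacer_id = character(0), target_id = character(0),
      target_start = integer(0), strand = character(0),
      mismatches = integer(0), identity = numeric(0)
    ))
  }
  arrange(bind_rows(out), .data$spacer_id, .data$target_id, .data$target_start)
}

#' Summarise spacer targeting
#'
#' @param matches Match tibble from [match_spacers()].
#' @param spacers Character vector of all unique spacers queried (the
#'   denominator for the spacer fraction); a named vector's names must
#'   match `matches$spacer_id`.
#' @param circular_populations Character vector of non-redundant circular
#'   population identifiers (the denominator for the population fraction).
#' @return Tibble with one row: `n_spacers`, `n_spacers_matched`,
#'   `frac_spacers_with_target`, `n_populations`, `n_populations_targeted`,
#'   `frac_circular_targeted`.
#' @export
summarize_targeting <- function(matches, spacers, circular_populations) {
  n_sp <- length(spacers)
  n_pop <- length(circular_populations)
  if (n_sp == 0 || n_pop == 0) {
    abort("zero denominator in targeting summary", class = "crisprcensus_input_error")
  }
  sp_ids <- names(spacers) %||% spacers
  n_matched <- length(intersect(unique(matches$spacer_id), sp_ids))
  targeted <- length(intersect(unique(matches$target_id), circular_populations))
  tibble(
    n_spacers = n_sp,
    n_spacers_matched = n_matched,
    frac_spacers_with_target = n_matched / n_sp,
    n_populations = n_pop,
    n_populations_targeted = targeted,
    frac_circular_targeted = targeted / n_pop
  )
}

#' Find self-targeting spacers
#'
#' Matches a genome's own spacers against its scaffolds, excluding any
#' match that overlaps a detected array interval extended by
#' `exclusion_flank` on each side (the spacer's own occurrence in the
#' array).
#'
#' @param arrays Array tibble from [detect_arrays()] for this genome.
#' @param host_scaffolds Named character vector of the host's scaffolds.
#' @param min_identity Minimum identity fraction.
#' @param exclusion_flank Exclusion zone around each array (bp).
#' @return Match tibble as in [match_spacers()].
#' @export
find_self_targets <- function(arrays, host_scaffolds, min_identity = 0.90,
                              exclusion_flank = 500L) {
  if (nrow(arrays) == 0) {
    return(match_spacers(character(0), host_scaffolds, min_identity))
  }
  sp <- purrr::pmap(arrays, function(scaffold, start, spacers, ...) {
    setNames(spacers$seq, paste0(scaffold, ":", start, "|", seq_len(nrow(spacers))))
  })
  sp <- unlist(sp)
  hits <- match_spacers(sp, host_scaffolds, min_identity)
  if (nrow(hits) == 0) return(hits)
  sp_len <- nchar(sp)[match(hits$spacer_id, names(sp))]
  excluded <- vapply(seq_len(nrow(hits)), function(i) {
    any(arrays$scaffold == hits$target_id[i] &
          arrays$start - exclusion_flank < hits$target_start[i] + sp_len[i] &
          arrays$end + exclusion_flank > hits$target_start[i])
  }, logical(1))
  hits[!excluded, ]
}
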