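#' Default viral annotation lexicon
#'
#' Seventeen virus-specific annotation terms plus cellular exclusion terms.
#' `"holing"` is carried alongside `"holin"`: the published term list
#' spells it with a g, most annotations do not, so both are matched.
#'
#' @return List with `viral_terms` and `cellular_terms`, lowercase.
#' @export
viral_lexicon <- function() {
  list(
    viral_terms = c(
      "capsid", "phage", "terminase", "baseplate", "base plate", "prohead",
      "virion", "holing", "holin", "virus", "viral", "tape measure",
      "tapemeasure", "neck", "tail", "p22", "head", "t4"
    ),
    cellular_terms = c(
      "trna synthetase", "ribosomal protein", "preprotein translocase",
      "dna gyrase subunit a"
    )
  )
}

#' Identify circularised scaffolds from paired-read end links
#'
#' A scaffold is called circular when its 5' and 3' ends are connected by
#' at least `min_self_pairs` read pairs, no link connects it to any other
#' scaffold (with at least `other_link_min` pairs), and it is at least
#' `min_len` bp long.
#'
#' @param links Link tibble from [read_link_table()].
#' @param scaffold_lengths Named integer vector of scaffold lengths (bp).
#' @param min_self_pairs Minimum read pairs joining a scaffold's own ends.
#' @param min_len Minimum scaffold length.
#' @param other_link_min Read pairs to another scaffold at or above this
#'   count veto circularity.
#' @return Tibble `scaffold`, `length_bp`, `self_pairs`, `other_links`,
#'   `is_circular`.
#' @export
detect_circular <- function(links, scaffold_lengths, min_self_pairs = 5L,
                            min_len = 5000L, other_link_min = 1L) {
  ids <- names(scaffold_lengths)
  self <- filter(links, .data$scaffold_a == .data$scaffold_b,
                 .data$end_a != .data$end_b)
  self <- if (nrow(self) == 0) {
    tibble(scaffold_a = character(0), self_pairs = integer(0))
  } else {
    self |>
      group_by(.data$scaffold_a) |>
      summarise(self_pairs = max(.data$n_pairs), .groups = "drop")
  }
  cross <- links |>
    filter(.data$scaffold_a != .data$scaffold_b, .data$n_pairs >= other_link_min)
  crossed <- unique(c(cross$scaffold_a, cross$scaffold_b))
  tibble(
    scaffold = ids,
    length_bp = as.integer(unname(scaffold_lengths)),
    self_pairs = as.integer(self$self_pairs[match(ids, self$scaffold_a)]) |>
      tidyr::replace_na(0L),
    other_links = ids %in% crossed
  ) |>
    mutate(is_circular = .data$self_pairs >= min_self_pairs &
             !.data$other_links & .data$length_bp >= min_len)
}

#' Classify a scaffold as viral from its ORF annotations
#'
#' A scaffold is viral when it cannot be assigned to a cellular lineage,
#' carries two or more ORFs matching virus-specific terms, and no ORF
#' matching a cellular-specific term. Matching is case-insensitive
#' substring; multiword terms must appear contiguously.
#'
#' @param annotations Character vector of ORF annotation strings for one
#'   scaffold.
#' @param lexicon Lexicon from [viral_lexicon()].
#' @param taxonomy_assignable Whether the scaffold was assigned to a
#'   cellular lineage by upstream profiling.
#' @return Logical scalar.
#' @export
classify_viral <- function(annotations, lexicon = viral_lexicon(),
                           taxonomy_assignable = FALSE) {
  if (isTRUE(taxonomy_assignable)) return(FALSE)
  ann <- tolower(annotations)
  hits_any <- function(terms) {
    vapply(ann, function(a) any(stringr::str_detect(a, stringr::fixed(terms))),
           logical(1))
  }
  n_viral <- sum(hits_any(lexicon$viral_terms))
  n_cellular <- sum(hits_any(lexicon$cellular_terms))
  n_viral >= 2 && n_cellular == 0
}

#' Dereplicate sequences into populations
#'
#' Two sequences belong to the same population when they are at least
#' `min_identity` identical over at least `min_coverage` of the shorter
#' sequence (banded global alignment of the shorter within the longer).
#' Populations are single-linkage connected components; the representative
#' is the longest member and names the population.
#'
#' @param sequences Named character vector.
#' @param min_identity Identity threshold over the aligned span.
#' @param min_coverage Required aligned fraction of the shorter sequence.
#' @return Tibble `scaffold`, `population`, `is_representative`.
#' @export
dereplicate <- function(sequences, min_identity = 0.99, min_coverage = 0.99) {
  if (length(sequences) == 0) {
    abort("dereplicate() needs at least one sequence", class = "crisprcensus_input_error")
  }
  ids <- names(sequences) %||% paste0("seq_", seq_along(sequences))
  n <- length(sequences)
  lens <- nchar(sequences)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (find(i) == find(j)) next
        if (!kmer_prefilter(sequences[i], sequences[j])) next
        pr <- seq_pair_similarity(sequences[i], sequences[j])
        if (pr$identity >= min_identity && pr$coverage >= min_coverage) link(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  rep_of <- vapply(unique(roots), function(r) {
    members <- which(roots == r)
    members[which.max(lens[members])]
  }, integer(1))
  names(rep_of) <- as.character(unique(roots))
  tibble(
    scaffold = ids,
    population = ids[rep_of[as.character(roots)]],
    is_representative = seq_len(n) == rep_of[as.character(roots)]
  )
}

# deterministic evenly spaced 31-mer probes from the shorter sequence;
# near-identical pairs share most probes, unrelated pairs share none
kmer_prefilter <- function(a, b, k = 31L, n_probes = 20L, min_hits = NULL) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (nchar(a) <= k) return(TRUE)
  starts <- unique(pmax(1L, floor(seq(1, nchar(a) - k, length.out = n_probes))))
  probes <- substring(a, starts, starts + k - 1L)
  hits <- sum(vapply(probes, function(p) grepl(p, b, fixed = TRUE), logical(1)))
  hits >= (min_hits %||% ceiling(length(probes) / 4))
}

# identity over the aligned span and aligned coverage of the shorter
# sequence; comparable-length pairs use a global edit-distance alignment,
# length-discordant pairs a global-in-shorter / local-in-longer alignment
seq_pair_similarity <- function(a, b) {
  if (nchar(a) <= nchar(b)) { shorter <- a; longer <- b } else { shorter <- b; longer <- a }
  ls <- nchar(shorter); ll <- nchar(longer)
  if (shorter == longer) return(list(identity = 1, coverage = 1))
  if (ls / ll >= 0.9) {
    tr <- attr(utils::adist(shorter, longer, counts = TRUE), "counts")[1, 1, ]
    matches <- ls - tr[["sub"]] - tr[["del"]]
    span <- matches + tr[["sub"]] + tr[["ins"]] + tr[["del"]]
    return(list(
      identity = matches / span,
      coverage = (matches + tr[["sub"]]) / ls
    ))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(shorter), Biostrings::DNAString(longer),
    type = "global-local"
  )
  span <- Biostrings::nchar(aln)  # alignment length incl. gaps
  matches <- Biostrings::nmatch(aln)
  mismatches <- Biostrings::nmismatch(aln)
  list(
    identity = matches / span,
    coverage = (matches + mismatches) / ls
  )
}

#' Build the viral scaffold table
#'
#' Combines circularity evidence, annotation-based classification and
#' dereplication into one table of viral scaffolds.
#'
#' @param sequences Named character vector of candidate scaffolds.
#' @param links Link tibble.
#' @param annotations Optional tibble `scaffold`, `annotation` (one row per
#'   ORF) used for keyword classification of non-circular scaffolds.
#' @param lexicon Lexicon from [viral_lexicon()].
#' @param min_self_pairs,min_len,min_identity,min_coverage Thresholds, see
#'   [detect_circular()] and [dereplicate()].
#' @return Tibble `scaffold`, `length_bp`, `is_circular`,
#'   `circular_support`, `is_viral`, `population`.
#' @export
viral_scaffold_table <- function(sequences, links, annotations = NULL,
                                 lexicon = viral_lexicon(),
                                 min_self_pairs = 5L, min_len = 5000L,
                                 min_identity = 0.99, min_coverage = 0.99) {
  circ <- detect_circular(links, nchar(sequences),
                          min_self_pairs = min_self_pairs, min_len = min_len)
  viral_by_ann <- rep(FALSE, length(sequences))
  names(viral_by_ann) <- names(sequences)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    for (scf in unique(annotations$scaffold)) {
      if (!scf %in% names(viral_by_ann)) next
      viral_by_ann[scf] <-
        classify_viral(annotations$annotation[annotations$scaffold == scf],
                       lexicon = lexicon)
    }
  }
  pops <- dereplicate(sequences, min_identity, min_coverage)
  circ |>
    mutate(
      is_viral = .data$is_circular | viral_by_ann[.data$scaffold],
      circular_support = .data$self_pairs
    ) |>
    left_join(select(pops, "scaffold", "population"), by = "scaffold") |>
    select("scaffold", "length_bp", "is_circular", "circular_support",
           "is_viral", "population")
}
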