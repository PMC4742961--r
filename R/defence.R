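#' Default defence-system lexicon
#'
#' Term lists for rule-based annotation of restriction enzymes, abortive
#' infection / toxin-antitoxin systems and BREX. Whole-word exclusions are
#' matched case-insensitively except the single-letter subunit tokens `M`
#' and `S`, which match case-sensitively as standalone tokens.
#'
#' @return Nested list of term vectors.
#' @export
defence_lexicon <- function() {
  list(
    restriction = list(
      include = "restriction",
      exclude_words = c(
        "methyltransferase", "methylase", "methylation",
        "restriction alleviation", "antirestriction", "M", "mod",
        "specificity", "S", "McrC", "hsdS", "hsdM", "DptF", "DptG", "dam",
        "ccrM", "yhdJ", "DNMT1", "E2.1.1.113", "E2.1.1.72", "EC:2.1.1.113",
        "EC:2.1.1.72", "ArdA", "ArdC", "lar"
      ),
      case_sensitive_words = c("M", "S")
    ),
    abi = list(
      substring_terms = "abortive",
      word_terms = "abi"
    ),
    toxin_antitoxin = list(
      terms = c(
        "antitoxin", "anti-toxin", "antidote-toxin", "addiction module",
        "mazE", "mazF", "ChpAK", "ChpAI", "mosT", "mosA", "yeeV", "yeeU",
        "pasB", "pasA", "pemK", "pis", "pemI", "vapB", "vapC", "relE",
        "relE4", "stbE", "prevent-host-death", "doc", "phd", "txe", "yoeB",
        "yefM", "cogG", "metJ", "relB", "dinJ", "yafQ", "parE", "parDB",
        "parD1", "hicA", "hicB", "hipA", "hipB", "ccdB", "ccdA"
      ),
      exclude = c("topoisomerase", "cytochrome", "chemotaxis", "motility")
    ),
    brex = list(marker = "pglz")
  )
}

#' Read or write a lexicon as YAML
#'
#' @param path YAML path.
#' @param lexicon Lexicon list (for writing).
#' @return The lexicon list (read) or `path` invisibly (write).
#' @export
read_lexicon <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  yaml::write_yaml(lexicon, path)
  invisible(path)
}

# split an annotation into tokens; characters outside [A-Za-z0-9.:-]
# delimit, so EC numbers like EC:2.1.1.72 survive as single tokens
tokenize_annotation <- function(annotation) {
  toks <- strsplit(annotation, "[^A-Za-z0-9.:-]+")[[1]]
  toks[nzchar(toks)]
}

# TRUE if annotation contains `word` as a complete token; multi-word terms
# are compared as contiguous token runs
has_word <- function(annotation, word, case_sensitive = FALSE) {
  toks <- tokenize_annotation(annotation)
  wtoks <- tokenize_annotation(word)
  if (!case_sensitive) {
    toks <- tolower(toks)
    wtoks <- tolower(wtoks)
  }
  nw <- length(wtoks)
  if (nw == 0 || length(toks) < nw) return(FALSE)
  if (nw == 1) return(wtoks %in% toks)
  any(vapply(seq_len(length(toks) - nw + 1), function(i) {
    all(toks[i:(i + nw - 1)] == wtoks)
  }, logical(1)))
}

#' Count restriction enzymes in a genome
#'
#' An ORF counts as a restriction enzyme if it has a REBASE hit at
#' E-value <= 1e-10 with coverage >= 0.80, or its annotation contains the
#' substring "restriction" and none of the excluded terms as a complete
#' word (methylation/specificity subunits and anti-restriction factors).
#' Each ORF counts at most once.
#'
#' @param orfs ORF tibble for one genome; REBASE hits are rows with
#'   `hit_source == "rebase"` carrying `hit_evalue` and `hit_coverage`.
#' @param lexicon Lexicon from [defence_lexicon()].
#' @param rebase_evalue,rebase_coverage REBASE hit thresholds.
#' @return Integer count.
#' @export
count_restriction_enzymes <- function(orfs, lexicon = defence_lexicon(),
                                      rebase_evalue = 1e-10,
                                      rebase_coverage = 0.80) {
  lx <- lexicon$restriction
  per_orf <- orfs |>
    group_by(.data$scaffold, .data$orf_index) |>
    summarise(
      annotation = .data$annotation[1],
      rebase_ok = any(.data$hit_source == "rebase" &
                        .data$hit_evalue <= rebase_evalue &
                        !is.na(.data$hit_coverage) &
                        .data$hit_coverage >= rebase_coverage, na.rm = TRUE),
      .groups = "drop"
    )
  by_annotation <- vapply(per_orf$annotation, function(a) {
    if (is.na(a) || !grepl("restriction", a, ignore.case = TRUE)) return(FALSE)
    for (w in lx$exclude_words) {
      cs <- w %in% lx$case_sensitive_words
      if (has_word(a, w, case_sensitive = cs)) return(FALSE)
    }
    TRUE
  }, logical(1))
  sum(per_orf$rebase_ok | by_annotation)
}

#' Detect abortive-infection / toxin-antitoxin defence
#'
#' Abi genes carry "abortive" (substring) or "abi" (whole word) in their
#' annotation. Toxin-antitoxin genes come from TADB hits (E-value <=
#' 1e-10, coverage >= 0.80) or the annotation term list, excluding ORFs
#' mentioning topoisomerase/cytochrome/chemotaxis/motility. The system is
#' present with at least one Abi gene or at least two TA genes.
#'
#' @param orfs ORF tibble for one genome.
#' @param lexicon Lexicon from [defence_lexicon()].
#' @param tadb_evalue,tadb_coverage TADB hit thresholds.
#' @return Tibble with one row: `abi_count`, `ta_genes`, `present`.
#' @export
detect_abortive_infection <- function(orfs, lexicon = defence_lexicon(),
                                      tadb_evalue = 1e-10,
                                      tadb_coverage = 0.80) {
  lx <- lexicon
  per_orf <- orfs |>
    group_by(.data$scaffold, .data$orf_index) |>
    summarise(
      annotation = .data$annotation[1],
      tadb_ok = any(.data$hit_source == "tadb" &
                      .data$hit_evalue <= tadb_evalue &
                      !is.na(.data$hit_coverage) &
                      .data$hit_coverage >= tadb_coverage, na.rm = TRUE),
      .groups = "drop"
    )
  ann <- per_orf$annotation
  ann[is.na(ann)] <- ""
  is_abi <- vapply(ann, function(a) {
    grepl("abortive", a, ignore.case = TRUE) ||
      any(vapply(lx$abi$word_terms, function(w) has_word(a, w), logical(1)))
  }, logical(1))
  excluded <- vapply(ann, function(a) {
    any(vapply(lx$toxin_antitoxin$exclude, function(w) {
      grepl(w, a, ignore.case = TRUE)
    }, logical(1)))
  }, logical(1))
  ta_by_term <- vapply(ann, function(a) {
    any(vapply(lx$toxin_antitoxin$terms, function(w) has_word(a, w), logical(1)))
  }, logical(1))
  is_ta <- (per_orf$tadb_ok | ta_by_term) & !excluded
  tibble(
    abi_count = sum(is_abi),
    ta_genes = sum(is_ta),
    present = sum(is_abi) >= 1 || sum(is_ta) >= 2
  )
}

#' Detect a BREX system
#'
#' Present when any ORF is annotated with the PglZ marker (case-insensitive
#' token; the published annotation rule spells it "plgZ", both spellings
#' are accepted) or carries a PglZ profile hit with E-value < 1e-5.
#'
#' @param orfs ORF tibble for one genome; PglZ hits have
#'   `hit_source == "pglz"`.
#' @param pglz_evalue E-value threshold (strict).
#' @return Logical scalar.
#' @export
detect_brex <- function(orfs, pglz_evalue = 1e-5) {
  by_hit <- any(orfs$hit_source == "pglz" & orfs$hit_evalue < pglz_evalue,
                na.rm = TRUE)
  ann <- unique(orfs$annotation)
  ann <- ann[!is.na(ann)]
  by_ann <- any(vapply(ann, function(a) {
    has_word(a, "pglz") || has_word(a, "plgz")
  }, logical(1)))
  by_hit || by_ann
}

#' Score pathway completeness for a genome
#'
#' A stage is satisfied when at least one of its orthologue (KO)
#' identifiers was hit in the genome. The fraction of satisfied stages over
#' the pathway's combined modules sets the status: present at >= 0.75,
#' absent at <= 1/3, inconclusive in between.
#'
#' @param genome_kos Character vector of KO identifiers hit in the genome
#'   (best-hit assignments from upstream profiling).
#' @param module_defs Module definitions from [read_module_defs()].
#' @param pathway Name of the pathway in `module_defs`.
#' @return Tibble with one row: `pathway`, `n_stages`, `n_satisfied`,
#'   `fraction_stages`, `status`.
#' @export
pathway_status <- function(genome_kos, module_defs, pathway) {
  if (!pathway %in% names(module_defs)) {
    abort(paste0("unknown pathway '", pathway, "'"), class = "crisprcensus_input_error")
  }
  stages <- module_defs[[pathway]]$stages
  if (length(stages) == 0) {
    abort("empty module definition", class = "crisprcensus_input_error")
  }
  satisfied <- vapply(stages, function(s) any(s %in% genome_kos), logical(1))
  frac <- mean(satisfied)
  status <- if (frac >= 0.75) "present" else if (frac <= 1 / 3) "absent" else "inconclusive"
  tibble(
    pathway = pathway,
    n_stages = length(stages),
    n_satisfied = sum(satisfied),
    fraction_stages = frac,
    status = status
  )
}

#' Per-genome defence inventory
#'
#' Runs all defence classifiers and pathway scoring for one genome.
#'
#' @param orfs ORF tibble for the genome.
#' @param genome_kos KO identifiers hit in the genome.
#' @param module_defs Module definitions (needs pathways `nucleotide` and
#'   `fatty_acid`).
#' @param lexicon Lexicon from [defence_lexicon()].
#' @param genome_id Identifier copied into the result.
#' @return One-row tibble `genome`, `n_restriction`, `abi_present`,
#'   `ta_genes`, `brex`, `nucleotide_status`, `fattyacid_fraction`.
#' @export
defence_inventory <- function(orfs, genome_kos = character(0),
                              module_defs = NULL,
                              lexicon = defence_lexicon(),
                              genome_id = NA_character_) {
  abi <- detect_abortive_infection(orfs, lexicon)
  nuc <- if (!is.null(module_defs) && "nucleotide" %in% names(module_defs)) {
    pathway_status(genome_kos, module_defs, "nucleotide")$status
  } else NA_character_
  fat <- if (!is.null(module_defs) && "fatty_acid" %in% names(module_defs)) {
    pathway_status(genome_kos, module_defs, "fatty_acid")$fraction_stages
  } else NA_real_
  tibble(
    genome = genome_id,
    n_restriction = count_restriction_enzymes(orfs, lexicon),
    abi_present = abi$present,
    ta_genes = abi$ta_genes,
    brex = detect_brex(orfs),
    nucleotide_status = nuc,
    fattyacid_fraction = fat
  )
}
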