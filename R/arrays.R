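#' Array detector parameters
#'
#' Bounds follow common CRISPR definitions: direct repeats of 23-55 bp
#' separated by 25-72 bp spacers, at least 3 repeat units.
#'
#' @param repeat_len Length bounds for the repeat unit (bp).
#' @param spacer_len Length bounds for spacers (bp).
#' @param min_units Minimum number of repeat copies.
#' @param max_repeat_mismatch_frac Maximum per-copy mismatch fraction
#'   against the consensus.
#' @param seed_k Exact seed-match length used to find candidate periods.
#' @param flank_uniqueness_bp Repeat must occur nowhere on the scaffold
#'   outside the array plus this flank.
#' @return A list of detector parameters.
#' @export
array_params <- function(repeat_len = c(23L, 55L),
                         spacer_len = c(25L, 72L),
                         min_units = 3L,
                         max_repeat_mismatch_frac = 0.2,
                         seed_k = 11L,
                         flank_uniqueness_bp = 1000L) {
  stopifnot(
    length(repeat_len) == 2, repeat_len[1] > 0, repeat_len[1] <= repeat_len[2],
    length(spacer_len) == 2, spacer_len[1] > 0, spacer_len[1] <= spacer_len[2],
    min_units >= 2, max_repeat_mismatch_frac >= 0, max_repeat_mismatch_frac < 1,
    seed_k > 0
  )
  list(
    repeat_len = as.integer(repeat_len),
    spacer_len = as.integer(spacer_len),
    min_units = as.integer(min_units),
    max_repeat_mismatch_frac = max_repeat_mismatch_frac,
    seed_k = as.integer(seed_k),
    flank_uniqueness_bp = as.integer(flank_uniqueness_bp)
  )
}

# maximal runs of TRUE in a logical vector; returns start (1-based) + length
true_runs <- function(x, min_len) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(NULL)
  list(start = ends[keep] - r$lengths[keep] + 1L, len = r$lengths[keep])
}

# columns (relative offsets, 1-based position = start0 + off) at which all
# unit copies carry the same base; N and out-of-bounds never agree
agree_columns <- function(bytes, starts0, lo, hi) {
  n <- length(bytes)
  offs <- lo:hi
  grab <- function(s0) {
    idx <- s0 + offs
    out <- rep(as.raw(0), length(offs))
    inb <- idx >= 1 & idx <= n
    out[inb] <- bytes[idx[inb]]
    out
  }
  ref <- grab(starts0[1])
  ok <- ref != as.raw(0) & ref != charToRaw("N")
  for (j in seq_along(starts0)[-1]) {
    v <- grab(starts0[j])
    ok <- ok & v == ref & v != as.raw(0)
  }
  ok
}

#' Detect CRISPR arrays on a scaffold
#'
#' A self-contained seed-extend-chain detector: (1) exact `seed_k`-mer
#' matches recurring at a fixed period within the repeat+spacer length
#' bounds are found by comparing the scaffold against itself at every
#' admissible shift; (2) consecutive seeds at the same period are chained;
#' (3) repeat boundaries are refined to the maximal interval over which all
#' unit copies agree; (4) candidates must have >= `min_units` units,
#' in-bounds repeat and spacer lengths, per-copy mismatch fraction within
#' tolerance, no sub-period internal structure (rejects tandem repeats),
#' and a repeat that occurs nowhere else on the scaffold outside the array
#' plus flank. Overlapping candidates are resolved by most units, then
#' longest span.
#'
#' @param scaffold Nucleotide string.
#' @param params Parameters from [array_params()].
#' @param scaffold_id,genome_id Identifiers copied into the result.
#' @return Tibble with one row per array: `genome`, `scaffold`, `start`,
#'   `end` (0-based half-open), `n_units`, `repeat_consensus`,
#'   `duplicate_spacers`, and list columns `repeats` and `spacers` (the
#'   latter a tibble of `seq`, `start`, `end`).
#' @export
detect_arrays <- function(scaffold, params = array_params(),
                          scaffold_id = "scaffold", genome_id = NA_character_) {
  if (!nzchar(scaffold)) {
    abort("empty scaffold", class = "crisprcensus_input_error")
  }
  p <- params
  n <- nchar(scaffold)
  d_min <- p$repeat_len[1] + p$spacer_len[1]
  d_max <- p$repeat_len[2] + p$spacer_len[2]
  empty <- tibble(
    genome = character(0), scaffold = character(0),
    start = integer(0), end = integer(0), n_units = integer(0),
    repeat_consensus = character(0), duplicate_spacers = logical(0),
    repeats = list(), spacers = list()
  )
  if (n < d_min + p$repeat_len[1]) return(empty)
  bytes <- charToRaw(toupper(scaffold))
  nb <- charToRaw("N")

  candidates <- list()
  for (d in d_min:min(d_max, n - p$seed_k)) {
    eq <- bytes[seq_len(n - d)] == bytes[(d + 1):n] &
      bytes[seq_len(n - d)] != nb
    runs <- true_runs(eq, p$seed_k)
    if (is.null(runs)) next
    # chain runs whose starts are one period apart
    ord <- order(runs$start)
    st <- runs$start[ord]; ln <- runs$len[ord]
    i <- 1
    while (i <= length(st)) {
      chain <- i
      while (TRUE) {
        nxt <- which(abs(st - (st[chain[length(chain)]] + d)) <= 5L)
        if (length(nxt) == 0) break
        chain <- c(chain, nxt[1])
      }
      i <- max(chain) + 1L
      m_units <- length(chain) + 1L          # k runs link k+1 repeat copies
      if (m_units < p$min_units) next
      # intersect runs in first-unit coordinates, then refine boundaries
      o_lo <- max(st[chain] - (seq_along(chain) - 1L) * d)
      o_hi <- min(st[chain] + ln[chain] - (seq_along(chain) - 1L) * d)
      if (o_hi - o_lo < p$seed_k) next
      unit_starts <- (o_lo - 1L) + (seq_len(m_units) - 1L) * d  # 0-based anchor
      margin <- p$repeat_len[2]
      ok <- agree_columns(bytes, unit_starts, lo = -margin + 1L,
                          hi = (o_hi - o_lo) + margin)
      # maximal all-agree interval containing the seed core
      # (offset `o` maps to index `o + margin` in ok; seed core is offs 1..len)
      lo <- margin + 1L; hi <- margin + (o_hi - o_lo)
      if (!all(ok[lo:hi])) {
        # trim core to its widest agreeing sub-run
        sub <- true_runs(ok[lo:hi], 1L)
        if (is.null(sub)) next
        j <- which.max(sub$len)
        lo2 <- lo + sub$start[j] - 1L; hi <- lo2 + sub$len[j] - 1L; lo <- lo2
      }
      while (lo > 1 && ok[lo - 1]) lo <- lo - 1L
      while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1L
      rep_len <- hi - lo + 1L
      if (rep_len > p$repeat_len[2]) next
      if (rep_len < p$repeat_len[1]) next
      sp_len <- d - rep_len
      if (sp_len < p$spacer_len[1] || sp_len > p$spacer_len[2]) next
      rep_start0 <- unit_starts[1] + (lo - margin - 1L)  # 0-based
      if (rep_start0 < 0 || rep_start0 + (m_units - 1L) * d + rep_len > n) next
      candidates[[length(candidates) + 1L]] <- list(
        d = d, rep_start0 = rep_start0, rep_len = rep_len, m = m_units
      )
    }
  }
  if (length(candidates) == 0) return(empty)

  built <- purrr::map(candidates, function(cd) {
    build_array(scaffold, bytes, cd, p, scaffold_id, genome_id)
  })
  built <- purrr::compact(built)
  if (length(built) == 0) return(empty)
  out <- bind_rows(built)
  # resolve overlaps: most units, then longest span
  out <- arrange(out, dplyr::desc(.data$n_units), dplyr::desc(.data$end - .data$start))
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j]) next
      if (out$scaffold[j] == out$scaffold[i] &&
          out$start[j] < out$end[i] && out$end[j] > out$start[i]) {
        keep[j] <- FALSE
      }
    }
  }
  arrange(out[keep, ], .data$start)
}

# assemble + validate one candidate chain into an array row (or NULL)
build_array <- function(scaffold, bytes, cd, p, scaffold_id, genome_id) {
  m <- cd$m; d <- cd$d; rl <- cd$rep_len
  starts0 <- cd$rep_start0 + (seq_len(m) - 1L) * d
  reps <- substring(scaffold, starts0 + 1L, starts0 + rl)
  consensus <- consensus_string(reps)
  mm <- vapply(reps, function(r) hamming(r, consensus) / rl, numeric(1))
  if (any(mm > p$max_repeat_mismatch_frac)) return(NULL)
  sp_starts0 <- starts0[-m] + rl
  spacers <- substring(scaffold, sp_starts0 + 1L, sp_starts0 + (d - rl))
  arr_start <- starts0[1]
  arr_end <- starts0[m] + rl
  region <- substr(scaffold, arr_start + 1L, arr_end)
  # reject internally periodic regions (tandem repeats masquerading with
  # truncated units): any period below the minimum repeat+spacer length
  if (has_short_period(region, max_period = p$repeat_len[1] + p$spacer_len[1] - 1L)) {
    return(NULL)
  }
  # curation stand-in: the repeat must be unique to the array locus
  occ <- gregexpr(consensus, scaffold, fixed = TRUE)[[1]]
  if (occ[1] != -1) {
    occ0 <- occ - 1L
    fl <- p$flank_uniqueness_bp
    if (any(occ0 < arr_start - fl | occ0 + rl > arr_end + fl)) return(NULL)
  }
  tibble(
    genome = genome_id, scaffold = scaffold_id,
    start = arr_start, end = arr_end, n_units = m,
    repeat_consensus = consensus,
    duplicate_spacers = anyDuplicated(spacers) > 0,
    repeats = list(reps),
    spacers = list(tibble(
      seq = spacers, start = sp_starts0, end = sp_starts0 + (d - rl)
    ))
  )
}

consensus_string <- function(strings) {
  if (length(strings) == 1) return(strings)
  mat <- do.call(rbind, strsplit(strings, ""))
  paste(apply(mat, 2, function(col) {
    tab <- table(col)
    names(tab)[which.max(tab)]  # ties broken alphabetically by table order
  }), collapse = "")
}

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# TRUE if the region matches itself at any shift 1..max_period with <= 10%
# mismatches over the overlap (detects tandem-repeat structure)
has_short_period <- function(region, max_period) {
  rb <- charToRaw(region)
  n <- length(rb)
  for (s in seq_len(min(max_period, n - 1L))) {
    ov <- n - s
    if (ov < 10) break
    mism <- sum(rb[seq_len(ov)] != rb[(s + 1):n])
    if (mism / ov <= 0.1) return(TRUE)
  }
  FALSE
}

#' Detect arrays across a set of scaffolds
#'
#' @param scaffolds Named character vector of scaffolds.
#' @param params Parameters from [array_params()].
#' @param genome_id Identifier copied into the result.
#' @return Tibble as in [detect_arrays()], all scaffolds combined.
#' @export
detect_arrays_genome <- function(scaffolds, params = array_params(),
                                 genome_id = NA_character_) {
  res <- purrr::imap(scaffolds, function(s, id) {
    detect_arrays(s, params, scaffold_id = id, genome_id = genome_id)
  })
  bind_rows(res)
}

#' Unique spacers across arrays
#'
#' Spacers are canonicalised to the lexicographic minimum of the spacer and
#' its reverse complement before deduplication, so a spacer and its reverse
#' complement count once.
#'
#' @param arrays Array tibble from [detect_arrays()].
#' @return Sorted character vector of canonical spacer sequences.
#' @export
unique_spacers <- function(arrays) {
  if (nrow(arrays) == 0) return(character(0))
  sp <- unlist(purrr::map(arrays$spacers, "seq"), use.names = FALSE)
  if (length(sp) == 0) return(character(0))
  canon <- vapply(sp, function(s) min(s, revcomp(s)), character(1))
  sort(unique(unname(canon)))
}

#' All-versus-all repeat similarity
#'
#' Global (Needleman-Wunsch) alignment of every repeat pair with match +5,
#' mismatch -4, gap opening -10, gap extension -0.5; scores are normalised
#' by the geometric mean of the two self-scores,
#' `s_ij = max(0, S_ij) / sqrt(S_ii * S_jj)`, giving a symmetric matrix in
#' `[0, 1]` with unit diagonal.
#'
#' @param repeats Character vector of repeat sequences (named or not).
#' @return Symmetric numeric matrix with repeat identifiers as dimnames.
#' @export
repeat_similarity_matrix <- function(repeats) {
  if (length(repeats) == 0 || any(!nzchar(repeats))) {
    abort("repeats must be non-empty sequences", class = "crisprcensus_input_error")
  }
  ids <- names(repeats) %||% paste0("repeat_", seq_along(repeats))
  n <- length(repeats)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 5, mismatch = -4, baseOnly = FALSE
  )
  score_pair <- function(a, b) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      type = "global", substitutionMatrix = submat,
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE
    )
  }
  self <- vapply(repeats, function(r) score_pair(r, r), numeric(1))
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- max(0, score_pair(repeats[i], repeats[j]))
        m[i, j] <- m[j, i] <- s / sqrt(self[i] * self[j])
      }
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Write arrays and their spacers to disk
#'
#' Arrays go to a TSV (`genome`, `scaffold`, `start`, `end`, `n_units`,
#' `repeat_consensus`), spacers to a FASTA with ids
#' `<genome>|<scaffold>:<array start>|<ordinal>`.
#'
#' @param arrays Array tibble from [detect_arrays()].
#' @param tsv_path,fasta_path Output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_arrays <- function(arrays, tsv_path, fasta_path = NULL) {
  flat <- select(
    arrays, "genome", "scaffold", "start", "end", "n_units", "repeat_consensus"
  )
  readr::write_tsv(flat, tsv_path)
  if (!is.null(fasta_path)) {
    sp <- purrr::pmap(arrays, function(genome, scaffold, start, spacers, ...) {
      setNames(
        spacers$seq,
        paste0(genome, "|", scaffold, ":", start, "|", seq_len(nrow(spacers)))
      )
    })
    sp <- unlist(sp)
    if (length(sp) > 0) write_fasta(sp, fasta_path)
  }
  invisible(tsv_path)
}
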