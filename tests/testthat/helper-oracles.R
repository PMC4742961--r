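# Independent brute-force oracles used to validate the package's
# closed-form / optimised implementations. These deliberately share no code
# with the package: plain loops, plain arithmetic.

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Probability that a uniformly placed contiguous gap of length M = G - R
# covers a fixed central window of length L, by enumerating every gap start.
oracle_miss_probability <- function(G, R, L = 775) {
  M <- G - R
  if (M == 0) return(0)
  a <- (G - L) %/% 2
  covered <- 0L
  for (gs in 0:(G - M)) {
    if (gs <= a && gs + M >= a + L) covered <- covered + 1L
  }
  covered / (G - M + 1)
}

# P(sum of independent Bernoulli(d_i) <= k) by 2^n enumeration (n <= 20).
oracle_poibin_tail <- function(d, k) {
  n <- length(d)
  stopifnot(n <= 20)
  total <- 0
  for (x in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(x)[seq_len(n)])
    if (sum(bits) <= k) {
      total <- total + prod(ifelse(bits == 1, d, 1 - d))
    }
  }
  total
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
# (point-mass rule: sum probabilities of tables no more probable than the
# observed one, with a relative tolerance as in stats::fisher.test).
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b       # row 1 total
  n2 <- c + d      # row 2 total
  k <- a + c       # column 1 total
  support <- max(0, k - n2):min(k, m)
  probs <- vapply(support, function(x) dhyper(x, m, n2, k), numeric(1))
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (no ties), mirroring R's two-sided rule min(2 * one-sided, 1).
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_stat <- function(xi) {
    r <- rank(pooled)
    sum(r[xi]) - nx * (nx + 1) / 2
  }
  obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  p_le <- mean(us <= obs)
  p_ge <- mean(us >= obs)
  one_sided <- if (obs > nx * ny / 2) p_ge else p_le
  min(2 * one_sided, 1)
}

# All gapless matches of a spacer against one target, both strands, by
# per-offset character comparison. N never matches anything else.
oracle_spacer_matches <- function(spacer, target, min_identity = 0.90) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  L <- nchar(spacer)
  tl <- nchar(target)
  tchars <- strsplit(target, "")[[1]]
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else rc(spacer)
    pchars <- strsplit(pat, "")[[1]]
    if (tl < L) next
    for (off in 0:(tl - L)) {
      seg <- tchars[(off + 1):(off + L)]
      mm <- sum(seg != pchars)  # literal comparison: N == N, N != base
      if ((L - mm) / L >= min_identity - 1e-12) {
        rows[[length(rows) + 1L]] <- data.frame(
          target_start = off, strand = strand, mismatches = mm,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(target_start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$target_start, out$strand), , drop = FALSE]
}

# Build a minimal ORF tibble with the full hit-column schema.
orf_tbl <- function(annotation, scaffold = "scf1",
                    orf_index = seq_along(annotation) - 1L,
                    start = orf_index * 1000L, end = start + 900L,
                    strand = "+", genome = "g1",
                    hit_source = NA_character_, hit_family = NA_character_,
                    hit_evalue = NA_real_, hit_coverage = NA_real_) {
  tibble::tibble(
    genome = genome, scaffold = scaffold, orf_index = as.integer(orf_index),
    start = as.integer(start), end = as.integer(end), strand = strand,
    annotation = annotation, hit_source = hit_source,
    hit_family = hit_family, hit_evalue = hit_evalue,
    hit_coverage = hit_coverage
  )
}

# Substitute bases at n distinct random positions (always to a different
# base, so the Hamming distance is exactly n).
mutate_n_subs <- function(seq, n) {
  mutate_n_subs_at(seq, sample.int(nchar(seq), n))
}

mutate_n_subs_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Replace (not insert) a substring at a 0-based position.
overwrite_at <- function(seq, piece, at0) {
  paste0(substr(seq, 1, at0), piece,
         substr(seq, at0 + nchar(piece) + 1L, nchar(seq)))
}
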