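#' Estimate genome completeness from single-copy genes
#'
#' Completeness is the fraction of expected single-copy genes recovered
#' (51 expected for bacteria, 54 for archaea), clamped to a floor of 0.01
#' so downstream divisions are defined.
#'
#' @param scg_found Number of single-copy genes found.
#' @param scg_expected Number expected (51 bacteria / 54 archaea).
#' @return Completeness fraction in (0, 1].
#' @export
estimate_completeness <- function(scg_found, scg_expected) {
  if (any(scg_expected <= 0)) {
    abort("scg_expected must be positive", class = "crisprcensus_input_error")
  }
  if (any(scg_found < 0) || any(scg_found > scg_expected)) {
    abort("scg_found must be in [0, scg_expected]", class = "crisprcensus_input_error")
  }
  pmax(scg_found / scg_expected, 0.01)
}

#' Expected single-copy gene counts per domain
#' @param domain `"bacteria"` or `"archaea"`.
#' @return Integer vector.
#' @export
scg_expected_for <- function(domain) {
  ifelse(domain == "archaea", 54L, 51L)
}

#' Estimate full genome length from recovered nucleotides
#'
#' @param recovered_bp Nucleotides recovered for the genome.
#' @param completeness Estimated completeness in (0, 1].
#' @return Estimated full genome length, `round(recovered / completeness)`.
#' @export
estimate_genome_length <- function(recovered_bp, completeness) {
  if (any(completeness <= 0) || any(completeness > 1)) {
    abort("completeness must be in (0, 1]", class = "crisprcensus_input_error")
  }
  round(recovered_bp / completeness)
}

#' Probability of missing a fixed-length segment through genome
#' incompleteness
#'
#' Conservative contiguous-gap model: the `G - R` missing nucleotides are
#' assumed to form a single gap placed uniformly at random among its
#' `G - M + 1` admissible starts, and the segment of interest (default:
#' cas1, 775 bp) occupies a fixed window at the genome's centre. The
#' returned probability is that the gap covers the whole window, which for
#' interior-feasible configurations reduces to
#' `max(0, M - L + 1) / (G - M + 1)`. Concentrating all missing sequence in
#' one gap maximises the chance of losing the whole segment, so the model
#' is conservative.
#'
#' @param G Estimated full genome length (bp).
#' @param R Recovered nucleotides (bp), `0 <= R <= G`.
#' @param L Segment length (bp), default 775.
#' @return Probability in [0, 1]. Vectorised over `G` and `R`.
#' @export
miss_probability <- function(G, R, L = 775) {
  if (any(L <= 0) || any(L > G)) {
    abort("need 0 < L <= G", class = "crisprcensus_input_error")
  }
  if (any(R < 0) || any(R > G)) {
    abort("need 0 <= R <= G", class = "crisprcensus_input_error")
  }
  M <- G - R
  a <- (G - L) %/% 2                 # fixed window [a, a + L), 0-based
  lo <- pmax(0, a + L - M)           # gap starts covering the window
  hi <- pmin(a, G - M)
  pmax(0, hi - lo + 1) / (G - M + 1)
}

#' Poisson-binomial lower tail of the detection count
#'
#' Each of `n` genomes independently carries the feature with probability
#' `q` and, if carried, survives incompleteness with probability
#' `1 - p_i`, so it is detected with probability `d_i = q * (1 - p_i)`.
#' Returns `P(D <= k_observed)` for the Poisson-binomial sum `D`, by exact
#' dynamic programming over counts `0..k` with log-space accumulation, so
#' magnitudes far below double underflow of intermediate products are
#' representable.
#'
#' @param p_list Per-genome miss probabilities `p_i`.
#' @param q Reference carriage rate (default 0.40).
#' @param k_observed Observed number of detections.
#' @param log_p Return the natural log of the tail probability.
#' @return Tail probability (or its log).
#' @export
deficit_tail <- function(p_list, q = 0.40, k_observed, log_p = FALSE) {
  stopifnot(all(p_list >= 0), all(p_list <= 1), q >= 0, q <= 1)
  n <- length(p_list)
  k <- as.integer(k_observed)
  stopifnot(k >= 0, k <= n)
  d <- q * (1 - p_list)
  # log P(count = j) for j = 0..k; counts beyond k never return below it
  logf <- c(0, rep(-Inf, k))
  for (i in seq_len(n)) {
    ld <- log(d[i]); l1d <- log1p(-d[i])
    shifted <- c(-Inf, head(logf, k) + ld)
    logf <- logsumexp2(logf + l1d, shifted)
  }
  total <- logsumexp(logf)
  if (log_p) total else exp(total)
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Incidence rates with completeness correction
#'
#' The raw rate is the fraction of genomes with a detection. The corrected
#' rate divides detections by the summed completeness, treating a present
#' system's detection probability as the genome's completeness; it is
#' capped at 1 and can only exceed the raw rate when some genome is
#' incomplete.
#'
#' @param detections Logical vector, one per genome.
#' @param completeness_list Completeness fractions in (0, 1].
#' @return Tibble with one row: `n`, `n_present`, `raw_rate`,
#'   `corrected_rate`.
#' @export
corrected_incidence <- function(detections, completeness_list) {
  if (length(detections) != length(completeness_list)) {
    abort("detections and completeness_list lengths differ",
          class = "crisprcensus_input_error")
  }
  if (any(completeness_list <= 0) || any(completeness_list > 1)) {
    abort("completeness must be in (0, 1]", class = "crisprcensus_input_error")
  }
  n <- length(detections)
  k <- sum(detections)
  tibble(
    n = n,
    n_present = as.integer(k),
    raw_rate = k / n,
    corrected_rate = min(1, k / sum(completeness_list))
  )
}

#' Genus sampling weights
#'
#' Each genome receives a weight inversely proportional to the number of
#' genomes sampled from its genus, so every genus contributes a total
#' weight of exactly 1.
#'
#' @param genus_labels Character vector of genus assignments.
#' @return Numeric weights, same length and order.
#' @export
genus_weights <- function(genus_labels) {
  if (length(genus_labels) == 0) {
    abort("empty genus labels", class = "crisprcensus_input_error")
  }
  1 / stats::ave(seq_along(genus_labels), genus_labels, FUN = length)
}

#' Genus-weighted lifestyle association
#'
#' Weighted logistic regression of defence-system presence on obligate
#' symbiotic lifestyle with domain (bacteria/archaea) as covariate. With
#' integer weights the fit equals the fit on row-replicated unweighted
#' data. Perfect separation is flagged rather than raised: the fit is
#' treated as separated when the fitted lifestyle log-odds exceed 10 in
#' magnitude (an odds ratio beyond ~22,000, outside any plausible biological
#' effect and symptomatic of a diverging maximum-likelihood estimate).
#'
#' @param presence Logical vector: defence system present.
#' @param is_obligate_symbiont Logical vector.
#' @param domain_label Character vector (`bacteria`/`archaea`).
#' @param weights Observation weights, e.g. from [genus_weights()].
#' @return Object of class `lifestyle_assoc`: a list with `fit`,
#'   `coefficient` (lifestyle log-odds), `p_value`, `separation`.
#' @export
lifestyle_association <- function(presence, is_obligate_symbiont,
                                  domain_label = NULL, weights = NULL) {
  n <- length(presence)
  stopifnot(length(is_obligate_symbiont) == n)
  if (length(unique(is_obligate_symbiont)) < 2 ||
      min(table(is_obligate_symbiont)) < 2) {
    abort("need at least 2 genomes in each lifestyle class",
          class = "crisprcensus_input_error")
  }
  w <- weights %||% rep(1, n)
  dat <- data.frame(
    presence = as.numeric(presence),
    lifestyle = as.numeric(is_obligate_symbiont),
    w = w
  )
  form <- presence ~ lifestyle
  if (!is.null(domain_label) && length(unique(domain_label)) > 1) {
    dat$domain <- factor(domain_label)
    form <- presence ~ lifestyle + domain
  }
  fit <- withCallingHandlers(
    # tight convergence so weighted and row-replicated fits agree closely
    glm(form, family = binomial(), data = dat, weights = w,
        control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(wrn) {
      # muffle non-integer weight and numerically-0/1 fit warnings;
      # separation is diagnosed from the estimate below
      invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)$coefficients
  coefficient <- unname(co["lifestyle", "Estimate"])
  separation <- abs(coefficient) > 10
  structure(
    list(
      fit = fit,
      coefficient = if (separation) sign(coefficient) * Inf else coefficient,
      p_value = unname(co["lifestyle", "Pr(>|z|)"]),
      separation = separation
    ),
    class = "lifestyle_assoc"
  )
}

#' @export
print.lifestyle_assoc <- function(x, ...) {
  cat("Genus-weighted lifestyle association (logistic regression)\n")
  cat(sprintf("  lifestyle coefficient: %.4g\n", x$coefficient))
  cat(sprintf("  p-value:               %.4g\n", x$p_value))
  if (x$separation) cat("  WARNING: perfect separation detected\n")
  invisible(x)
}

#' @method tidy lifestyle_assoc
#' @export
tidy.lifestyle_assoc <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"],
    statistic = co[, "z value"],
    p.value = co[, "Pr(>|z|)"]
  )
}

#' @method glance lifestyle_assoc
#' @export
glance.lifestyle_assoc <- function(x, ...) {
  tibble(
    coefficient = x$coefficient,
    p.value = x$p_value,
    separation = x$separation,
    null.deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    nobs = length(x$fit$y)
  )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the hypergeometric point-mass rule: the sum of
#' probabilities of all tables (with the observed margins) no more
#' probable than the observed one.
#'
#' @param a,b,c,d Cell counts, row-wise.
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) abort("negative cell count", class = "crisprcensus_input_error")
  if (sum(counts) == 0) abort("all-zero table", class = "crisprcensus_input_error")
  stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact by enumeration when both samples are small (min size <= 8, no
#' ties), otherwise the normal approximation with tie correction.
#'
#' @param x,y Numeric samples.
#' @return p-value (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("empty sample", class = "crisprcensus_input_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 8
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value
  )
}
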