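test_that("completeness is found/expected with a 1% floor", {
  expect_equal(estimate_completeness(26, 51), 26 / 51)
  expect_equal(estimate_completeness(54, 54), 1)
  expect_equal(estimate_completeness(0, 51), 0.01)
  expect_error(estimate_completeness(52, 51), class = "crisprcensus_input_error")
  expect_error(estimate_completeness(1, 0), class = "crisprcensus_input_error")
  expect_equal(scg_expected_for(c("bacteria", "archaea")), c(51L, 54L))
})

test_that("genome length estimate divides recovered bp by completeness", {
  expect_equal(estimate_genome_length(800000, 0.8), 1000000)
  expect_equal(estimate_genome_length(1234567, 1), 1234567)
  expect_error(estimate_genome_length(100, 0), class = "crisprcensus_input_error")
})

test_that("miss probability matches its frozen reference value", {
  # G = 1e6, R = 5e5, L = 775: (M - L + 1)/(G - M + 1) = 499226/500001
  expect_equal(miss_probability(1e6, 5e5, 775), 499226 / 500001)
  expect_equal(miss_probability(1e6, 1e6, 775), 0)    # complete genome
  expect_equal(miss_probability(775, 0, 775), 1)      # everything missing
  expect_error(miss_probability(100, 50, 200), class = "crisprcensus_input_error")
  expect_error(miss_probability(100, 120, 50), class = "crisprcensus_input_error")
})

test_that("miss probability is vectorised and monotone in incompleteness", {
  G <- 50000
  R <- seq(0, G, by = 1000)
  p <- miss_probability(G, R, 775)
  expect_length(p, length(R))
  expect_true(all(diff(p) <= 0))   # more recovered, less likely to miss
  expect_true(all(p >= 0 & p <= 1))
  # single-element agreement with scalar calls
  expect_equal(p[3], miss_probability(G, R[3], 775))
})

test_that("miss probability equals gap-start enumeration on random cases", {
  set.seed(701)
  for (i in 1:60) {
    G <- sample(10:400, 1)
    L <- sample.int(G, 1)
    R <- sample(0:G, 1)
    expect_equal(miss_probability(G, R, L), oracle_miss_probability(G, R, L),
                 info = sprintf("G=%d R=%d L=%d", G, R, L))
  }
})

test_that("deficit tail equals 2^n enumeration and handles edge cases", {
  set.seed(702)
  for (i in 1:6) {
    n <- sample(5:12, 1)
    p <- runif(n)
    q <- runif(1, 0.2, 1)
    k <- sample(0:n, 1)
    expect_equal(deficit_tail(p, q, k), oracle_poibin_tail(q * (1 - p), k),
                 tolerance = 1e-12)
  }
  # two genomes, each detected w.p. 0.5: P(D = 0) = 0.25
  expect_equal(deficit_tail(c(0, 0), q = 0.5, k_observed = 0), 0.25)
  expect_equal(deficit_tail(c(0.3, 0.7), q = 0.4, k_observed = 2), 1)
  # log version agrees with the linear one
  p <- runif(10)
  expect_equal(deficit_tail(p, 0.4, 3, log_p = TRUE),
               log(deficit_tail(p, 0.4, 3)))
  # tail is non-decreasing in k
  tails <- vapply(0:10, function(k) deficit_tail(p, 0.4, k), numeric(1))
  expect_true(all(diff(tails) >= 0))
})

test_that("deficit tail stays finite in log space far below underflow", {
  lp <- deficit_tail(rep(0, 2000), q = 0.9, k_observed = 0, log_p = TRUE)
  expect_equal(lp, 2000 * log(0.1))
  expect_true(is.finite(lp))
})

test_that("corrected incidence divides detections by summed completeness", {
  r <- corrected_incidence(c(rep(TRUE, 3), rep(FALSE, 7)), rep(0.75, 10))
  expect_equal(r$raw_rate, 0.3)
  expect_equal(r$corrected_rate, 0.4)
  expect_equal(r$n_present, 3L)
  # complete genomes: no correction
  r2 <- corrected_incidence(c(TRUE, FALSE), c(1, 1))
  expect_equal(r2$corrected_rate, r2$raw_rate)
  # the cap keeps the rate a probability
  r3 <- corrected_incidence(rep(TRUE, 4), rep(0.5, 4))
  expect_equal(r3$corrected_rate, 1)
  expect_error(corrected_incidence(TRUE, c(0.5, 0.5)),
               class = "crisprcensus_input_error")
  expect_error(corrected_incidence(TRUE, 0), class = "crisprcensus_input_error")
})

test_that("genus weights give every genus total weight 1", {
  g <- c("a", "b", "a", "c", "a", "b")
  w <- genus_weights(g)
  expect_equal(as.numeric(tapply(w, g, sum)), c(1, 1, 1))
  expect_equal(w, c(1/3, 1/2, 1/3, 1, 1/3, 1/2))
  expect_error(genus_weights(character(0)), class = "crisprcensus_input_error")
})

test_that("lifestyle association recovers the sign of a planted effect", {
  set.seed(703)
  n <- 400
  sym <- runif(n) < 0.4
  # symbionts depleted: carriage 0.1 vs 0.5
  pres <- runif(n) < ifelse(sym, 0.1, 0.5)
  dom <- sample(c("bacteria", "archaea"), n, replace = TRUE, prob = c(0.9, 0.1))
  fit <- lifestyle_association(pres, sym, dom,
                               weights = genus_weights(sample(letters, n, TRUE)))
  expect_s3_class(fit, "lifestyle_assoc")
  expect_true(fit$coefficient < 0)
  expect_true(fit$p_value < 0.05)
  expect_false(fit$separation)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
  expect_true("lifestyle" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$coefficient, fit$coefficient)
  expect_output(print(fit), "lifestyle coefficient")
})

test_that("perfect separation is flagged, not raised", {
  pres <- c(rep(TRUE, 10), rep(FALSE, 10))
  sym <- pres
  fit <- lifestyle_association(pres, sym)
  expect_true(fit$separation)
  expect_true(is.infinite(fit$coefficient))
  expect_error(lifestyle_association(c(TRUE, FALSE), c(TRUE, TRUE)),
               class = "crisprcensus_input_error")
})

test_that("Fisher exact matches hypergeometric enumeration", {
  # frozen case: table (3,1;1,3) has two-sided p = 34/70
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70)
  for (a in 0:3) for (b in 0:3) for (c in 0:3) for (d in 0:3) {
    if (a + b + c + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, c, d), oracle_fisher_2x2(a, b, c, d),
                 tolerance = 1e-10, info = paste(a, b, c, d))
  }
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), class = "crisprcensus_input_error")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), class = "crisprcensus_input_error")
})

test_that("Mann-Whitney matches permutation enumeration when exact", {
  # frozen case: x below y entirely, exact two-sided p = 1/3
  expect_equal(mann_whitney(c(1, 2), c(3, 4)), 1 / 3)
  set.seed(704)
  for (i in 1:5) {
    nx <- sample(2:5, 1); ny <- sample(2:6, 1)
    v <- sample(seq(0.1, 50, by = 0.1), nx + ny)  # distinct values
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(mann_whitney(x, y), oracle_mann_whitney(x, y),
                 tolerance = 1e-10)
  }
  # ties fall back to the corrected normal approximation, silently
  expect_no_warning(p <- mann_whitney(c(1, 2, 2, 3), c(2, 4, 5, 6)))
  expect_true(p > 0 && p <= 1)
  expect_error(mann_whitney(numeric(0), 1), class = "crisprcensus_input_error")
})
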