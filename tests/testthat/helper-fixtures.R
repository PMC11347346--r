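# Shared fixtures and small independent oracles used across test files.

# Published regimen-comparison table: fractions, dose/fraction, duration in
# weeks, reference BED values (Gy) for the DD, DI and no-repopulation
# variants, and a BID flag. The 35 x 2 row is the standard regimen.
reference_bed_table <- function() {
  read.table(header = TRUE, text = "
    m    d    weeks  dd    di    simp  bid
    38   1.8  3.8    65.68 75.13 80.71 1
    18   3    3.6    63.86 64.84 70.20 0
    20   2.75 4      63.60 64.32 70.13 0
    25   2.4  5      63.25 64.80 74.40 0
    20   2.6  4      63.03 59.72 65.52 0
    21   2.55 4.2    62.95 60.53 67.21 0
    30   2.2  6      62.90 65.81 80.52 0
    22   2.4  4.4    62.72 58.06 65.47 0
    60   1.1  6      62.33 58.55 73.26 1
    35   2    7      62.19 64.17 84.00 0
    40   1.6  8      60.95 49.30 74.24 0
    25   2    5      57.73 50.40 60.00 0
    40   1.27 4      55.46 51.45 57.25 1")
}

as_regimen_frame <- function(tab) {
  data.frame(fractions = tab$m, dose_per_fraction = tab$d,
             fractions_per_day = ifelse(tab$bid == 1, 2L, 1L),
             duration_weeks = tab$weeks)
}

# Small effectful cohort for forest/causal unit tests.
small_effect_cohort <- function(n = 800, seed = 1, ...) {
  sample_cohort(randomized_cohort_spec(n_patients = n, seed = seed, ...))
}

# Exhaustive-pair Harrell concordance oracle (ties in risk count 1/2;
# pairs are comparable when the smaller time is an event).
concordance_oracle <- function(risk, time, event) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- time[i]; tj <- time[j]
      first <- if (ti < tj) i else if (tj < ti) j else NA
      if (is.na(first) || event[[first]] != 1) next
      other <- if (first == i) j else i
      # at equal times the pair is not comparable unless one is an event
      # and the other censored later; with ti == tj skip (handled above)
      den <- den + 1
      if (risk[first] > risk[other]) num <- num + 1
      else if (risk[first] == risk[other]) num <- num + 0.5
    }
  }
  num / den
}

# Logrank statistic oracle via observed-minus-expected summation.
logrank_oracle <- function(time, event, group) {
  stopifnot(all(group %in% c(0, 1)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n - d) / (n - 1) * (n1 / n) * (1 - n1 / n)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Exact permutation-enumeration Shapley oracle for a tiny model: v(S) is
# the mean model output over the background with S features from x.
shapley_oracle <- function(f, x, background, features) {
  p <- length(features)
  vfun <- function(S) {
    d <- background
    for (nm in S) d[[nm]] <- x[[nm]]
    mean(f(d))
  }
  phi <- setNames(numeric(p), features)
  perms <- gtools_permutations(p)
  for (r in seq_len(nrow(perms))) {
    S <- character(0)
    for (j in perms[r, ]) {
      nm <- features[j]
      phi[nm] <- phi[nm] + vfun(c(S, nm)) - vfun(S)
      S <- c(S, nm)
    }
  }
  phi / nrow(perms)
}

# All permutations of 1..n (tiny n only).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- (1:n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
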