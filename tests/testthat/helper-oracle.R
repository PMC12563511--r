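# Independent brute-force reference implementation of the ordinal
# statistics, used as the oracle in equivalence tests. Deliberately naive:
# literal stable sort, explicit tie-group collapse, string-keyed counting.

oracle_amp_perm <- function(v) {
  o <- order(v)                       # stable ascending sort
  pos <- integer(length(v))
  pos[o] <- seq_along(v)              # position of each element in the sort
  for (val in unique(v)) {            # tie groups take their minimum position
    idx <- which(v == val)
    pos[idx] <- min(pos[idx])
  }
  pos
}

oracle_pattern_table <- function(x, m, tau) {
  n <- length(x) - (m - 1) * tau
  keys <- character(n)
  for (t in seq_len(n)) {
    v <- x[t + (0:(m - 1)) * tau]
    keys[t] <- paste(oracle_amp_perm(v), collapse = ",")
  }
  table(keys) / n
}

oracle_rev_key <- function(key) {
  paste(rev(strsplit(key, ",", fixed = TRUE)[[1]]), collapse = ",")
}

oracle_pe <- function(ptab) {
  p <- as.numeric(ptab)
  -sum(p * log(p))
}

oracle_ptirr <- function(ptab) {
  fwd <- names(ptab)
  all_keys <- union(fwd, vapply(fwd, oracle_rev_key, character(1)))
  total <- 0
  for (k in all_keys) {
    pf <- if (k %in% fwd) as.numeric(ptab[k]) else 0
    kr <- oracle_rev_key(k)
    pb <- if (kr %in% fwd) as.numeric(ptab[kr]) else 0
    total <- total + pf * abs(pf - pb) / (pf + pb)
  }
  total
}

# Construct a pattern_distribution object directly from named forward
# probabilities ("j1,j2,..." keys), bypassing any series: lets identity
# tests exercise the index formulas on arbitrary synthetic distributions.
make_synthetic_distribution <- function(prob, m) {
  m <- as.integer(m)
  keys <- names(prob)
  patterns <- t(vapply(strsplit(keys, ",", fixed = TRUE),
                       function(k) as.integer(k), integer(m)))
  enc <- function(p) sum((p - 1) * m^(seq_len(m) - 1))
  codes <- apply(patterns, 1, enc)
  rev_codes <- apply(patterns, 1, function(p) enc(rev(p)))
  n <- 1000L
  structure(list(
    patterns = patterns,
    counts = stats::setNames(round(prob * n), keys),
    prob = prob, n_vectors = n,
    U = length(codes), V = length(unique(c(codes, rev_codes))),
    m = m, tau = 1L, tie_tol = 0,
    codes = codes, v_codes = sort(unique(c(codes, rev_codes)))
  ), class = "pattern_distribution")
}

# shared fixture: a small MEG-like cohort used by several test files
make_small_cohort <- function(seed = 7, n_per_group = c(HC = 5, SZ = 5),
                              n_channels = 6, n_samples = 3000,
                              sample_rate_hz = 300, ...) {
  gen_cohort(n_per_group = n_per_group, n_channels = n_channels,
             n_samples = n_samples, sample_rate_hz = sample_rate_hz,
             seed = seed, ...)
}
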