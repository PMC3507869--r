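# Small programmatic fixtures shared across test files.

# a tiny deterministic MSAP matrix
tiny_msap <- function(enzyme = "HpaII") {
  msap_matrix(rbind(c(1L, 0L, 1L), c(0L, 0L, 1L)),
              sample_ids = c("s1", "s2"),
              line_ids = c("L1", "L1"),
              generations = "S2", enzyme = enzyme)
}

# random binary profile matrix with row names
random_binary <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(rbinom(n * p, 1L, 0.5), n, p)
  rownames(m) <- paste0("s", seq_len(n))
  m
}

# Independent brute-force AMOVA oracle: same quantities computed directly
# from the defining double sums, sharing no code with amova().
brute_amova <- function(profiles, grouping) {
  n <- nrow(profiles)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d2[i, j] <- sum((profiles[i, ] - profiles[j, ])^2)
    }
  }
  f <- factor(grouping)
  sizes <- tabulate(f)
  g <- nlevels(f)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (lev in seq_len(g)) {
    members <- which(as.integer(f) == lev)
    acc <- 0
    for (i in members) for (j in members) if (i < j) acc <- acc + d2[i, j]
    ss_within <- ss_within + acc / length(members)
  }
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / (g - 1)
  ms_within <- ss_within / (n - g)
  n0 <- (n - sum(sizes^2) / n) / (g - 1)
  va <- (ms_among - ms_within) / n0
  vw <- ms_within
  phi <- if (max(0, va) + vw <= 0) 0 else max(0, va) / (max(0, va) + vw)
  list(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
       Va = va, Vw = vw, phi_pt = phi)
}

# exact dose-response data lying on a known curve, with replicates
exact_dose_table <- function(A, b, m, doses = c(0, 0.01, 0.1, 0.5, 1.0, 1.5),
                             reps = 4) {
  data.frame(dose = rep(doses, each = reps),
             rep = rep(seq_len(reps), length(doses)),
             percent = rep(logistic100(doses, A, b, m), each = reps))
}
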