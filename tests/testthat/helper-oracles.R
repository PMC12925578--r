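# Independent brute-force oracles used against the package implementations.

# Two-sided Mann-Whitney p by enumerating every labeling of the pooled sample:
# fraction of labelings whose U is at least as far from the null mean as the
# observed U.
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  obs_r <- rank(pooled)
  U_obs <- sum(obs_r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  sets <- utils::combn(n, n1)
  Us <- apply(sets, 2, function(idx) sum(obs_r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# All permutations of 1..n (small n only).
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * m + 1L):(i * m)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], m)
  }
  out
}

# Two-sided exact Spearman p by enumerating all n! rank assignments of y.
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  P <- oracle_perms(n)
  rx <- rank(x)
  rhos <- apply(P, 1, function(p) stats::cor(rx, p))
  mean(abs(rhos) >= abs(stats::cor(rx, rank(y))) - 1e-9)
}

# Minimal event table builder for flow-pipeline unit tests.
make_events <- function(epcam, psma,
                        sample_id = "P1_c0", session_id = "S1",
                        cycle = 0L, response = "Responder",
                        is_control = FALSE, patient_id = "P1",
                        id_prefix = "ev") {
  n <- length(epcam)
  data.frame(event_id = paste0(id_prefix, seq_len(n)),
             patient_id = patient_id, sample_id = sample_id,
             session_id = session_id, cycle = cycle, response = response,
             epcam_mfi = epcam, psma_mfi = psma, is_control = is_control,
             stringsAsFactors = FALSE)
}
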