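# Independent oracles used across the suite.

# Exact coverage probability by full enumeration of all k^n outcome
# sequences (feasible only for tiny libraries).
coverage_enum_oracle <- function(n, probs) {
  k <- length(probs)
  if (n == 0L) return(0)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  pr <- apply(seqs, 1L, function(s) prod(probs[s]))
  covered <- apply(seqs, 1L, function(s) length(unique(s)) == k)
  sum(pr[covered])
}

# Brute-force minimum residue-ligand heavy-atom distance, computed with
# plain loops straight off the parsed model.
min_dist_oracle <- function(model) {
  prot <- model$protein
  lig <- model$ligand
  key <- paste(prot$chain, prot$resno, prot$insert)
  out <- vapply(unique(key), function(kk) {
    rows <- which(key == kk)
    best <- Inf
    for (i in rows) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
                    (prot$z[i] - lig$z[j])^2)
        if (d < best) best <- d
      }
    }
    best / 10  # nm
  }, numeric(1))
  sort(out)
}

# Single coupon-collector waiting time: draws needed to see all k
# equiprobable variants at least once.
coupon_waiting_time <- function(k, cap = 50L * k) {
  draws <- sample.int(k, cap, replace = TRUE)
  first <- match(seq_len(k), draws)
  if (anyNA(first)) return(NA_integer_)
  max(first)
}

# A fresh default-condition screen simulation joined with its ground truth.
simulated_screen_joined <- function(seed) {
  sim <- simulate_screen(generator_config(seed = seed))
  recs <- screen_records(process_plate_scans(sim$scans))
  merge(recs, sim$truth, by = "clone")
}
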