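# Fixture builders shared across tests.  Everything is generated in code;
# no data files.

# Random pedigree with founders and (possibly inbred) descendants.
# Row order is scrambled so sorting is exercised.
random_pedigree_frame <- function(n, n_founders = max(3L, n %/% 5L),
                                  scramble = TRUE) {
  animal <- paste0("A", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in (n_founders + 1L):n) {
    s <- sample.int(i - 1L, 1L)
    d <- sample.int(i - 1L, 1L)
    if (s == d) d <- if (d > 1L) d - 1L else d + 1L
    sire[i] <- animal[s]
    dam[i] <- animal[d]
  }
  df <- data.frame(animal = animal, sire = sire, dam = dam,
                   stringsAsFactors = FALSE)
  if (scramble) df <- df[sample.int(n), ]
  df
}

random_pedigree <- function(n, ...) {
  df <- random_pedigree_frame(n, ...)
  pedigree(df$animal, df$sire, df$dam)
}

# Founder-only pedigree: A = identity.
founder_pedigree <- function(n, prefix = "D") {
  pedigree(paste0(prefix, seq_len(n)), rep("0", n), rep("0", n))
}

# Single-trait records on given animals with constant factor levels.
flat_records <- function(ids, outcome, parity = 1) {
  data.frame(doe_id = ids, parity = parity, outcome = outcome,
             year = "y1", season = "s1", age_class = "a1",
             stringsAsFactors = FALSE)
}

# Small herd dataset for sampler and CV tests.
small_herd <- function(seed, n_does = 600, n_gen = 3) {
  cfg <- sim_config(n_founder_sires = 25, n_founder_dams = 320,
                    n_generations = n_gen,
                    offspring_per_gen = ceiling(1.2 * n_does / (n_gen - 1)),
                    n_recorded_does = n_does, seed = seed)
  simulate_dataset(cfg)
}
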