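# Shared fixture builders: everything is generated in code at test time.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

random_sequence <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# a 60-residue substrate with two planted sites (length 6-9, depth 0.5-1),
# as used by the site-recovery benchmarks
planted_titration <- function(seed, noise_sd = 0.05) {
  set.seed(seed)
  seqv <- sample(AA20, 60, replace = TRUE)
  l1 <- sample(6:9, 1); s1 <- sample(3:20, 1)
  l2 <- sample(6:9, 1); s2 <- sample(35:50, 1)
  sites <- data.frame(start = c(s1, s2), end = c(s1 + l1 - 1, s2 + l2 - 1),
                      depth = round(stats::runif(2, 0.5, 1), 3))
  spec <- titration_spec(paste(seqv, collapse = ""), sites = sites,
                         noise_sd = noise_sd, seed = seed)
  list(spec = spec, sites = sites, seq = seqv)
}

# truth sites with at least `min_run` scoreable (non-proline) residues;
# only these are recoverable under the run-length rule
eligible_sites <- function(seqv, sites, min_run = 5) {
  ok <- vapply(seq_len(nrow(sites)), function(i)
    sum(seqv[sites$start[i]:sites$end[i]] != "P") >= min_run, logical(1L))
  sites[ok, , drop = FALSE]
}
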