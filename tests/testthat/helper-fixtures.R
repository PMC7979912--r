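# shared fixtures, built in code

calibratedParams <- function(arch, eps = 2) {
  ktamParams(arch, epsilon = eps, concentration = 1e-6)
}

csArch <- function(n) architecture("CS", n = n)

fastGrowthParams <- function() {
  growthParams(v = 0.25, k_stall = 2e-4, k_resume = 2e-3,
               k_term = 1 / (12 * 3600), seed_conc = 2e-9, slat_conc = 1e-6)
}

randomGenome <- function(n, seed = 99) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force oracle for the longest non-overlapping self-complementary
# stem (O(L^4)); independent of the DP in scoreSelfStructure
bruteSelfStructure <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  rc <- function(x) crisscross::revcomp(paste(x, collapse = ""))
  best <- 0L
  for (k in seq_len(L %/% 2)) {
    for (a in seq_len(L - 2 * k + 1)) {
      sub1 <- paste(s[a:(a + k - 1)], collapse = "")
      for (b in (a + k):(L - k + 1)) {
        sub2 <- paste(s[b:(b + k - 1)], collapse = "")
        if (sub2 == rc(strsplit(sub1, "")[[1]])) {
          best <- max(best, k)
          break
        }
      }
    }
  }
  best
}

# small assigned blueprint reused across designer tests (cached per session)
v6Blueprint <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- assignSequences(buildBlueprint(domainLayout(6, 10.5),
                                               "full"), rng_seed = 42)
    cache
  }
})
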