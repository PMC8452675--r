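# shared fixtures: all built in code, no files

# a freq_set from an explicit frequency matrix
make_freq_set <- function(freq, pops = NULL, markers = NULL) {
  freq <- as.matrix(freq)
  colnames(freq) <- pops %||% paste0("pop", seq_len(ncol(freq)))
  rownames(freq) <- markers %||% paste0("mk", seq_len(nrow(freq)))
  structure(freq, class = c("freq_set", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one read-count record
rc_record <- function(A = 0, C = 0, G = 0, T = 0, gt = "",
                      sample = "s1", marker = "mk1") {
  data.frame(sample = sample, marker = marker,
             reads_A = A, reads_C = C, reads_G = G, reads_T = T,
             called_genotype = gt, stringsAsFactors = FALSE)
}

# dosage matrix -> aim_profiles
make_profiles <- function(d, markers = NULL, samples = NULL) {
  d <- as.matrix(d)
  markers <- markers %||% paste0("mk", seq_len(ncol(d)))
  samples <- samples %||% paste0("s", seq_len(nrow(d)))
  dimnames(d) <- list(samples, markers)
  structure(d, class = c("aim_profiles", "matrix", "array"))
}

# reference db straight from allele-1 frequencies and a nominal size
db_from_freqs <- function(freq_matrix, n_ind = 1000L) {
  counts <- round(freq_matrix * 2 * n_ind)
  totals <- matrix(2L * n_ind, nrow(freq_matrix), ncol(freq_matrix),
                   dimnames = dimnames(freq_matrix))
  suppressWarnings(reference_db(counts, totals))
}

# independent brute-force oracle for the exact HWE test: direct summation of
# the conditional distribution written from the closed form (kept separate
# from the package implementation on purpose)
hwe_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * n - nA
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  logp <- vapply(hets, function(h) {
    a <- (nA - h) / 2; b <- (nB - h) / 2
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(nAB, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# exhaustive-enumeration oracle for log-likelihood moments over <= 3 loci
moments_oracle <- function(q) {
  stopifnot(length(q) <= 3)
  probs <- lapply(q, function(qq) c(`0` = (1 - qq)^2, `1` = 2 * qq * (1 - qq),
                                    `2` = qq^2))
  grids <- expand.grid(lapply(probs, function(p) seq_along(p)))
  pr <- apply(grids, 1, function(idx)
    prod(vapply(seq_along(q), function(j) probs[[j]][idx[j]], numeric(1))))
  ll <- apply(grids, 1, function(idx)
    sum(vapply(seq_along(q), function(j) log(probs[[j]][idx[j]]), numeric(1))))
  e <- sum(pr * ll)
  list(mean = e, var = sum(pr * ll^2) - e^2)
}
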