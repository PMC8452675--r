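# Marker-independence filters: exact Hardy-Weinberg tests (full enumeration
# or a Markov-chain estimate), EM/permutation exact tests for pairwise LD on
# unphased genotypes, Bonferroni correction, and performance-based pruning of
# linked marker pairs.

#' Genotype counts per marker and population
#'
#' @param profiles An `aim_profiles` dosage matrix.
#' @param population Character vector of population labels, one per profile.
#' @return `data.frame` with `marker`, `population`, `n_AA` (dosage 2),
#'   `n_AB`, `n_BB`, `n`.
#' @export
genotype_counts <- function(profiles, population) {
  stop_if(length(population) != nrow(profiles),
          "population labels must match profile rows")
  d <- unclass(profiles)
  out <- list()
  for (pop in unique(population)) {
    sub <- d[population == pop, , drop = FALSE]
    out[[pop]] <- data.frame(
      marker = colnames(sub),
      population = pop,
      n_AA = colSums(sub == 2L, na.rm = TRUE),
      n_AB = colSums(sub == 1L, na.rm = TRUE),
      n_BB = colSums(sub == 0L, na.rm = TRUE),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$n <- res$n_AA + res$n_AB + res$n_BB
  res
}

# log P(n_AB heterozygotes | allele counts nA, nB) under the exact HWE null
hwe_config_logprob <- function(nhet, nA, nB) {
  n <- (nA + nB) / 2
  a <- (nA - nhet) / 2
  b <- (nB - nhet) / 2
  lfactorial(n) - lfactorial(a) - lfactorial(nhet) - lfactorial(b) +
    nhet * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
}

hwe_support <- function(nA, nB) {
  nmin <- min(nA, nB)
  seq.int(nmin %% 2L, nmin, by = 2L)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Conditional exact test given the observed allele counts: the p-value is the
#' total probability of all heterozygote configurations no more probable than
#' the observed one. `method = "enumeration"` sums the complete conditional
#' distribution (always feasible for biallelic SNPs at study scale);
#' `method = "markov_chain"` estimates the same p-value with a
#' Metropolis-Hastings chain over heterozygote counts (the conventional
#' Monte-Carlo alternative, default 1,000,000 steps).
#'
#' @param n_AA,n_AB,n_BB Genotype counts (allele A = allele 1).
#' @param method `"enumeration"` or `"markov_chain"`.
#' @param steps Markov-chain steps.
#' @param seed Seed for the chain.
#' @return The p-value; 1 for a monomorphic table (single possible
#'   configuration).
#' @examples
#' hwe_exact_test(74, 0, 2)    # strong heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB,
                           method = c("enumeration", "markov_chain"),
                           steps = 1e6, seed = 1L) {
  method <- match.arg(method)
  counts <- c(n_AA, n_AB, n_BB)
  stop_if(any(!is.finite(counts)) || any(counts < 0) ||
            any(counts != round(counts)),
          "genotype counts must be non-negative integers")
  stop_if(sum(counts) < 1, "empty genotype table")
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  if (nA == 0 || nB == 0) return(1.0)   # monomorphic
  hets <- hwe_support(nA, nB)
  logp <- hwe_config_logprob(hets, nA, nB)
  obs <- logp[match(n_AB, hets)]
  if (method == "enumeration") {
    p <- exp(logp)
    return(min(1, sum(p[logp <= obs + 1e-12])))
  }
  # Metropolis-Hastings over the heterozygote count (proposal: +/- 2 uniformly).
  # The returned estimate carries a batch-means Monte-Carlo standard error in
  # attribute "mc_se" so callers can compare against enumeration honestly.
  set.seed(as.integer(seed))
  if (length(hets) == 1L) return(1.0)
  idx <- match(n_AB, hets)
  u <- log(stats::runif(steps))
  prop <- sample(c(-1L, 1L), steps, replace = TRUE)
  state <- integer(steps)
  for (s in seq_len(steps)) {
    j <- idx + prop[s]
    if (j >= 1L && j <= length(hets) && u[s] < logp[j] - logp[idx]) {
      idx <- j
    }
    state[s] <- idx
  }
  extreme <- as.numeric(logp[state] <= obs + 1e-12)
  p_hat <- mean(extreme)
  n_batch <- 50L
  bsize <- steps %/% n_batch
  bm <- colMeans(matrix(extreme[seq_len(n_batch * bsize)], nrow = bsize))
  structure(p_hat, mc_se = stats::sd(bm) / sqrt(n_batch))
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise significance level in (0,1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`; comparisons use `p < bonferroni_threshold(...)`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stop_if(!is_count(m), "m must be a positive integer")
  stop_if(!is.finite(alpha) || alpha <= 0 || alpha >= 1,
          "alpha must lie in (0,1)")
  alpha / m
}

#' Number of unordered marker pairs
#'
#' @param m Marker count (>= 2).
#' @return `m (m - 1) / 2`.
#' @export
count_marker_pairs <- function(m) {
  stop_if(!is_count(m) || m < 2, "m must be an integer >= 2")
  m * (m - 1) / 2
}

# Haplotype counts (11, 10, 01, 00) contributed by each unambiguous genotype
# cell, cells in column-major order over (dosage1 + 1, dosage2 + 1); the
# double heterozygote row (cell 5) is zero - it is resolved in the E-step.
.LD_UNAMB <- local({
  u <- matrix(0, 9, 4)
  cell <- 0L
  for (j in 0:2) for (i in 0:2) {
    cell <- cell + 1L
    if (i == 1 && j == 1) next
    # locus-1 allele pair sorted descending aligns with locus-2's:
    # unambiguous whenever at most one locus is heterozygous
    a <- c(rep(1, i), rep(0, 2 - i))
    b <- c(rep(1, j), rep(0, 2 - j))
    for (k in 1:2) {
      idx <- if (a[k] == 1 && b[k] == 1) 1 else if (a[k] == 1) 2 else
        if (b[k] == 1) 3 else 4
      u[cell, idx] <- u[cell, idx] + 1
    }
  }
  u
})

# closed-form two-locus genotype-cell probabilities from haplotype
# frequencies h = (p11, p10, p01, p00), cells column-major as above
ld_cell_probs <- function(h) {
  p11 <- h[1]; p10 <- h[2]; p01 <- h[3]; p00 <- h[4]
  pmax(c(p00^2, 2 * p10 * p00, p10^2,
         2 * p01 * p00, 2 * (p11 * p00 + p10 * p01), 2 * p11 * p10,
         p01^2, 2 * p11 * p01, p11^2), 1e-300)
}

# EM haplotype-frequency estimation for two biallelic loci from unphased
# genotypes; returns maximized log-likelihood under linkage and independence.
ld_em_loglik <- function(d1, d2, max_iter = 200, tol = 1e-9) {
  n <- length(d1)
  tab <- tabulate(3L * d2 + d1 + 1L, nbins = 9L)  # column-major 3x3 counts
  ndh <- tab[5L]                                  # double heterozygotes
  p1 <- sum(d1) / (2 * n)
  p2 <- sum(d2) / (2 * n)
  h <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  h <- pmax(h, 1e-12); h <- h / sum(h)
  base_cnt <- drop(tab %*% .LD_UNAMB)
  for (it in seq_len(max_iter)) {
    pcis <- h[1] * h[4]
    ptrans <- h[2] * h[3]
    wcis <- if (pcis + ptrans > 0) pcis / (pcis + ptrans) else 0.5
    cnt <- base_cnt + ndh * c(wcis, 1 - wcis, 1 - wcis, wcis)
    hn <- cnt / (2 * n)
    hn <- pmax(hn, 1e-12); hn <- hn / sum(hn)
    if (max(abs(hn - h)) < tol) { h <- hn; break }
    h <- hn
  }
  h0 <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  h0 <- pmax(h0, 1e-12); h0 <- h0 / sum(h0)
  list(loglik_full = sum(tab * log(ld_cell_probs(h))),
       loglik_null = sum(tab * log(ld_cell_probs(h0))),
       haplotypes = h)
}

#' Exact test for linkage disequilibrium between two markers
#'
#' Likelihood-ratio test of linkage versus independence on unphased two-locus
#' genotypes: haplotype frequencies are estimated by EM, the statistic is
#' twice the log-likelihood gain over the product of allele frequencies, and
#' the null distribution is obtained by permuting one marker's genotype
#' column. Only complete observations (both dosages non-missing) are used.
#'
#' @param d1,d2 Allele-1 dosage vectors in `{0,1,2}` (`NA` = missing).
#' @param permutations Number of permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @return List of class `ld_result`: `statistic`, `p_value`
#'   (`(1 + #perm >= obs)/(1 + permutations)`), `n` complete individuals.
#'   A monomorphic marker gives `p_value = 1` by convention.
#' @export
ld_exact_test <- function(d1, d2, permutations = 1000L, seed = 1L) {
  keep <- !is.na(d1) & !is.na(d2)
  d1 <- as.integer(d1[keep]); d2 <- as.integer(d2[keep])
  n <- length(d1)
  stop_if(n < 2L, "need >= 2 complete individuals")
  out <- function(stat, p) structure(
    list(statistic = stat, p_value = p, n = n), class = "ld_result")
  if (length(unique(d1)) == 1L || length(unique(d2)) == 1L) {
    return(out(0, 1.0))
  }
  fit <- ld_em_loglik(d1, d2)
  stat <- 2 * (fit$loglik_full - fit$loglik_null)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(permutations)) {
    dp <- d2[sample.int(n)]
    fb <- ld_em_loglik(d1, dp)
    sb <- 2 * (fb$loglik_full - fb$loglik_null)
    if (sb >= stat - 1e-12) exceed <- exceed + 1L
  }
  out(stat, (1 + exceed) / (1 + permutations))
}

#' Pairwise LD tests across a marker set
#'
#' Runs [ld_exact_test()] for every marker pair within each population, using
#' only individuals with full profiles (no missing call at any marker), as
#' the downstream pruning assumes.
#'
#' @param profiles An `aim_profiles` dosage matrix.
#' @param population Population labels per profile (single population if
#'   omitted).
#' @param permutations,seed Passed to [ld_exact_test()].
#' @return `data.frame`: `marker1`, `marker2`, `population`, `statistic`,
#'   `p_value`, `n`.
#' @export
ld_test_all <- function(profiles, population = NULL, permutations = 1000L,
                        seed = 1L) {
  if (is.null(population)) population <- rep("all", nrow(profiles))
  d <- unclass(profiles)
  complete <- rowSums(is.na(d)) == 0L
  res <- list()
  mks <- colnames(d)
  for (pop in unique(population)) {
    sub <- d[complete & population == pop, , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in seq_len(ncol(sub) - 1L)) for (j in seq.int(i + 1L, ncol(sub))) {
      r <- ld_exact_test(sub[, i], sub[, j], permutations,
                         seed = seed + i * 1009L + j)
      res[[length(res) + 1L]] <- data.frame(
        marker1 = mks[i], marker2 = mks[j], population = pop,
        statistic = r$statistic, p_value = r$p_value, n = r$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Prune one marker from each significantly linked pair
#'
#' Pairs significant at the corrected level are processed most significant
#' first; in each pair still fully retained, the worse-performing marker is
#' removed. "Best performance" is a lexicographic comparison: fewest
#' genotype dropouts, then lowest mean noise, then smallest deviation of the
#' heterozygote balance from 1, then locus balance closest to the panel mean.
#' Exact ties are broken by keeping the marker with the shortest amplicon
#' (read length). Every removal is logged with the rule that decided it.
#'
#' @param ld LD results (`data.frame` as from [ld_test_all()]).
#' @param threshold Corrected significance level; pairs with
#'   `p_value < threshold` are pruned.
#' @param performance `data.frame` with `marker`, `dropouts`, `mean_noise`,
#'   `hb_deviation`, `locus_balance`, `amplicon_length` (see [qc_report()]
#'   and [synthetic_panel()]).
#' @return List: `retained`, `removed` (character vectors), `log`
#'   (`data.frame` of removals with the deciding rule).
#' @export
prune_linked_markers <- function(ld, threshold, performance) {
  sig <- ld[ld$p_value < threshold, , drop = FALSE]
  markers <- unique(c(ld$marker1, ld$marker2))
  need <- unique(c(sig$marker1, sig$marker2))
  missing_perf <- setdiff(need, performance$marker)
  stop_if(length(missing_perf) > 0L,
          paste("no performance record for:",
                paste(missing_perf, collapse = ", ")))
  perf <- performance
  rownames(perf) <- performance$marker
  lb_center <- mean(performance$locus_balance)
  removed <- character()
  logs <- list()
  if (nrow(sig) > 0L) {
    sig <- sig[order(sig$p_value, sig$marker1, sig$marker2), , drop = FALSE]
    for (r in seq_len(nrow(sig))) {
      a <- sig$marker1[r]; b <- sig$marker2[r]
      if (a %in% removed || b %in% removed) next
      key <- function(mk) c(perf[mk, "dropouts"], perf[mk, "mean_noise"],
                            abs(perf[mk, "hb_deviation"]),
                            abs(perf[mk, "locus_balance"] - lb_center))
      ka <- key(a); kb <- key(b)
      cmp <- 0L; rule <- "tie"
      metrics <- c("dropouts", "mean_noise", "hb_deviation", "locus_balance")
      for (s in seq_along(ka)) {
        if (ka[s] != kb[s]) {
          cmp <- if (ka[s] < kb[s]) -1L else 1L
          rule <- metrics[s]
          break
        }
      }
      if (cmp == 0L) {
        rule <- "amplicon_length"
        drop_mk <- if (perf[a, "amplicon_length"] >= perf[b, "amplicon_length"])
          a else b
      } else {
        drop_mk <- if (cmp < 0L) b else a
      }
      removed <- c(removed, drop_mk)
      logs[[length(logs) + 1L]] <- data.frame(
        removed = drop_mk, kept = setdiff(c(a, b), drop_mk),
        population = sig$population[r], p_value = sig$p_value[r],
        rule = rule, stringsAsFactors = FALSE)
    }
  }
  list(
    retained = setdiff(markers, removed),
    removed = removed,
    log = if (length(logs)) do.call(rbind, logs) else
      data.frame(removed = character(), kept = character(),
                 population = character(), p_value = numeric(),
                 rule = character(), stringsAsFactors = FALSE)
  )
}

#' HWE tests across markers and populations
#'
#' @param counts Output of [genotype_counts()].
#' @param method,steps,seed Passed to [hwe_exact_test()].
#' @return The input with a `p_value` column appended.
#' @export
hwe_test_all <- function(counts, method = "enumeration", steps = 1e6,
                         seed = 1L) {
  counts$p_value <- vapply(seq_len(nrow(counts)), function(i) {
    hwe_exact_test(counts$n_AA[i], counts$n_AB[i], counts$n_BB[i],
                   method = method, steps = steps, seed = seed + i)
  }, numeric(1))
  counts
}

#' Flag markers failing HWE in at least `min_populations` populations
#'
#' @param hwe Output of [hwe_test_all()].
#' @param threshold Corrected significance level.
#' @param min_populations Number of failing populations required to flag a
#'   marker for exclusion (default 1).
#' @return `data.frame`: `marker`, `n_failing`, `flagged`.
#' @export
hwe_flag_markers <- function(hwe, threshold, min_populations = 1L) {
  fail <- hwe$p_value < threshold
  agg <- stats::aggregate(list(n_failing = fail),
                          by = list(marker = hwe$marker), FUN = sum)
  agg$flagged <- agg$n_failing >= min_populations
  agg
}
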