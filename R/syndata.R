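# Synthetic multi-population AIM data: Balding-Nichols reference frequencies,
# HWE genotype profiles, two-way admixture, and an amplicon read-count layer.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator: number of
#' differentiated populations, marker count, ancestral allele frequencies,
#' per-population FST, sample sizes, an optional admixture scenario, and the
#' read-count model (negative-binomial total depth, heterozygote allele bias,
#' per-read error rate).
#'
#' @param n_populations Number of populations (>= 1).
#' @param n_markers Number of biallelic markers (>= 1).
#' @param ancestral_freqs Ancestral allele-1 frequency per marker, each in
#'   (0,1). A single value is recycled; default draws nothing - `0.5` for all
#'   markers.
#' @param fst Per-population differentiation in `[0,1)`. A single value is
#'   recycled to all populations.
#' @param n_individuals Individuals per population (>= 1), recycled.
#' @param admixture Optional list with elements `pops` (two population names
#'   or indices) and `alpha` (proportion of ancestry from the first, in
#'   `[0,1]`).
#' @param depth_mean Mean total read depth per locus (> 0).
#' @param depth_dispersion Negative-binomial size parameter; `Inf` gives
#'   Poisson depth.
#' @param allele_bias Expected fraction of a heterozygote's reads carrying
#'   allele 1, in (0,1). `0.5` means no bias.
#' @param error_rate Per-read probability of being converted to a uniformly
#'   chosen non-genotype nucleotide, in `[0, 0.5)`.
#' @param clamp_eps Frequencies are clamped to `[clamp_eps, 1 - clamp_eps]`
#'   after simulation so downstream log-likelihoods stay finite.
#' @param seed Root integer seed; all generator randomness flows from it via
#'   fixed per-operation substreams.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_populations = 3, n_markers = 50, fst = 0.05,
#'                   n_individuals = 20, seed = 7)
#' @export
sim_config <- function(n_populations,
                       n_markers,
                       ancestral_freqs = 0.5,
                       fst = 0.05,
                       n_individuals = 100,
                       admixture = NULL,
                       depth_mean = 200,
                       depth_dispersion = 10,
                       allele_bias = 0.5,
                       error_rate = 0.002,
                       clamp_eps = 1e-3,
                       seed = 1L) {
  stop_if(!is_count(n_populations), "n_populations must be a positive integer")
  stop_if(!is_count(n_markers), "n_markers must be a positive integer")
  ancestral_freqs <- rep_len(as.numeric(ancestral_freqs), n_markers)
  stop_if(any(!is.finite(ancestral_freqs)) ||
            any(ancestral_freqs <= 0) || any(ancestral_freqs >= 1),
          "ancestral_freqs must all lie strictly inside (0,1)")
  fst <- rep_len(as.numeric(fst), n_populations)
  stop_if(any(!is.finite(fst)) || any(fst < 0) || any(fst >= 1),
          "fst must lie in [0,1)")
  n_individuals <- rep_len(as.integer(n_individuals), n_populations)
  stop_if(any(is.na(n_individuals)) || any(n_individuals < 1),
          "n_individuals must all be >= 1")
  stop_if(!is.finite(depth_mean) || depth_mean <= 0, "depth_mean must be > 0")
  stop_if(is.na(depth_dispersion) || depth_dispersion <= 0,
          "depth_dispersion must be > 0 (Inf for Poisson)")
  stop_if(!is.finite(allele_bias) || allele_bias <= 0 || allele_bias >= 1,
          "allele_bias must lie in (0,1)")
  stop_if(!is.finite(error_rate) || error_rate < 0 || error_rate >= 0.5,
          "error_rate must lie in [0, 0.5)")
  stop_if(!is.finite(clamp_eps) || clamp_eps <= 0 || clamp_eps >= 0.5,
          "clamp_eps must lie in (0, 0.5)")
  stop_if(!is_count(seed + 1L), "seed must be an integer")
  if (!is.null(admixture)) {
    stop_if(!is.list(admixture) || is.null(admixture$pops) ||
              is.null(admixture$alpha) || length(admixture$pops) != 2L,
            "admixture must be list(pops = c(A, B), alpha = x)")
    stop_if(admixture$alpha < 0 || admixture$alpha > 1,
            "admixture alpha must lie in [0,1]")
  }
  structure(list(
    n_populations = as.integer(n_populations),
    n_markers = as.integer(n_markers),
    ancestral_freqs = ancestral_freqs,
    fst = fst,
    n_individuals = n_individuals,
    admixture = admixture,
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    allele_bias = allele_bias,
    error_rate = error_rate,
    clamp_eps = clamp_eps,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  populations :", x$n_populations,
      " (n =", paste(x$n_individuals, collapse = ", "), ")\n")
  cat("  markers     :", x$n_markers, "\n")
  cat("  FST         :", paste(format(x$fst), collapse = ", "), "\n")
  cat("  depth model : NB(mean =", x$depth_mean,
      ", size =", x$depth_dispersion, ")\n")
  cat("  allele bias :", x$allele_bias, " error rate:", x$error_rate, "\n")
  cat("  seed        :", x$seed, "\n")
  invisible(x)
}

# Fixed per-operation substreams derived from the root seed. Offsets are part
# of the documented contract: changing them changes every downstream draw.
.substreams <- c(frequencies = 11L, genotypes = 29L, admixture = 47L,
                 readcounts = 83L, panel = 131L)

substream_seed <- function(seed, op) {
  off <- .substreams[[op]]
  as.integer((as.double(seed) * 2654435761 + off) %% 2147483647)
}

#' Draw per-population reference allele frequencies (Balding-Nichols)
#'
#' For each population with differentiation `F` and each marker with ancestral
#' frequency `p`, the allele-1 frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, i.e. mean `p` and variance `p(1-p)F`.
#' `F = 0` returns the ancestral frequencies exactly. Draws are clamped to
#' `[clamp_eps, 1 - clamp_eps]`.
#'
#' @param config A [sim_config()].
#' @return A `freq_set`: numeric matrix (markers x populations) with marker
#'   row names, population column names, and the ancestral frequencies kept
#'   as attribute `ancestral`.
#' @export
sample_reference_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "frequencies"))
  m <- config$n_markers
  p <- config$ancestral_freqs
  freq <- matrix(NA_real_, nrow = m, ncol = config$n_populations,
                 dimnames = list(paste0("mk", seq_len(m)),
                                 paste0("pop", seq_len(config$n_populations))))
  for (k in seq_len(config$n_populations)) {
    f <- config$fst[k]
    if (f == 0) {
      freq[, k] <- p
    } else {
      freq[, k] <- stats::rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    }
  }
  eps <- config$clamp_eps
  freq[] <- pmin(pmax(freq, eps), 1 - eps)
  structure(freq, ancestral = p, class = c("freq_set", "matrix", "array"))
}

freq_column <- function(freqs, population) {
  stop_if(!population %in% colnames(freqs),
          sprintf("unknown population '%s'", population))
  freqs[, population]
}

new_aim_profiles <- function(dosage, markers, samples) {
  dimnames(dosage) <- list(samples, markers)
  structure(dosage, class = c("aim_profiles", "matrix", "array"))
}

#' Subset profiles, keeping class and panel provenance
#'
#' @param x An `aim_profiles` dosage matrix.
#' @param i,j Row (sample) and column (marker) indices.
#' @param ... Ignored.
#' @param drop Ignored; dimensions are always kept.
#' @export
`[.aim_profiles` <- function(x, i, j, ..., drop = FALSE) {
  xm <- unclass(x)
  if (missing(i)) i <- seq_len(nrow(xm))
  if (missing(j)) j <- seq_len(ncol(xm))
  out <- xm[i, j, drop = FALSE]
  prov <- attr(x, "panel")
  if (!is.null(prov)) attr(out, "panel") <- prov[colnames(out)]
  structure(out, class = c("aim_profiles", "matrix", "array"))
}

#' Simulate Hardy-Weinberg genotype profiles from one population
#'
#' Genotypes are drawn marker-independently with HWE probabilities
#' `p^2, 2p(1-p), (1-p)^2`; the allele-1 dosage at each marker is therefore
#' Binomial(2, p). No calls are missing.
#'
#' @param freqs A `freq_set` from [sample_reference_frequencies()].
#' @param population Column name of the source population.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param prefix Sample-ID prefix.
#' @return An `aim_profiles` object: integer matrix (samples x markers) of
#'   allele-1 dosages in `{0,1,2}`, `NA` meaning a missing call.
#' @export
simulate_genotypes <- function(freqs, population, n, seed, prefix = population) {
  p <- freq_column(freqs, population)
  stop_if(!is_count(n), "n must be a positive integer")
  set.seed(as.integer(seed))
  d <- matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), nrow = n)
  new_aim_profiles(d, rownames(freqs), sprintf("%s_%03d", prefix, seq_len(n)))
}

#' Simulate one two-way admixed profile
#'
#' Each of the two allele copies at each marker originates from `popA` with
#' probability `alpha`, otherwise from `popB`, independently across copies and
#' markers. `alpha = 1` reduces exactly to a `popA` genotype and `alpha = 0`
#' to a `popB` genotype.
#'
#' @inheritParams simulate_genotypes
#' @param popA,popB Source population column names.
#' @param alpha Proportion of ancestry from `popA`, in `[0,1]`.
#' @param sample_id Sample ID for the returned profile.
#' @return A single-row `aim_profiles` object.
#' @export
simulate_admixed_profile <- function(freqs, popA, popB, alpha, seed,
                                     sample_id = "admixed_001") {
  stop_if(!is.finite(alpha) || alpha < 0 || alpha > 1,
          "alpha must lie in [0,1]")
  pA <- freq_column(freqs, popA)
  pB <- freq_column(freqs, popB)
  set.seed(as.integer(seed))
  m <- length(pA)
  # per allele copy: source indicator, then allele-1 Bernoulli at the source's p
  src <- matrix(stats::runif(2L * m) < alpha, nrow = 2L)
  pmat <- matrix(rep(pB, each = 2L), nrow = 2L)
  pmat[src] <- rep(pA, each = 2L)[src]
  d <- matrix(as.integer(colSums(matrix(stats::runif(2L * m), nrow = 2L) < pmat)),
              nrow = 1L)
  new_aim_profiles(d, rownames(freqs), sample_id)
}

#' Simulate per-nucleotide read counts for genotype profiles
#'
#' Total depth per locus is negative binomial (`depth_mean`,
#' `depth_dispersion`; Poisson when dispersion is infinite). For
#' heterozygotes, allele-1 reads are Binomial(depth, `allele_bias`). Each read
#' is then independently converted to one of the three other nucleotides with
#' probability `error_rate` (uniformly over the three). A candidate genotype
#' is called from the resulting counts with the upstream caller's
#' minimum-allele-frequency rule (nucleotides holding at least
#' `min_allele_freq` of the reads, two at most, ordered by count), and the
#' simulated truth is recorded alongside for QC-accuracy testing.
#'
#' @param profiles An `aim_profiles` dosage matrix.
#' @param config The [sim_config()] providing the read-count model.
#' @param panel A panel definition (see [synthetic_panel()]) giving each
#'   marker's two alleles; defaults to a deterministic synthetic panel.
#' @param min_allele_freq Caller threshold for including a nucleotide in the
#'   candidate genotype (default 0.1, the genotyper plug-in default).
#' @return A `data.frame` of read-count records: `sample`, `marker`,
#'   `reads_A/C/G/T`, `called_genotype`, `true_genotype` (genotypes as
#'   unordered pairs like `"AG"`; `""` when no nucleotide reaches the caller
#'   threshold).
#' @export
simulate_read_counts <- function(profiles, config, panel = NULL,
                                 min_allele_freq = 0.1) {
  stopifnot(inherits(profiles, "aim_profiles"), inherits(config, "sim_config"))
  markers <- colnames(profiles)
  if (is.null(panel)) {
    panel <- synthetic_panel(length(markers), markers = markers,
                             seed = config$seed)
  }
  stop_if(!all(markers %in% panel$marker), "panel missing profile markers")
  panel <- panel[match(markers, panel$marker), ]
  set.seed(substream_seed(config$seed, "readcounts"))
  nuc <- c("A", "C", "G", "T")
  ns <- nrow(profiles); nm <- ncol(profiles)
  n <- ns * nm
  depth <- if (is.infinite(config$depth_dispersion)) {
    stats::rpois(n, config$depth_mean)
  } else {
    stats::rnbinom(n, mu = config$depth_mean, size = config$depth_dispersion)
  }
  dos <- as.vector(profiles)                       # column-major: marker blocks
  a1 <- rep(panel$allele1, each = ns)
  a2 <- rep(panel$allele2, each = ns)
  # reads carrying allele 1 before error
  r1 <- integer(n)
  hom1 <- !is.na(dos) & dos == 2L
  het <- !is.na(dos) & dos == 1L
  r1[hom1] <- depth[hom1]
  r1[het] <- stats::rbinom(sum(het), depth[het], config$allele_bias)
  r2 <- depth - r1
  counts <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, nuc))
  idx1 <- cbind(seq_len(n), match(a1, nuc))
  idx2 <- cbind(seq_len(n), match(a2, nuc))
  counts[idx1] <- r1
  counts[idx2] <- counts[idx2] + r2
  if (config$error_rate > 0) {
    for (j in seq_len(4L)) {
      src <- counts[, j]
      err <- stats::rbinom(n, src, config$error_rate)
      if (!any(err > 0)) next
      counts[, j] <- counts[, j] - err
      others <- setdiff(seq_len(4L), j)
      split3 <- sapply(seq_len(n), function(i) {
        if (err[i] == 0) return(c(0L, 0L, 0L))
        as.integer(stats::rmultinom(1, err[i], rep(1 / 3, 3)))
      })
      counts[, others] <- counts[, others] + t(split3)
    }
  }
  true_gt <- ifelse(is.na(dos), "",
                    ifelse(dos == 2L, paste0(a1, a1),
                           ifelse(dos == 1L, sort_pair(a1, a2), paste0(a2, a2))))
  called <- call_genotype(counts, min_allele_freq)
  data.frame(
    sample = rep(rownames(profiles), times = nm),
    marker = rep(markers, each = ns),
    reads_A = counts[, "A"], reads_C = counts[, "C"],
    reads_G = counts[, "G"], reads_T = counts[, "T"],
    called_genotype = called,
    true_genotype = true_gt,
    stringsAsFactors = FALSE
  )
}

# naive caller mirroring the plug-in's minimum allele frequency rule
call_genotype <- function(counts, min_allele_freq) {
  nuc <- colnames(counts)
  apply(counts, 1L, function(x) {
    tot <- sum(x)
    if (tot == 0L) return("")
    keep <- which(x / tot >= min_allele_freq)
    if (length(keep) == 0L) return("")
    keep <- keep[order(x[keep], decreasing = TRUE)][seq_len(min(2L, length(keep)))]
    if (length(keep) == 1L) paste0(nuc[keep], nuc[keep])
    else paste0(sort(nuc[keep]), collapse = "")
  })
}

sort_pair <- function(a, b) {
  ifelse(a <= b, paste0(a, b), paste0(b, a))
}

#' Generate a deterministic synthetic panel definition
#'
#' Produces a marker table with the fields real panel definitions carry:
#' rs-style marker ID, chromosome, 1-based position, the two alleles, panel
#' name, and amplicon length. Alleles and lengths are pseudo-random but fully
#' determined by the seed.
#'
#' @param n_markers Number of markers.
#' @param markers Optional marker IDs (default `mk1..mkn`).
#' @param panel_name Panel label stored in the `panel` column.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `marker`, `chrom`, `pos`, `allele1`,
#'   `allele2`, `panel`, `amplicon_length`.
#' @export
synthetic_panel <- function(n_markers, markers = NULL, panel_name = "synthetic",
                            seed = 1L) {
  stop_if(!is_count(n_markers), "n_markers must be a positive integer")
  if (is.null(markers)) markers <- paste0("mk", seq_len(n_markers))
  stop_if(length(markers) != n_markers, "markers length mismatch")
  set.seed(substream_seed(seed, "panel"))
  nuc <- c("A", "C", "G", "T")
  a1 <- sample(nuc, n_markers, replace = TRUE)
  shift <- sample(1:3, n_markers, replace = TRUE)
  a2 <- nuc[((match(a1, nuc) - 1L + shift) %% 4L) + 1L]
  swap <- a2 < a1                       # allele1 alphabetically first
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  data.frame(
    marker = markers,
    chrom = sample(paste0("chr", 1:22), n_markers, replace = TRUE),
    pos = sample.int(2e8, n_markers),
    allele1 = a1, allele2 = a2,
    panel = panel_name,
    amplicon_length = sample(80:140, n_markers, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Build a simulated multi-population study
#'
#' Convenience wrapper: draws reference frequencies, simulates `n_individuals`
#' HWE profiles per population (plus the optional admixed individual), and a
#' population label vector.
#'
#' @param config A [sim_config()].
#' @return List with `freqs`, `profiles` (row-bound `aim_profiles`),
#'   `population` (character vector aligned with profile rows), `panel`.
#' @export
simulate_study <- function(config) {
  freqs <- sample_reference_frequencies(config)
  pops <- colnames(freqs)
  prof_list <- vector("list", length(pops))
  for (k in seq_along(pops)) {
    prof_list[[k]] <- simulate_genotypes(
      freqs, pops[k], config$n_individuals[k],
      seed = substream_seed(config$seed, "genotypes") + k)
  }
  profiles <- do.call(rbind, prof_list)
  population <- rep(pops, config$n_individuals)
  if (!is.null(config$admixture)) {
    adm <- simulate_admixed_profile(
      freqs, config$admixture$pops[1], config$admixture$pops[2],
      config$admixture$alpha,
      seed = substream_seed(config$seed, "admixture"))
    profiles <- rbind(profiles, adm)
    population <- c(population, "admixed")
  }
  profiles <- new_aim_profiles(profiles, rownames(freqs),
                               make.unique(rownames(profiles)))
  panel <- synthetic_panel(config$n_markers, markers = rownames(freqs),
                           seed = config$seed)
  list(freqs = freqs, profiles = profiles, population = population,
       panel = panel)
}
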