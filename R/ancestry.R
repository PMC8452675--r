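# Likelihood-based population assignment: reference allele-count databases
# over meta-populations, shrunken frequency estimates with leave-one-out,
# profile log-likelihoods with analytic moments, the z-score outlier gate,
# pairwise log-likelihood-ratio evidence weights, and the three-way
# Accepted / Ambiguous / Rejected classification.

#' Reference allele-count database over meta-populations
#'
#' @param counts Integer matrix (markers x meta-populations) of allele-1
#'   counts.
#' @param totals Integer matrix of total allele counts (2 x individuals typed
#'   at the marker), same shape.
#' @param mapping Optional named character vector: source population ->
#'   meta-population.
#' @param min_size Reference sizes (in individuals) below this trigger a
#'   warning (default 75), not an error.
#' @return An object of class `ref_db`.
#' @export
reference_db <- function(counts, totals, mapping = NULL, min_size = 75L) {
  stop_if(!is.matrix(counts) || !is.matrix(totals) ||
            !identical(dim(counts), dim(totals)),
          "counts and totals must be matrices of identical shape")
  stop_if(any(counts < 0) || any(totals < 0) || any(counts > totals),
          "need 0 <= allele-1 count <= total count")
  stop_if(is.null(colnames(counts)) || is.null(rownames(counts)),
          "counts needs marker row names and meta-population column names")
  n_ind <- apply(totals, 2L, max) / 2
  small <- n_ind < min_size
  if (any(small)) {
    warning(sprintf("reference meta-population(s) below %d individuals: %s",
                    min_size, paste(colnames(counts)[small], collapse = ", ")),
            call. = FALSE)
  }
  structure(list(counts = counts, totals = totals, mapping = mapping,
                 min_size = min_size),
            class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  cat("Reference database:", ncol(x$counts), "meta-populations,",
      nrow(x$counts), "markers\n")
  cat("  ", paste(sprintf("%s (n ~ %d)", colnames(x$counts),
                          as.integer(apply(x$totals, 2, max) / 2)),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Build a reference database from genotype profiles
#'
#' Sums allele-1 dosages per marker within each meta-population; totals count
#' two alleles per non-missing genotype.
#'
#' @param profiles An `aim_profiles` dosage matrix.
#' @param population Population label per profile.
#' @param mapping Optional named character vector population ->
#'   meta-population; identity when omitted.
#' @param min_size Passed to [reference_db()].
#' @return A `ref_db`.
#' @export
build_reference_db <- function(profiles, population, mapping = NULL,
                               min_size = 75L) {
  stop_if(length(population) != nrow(profiles),
          "population labels must match profile rows")
  meta <- if (is.null(mapping)) population else {
    stop_if(!all(population %in% names(mapping)),
            "every population needs a meta-population mapping")
    unname(mapping[population])
  }
  d <- unclass(profiles)
  metas <- unique(meta)
  counts <- totals <- matrix(
    0L, nrow = ncol(d), ncol = length(metas),
    dimnames = list(colnames(d), metas))
  for (k in metas) {
    sub <- d[meta == k, , drop = FALSE]
    counts[, k] <- as.integer(colSums(sub, na.rm = TRUE))
    totals[, k] <- as.integer(2L * colSums(!is.na(sub)))
  }
  reference_db(counts, totals, mapping = mapping, min_size = min_size)
}

db_meta <- function(db, meta) {
  stop_if(!meta %in% colnames(db$counts),
          sprintf("unknown meta-population '%s'", meta))
  meta
}

#' Shrunken allele-frequency estimates with optional leave-one-out
#'
#' Frequency `f = (x + a) / (n + 2a)` with pseudo-count `a` (default 1/2) and
#' sampling variance `f (1 - f) / (n + 2a + 1)`. With `exclude_profile` set,
#' that individual's two allele copies are first subtracted at every marker
#' where it has a call (the out-of-sample / leave-one-out estimate).
#'
#' @param db A `ref_db`.
#' @param meta Meta-population name.
#' @param exclude_profile Optional dosage vector (named by marker or aligned
#'   with the db's markers) to remove from the counts.
#' @param a Pseudo-count; `a = 0` gives unshrunk estimates and can produce
#'   frequencies of exactly 0 or 1 (infinite log-likelihood risk).
#' @return List with `freq` and `var`, both named by marker.
#' @export
estimate_frequencies <- function(db, meta, exclude_profile = NULL, a = 0.5) {
  meta <- db_meta(db, meta)
  # explicit names: single-marker subsets would otherwise drop them
  x <- stats::setNames(db$counts[, meta], rownames(db$counts))
  n <- stats::setNames(db$totals[, meta], rownames(db$counts))
  if (!is.null(exclude_profile)) {
    dos <- align_profile(exclude_profile, rownames(db$counts))
    has <- !is.na(dos)
    x[has] <- x[has] - dos[has]
    n[has] <- n[has] - 2L
    stop_if(any(x < 0) || any(n < 0),
            "leave-one-out subtraction below zero: profile not in reference")
  }
  f <- (x + a) / (n + 2 * a)
  list(freq = f, var = f * (1 - f) / (n + 2 * a + 1))
}

align_profile <- function(profile, markers) {
  if (inherits(profile, "aim_profiles")) {
    stop_if(nrow(profile) != 1L, "expected a single profile")
    profile <- unclass(profile)[1L, ]
  }
  if (!is.null(names(profile))) {
    out <- rep(NA_integer_, length(markers))
    names(out) <- markers
    common <- intersect(names(profile), markers)
    out[common] <- profile[common]
    out
  } else {
    stop_if(length(profile) != length(markers),
            "unnamed profile must match the marker set length")
    stats::setNames(as.integer(profile), markers)
  }
}

# per-marker log genotype probabilities under HWE at frequency q
geno_logprobs <- function(q) {
  list(l0 = 2 * log1p(-q), l1 = log(2) + log(q) + log1p(-q), l2 = 2 * log(q))
}

#' Profile log-likelihood under a frequency set
#'
#' `sum over non-missing markers of log P(genotype)` with HWE probabilities
#' `q^2, 2q(1-q), (1-q)^2`. Missing genotypes contribute nothing.
#'
#' @param profile Dosage vector (or 1-row `aim_profiles`), `NA` = missing.
#' @param freq Named frequency vector (e.g. `estimate_frequencies()$freq`).
#' @return List: `loglik`, `n_loci` (non-missing markers used).
#' @export
profile_loglik <- function(profile, freq) {
  dos <- align_profile(profile, names(freq))
  use <- !is.na(dos)
  q <- freq[use]
  stop_if(any(q <= 0 | q >= 1), "frequencies of 0 or 1: increase pseudo-count")
  lp <- geno_logprobs(q)
  d <- dos[use]
  ll <- sum(ifelse(d == 2L, lp$l2, ifelse(d == 1L, lp$l1, lp$l0)))
  list(loglik = if (length(d)) ll else 0, n_loci = sum(use))
}

#' Expectation and standard deviation of the profile log-likelihood
#'
#' Per locus, `E = sum_g P(g) log P(g)` and
#' `Var = sum_g P(g) log^2 P(g) - E^2`; loci are independent so totals add
#' and `SD = sqrt(sum Var)`. With `freq_var` supplied and
#' `include_freq_var = TRUE`, a second-order correction
#' `var(q) * sum_g P(g) (d log P(g) / dq)^2` is added to each locus variance
#' to propagate reference allele-frequency uncertainty (off by default).
#'
#' @param freq Named frequency vector.
#' @param loci Markers to include (non-missing set of the tested profile).
#' @param freq_var Optional per-marker frequency sampling variances.
#' @param include_freq_var Add the frequency-uncertainty correction.
#' @return List: `mean`, `sd`, `var`.
#' @export
loglik_moments <- function(freq, loci = names(freq), freq_var = NULL,
                           include_freq_var = FALSE) {
  stop_if(length(loci) == 0L, "empty locus set")
  q <- freq[loci]
  lp <- geno_logprobs(q)
  p0 <- (1 - q)^2; p1 <- 2 * q * (1 - q); p2 <- q^2
  e <- p0 * lp$l0 + p1 * lp$l1 + p2 * lp$l2
  v <- p0 * lp$l0^2 + p1 * lp$l1^2 + p2 * lp$l2^2 - e^2
  if (include_freq_var && !is.null(freq_var)) {
    # d log P / dq: -2/(1-q), (1-2q)/(q(1-q)), 2/q for dosages 0,1,2
    g0 <- -2 / (1 - q); g1 <- (1 - 2 * q) / (q * (1 - q)); g2 <- 2 / q
    v <- v + freq_var[loci] * (p0 * g0^2 + p1 * g1^2 + p2 * g2^2)
  }
  list(mean = sum(e), sd = sqrt(sum(v)), var = sum(v))
}

#' z-score outlier statistic for a profile against a meta-population
#'
#' `z = (E[l] - l) / SD[l]` over the profile's non-missing markers: large
#' positive values mean the profile fits the reference worse than a typical
#' member, and `z > 1.64` (one-sided P < 0.05) rejects the meta-population as
#' origin. With `loo = TRUE` the profile's own alleles are removed from the
#' reference counts before estimating frequencies (the out-of-sample
#' procedure required when the tested individual is part of the reference).
#'
#' @param profile Dosage vector or 1-row `aim_profiles`.
#' @param db A `ref_db`.
#' @param meta Meta-population tested.
#' @param loo Leave the profile out of the reference counts first.
#' @param a Pseudo-count for frequency shrinkage.
#' @param include_freq_var Propagate reference-frequency variance into SD.
#' @return List: `z`, `loglik`, `expected`, `sd`, `n_loci`.
#' @export
z_score <- function(profile, db, meta, loo = FALSE, a = 0.5,
                    include_freq_var = FALSE) {
  est <- estimate_frequencies(db, meta,
                              exclude_profile = if (loo) profile else NULL,
                              a = a)
  dos <- align_profile(profile, rownames(db$counts))
  loci <- names(dos)[!is.na(dos)]
  stop_if(length(loci) == 0L, "profile shares no markers with the database")
  ll <- profile_loglik(dos, est$freq)
  mo <- loglik_moments(est$freq, loci, freq_var = est$var,
                       include_freq_var = include_freq_var)
  stop_if(mo$sd == 0, "degenerate reference: SD of log-likelihood is zero")
  list(z = (mo$mean - ll$loglik) / mo$sd, loglik = ll$loglik,
       expected = mo$mean, sd = mo$sd, n_loci = ll$n_loci)
}

#' Log likelihood ratio between two meta-populations
#'
#' `log LR = l_A - l_B` over the profile's non-missing markers shared by both
#' references. The standard error is
#' `sqrt(sum_j Var_A[log P_A(g) - log P_B(g)])` with the per-locus variance
#' taken under meta A's genotype distribution. Antisymmetric in (A, B).
#'
#' @param profile Dosage vector or 1-row `aim_profiles`.
#' @param db A `ref_db`.
#' @param meta_a,meta_b Numerator and denominator meta-populations.
#' @param a Pseudo-count.
#' @param loo_meta Optional meta-population from whose counts the profile
#'   must be left out (its own origin, when part of the reference).
#' @return List: `log_lr`, `se`, `n_loci`.
#' @export
log_lr <- function(profile, db, meta_a, meta_b, a = 0.5, loo_meta = NULL) {
  excl_a <- if (!is.null(loo_meta) && identical(loo_meta, meta_a)) profile
  excl_b <- if (!is.null(loo_meta) && identical(loo_meta, meta_b)) profile
  fa <- estimate_frequencies(db, meta_a, exclude_profile = excl_a, a = a)$freq
  fb <- estimate_frequencies(db, meta_b, exclude_profile = excl_b, a = a)$freq
  dos <- align_profile(profile, rownames(db$counts))
  use <- !is.na(dos)
  la <- profile_loglik(dos, fa)
  lb <- profile_loglik(dos, fb)
  qa <- fa[use]; qb <- fb[use]
  lpa <- geno_logprobs(qa); lpb <- geno_logprobs(qb)
  t0 <- lpa$l0 - lpb$l0; t1 <- lpa$l1 - lpb$l1; t2 <- lpa$l2 - lpb$l2
  p0 <- (1 - qa)^2; p1 <- 2 * qa * (1 - qa); p2 <- qa^2
  m <- p0 * t0 + p1 * t1 + p2 * t2
  v <- p0 * t0^2 + p1 * t1^2 + p2 * t2^2 - m^2
  list(log_lr = la$loglik - lb$loglik, se = sqrt(sum(v)), n_loci = la$n_loci)
}

#' Classify an AIM profile against every meta-population
#'
#' Computes the z-score for each meta-population (leaving the profile out of
#' its own reference when `origin` names one), gates at
#' `z <= qnorm(1 - alpha)` (1.64 at alpha = 0.05), and applies the decision
#' tree: *Rejected* when no meta-population is accepted; *Accepted* when
#' exactly one is, or when several are but the best likelihood is one-sided
#' significantly higher than every other accepted alternative
#' (`log LR / SE > qnorm(1 - alpha)`); otherwise *Ambiguous*. Pairwise log-LRs
#' are computed (and stored) only when the profile is not Rejected.
#'
#' @param profile Dosage vector or 1-row `aim_profiles`.
#' @param db A `ref_db`.
#' @param alpha Significance level for both the z gate and the LR test.
#' @param origin Meta-population whose reference contains this profile
#'   (enables leave-one-out there); `NULL` for an outside profile.
#' @param a Pseudo-count.
#' @param include_freq_var Propagate frequency variance into the z SD.
#' @return An `assignment_result`: list with `sample`, `table` (per-meta z,
#'   log-likelihood, expectation, SD, per-meta category), `accepted`,
#'   `category`, `log_lr` and `log_lr_se` (matrices, `NULL` when Rejected),
#'   `n_loci`, `alpha`, `z_crit`.
#' @export
classify_profile <- function(profile, db, alpha = 0.05, origin = NULL,
                             a = 0.5, include_freq_var = FALSE) {
  metas <- colnames(db$counts)
  zcrit <- stats::qnorm(1 - alpha)
  zs <- lapply(metas, function(k) {
    z_score(profile, db, k, loo = identical(origin, k), a = a,
            include_freq_var = include_freq_var)
  })
  names(zs) <- metas
  z <- vapply(zs, `[[`, numeric(1), "z")
  ll <- vapply(zs, `[[`, numeric(1), "loglik")
  accepted <- metas[z <= zcrit]
  lr <- lr_se <- NULL
  best <- NULL
  if (length(accepted) == 0L) {
    category <- "Rejected"
  } else {
    lr <- lr_se <- matrix(0, length(metas), length(metas),
                          dimnames = list(metas, metas))
    for (i in seq_along(metas)) for (j in seq_along(metas)) {
      if (i == j) next
      r <- log_lr(profile, db, metas[i], metas[j], a = a, loo_meta = origin)
      lr[i, j] <- r$log_lr
      lr_se[i, j] <- r$se
    }
    best <- accepted[which.max(ll[accepted])]
    if (length(accepted) == 1L) {
      category <- "Accepted"
    } else {
      others <- setdiff(accepted, best)
      sig <- vapply(others, function(k) {
        se <- lr_se[best, k]
        se > 0 && lr[best, k] / se > zcrit
      }, logical(1))
      category <- if (all(sig)) "Accepted" else "Ambiguous"
    }
  }
  meta_cat <- ifelse(z > zcrit, "Rejected",
                     ifelse(metas == (best %||% "") & category == "Accepted",
                            "Accepted", "Ambiguous"))
  sample_id <- if (inherits(profile, "aim_profiles")) rownames(profile) else "profile"
  structure(list(
    sample = sample_id,
    table = data.frame(
      meta = metas, z = z, loglik = ll,
      expected = vapply(zs, `[[`, numeric(1), "expected"),
      sd = vapply(zs, `[[`, numeric(1), "sd"),
      category = meta_cat, row.names = NULL, stringsAsFactors = FALSE),
    accepted = accepted, category = category,
    log_lr = lr, log_lr_se = lr_se,
    n_loci = zs[[1L]]$n_loci, alpha = alpha, z_crit = zcrit
  ), class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("Profile", x$sample, "-", x$category,
      sprintf("(%d loci, z gate at %.3f)\n", x$n_loci, x$z_crit))
  print(x$table, digits = 4)
  invisible(x)
}

#' Vectorized assignment of many profiles
#'
#' Computes, for every profile and meta-population, the log-likelihood, its
#' expectation and SD, the z-score (with leave-one-out against the profile's
#' own meta-population when `origin` is given), the per-meta
#' Accepted/Ambiguous/Rejected category and the per-profile overall category.
#' Matrix algebra throughout: suitable for thousands of profiles.
#'
#' @param profiles An `aim_profiles` dosage matrix.
#' @param db A `ref_db`.
#' @param origin Optional character vector: each profile's own
#'   meta-population (must be a db column to enable leave-one-out; other
#'   values disable it for that profile).
#' @param alpha Significance level.
#' @param a Pseudo-count.
#' @return `data.frame` with one row per profile x meta-population: `sample`,
#'   `origin`, `meta`, `z`, `loglik`, `category` (per-meta), and
#'   `overall` (per-profile category, repeated across its rows).
#' @export
assign_profiles <- function(profiles, db, origin = NULL, alpha = 0.05,
                            a = 0.5) {
  d <- unclass(profiles)
  markers <- rownames(db$counts)
  stop_if(!all(colnames(d) %in% markers),
          "profiles carry markers absent from the database")
  d <- d[, markers[markers %in% colnames(d)], drop = FALSE]
  metas <- colnames(db$counts)
  zcrit <- stats::qnorm(1 - alpha)
  n <- nrow(d)
  M <- !is.na(d)                         # non-missing indicator
  I2 <- (!is.na(d) & d == 2L) + 0; I1 <- (!is.na(d) & d == 1L) + 0
  I0 <- (!is.na(d) & d == 0L) + 0
  mk <- colnames(d)
  ll <- e <- v <- matrix(NA_real_, n, length(metas),
                         dimnames = list(rownames(d), metas))
  for (k in metas) {
    x <- db$counts[mk, k]; tot <- db$totals[mk, k]
    loo_k <- if (is.null(origin)) rep(FALSE, n) else origin == k
    # plain (out-of-reference) estimate, one frequency vector for all rows
    f <- (x + a) / (tot + 2 * a)
    F <- matrix(f, n, length(mk), byrow = TRUE)
    if (any(loo_k)) {
      rows <- which(loo_k)
      Dk <- d[rows, , drop = FALSE]
      Xk <- matrix(x, length(rows), length(mk), byrow = TRUE)
      Tk <- matrix(tot, length(rows), length(mk), byrow = TRUE)
      has <- !is.na(Dk)
      Xk[has] <- Xk[has] - Dk[has]
      Tk[has] <- Tk[has] - 2L
      stop_if(any(Xk < 0) || any(Tk < 0),
              "leave-one-out subtraction below zero: origin mislabeled?")
      F[rows, ] <- (Xk + a) / (Tk + 2 * a)
    }
    L0 <- 2 * log1p(-F); L1 <- log(2) + log(F) + log1p(-F); L2 <- 2 * log(F)
    P0 <- (1 - F)^2; P1 <- 2 * F * (1 - F); P2 <- F^2
    Ej <- P0 * L0 + P1 * L1 + P2 * L2
    Vj <- P0 * L0^2 + P1 * L1^2 + P2 * L2^2 - Ej^2
    ll[, k] <- rowSums(M * (I2 * L2 + I1 * L1 + I0 * L0), na.rm = TRUE)
    e[, k] <- rowSums(M * Ej)
    v[, k] <- rowSums(M * Vj)
  }
  z <- (e - ll) / sqrt(v)
  acc <- z <= zcrit
  overall <- character(n)
  meta_cat <- matrix("Ambiguous", n, length(metas),
                     dimnames = list(rownames(d), metas))
  meta_cat[!acc] <- "Rejected"
  for (i in seq_len(n)) {
    accepted <- metas[acc[i, ]]
    if (length(accepted) == 0L) {
      overall[i] <- "Rejected"
      next
    }
    best <- accepted[which.max(ll[i, accepted])]
    if (length(accepted) == 1L) {
      overall[i] <- "Accepted"
      meta_cat[i, best] <- "Accepted"
    } else {
      others <- setdiff(accepted, best)
      sig <- vapply(others, function(kk) {
        r <- log_lr(d[i, ], db, best, kk, a = a,
                    loo_meta = if (!is.null(origin) &&
                                     origin[i] %in% metas) origin[i])
        r$se > 0 && r$log_lr / r$se > zcrit
      }, logical(1))
      if (all(sig)) {
        overall[i] <- "Accepted"
        meta_cat[i, best] <- "Accepted"
      } else {
        overall[i] <- "Ambiguous"
      }
    }
  }
  data.frame(
    sample = rep(rownames(d), times = length(metas)),
    origin = if (is.null(origin)) NA_character_ else rep(origin, length(metas)),
    meta = rep(metas, each = n),
    z = as.vector(z),
    loglik = as.vector(ll),
    category = as.vector(meta_cat),
    overall = rep(overall, times = length(metas)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Leave-one-out cross-validation summary of assignment effectiveness
#'
#' Tests every profile against every meta-population (leave-one-out for its
#' own) and tabulates, per origin x tested meta-population, the percentage of
#' profiles whose test fell in each category. Each origin/tested cell's three
#' percentages sum to 100 up to rounding.
#'
#' @param profiles An `aim_profiles` dosage matrix.
#' @param db A `ref_db` built from (at least) these profiles.
#' @param origin Character vector: each profile's meta-population of origin.
#' @param alpha,a Passed to [assign_profiles()].
#' @return `data.frame`: `origin`, `meta` (tested), `n`, `accepted_pct`,
#'   `ambiguous_pct`, `rejected_pct`.
#' @export
cross_validate <- function(profiles, db, origin, alpha = 0.05, a = 0.5) {
  stop_if(length(origin) != nrow(profiles),
          "origin labels must match profile rows")
  stop_if(!all(origin %in% colnames(db$counts)),
          "every profile must map to a database meta-population")
  res <- assign_profiles(profiles, db, origin = origin, alpha = alpha, a = a)
  cells <- split(res, list(res$origin, res$meta), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(cc) {
    data.frame(
      origin = cc$origin[1L], meta = cc$meta[1L], n = nrow(cc),
      accepted_pct = 100 * mean(cc$category == "Accepted"),
      ambiguous_pct = 100 * mean(cc$category == "Ambiguous"),
      rejected_pct = 100 * mean(cc$category == "Rejected"),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$origin, out$meta), ]
}
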