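# population assignment: frequency estimation, log-likelihood moments,
# z-score gate, log-LR, classification, cross-validation

test_that("frequency estimation shrinks and leaves one out correctly", {
  counts <- matrix(50L, 1, 1, dimnames = list("mk1", "A"))
  totals <- matrix(100L, 1, 1, dimnames = list("mk1", "A"))
  db <- suppressWarnings(reference_db(counts, totals))
  est <- estimate_frequencies(db, "A", a = 0.5)
  expect_equal(unname(est$freq), 50.5 / 101)
  expect_equal(unname(est$var), 0.5 * 0.5 / 102)
  # leave out an AA individual (dosage 2): counts become 48 / 98
  loo <- estimate_frequencies(db, "A", exclude_profile = c(mk1 = 2L), a = 0.5)
  expect_equal(unname(loo$freq), 48.5 / 99)
  # a = 0 with zero counts: frequency exactly 0 (degenerate, flagged downstream)
  db0 <- suppressWarnings(reference_db(
    matrix(0L, 1, 1, dimnames = list("mk1", "A")), totals))
  expect_equal(unname(estimate_frequencies(db0, "A", a = 0)$freq), 0)
  expect_error(profile_loglik(c(mk1 = 1L),
                              estimate_frequencies(db0, "A", a = 0)$freq),
               "pseudo-count")
  # subtraction below zero is a data-integrity error
  expect_error(estimate_frequencies(db0, "A", exclude_profile = c(mk1 = 2L)),
               "below zero")
  expect_error(estimate_frequencies(db, "nope"), "unknown meta")
})

test_that("profile log-likelihood is the HWE sum over non-missing loci", {
  f <- c(mk1 = 0.5)
  expect_equal(profile_loglik(c(mk1 = 1L), f)$loglik, log(0.5))
  # empty profile: zero log-likelihood with zero loci used
  empty <- profile_loglik(c(mk1 = NA_integer_), f)
  expect_equal(empty$loglik, 0)
  expect_equal(empty$n_loci, 0L)
  # additivity over 10 markers
  set.seed(81)
  q <- runif(10, 0.2, 0.8)
  names(q) <- paste0("mk", 1:10)
  dos <- rbinom(10, 2, q); names(dos) <- names(q)
  total <- profile_loglik(dos, q)$loglik
  single <- sum(vapply(1:10, function(j)
    profile_loglik(dos[j], q[j])$loglik, numeric(1)))
  expect_equal(total, single, tolerance = 1e-12)
})

test_that("log-likelihood moments match hand and brute-force enumeration", {
  mo <- loglik_moments(c(mk1 = 0.5))
  expect_equal(mo$mean, -1.039721, tolerance = 1e-6)
  expect_equal(mo$sd, 0.3465736, tolerance = 1e-6)
  # brute-force oracle on 1-3 loci, tolerance 1e-10
  set.seed(82)
  for (k in 1:3) {
    q <- runif(k, 0.05, 0.95); names(q) <- paste0("mk", seq_len(k))
    mo <- loglik_moments(q)
    or <- moments_oracle(q)
    expect_equal(mo$mean, or$mean, tolerance = 1e-10)
    expect_equal(mo$var, or$var, tolerance = 1e-10)
  }
  # degenerate limit: q -> 1 gives E -> 0-, SD -> 0+
  mo1 <- loglik_moments(c(mk1 = 1 - 1e-9))
  expect_lt(mo1$mean, 0); expect_gt(mo1$mean, -1e-6)
  expect_lt(mo1$sd, 1e-3)
  # independence scaling over 100 identical loci
  q100 <- rep(0.5, 100); names(q100) <- paste0("mk", 1:100)
  mo100 <- loglik_moments(q100)
  expect_equal(mo100$mean, 100 * -1.039721, tolerance = 1e-4)
  expect_equal(mo100$sd, 10 * 0.3465736, tolerance = 1e-6)
  expect_error(loglik_moments(c(mk1 = 0.5), loci = character(0)), "empty")
})

test_that("z-score is the standardized log-likelihood with the stated sign", {
  f <- make_freq_set(matrix(0.5, 1, 1), pops = "A")
  db <- db_from_freqs(f, n_ind = 10000L)   # frequency ~ 0.5 after shrinkage
  z_het <- z_score(c(mk1 = 1L), db, "A")
  z_hom <- z_score(c(mk1 = 2L), db, "A")
  expect_equal(z_het$z, -1.0, tolerance = 1e-3)
  expect_equal(z_hom$z, 1.0, tolerance = 1e-3)
  # centering: a profile whose loglik equals the expectation has z = 0
  expect_equal((z_het$expected - z_het$loglik) / z_het$sd, z_het$z)
  expect_error(z_score(c(other = 1L), db, "A"), "no markers")
})

test_that("log-LR is antisymmetric, telescoping, and zero against itself", {
  set.seed(83)
  f <- make_freq_set(cbind(runif(30, .2, .8), runif(30, .2, .8),
                           runif(30, .2, .8)), pops = c("A", "B", "C"))
  db <- db_from_freqs(f)
  prof <- unclass(simulate_genotypes(f, "A", 1, seed = 84))[1, ]
  expect_equal(log_lr(prof, db, "A", "A")$log_lr, 0)
  ab <- log_lr(prof, db, "A", "B"); ba <- log_lr(prof, db, "B", "A")
  expect_equal(ab$log_lr, -ba$log_lr, tolerance = 1e-12)
  bc <- log_lr(prof, db, "B", "C"); ac <- log_lr(prof, db, "A", "C")
  expect_equal(ab$log_lr + bc$log_lr, ac$log_lr, tolerance = 1e-10)
  expect_gt(ab$se, 0)
})

test_that("mean log-LR grows with marker count (KL additivity)", {
  set.seed(85)
  m <- 120
  f <- make_freq_set(cbind(runif(m, .15, .85), runif(m, .15, .85)),
                     pops = c("A", "B"))
  db <- db_from_freqs(f)
  profs <- simulate_genotypes(f, "A", 150, seed = 86)
  lr_at <- function(mk) {
    mean(vapply(seq_len(nrow(profs)), function(i)
      log_lr(unclass(profs)[i, mk], db, "A", "B")$log_lr, numeric(1)))
  }
  mks <- rownames(f)
  lr30 <- lr_at(mks[1:30]); lr60 <- lr_at(mks[1:60]); lr120 <- lr_at(mks)
  expect_gt(lr60, lr30)
  expect_gt(lr120, lr60)
  expect_gt(lr30, 0)
})

test_that("classification follows the decision tree", {
  set.seed(87)
  m <- 150
  fA <- runif(m, .1, .9)
  # B well separated from A; C duplicates A exactly (indistinguishable)
  fB <- pmin(pmax(fA + sample(c(-1, 1), m, TRUE) * 0.35, 0.02), 0.98)
  f <- make_freq_set(cbind(fA, fB, fA), pops = c("A", "B", "C"))
  db <- db_from_freqs(f)
  profs <- simulate_genotypes(f, "A", 60, seed = 88)
  res <- lapply(seq_len(nrow(profs)), function(i)
    classify_profile(profs[i, , drop = FALSE], db))
  cats <- vapply(res, `[[`, character(1), "category")
  # A and its duplicate C are both accepted but rarely separable: Ambiguous
  expect_gt(mean(cats == "Ambiguous"), 0.8)
  # internal consistency: category re-derivable from the stored fields
  for (r in res[1:10]) {
    acc <- r$table$meta[r$table$z <= r$z_crit]
    if (length(acc) == 0) expect_equal(r$category, "Rejected")
    if (length(acc) == 1) expect_equal(r$category, "Accepted")
    if (length(acc) > 1) {
      best <- acc[which.max(r$table$loglik[match(acc, r$table$meta)])]
      # a zero SE (identical references) can never be significantly different
      sig <- all(vapply(setdiff(acc, best), function(k) {
        se <- r$log_lr_se[best, k]
        se > 0 && r$log_lr[best, k] / se > r$z_crit
      }, logical(1)))
      expect_equal(r$category, if (sig) "Accepted" else "Ambiguous")
    }
    # log-LR matrix antisymmetric when stored
    if (!is.null(r$log_lr)) {
      expect_equal(r$log_lr, -t(r$log_lr), tolerance = 1e-10)
    }
  }
  # single well-separated reference: Accepted; rejected profiles carry no LRs
  db2 <- db_from_freqs(make_freq_set(cbind(fA, fB), pops = c("A", "B")))
  r1 <- classify_profile(profs[1, , drop = FALSE], db2)
  expect_true(r1$category %in% c("Accepted", "Ambiguous"))
  # a profile from nowhere near either reference is Rejected with NULL LRs
  far <- make_profiles(matrix(ifelse(fA > 0.5, 0L, 2L), 1, m),
                       markers = rownames(f))
  r2 <- classify_profile(far, db2)
  expect_equal(r2$category, "Rejected")
  expect_null(r2$log_lr)
})

test_that("leave-one-out is necessary: including self deflates z", {
  set.seed(89)
  m <- 100; n <- 40
  f <- make_freq_set(matrix(runif(m, .2, .8), m, 1), pops = "A")
  profs <- simulate_genotypes(f, "A", n, seed = 90)
  db <- suppressWarnings(build_reference_db(profs, rep("A", n)))
  z_loo <- vapply(seq_len(n), function(i)
    z_score(unclass(profs)[i, ], db, "A", loo = TRUE)$z, numeric(1))
  z_in <- vapply(seq_len(n), function(i)
    z_score(unclass(profs)[i, ], db, "A", loo = FALSE)$z, numeric(1))
  # paired comparison: keeping the tested profile in its own reference
  # systematically shifts z downward (optimistic fit)
  expect_lt(mean(z_in - z_loo), 0)
  expect_gt(mean(z_in < z_loo), 0.8)
})

test_that("vectorized assignment agrees with the per-profile path", {
  set.seed(91)
  m <- 60
  f <- make_freq_set(cbind(runif(m, .2, .8), runif(m, .2, .8)),
                     pops = c("A", "B"))
  profs <- rbind(simulate_genotypes(f, "A", 15, seed = 92),
                 simulate_genotypes(f, "B", 15, seed = 93))
  profs <- make_profiles(profs, markers = rownames(f),
                         samples = paste0("s", 1:30))
  origin <- rep(c("A", "B"), each = 15)
  db <- suppressWarnings(build_reference_db(profs, origin))
  long <- assign_profiles(profs, db, origin = origin)
  for (i in c(1, 8, 20, 30)) {
    r <- classify_profile(profs[i, , drop = FALSE], db, origin = origin[i])
    rows <- long[long$sample == rownames(profs)[i], ]
    expect_equal(rows$z[match(r$table$meta, rows$meta)], r$table$z,
                 tolerance = 1e-10)
    expect_equal(unique(rows$overall), r$category)
  }
})

test_that("cross-validation cells close to 100% and flag indistinguishables", {
  set.seed(94)
  m <- 80
  fA <- runif(m, .2, .8)
  f <- make_freq_set(cbind(fA, fA), pops = c("A", "B"))  # B duplicates A
  profs <- rbind(simulate_genotypes(f, "A", 20, seed = 95),
                 simulate_genotypes(f, "B", 20, seed = 96))
  profs <- make_profiles(profs, markers = rownames(f),
                         samples = paste0("s", 1:40))
  origin <- rep(c("A", "B"), each = 20)
  db <- suppressWarnings(build_reference_db(profs, origin))
  cv <- cross_validate(profs, db, origin)
  expect_equal(cv$accepted_pct + cv$ambiguous_pct + cv$rejected_pct,
               rep(100, nrow(cv)), tolerance = 1e-9)
  own <- cv[cv$origin == cv$meta, ]
  # indistinguishable references: Ambiguous dominates, Accepted is rare
  expect_true(all(own$ambiguous_pct > own$accepted_pct))
  expect_error(cross_validate(profs, db, rep("X", 40)), "meta-population")
})

test_that("small references warn, undersized mapping errors are caught", {
  f <- make_freq_set(matrix(0.5, 5, 1), pops = "A")
  profs <- simulate_genotypes(f, "A", 10, seed = 97)
  expect_warning(build_reference_db(profs, rep("A", 10)), "below 75")
  expect_error(build_reference_db(profs, rep("A", 9)), "match profile rows")
})
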