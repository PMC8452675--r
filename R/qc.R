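# Genotype acceptance from per-nucleotide read counts: heterozygote balance,
# noise fraction, the two acceptance criteria sets, sample missingness filter,
# and duplicate-marker panel merging.

NUCS <- c("A", "C", "G", "T")

split_genotype <- function(gt) {
  # "AG" -> c("A","G"); "" / NA -> c(NA, NA)
  bad <- is.na(gt) | nchar(gt) != 2L
  a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 2L, 2L)
  a1[bad] <- NA_character_; a2[bad] <- NA_character_
  list(a1 = a1, a2 = a2, het = !bad & a1 != a2)
}

count_matrix <- function(records) {
  need <- paste0("reads_", NUCS)
  stop_if(!all(need %in% names(records)),
          paste("records must carry columns", paste(need, collapse = ", ")))
  m <- as.matrix(records[, need])
  colnames(m) <- NUCS
  storage.mode(m) <- "double"
  stop_if(any(!is.finite(m)) || any(m < 0), "read counts must be >= 0")
  m
}

#' Heterozygote balance (Hb)
#'
#' For a heterozygous call, the number of reads for one nucleotide divided by
#' the number of reads for the other, taking the nucleotides of the called
#' genotype in the order A, C, G, T (the alphabetically first nucleotide is
#' the numerator). Homozygous or missing calls get `NA` (the balance criteria
#' apply only to heterozygotes); a zero denominator yields `Inf`, which fails
#' every balance window downstream.
#'
#' @param records Read-count records: a `data.frame` with `reads_A` ..
#'   `reads_T` and `called_genotype` (e.g. from [simulate_read_counts()] or
#'   [read_genotyper_csv()]).
#' @return Numeric vector of balances (one per record).
#' @examples
#' heterozygote_balance(data.frame(reads_A = 100, reads_C = 0, reads_G = 50,
#'                                 reads_T = 0, called_genotype = "AG"))
#' @export
heterozygote_balance <- function(records) {
  cnt <- count_matrix(records)
  g <- split_genotype(records$called_genotype)
  hb <- rep(NA_real_, nrow(cnt))
  if (!any(g$het)) return(hb)
  i <- which(g$het)
  first <- pmin(g$a1[i], g$a2[i])
  second <- pmax(g$a1[i], g$a2[i])
  num <- cnt[cbind(i, match(first, NUCS))]
  den <- cnt[cbind(i, match(second, NUCS))]
  hb[i] <- ifelse(den == 0, Inf, num / den)
  hb
}

#' Noise fraction
#'
#' The number of reads different from the called genotype divided by the total
#' number of reads at the locus. `NA` when total depth is zero or the call is
#' missing.
#'
#' @inheritParams heterozygote_balance
#' @return Numeric vector of fractions in `[0,1]`.
#' @export
noise_fraction <- function(records) {
  cnt <- count_matrix(records)
  g <- split_genotype(records$called_genotype)
  depth <- rowSums(cnt)
  ingt <- cnt[cbind(seq_len(nrow(cnt)), match(g$a1, NUCS))]
  het <- g$het & !is.na(g$het)
  ingt[het] <- ingt[het] + cnt[cbind(which(het), match(g$a2[het], NUCS))]
  out <- (depth - ingt) / depth
  out[depth == 0 | is.na(g$a1)] <- NA_real_
  out
}

#' Apply the genotype acceptance criteria
#'
#' Two criteria sets decide whether the upstream caller's candidate genotype
#' is accepted: (1) read depth >= 45 and, for heterozygotes,
#' 0.3 <= Hb <= 3.0; (2) read depth 20 to 44 (inclusive), zero noise, and,
#' for heterozygotes, 0.7 <= Hb <= 1.3. Calls failing both are set to `NN`
#' (no data). All bounds are inclusive; "no noise" means a noise fraction of
#' exactly zero.
#'
#' @inheritParams heterozygote_balance
#' @param min_depth_1,min_depth_2,max_depth_2 Depth bounds of the two sets.
#' @param hb_window_1,hb_window_2 Heterozygote-balance windows (length-2).
#' @return A `data.frame` of genotype calls: `sample`, `marker`, `genotype`
#'   (`"NN"` when rejected), `depth`, `hb`, `noise`, `criteria_set` (1, 2 or
#'   `NA` when no rule fired).
#' @export
apply_acceptance_criteria <- function(records,
                                      min_depth_1 = 45L,
                                      min_depth_2 = 20L,
                                      max_depth_2 = 44L,
                                      hb_window_1 = c(0.3, 3.0),
                                      hb_window_2 = c(0.7, 1.3)) {
  cnt <- count_matrix(records)
  depth <- rowSums(cnt)
  hb <- heterozygote_balance(records)
  noise <- noise_fraction(records)
  g <- split_genotype(records$called_genotype)
  has_call <- !is.na(g$a1)
  hb_ok_1 <- !g$het | (!is.na(hb) & hb >= hb_window_1[1] & hb <= hb_window_1[2])
  hb_ok_2 <- !g$het | (!is.na(hb) & hb >= hb_window_2[1] & hb <= hb_window_2[2])
  crit1 <- has_call & depth >= min_depth_1 & hb_ok_1
  crit2 <- has_call & depth >= min_depth_2 & depth <= max_depth_2 &
    !is.na(noise) & noise == 0 & hb_ok_2
  set <- ifelse(crit1, 1L, ifelse(crit2, 2L, NA_integer_))
  genotype <- ifelse(is.na(set), "NN", as.character(records$called_genotype))
  data.frame(
    sample = records$sample,
    marker = records$marker,
    genotype = genotype,
    depth = as.integer(depth),
    hb = hb,
    noise = noise,
    criteria_set = set,
    stringsAsFactors = FALSE
  )
}

#' Assemble genotype calls into AIM profiles
#'
#' Turns a long genotype-call table into a dosage matrix (samples x markers)
#' against a panel definition. Dosage counts copies of the panel's allele 1;
#' `NN` and genotypes inconsistent with the panel alleles become `NA`.
#'
#' @param calls Output of [apply_acceptance_criteria()].
#' @param panel Panel definition with `marker`, `allele1`, `allele2`.
#' @return An `aim_profiles` dosage matrix with attribute `panel` (named
#'   character vector: panel provenance per marker).
#' @export
calls_to_profiles <- function(calls, panel) {
  markers <- panel$marker
  samples <- unique(calls$sample)
  d <- matrix(NA_integer_, nrow = length(samples), ncol = length(markers),
              dimnames = list(samples, markers))
  i <- match(calls$sample, samples)
  j <- match(calls$marker, markers)
  keep <- !is.na(j)
  a1 <- panel$allele1[j[keep]]; a2 <- panel$allele2[j[keep]]
  gt <- calls$genotype[keep]
  dos <- rep(NA_integer_, sum(keep))
  dos[gt == paste0(a1, a1)] <- 2L
  dos[gt == paste0(a2, a2)] <- 0L
  het <- gt == sort_pair(a1, a2)
  dos[het] <- 1L
  d[cbind(i[keep], j[keep])] <- dos
  out <- new_aim_profiles(d, markers, samples)
  attr(out, "panel") <- stats::setNames(as.character(panel$panel), markers)
  out
}

#' Missingness per profile
#'
#' @param profiles An `aim_profiles` dosage matrix.
#' @return Named numeric vector: fraction of markers with missing calls.
#' @export
missingness <- function(profiles) {
  rowMeans(is.na(unclass(profiles)))
}

#' Sample-level missingness filter
#'
#' Excludes every profile whose fraction of missing genotype calls is
#' strictly greater than `max_missing` (default 10%).
#'
#' @param profiles An `aim_profiles` dosage matrix.
#' @param max_missing Maximum tolerated missing fraction.
#' @return List with `retained` and `excluded` (`aim_profiles`) and `report`
#'   (`data.frame`: `sample`, `n_loci`, `n_missing`, `missing_fraction`,
#'   `excluded`).
#' @export
filter_samples <- function(profiles, max_missing = 0.10) {
  stop_if(nrow(profiles) == 0L, "no profiles supplied")
  miss <- missingness(profiles)
  excl <- miss > max_missing
  report <- data.frame(
    sample = rownames(profiles),
    n_loci = ncol(profiles),
    n_missing = as.integer(round(miss * ncol(profiles))),
    missing_fraction = miss,
    excluded = excl,
    row.names = NULL, stringsAsFactors = FALSE
  )
  keep_attr <- attr(profiles, "panel")
  sub <- function(idx) {
    out <- new_aim_profiles(unclass(profiles)[idx, , drop = FALSE],
                            colnames(profiles), rownames(profiles)[idx])
    attr(out, "panel") <- keep_attr
    out
  }
  list(retained = sub(which(!excl)), excluded = sub(which(excl)),
       report = report)
}

#' Merge panels with a duplicate-marker preference rule
#'
#' Combines per-panel profile matrices over the same samples into one profile
#' set. For markers typed in more than one panel the call from the preferred
#' panel is kept - even when it is `NN` - and the other panels' calls are
#' discarded. A duplicate marker without a preference entry is a configuration
#' error; nothing is chosen silently.
#'
#' @param profiles_by_panel Named list of `aim_profiles` (one per panel), all
#'   with identical sample sets.
#' @param preference Named character vector: duplicate marker -> panel whose
#'   call to keep.
#' @return An `aim_profiles` matrix over the union of markers, with panel
#'   provenance per marker in attribute `panel`.
#' @export
merge_panels <- function(profiles_by_panel, preference = character()) {
  stop_if(length(profiles_by_panel) < 1L, "no panels supplied")
  stop_if(is.null(names(profiles_by_panel)) ||
            any(names(profiles_by_panel) == ""),
          "profiles_by_panel must be a named list")
  samples <- rownames(profiles_by_panel[[1L]])
  for (p in profiles_by_panel) {
    stop_if(!identical(sort(rownames(p)), sort(samples)),
            "all panels must cover the same samples")
  }
  tab <- table(unlist(lapply(profiles_by_panel, colnames)))
  dups <- names(tab)[tab > 1L]
  missing_pref <- setdiff(dups, names(preference))
  stop_if(length(missing_pref) > 0L,
          paste("duplicate markers without a preference entry:",
                paste(missing_pref, collapse = ", ")))
  cols <- list(); prov <- character()
  for (panel_name in sort(names(profiles_by_panel))) {
    p <- profiles_by_panel[[panel_name]]
    p <- unclass(p)[samples, , drop = FALSE]
    for (mk in colnames(p)) {
      use <- !(mk %in% dups) || identical(unname(preference[mk]), panel_name)
      if (use) {
        cols[[mk]] <- p[, mk]
        prov[mk] <- panel_name
      }
    }
  }
  d <- do.call(cbind, cols)
  out <- new_aim_profiles(d, names(cols), samples)
  attr(out, "panel") <- prov
  out
}

#' Per-sample and per-locus QC summary
#'
#' @param calls Output of [apply_acceptance_criteria()].
#' @return List with `per_sample` (missingness) and `per_locus` (acceptance
#'   rate, dropouts, mean noise, mean |Hb - 1| over heterozygous accepted
#'   calls, mean locus balance = share of the sample's reads at the locus).
#' @export
qc_report <- function(calls) {
  acc <- calls$genotype != "NN"
  per_sample <- stats::aggregate(list(missing_fraction = !acc),
                                 by = list(sample = calls$sample), FUN = mean)
  depth_by_sample <- stats::ave(calls$depth, calls$sample, FUN = sum)
  lb <- ifelse(depth_by_sample > 0, calls$depth / depth_by_sample, NA_real_)
  hbdev <- ifelse(acc & !is.na(calls$hb) & is.finite(calls$hb),
                  abs(calls$hb - 1), NA_real_)
  per_locus <- do.call(rbind, lapply(split(seq_len(nrow(calls)), calls$marker),
    function(i) data.frame(
      marker = calls$marker[i[1L]],
      n = length(i),
      accepted_rate = mean(acc[i]),
      dropouts = sum(!acc[i]),
      mean_noise = mean(calls$noise[i], na.rm = TRUE),
      hb_deviation = if (all(is.na(hbdev[i]))) 0 else mean(hbdev[i], na.rm = TRUE),
      locus_balance = mean(lb[i], na.rm = TRUE),
      stringsAsFactors = FALSE)))
  rownames(per_locus) <- NULL
  list(per_sample = per_sample, per_locus = per_locus)
}
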