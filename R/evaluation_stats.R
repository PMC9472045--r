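# Evaluation statistics for annotation studies: label preprocessing
# (5-class to binary grouping, undetermined removal), unweighted Cohen
# kappa from the full contingency table, a paired Wilcoxon signed-rank
# timing comparison with an exact small-sample null, a learning-effect
# split, and table-style demographic summaries.

FIVE_CLASS <- c("normal", "borderline_mci", "mci", "borderline_dementia", "dementia")

#' Collapse 5-class adjudications to CN/CI
#'
#' The five ordinal adjudication classes (normal, borderline of normal and
#' MCI, MCI, borderline of MCI and dementia, dementia) are grouped so that
#' `normal` maps to CN and every other class to CI.
#'
#' @param labels character vector of 5-class labels; separators and case
#'   are normalised (e.g. "borderline-MCI" == "borderline_mci").
#' @return character vector over {CN, CI}.
#' @export
binarize_labels <- function(labels) {
  norm <- tolower(gsub("[ -]", "_", trimws(labels)))
  bad <- !norm %in% FIVE_CLASS
  if (any(bad)) {
    stop(sprintf("unknown adjudication class: %s",
                 paste(unique(labels[bad]), collapse = ", ")))
  }
  ifelse(norm == "normal", "CN", "CI")
}

#' Remove pairs the tool-side rater marked undetermined
#'
#' Undetermined patients have too little information in the record to be
#' compared against an external label set, so they are excluded before
#' computing agreement, with the exclusion count reported.
#'
#' @param labels_a tool-side labels (the side that may be undetermined).
#' @param labels_b comparison labels.
#' @return list(labels_a, labels_b, excluded).
#' @export
filter_undetermined <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  drop <- labels_a == "undetermined"
  list(labels_a = labels_a[!drop], labels_b = labels_b[!drop],
       excluded = sum(drop))
}

#' Cohen's kappa
#'
#' Unweighted chance-corrected agreement between two raters over nominal
#' labels: `po` is the observed agreement proportion, `pe` the agreement
#' expected from the marginal label frequencies, and
#' `kappa = (po - pe) / (1 - pe)`. When both raters use a single identical
#' category, `pe = 1` and kappa is undefined (flagged, not an error).
#'
#' @param labels_a,labels_b equal-length label vectors (rater A rows,
#'   rater B columns of the contingency table).
#' @param drop_undetermined apply [filter_undetermined()] on side A first.
#' @return list of class `kappa_result`: po, pe, kappa, kappa_defined, n,
#'   excluded_undetermined, table (contingency matrix).
#' @export
cohen_kappa <- function(labels_a, labels_b, drop_undetermined = FALSE) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  excluded <- 0L
  if (drop_undetermined) {
    f <- filter_undetermined(labels_a, labels_b)
    labels_a <- f$labels_a
    labels_b <- f$labels_b
    excluded <- f$excluded
  }
  n <- length(labels_a)
  if (n == 0L) stop("no label pairs to compare")
  cats <- sort(unique(c(labels_a, labels_b)))
  tab <- table(factor(labels_a, levels = cats), factor(labels_b, levels = cats))
  tab <- unclass(tab)
  po <- sum(diag(tab)) / n
  pe <- sum((rowSums(tab) / n) * (colSums(tab) / n))
  defined <- abs(1 - pe) > .Machine$double.eps^0.5
  kappa <- if (defined) (po - pe) / (1 - pe) else NA_real_
  structure(list(po = po, pe = pe, kappa = kappa, kappa_defined = defined,
                 n = n, excluded_undetermined = excluded, table = tab),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen kappa: %s (po = %.4f, pe = %.4f, n = %d%s)\n",
              if (x$kappa_defined) sprintf("%.4f", x$kappa) else "undefined",
              x$po, x$pe, x$n,
              if (x$excluded_undetermined)
                sprintf(", %d undetermined excluded", x$excluded_undetermined) else ""))
  print(x$table)
  invisible(x)
}

# Exact null distribution of the signed-rank statistic W for given absolute
# -difference ranks, by convolution: equivalent to enumerating all 2^n sign
# assignments. Ranks may be half-integers under average-rank ties, so the
# support is indexed on doubled ranks.
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  probs <- numeric(total + 1L)  # index k+1 <-> doubled statistic k
  probs[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), probs[seq_len(total + 1L - r)])
    probs <- (probs + shifted) / 2
  }
  probs
}

exact_signed_rank_p <- function(W, ranks) {
  probs <- signed_rank_null(ranks)
  w2 <- round(2 * W)
  idx <- seq_along(probs) - 1L
  p_le <- sum(probs[idx <= w2])
  p_ge <- sum(probs[idx >= w2])
  min(1, 2 * min(p_le, p_ge))
}

#' Paired Wilcoxon signed-rank timing comparison
#'
#' Compares paired per-patient adjudication times. Differences
#' `d = times_a - times_b` are formed; zero differences are dropped
#' (classical discard rule, count reported); absolute differences are
#' ranked with average ranks for ties; `W` is the sum of ranks of positive
#' differences. The two-sided p-value is exact (full sign-assignment null,
#' computed by convolution) when at most `exact_limit` nonzero differences
#' remain, otherwise a normal approximation with tie and continuity
#' corrections is used. Also reports the mean and SD of the differences
#' (all pairs, zeros included) and the median/min/max of the ratios
#' `times_a / times_b`.
#'
#' @param times_a,times_b equal-length vectors of positive minutes.
#' @param exact_limit largest nonzero-pair count for the exact null.
#' @return list of class `timing_result`.
#' @export
paired_timing_test <- function(times_a, times_b, exact_limit = 25L) {
  if (length(times_a) != length(times_b) || !length(times_a)) {
    stop("times_a and times_b must be equal-length, nonempty vectors")
  }
  d <- times_a - times_b
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  ratios <- if (all(times_b > 0)) times_a / times_b else rep(NA_real_, length(d))
  nz <- d != 0
  n_zero <- sum(!nz)
  dd <- d[nz]
  n <- length(dd)
  if (n == 0L) {
    res <- list(n = length(d), n_zero_dropped = n_zero, W = NA_real_,
                p_value = NA_real_, p_defined = FALSE, method = "none",
                message = "all paired differences are zero")
  } else {
    r <- rank(abs(dd))
    W <- sum(r[dd > 0])
    if (n <= exact_limit) {
      p <- exact_signed_rank_p(W, r)
      method <- "exact"
    } else {
      mu <- n * (n + 1) / 4
      ties <- table(r)
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
      method <- "normal_approx"
    }
    res <- list(n = length(d), n_zero_dropped = n_zero, W = W,
                p_value = max(p, .Machine$double.xmin), p_defined = TRUE,
                method = method, message = NULL)
  }
  res$mean_diff <- mean_diff
  res$sd_diff <- sd_diff
  res$median_ratio <- stats::median(ratios)
  res$min_ratio <- min(ratios)
  res$max_ratio <- max(ratios)
  structure(res, class = "timing_result")
}

#' @export
print.timing_result <- function(x, ...) {
  cat(sprintf("Paired Wilcoxon signed-rank (%s): n = %d (%d zero dropped)\n",
              x$method, x$n, x$n_zero_dropped))
  if (x$p_defined) {
    cat(sprintf("  W = %.1f, two-sided p = %.4g\n", x$W, x$p_value))
  } else {
    cat(sprintf("  p undefined: %s\n", x$message))
  }
  cat(sprintf("  diff mean %.2f (SD %.2f) min; ratio median %.2f, min-max %.2f-%.2f\n",
              x$mean_diff, x$sd_diff, x$median_ratio, x$min_ratio, x$max_ratio))
  invisible(x)
}

#' Learning-effect analysis
#'
#' Splits one annotator's chronologically ordered adjudication durations at
#' the midpoint (odd counts put the extra patient in the first half) and
#' compares the halves with a two-sided rank-sum test: a shorter second
#' half indicates growing familiarity with the tool.
#'
#' @param durations chronologically ordered durations in minutes (>= 4).
#' @return list with per-half medians and sizes and the rank-sum p-value.
#' @export
learning_effect <- function(durations) {
  n <- length(durations)
  if (n < 4L) stop("learning_effect requires at least 4 timed annotations")
  cut <- ceiling(n / 2)
  first <- durations[seq_len(cut)]
  second <- durations[(cut + 1L):n]
  p <- suppressWarnings(
    stats::wilcox.test(first, second, exact = FALSE, correct = TRUE)$p.value
  )
  if (is.nan(p)) p <- 1  # identical constant halves: no evidence of change
  list(n_first = length(first), n_second = length(second),
       median_first = stats::median(first), median_second = stats::median(second),
       p_value = p)
}

pct_cell <- function(count, n) {
  list(count = count, percent = round_half_up(100 * count / n, 1))
}

#' Cohort demographic summary
#'
#' Table-style cohort characteristics: sex, racial/ethnic minority groups
#' with their total, college education, marital status, age mean (SD),
#' encounter count median (min-max), primary-care-provider coverage, and
#' structured dementia evidence (ICD code or medication). Percents use the
#' full cohort size as denominator (missing values are excluded from
#' numerators only) and are rounded half-up to one decimal. Missing counts
#' are reported separately.
#'
#' @param charts list of `patient_chart` objects for the cohort.
#' @return list of class `demographic_summary`.
#' @export
demographic_summary <- function(charts) {
  if (!length(charts)) stop("cannot summarise an empty cohort")
  pats <- do.call(rbind, c(lapply(charts, function(ch) ch$patient),
                           make.row.names = FALSE))
  n <- nrow(pats)
  age <- vapply(charts, function(ch) {
    ref <- if (!is.na(ch$period_end)) ch$period_end else Sys.Date()
    as.numeric(ref - ch$patient$birth_date) / 365.25
  }, 0)
  n_enc <- vapply(charts, function(ch) nrow(ch$encounters), 0L)
  dementia <- vapply(charts, function(ch) {
    flag_dementia_icd(ch$diagnoses)$flag || flag_dementia_medications(ch$medications)$flag
  }, NA)
  minority_groups <- c("black", "hispanic", "asian", "indigenous")
  minorities <- lapply(minority_groups, function(g) pct_cell(sum(pats$ethnic_group == g), n))
  names(minorities) <- minority_groups
  structure(list(
    n = n,
    sex = list(male = pct_cell(sum(pats$sex == "male"), n),
               female = pct_cell(sum(pats$sex == "female"), n)),
    age = list(mean = mean(age), sd = stats::sd(age)),
    minorities = minorities,
    minority_total = pct_cell(sum(pats$ethnic_group %in% minority_groups), n),
    college = pct_cell(sum(pats$education == "college_or_more"), n),
    married = pct_cell(sum(pats$marital_status == "married"), n),
    encounters = list(median = stats::median(n_enc), min = min(n_enc), max = max(n_enc)),
    pcp = pct_cell(sum(!is.na(pats$pcp_id)), n),
    dementia_structured = pct_cell(sum(dementia), n),
    missing = list(sex = sum(pats$sex == "missing"),
                   ethnic_group = sum(pats$ethnic_group == "missing"),
                   education = sum(pats$education == "missing"),
                   marital_status = sum(pats$marital_status == "missing"))
  ), class = "demographic_summary")
}

#' @export
print.demographic_summary <- function(x, ...) {
  fmt <- function(cell) sprintf("%d (%.1f)", cell$count, cell$percent)
  cat(sprintf("Cohort (N = %d)\n", x$n))
  cat(sprintf("  Male %s, Female %s\n", fmt(x$sex$male), fmt(x$sex$female)))
  cat(sprintf("  Age mean %.1f (SD %.1f)\n", x$age$mean, x$age$sd))
  for (g in names(x$minorities)) cat(sprintf("  %s %s\n", g, fmt(x$minorities[[g]])))
  cat(sprintf("  Minorities (total) %s\n", fmt(x$minority_total)))
  cat(sprintf("  College education %s; Married %s\n", fmt(x$college), fmt(x$married)))
  cat(sprintf("  Encounters median %g (%g-%g)\n", x$encounters$median,
              x$encounters$min, x$encounters$max))
  cat(sprintf("  PCP %s; Dementia ICD code or medication %s\n",
              fmt(x$pcp), fmt(x$dementia_structured)))
  invisible(x)
}
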