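#' Percent prepulse inhibition
#'
#' `%PPI = 100 * (1 - PP/P)`: the percent reduction of the prepulse+pulse
#' response relative to the pulse-alone response. Positive values indicate
#' inhibition, negative values facilitation; the value is undefined (NA) when
#' the pulse-alone amplitude is not positive, and is never larger than 100.
#'
#' @param p_amp pulse-alone amplitude (uV).
#' @param pp_amp prepulse+pulse amplitude (uV). Vectorised.
#' @return Percent PPI, `NA_real_` where `p_amp <= 0`.
#' @export
#' @examples
#' percent_ppi(10, 5)    # 50
#' percent_ppi(10, 12)   # -20, facilitation
percent_ppi <- function(p_amp, pp_amp) {
  out <- 100 * (1 - pp_amp / p_amp)
  out[p_amp <= 0] <- NA_real_
  out
}

#' Per-subject PPI table for one modality
#'
#' Converts condition amplitudes into the three interval %PPI values.
#'
#' @param amplitudes named numeric vector with elements `P`, `P30`, `P60`,
#'   `P120` (uV; ASR or P2-N1).
#' @return Named numeric vector `PPI30`, `PPI60`, `PPI120`.
#' @export
ppi_from_amplitudes <- function(amplitudes) {
  p <- amplitudes[["P"]]
  c(PPI30 = unname(percent_ppi(p, amplitudes[["P30"]])),
    PPI60 = unname(percent_ppi(p, amplitudes[["P60"]])),
    PPI120 = unname(percent_ppi(p, amplitudes[["P120"]])))
}

#' Omnibus repeated-measures condition test with a normality gate
#'
#' Each condition column is tested for normality (Shapiro-Wilk, alpha 0.05).
#' If every column passes, a repeated-measures ANOVA
#' (`aov(value ~ condition + Error(subject/condition))`) is run; otherwise the
#' Friedman rank test. Constant columns count as non-normal. Only complete
#' cases enter the test.
#'
#' @param values numeric matrix, subjects x conditions (column names kept in
#'   the report).
#' @param alpha normality-gate alpha (default 0.05).
#' @return List of class `ppi_stat`: `test` ("rm_anova" or "friedman"),
#'   `statistic`, `df`, `p_value`, `normal` (per-condition gate outcome),
#'   `n_subjects`.
#' @export
omnibus_condition_test <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  if (nrow(values) < 3) stop("need at least 3 complete subjects", call. = FALSE)
  if (ncol(values) < 2) stop("need at least 2 conditions", call. = FALSE)
  normal <- apply(values, 2, function(x) {
    if (stats::sd(x) < 1e-12) return(FALSE)
    stats::shapiro.test(x)$p.value > alpha
  })
  if (all(normal)) {
    long <- data.frame(
      y = as.vector(values),
      condition = factor(rep(colnames(values), each = nrow(values)),
                         levels = colnames(values)),
      subject = factor(rep(seq_len(nrow(values)), ncol(values)))
    )
    fit <- stats::aov(y ~ condition + Error(subject / condition), data = long)
    tab <- summary(fit)[["Error: subject:condition"]][[1]]
    res <- list(test = "rm_anova",
                statistic = tab["condition", "F value"],
                df = c(tab["condition", "Df"], tab["Residuals", "Df"]),
                p_value = tab["condition", "Pr(>F)"])
  } else if (all(apply(values, 1, function(r) diff(range(r)) == 0))) {
    # every subject flat across conditions: the rank test carries no evidence
    # (the tie-corrected statistic is 0/0); report 0 with p = 1
    res <- list(test = "friedman", statistic = 0,
                df = ncol(values) - 1, p_value = 1)
  } else {
    ft <- stats::friedman.test(values)
    res <- list(test = "friedman",
                statistic = unname(ft$statistic),
                df = unname(ft$parameter),
                p_value = ft$p.value)
  }
  structure(c(res, list(normal = normal, n_subjects = nrow(values))),
            class = "ppi_stat")
}

#' @export
print.ppi_stat <- function(x, ...) {
  dfs <- paste(x$df, collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (n = %d)\n",
              x$test, x$statistic, dfs, x$p_value, x$n_subjects))
  invisible(x)
}

#' Pairwise post-hoc comparisons
#'
#' Parametric: Tukey HSD on the condition factor of a randomized-block fit
#' (`aov(value ~ condition + subject)`). Nonparametric: paired two-sided
#' Wilcoxon signed-rank tests per pair with Bonferroni multiplication by the
#' number of pairs tested (capped at 1); an all-ties pair yields p = 1 with a
#' warning. Intended to follow a significant omnibus test.
#'
#' @param values numeric matrix, subjects x conditions.
#' @param parametric use Tukey (`TRUE`) or Wilcoxon-Bonferroni (`FALSE`).
#' @param pairs 2-row character matrix of condition pairs, or `"all"` for
#'   every pair, or `"vs_first"` for the first column against each other.
#' @return data.frame: `a`, `b`, `p_value`, `adjustment`.
#' @export
posthoc_pairwise <- function(values, parametric,
                             pairs = "all") {
  values <- as.matrix(values)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  cn <- colnames(values)
  pr <- if (identical(pairs, "all")) {
    utils::combn(cn, 2)
  } else if (identical(pairs, "vs_first")) {
    rbind(cn[1], cn[-1])
  } else {
    pairs
  }
  if (parametric) {
    long <- data.frame(
      y = as.vector(values),
      condition = factor(rep(cn, each = nrow(values)), levels = cn),
      subject = factor(rep(seq_len(nrow(values)), ncol(values)))
    )
    fit <- stats::aov(y ~ condition + subject, data = long)
    tk <- stats::TukeyHSD(fit, "condition")$condition
    p <- vapply(seq_len(ncol(pr)), function(i) {
      key <- paste(pr[2, i], pr[1, i], sep = "-")
      alt <- paste(pr[1, i], pr[2, i], sep = "-")
      if (key %in% rownames(tk)) tk[key, "p adj"] else tk[alt, "p adj"]
    }, 0)
    adj <- "tukey"
  } else {
    m <- ncol(pr)
    p <- vapply(seq_len(ncol(pr)), function(i) {
      d <- values[, pr[1, i]] - values[, pr[2, i]]
      if (all(d == 0)) {
        warning("all paired differences tied for ", pr[1, i], " vs ", pr[2, i],
                "; p set to 1", call. = FALSE)
        return(1)
      }
      suppressWarnings(
        stats::wilcox.test(values[, pr[1, i]], values[, pr[2, i]],
                           paired = TRUE)$p.value)
    }, 0)
    p <- pmin(p * m, 1)
    adj <- "bonferroni"
  }
  data.frame(a = pr[1, ], b = pr[2, ], p_value = p, adjustment = adj,
             stringsAsFactors = FALSE)
}

#' Kendall correlation between muscular and neural %PPI
#'
#' Kendall tau-b (two-sided) between the ASR %PPI and each electrode's P2-N1
#' %PPI, per prepulse interval: nine correlations for the Fz/Cz/Pz montage.
#' Constant vectors give an undefined tau, reported as NA.
#'
#' @param ppi data.frame with columns `subject`, `modality` (`"ASR"` or an
#'   electrode name), `interval` (`PPI30`/`PPI60`/`PPI120`), `ppi`.
#' @param electrodes electrode modalities to correlate with ASR.
#' @return data.frame: `electrode`, `interval`, `tau`, `p_value`, `n`.
#' @export
cross_modality_correlation <- function(ppi, electrodes = c("Fz", "Cz", "Pz")) {
  rows <- list()
  for (el in electrodes) {
    for (iv in c("PPI30", "PPI60", "PPI120")) {
      a <- ppi[ppi$modality == "ASR" & ppi$interval == iv, c("subject", "ppi")]
      b <- ppi[ppi$modality == el & ppi$interval == iv, c("subject", "ppi")]
      mg <- merge(a, b, by = "subject")
      mg <- mg[stats::complete.cases(mg), , drop = FALSE]
      tau <- p <- NA_real_
      if (nrow(mg) >= 5 && stats::sd(mg$ppi.x) > 0 && stats::sd(mg$ppi.y) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(mg$ppi.x, mg$ppi.y, method = "kendall"))
        tau <- unname(ct$estimate)
        p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        electrode = el, interval = iv, tau = tau, p_value = p, n = nrow(mg),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Full statistical battery for a group PPI table
#'
#' For each modality: the omnibus condition test on the four amplitudes, the
#' omnibus test on the three %PPI values, and — when an omnibus test is
#' significant — the matching post hocs (amplitudes: pulse-alone against each
#' prepulse condition; %PPI: all three interval pairs), parametric or
#' nonparametric as chosen by the normality gate. Cross-modality Kendall
#' correlations complete the report.
#'
#' @param ppi_table data.frame with columns `subject`, `modality`, `condition`
#'   (P/P30/P60/P120), `amplitude`, plus %PPI columns handled internally.
#' @param alpha omnibus significance level gating the post hocs.
#' @return List of class `ppi_report` with one entry per modality
#'   (`amplitude_test`, `ppi_test`, `amplitude_posthoc`, `ppi_posthoc`,
#'   `amplitude_mean`, `ppi_mean`) plus `kendall`.
#' @export
ppi_statistics <- function(ppi_table, alpha = 0.05) {
  out <- list()
  long_ppi <- list()
  for (mod in unique(ppi_table$modality)) {
    sub <- ppi_table[ppi_table$modality == mod, , drop = FALSE]
    amp <- stats::reshape(sub[, c("subject", "condition", "amplitude")],
                          idvar = "subject", timevar = "condition",
                          direction = "wide")
    amp_m <- as.matrix(amp[, paste0("amplitude.", ppi_conditions())])
    colnames(amp_m) <- ppi_conditions()
    ppi_m <- t(apply(amp_m, 1, ppi_from_amplitudes))
    entry <- list(
      amplitude_mean = colMeans(amp_m, na.rm = TRUE),
      amplitude_se = apply(amp_m, 2, stats::sd, na.rm = TRUE) /
        sqrt(colSums(!is.na(amp_m))),
      ppi_mean = colMeans(ppi_m, na.rm = TRUE),
      ppi_se = apply(ppi_m, 2, stats::sd, na.rm = TRUE) /
        sqrt(colSums(!is.na(ppi_m))),
      amplitude_test = omnibus_condition_test(amp_m),
      ppi_test = omnibus_condition_test(ppi_m)
    )
    if (entry$amplitude_test$p_value < alpha) {
      entry$amplitude_posthoc <- posthoc_pairwise(
        amp_m, parametric = entry$amplitude_test$test == "rm_anova",
        pairs = "vs_first")
    }
    if (entry$ppi_test$p_value < alpha) {
      entry$ppi_posthoc <- posthoc_pairwise(
        ppi_m, parametric = entry$ppi_test$test == "rm_anova", pairs = "all")
    }
    out[[mod]] <- entry
    for (iv in colnames(ppi_m)) {
      long_ppi[[length(long_ppi) + 1L]] <- data.frame(
        subject = amp$subject, modality = mod, interval = iv,
        ppi = ppi_m[, iv], stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, long_ppi)
  if ("ASR" %in% unique(ppi_table$modality)) {
    out$kendall <- cross_modality_correlation(
      long, electrodes = setdiff(unique(ppi_table$modality), "ASR"))
  }
  structure(out, class = "ppi_report")
}
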