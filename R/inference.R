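#' Two-sample Mann-Whitney test with a fixed reporting convention
#'
#' Sorting-task scores are bounded, discrete and usually far from normal, so
#' group contrasts use the rank-based Mann-Whitney test. The reported
#' statistic is U for the first-named sample: the rank sum of `a` (midranks
#' for ties) minus `n_a(n_a+1)/2`. Z standardises U under the null with the
#' tie-corrected variance and no continuity correction, so the effect size
#' `r = |Z|/sqrt(N)` is on the same footing for exact and asymptotic p-values.
#'
#' The exact method computes the permutation null distribution of the rank
#' sum over all `choose(N, n_a)` group reassignments (midranks kept, so ties
#' are handled exactly) via a subset-sum count recursion, and reports the
#' two-sided p as the probability of a rank sum at least as far from its null
#' expectation as the observed one. The asymptotic method uses the normal
#' approximation. By default the exact method is used for `n_a + n_b <= 20`
#' when there are no ties, the asymptotic otherwise.
#'
#' If all values in both samples are identical the statistic is degenerate:
#' Z is defined as 0, p as 1, and the result is flagged.
#'
#' @param a,b numeric samples (first-named group is `a`).
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @return A list of class `mw_test`: `U`, `Z`, `p_value`, `method`, `n_a`,
#'   `n_b`, `degenerate`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6), method = "exact")  # U = 0, p = 0.1
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (anyNA(a) || anyNA(b)) stop("NA values in samples")
  na <- length(a); nb <- length(b); n <- na + nb
  if (na < 1 || nb < 1) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  ties <- any(duplicated(c(a, b)))
  ra <- sum(r[seq_len(na)])
  U <- ra - na * (na + 1) / 2
  mu <- na * nb / 2
  tie_tab <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(structure(list(U = U, Z = 0, p_value = 1, method = "degenerate",
                          n_a = na, n_b = nb, degenerate = TRUE),
                     class = "mw_test"))
  }
  Z <- (U - mu) / sqrt(sigma2)
  if (method == "auto") method <- if (n <= 20 && !ties) "exact" else "asymptotic"
  p <- if (method == "exact") {
    exact_ranksum_p(r, na)
  } else {
    2 * stats::pnorm(-abs(Z))
  }
  structure(list(U = U, Z = Z, p_value = min(p, 1), method = method,
                 n_a = na, n_b = nb, degenerate = FALSE),
            class = "mw_test")
}

# Exact two-sided permutation p for the rank sum of the first na ranks.
# Midranks are doubled to integers; the null distribution of the group-a
# rank sum over all choose(n, na) reassignments is counted by a subset-sum
# recursion. p = P(|S - E S| >= |s_obs - E S|).
exact_ranksum_p <- function(r, na) {
  n <- length(r)
  total <- choose(n, na)
  if (total > 2^52)
    stop("exact method infeasible for these sample sizes; use method = \"asymptotic\"")
  w <- as.integer(round(2 * r))
  smax <- sum(w)
  # f[j + 1, s + 1] = number of size-j subsets of w with sum s
  f <- matrix(0, na + 1, smax + 1)
  f[1, 1] <- 1
  done <- 0L
  for (x in w) {
    for (j in seq(min(na, done + 1L), 1)) {
      idx <- seq_len(smax + 1 - x)
      f[j + 1, idx + x] <- f[j + 1, idx + x] + f[j, idx]
    }
    done <- done + 1L
  }
  counts <- f[na + 1, ]
  svals <- 0:smax
  mu_s <- na * sum(w) / n
  obs <- sum(w[seq_len(na)])
  keep <- abs(svals - mu_s) >= abs(obs - mu_s) - 1e-9
  sum(counts[keep]) / total
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): U = %g, Z = %.3f, p = %.4g (n = %d vs %d)\n",
              x$method, x$U, x$Z, x$p_value, x$n_a, x$n_b))
  if (x$degenerate) cat("  note: all values identical; statistic degenerate\n")
  invisible(x)
}

#' Rank effect size r and its conventional magnitude bands
#'
#' `effect_size_r()` is the standardised-statistic effect size
#' `r = |Z| / sqrt(N)` for a two-sample rank test with `N = n_a + n_b`.
#' `classify_effect_size()` applies the conventional bands: below 0.1
#' negligible, 0.1 to 0.3 small, 0.3 to 0.5 medium, 0.5 and above large.
#'
#' @param Z standardised test statistic.
#' @param n_total total sample size across both groups (>= 2).
#' @return `effect_size_r()` a non-negative number; `classify_effect_size()`
#'   one of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @examples
#' classify_effect_size(effect_size_r(-3.2, 64))
#' @export
effect_size_r <- function(Z, n_total) {
  if (n_total < 2) stop("`n_total` must be >= 2")
  abs(Z) / sqrt(n_total)
}

#' @rdname effect_size_r
#' @param r effect size (>= 0).
#' @export
classify_effect_size <- function(r) {
  if (any(r < 0)) stop("`r` must be >= 0")
  as.character(cut(r, breaks = c(-Inf, 0.1, 0.3, 0.5, Inf), right = FALSE,
                   labels = c("negligible", "small", "medium", "large")))
}

#' Bonferroni-adjusted alpha
#'
#' Family-wise alpha divided by the number of comparisons; the study design
#' makes four pairwise comparisons per dependent variable, so the default
#' plan tests at 0.05 / 4 = 0.0125.
#'
#' @param family_alpha family-wise error rate.
#' @param m number of comparisons (>= 1).
#' @return adjusted per-comparison alpha.
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  if (m < 1) stop("`m` must be >= 1")
  family_alpha / m
}

#' The planned group contrasts
#'
#' Four pairwise contrasts per dependent variable: two talker-familiarity
#' effects (THI vs TLO at each accent level) and two accent-familiarity
#' effects (AHI vs ALO at each talker level), applied to each of the three
#' dependent measures — 12 tests in all, each judged at
#' `family_alpha / 4 = 0.0125` by default.
#'
#' @param dvs dependent variables to test.
#' @param family_alpha family-wise alpha per dependent variable.
#' @return A list of class `contrast_plan` with elements `contrasts` (data
#'   frame `type,group_a,group_b`), `dvs`, `family_alpha`, `m`,
#'   `alpha_adjusted`.
#' @export
contrast_plan <- function(dvs = c("n_clusters", "telling_together", "telling_apart"),
                          family_alpha = 0.05) {
  contrasts <- data.frame(
    type = c("talker", "talker", "accent", "accent"),
    group_a = c("THI_AHI", "THI_ALO", "THI_AHI", "TLO_AHI"),
    group_b = c("TLO_AHI", "TLO_ALO", "THI_ALO", "TLO_ALO"),
    stringsAsFactors = FALSE
  )
  m <- nrow(contrasts)
  structure(list(contrasts = contrasts, dvs = dvs, family_alpha = family_alpha,
                 m = m, alpha_adjusted = bonferroni_alpha(family_alpha, m)),
            class = "contrast_plan")
}

#' Run the planned pairwise group contrasts
#'
#' For every dependent variable and planned contrast, runs [mann_whitney()]
#' between the two groups, attaches the effect size r with its magnitude
#' class, per-group medians and ranges, and flags significance at the
#' Bonferroni-adjusted alpha. A contrast whose groups are not both non-empty
#' is reported with `NA` statistics and a message rather than run.
#'
#' @param scores a [score_cohort()] data frame (QC-retained participants).
#' @param plan a [contrast_plan()].
#' @param method passed to [mann_whitney()].
#' @return A data frame of class `group_comparisons`, one row per (dv,
#'   contrast), with columns `dv`, `type`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `U`, `Z`, `p_value`, `r`, `r_class`, `significant`, `median_a`,
#'   `median_b`, `min_a`, `max_a`, `min_b`, `max_b`; the adjusted alpha and
#'   plan are kept as attributes.
#' @export
compare_groups <- function(scores, plan = contrast_plan(), method = "auto") {
  grp <- group_code(scores$talker_familiarity, scores$accent_familiarity)
  alpha <- plan$alpha_adjusted
  rows <- list()
  for (dv in plan$dvs) {
    for (i in seq_len(nrow(plan$contrasts))) {
      ga <- plan$contrasts$group_a[i]; gb <- plan$contrasts$group_b[i]
      xa <- scores[[dv]][grp == ga]; xb <- scores[[dv]][grp == gb]
      row <- data.frame(dv = dv, type = plan$contrasts$type[i],
                        group_a = ga, group_b = gb,
                        n_a = length(xa), n_b = length(xb),
                        U = NA_real_, Z = NA_real_, p_value = NA_real_,
                        r = NA_real_, r_class = NA_character_,
                        significant = NA,
                        median_a = NA_real_, median_b = NA_real_,
                        min_a = NA_real_, max_a = NA_real_,
                        min_b = NA_real_, max_b = NA_real_,
                        stringsAsFactors = FALSE)
      if (length(xa) == 0 || length(xb) == 0) {
        message(sprintf("contrast %s vs %s on %s skipped: empty group",
                        ga, gb, dv))
      } else {
        tst <- mann_whitney(xa, xb, method = method)
        r <- effect_size_r(tst$Z, tst$n_a + tst$n_b)
        row$U <- tst$U; row$Z <- tst$Z; row$p_value <- tst$p_value
        row$r <- r; row$r_class <- classify_effect_size(r)
        row$significant <- tst$p_value < alpha
        row$median_a <- stats::median(xa); row$median_b <- stats::median(xb)
        row$min_a <- min(xa); row$max_a <- max(xa)
        row$min_b <- min(xb); row$max_b <- max(xb)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha_adjusted") <- alpha
  attr(out, "plan") <- plan
  class(out) <- c("group_comparisons", "data.frame")
  out
}

#' @export
print.group_comparisons <- function(x, digits = 3, ...) {
  cat(sprintf("Planned pairwise contrasts (%d tests, adjusted alpha = %g)\n",
              nrow(x), attr(x, "alpha_adjusted")))
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, digits)
  df$Z <- round(df$Z, digits)
  df$r <- round(df$r, digits)
  df$sig <- ifelse(is.na(df$significant), "?", ifelse(df$significant, "*", ""))
  print.data.frame(df[c("dv", "type", "group_a", "group_b", "U", "Z",
                        "p_value", "r", "r_class", "sig")], row.names = FALSE)
  invisible(x)
}

#' Export the comparison report
#'
#' @param comparisons a [compare_groups()] result.
#' @param path output path; `write_comparisons_json()` writes the records plus
#'   the adjusted alpha, `write_comparisons_csv()` a flat CSV with 6-decimal
#'   floats.
#' @export
write_comparisons_json <- function(comparisons, path) {
  jsonlite::write_json(
    list(alpha_adjusted = attr(comparisons, "alpha_adjusted"),
         comparisons = as.data.frame(comparisons)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_comparisons_json
#' @export
write_comparisons_csv <- function(comparisons, path) {
  out <- as.data.frame(comparisons)
  for (v in c("Z", "p_value", "r", "median_a", "median_b",
              "min_a", "max_a", "min_b", "max_b"))
    out[[v]] <- formatC(out[[v]], format = "f", digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
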