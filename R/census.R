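#' Per-line count summary
#'
#' Summarises per-animal nucleus counts of one genetic line and sex the way
#' census results are reported: mean count, coefficient of variation in
#' percent (sample SD / mean x 100) and number of animals.
#'
#' @param counts numeric vector of per-animal counts (n >= 1).
#' @param line genetic line label.
#' @param sex sex label.
#' @return a list of class `census_line_summary` with `line`, `sex`,
#'   `mean_count`, `cv_percent`, `n_animals`. A single animal gives
#'   `cv_percent = 0` with a warning (SD undefined).
#' @examples
#' line_summary(c(9888, 10100, 9700), "brp", "male")
#' @export
line_summary <- function(counts, line = "unknown", sex = "unknown") {
  if (!length(counts)) stop("`counts` must be non-empty")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  m <- mean(counts)
  cv <- if (length(counts) == 1) {
    warning("single animal: CV reported as 0", call. = FALSE)
    0
  } else if (m == 0) {
    0
  } else {
    100 * stats::sd(counts) / m
  }
  structure(
    list(
      line = as.character(line), sex = parse_sex(sex),
      mean_count = m, cv_percent = cv, n_animals = length(counts)
    ),
    class = "census_line_summary"
  )
}

#' @export
print.census_line_summary <- function(x, ...) {
  cat(sprintf(
    "%s (%s): %s (+/-%.2f%%, n=%d)\n",
    x$line, x$sex, format(round(x$mean_count), big.mark = ","),
    x$cv_percent, x$n_animals
  ))
  invisible(x)
}

#' Sample-size-weighted mean across line summaries
#'
#' Pools the mean counts of several lines of the *same* sex, weighting each
#' line by its number of animals: `sum(mean_i * n_i) / sum(n_i)`. This is
#' how "all neurons" counts are averaged across reporter lines.
#'
#' @param summaries list of [line_summary()] objects (or a data frame with
#'   columns `mean_count`, `n_animals`, `sex`), all of one sex.
#' @return the pooled mean (unrounded).
#' @examples
#' # female neuron lines: pooled mean 10312 (n = 16)
#' weighted_mean_count(list(
#'   line_summary_values(10776, 2.65, 6, "brp", "female"),
#'   line_summary_values(10097, 5.96, 5, "Syt1", "female"),
#'   line_summary_values(9971, 1.35, 5, "nSyb", "female")
#' ))
#' @export
weighted_mean_count <- function(summaries) {
  df <- summaries_to_df(summaries)
  if (!nrow(df)) stop("`summaries` must be non-empty")
  if (length(unique(df$sex)) != 1) {
    stop("cannot pool across sexes: summaries mix ",
         paste(unique(df$sex), collapse = " and "))
  }
  sum(df$mean_count * df$n_animals) / sum(df$n_animals)
}

#' Construct a line summary from already-computed values
#'
#' For entering published summary statistics (mean, CV%, n) directly.
#'
#' @param mean_count mean count.
#' @param cv_percent coefficient of variation, percent.
#' @param n_animals number of animals.
#' @param line,sex labels.
#' @return a `census_line_summary`.
#' @export
line_summary_values <- function(mean_count, cv_percent, n_animals,
                                line = "unknown", sex = "unknown") {
  stopifnot_scalar_number(mean_count, "mean_count", min = 0)
  stopifnot_scalar_number(cv_percent, "cv_percent", min = 0)
  stopifnot_scalar_number(n_animals, "n_animals", positive = TRUE)
  structure(
    list(
      line = as.character(line), sex = parse_sex(sex),
      mean_count = mean_count, cv_percent = cv_percent,
      n_animals = as.integer(n_animals)
    ),
    class = "census_line_summary"
  )
}

summaries_to_df <- function(summaries) {
  if (is.data.frame(summaries)) return(summaries)
  if (inherits(summaries, "census_line_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(
      line = s$line, sex = s$sex, mean_count = s$mean_count,
      cv_percent = s$cv_percent, n_animals = s$n_animals,
      stringsAsFactors = FALSE
    )
  }))
}

#' Percent difference between two lines
#'
#' Line-versus-line convention: `100 * (a - b) / b`, i.e. the comparison
#' line `b` is the denominator ("a labels x% more than b").
#'
#' @param a,b mean counts; `b > 0`.
#' @return signed percent (unrounded; report to 2 decimals).
#' @examples
#' pct_diff_line(10776, 10097) # brp labels +6.72% more than Syt1 (females)
#' @export
pct_diff_line <- function(a, b) {
  stopifnot_scalar_number(a, "a", min = 0)
  stopifnot_scalar_number(b, "b")
  if (b <= 0) stop("`b` must be strictly positive")
  100 * (a - b) / b
}

#' Percent difference between the sexes
#'
#' Sex-comparison convention: `100 * (male - female) / male`, i.e. the
#' *male* mean is the denominator. Negative values mean fewer in males.
#' The two percent conventions in this module are deliberately separate
#' functions because published census values require both.
#'
#' @param male,female mean counts; `male > 0`.
#' @return signed percent (unrounded).
#' @examples
#' pct_diff_sex(9396, 10312) # males have 9.75% fewer neurons
#' pct_diff_sex(4015, 3860)  # but 3.86% more glia
#' @export
pct_diff_sex <- function(male, female) {
  stopifnot_scalar_number(female, "female", min = 0)
  stopifnot_scalar_number(male, "male")
  if (male <= 0) stop("`male` must be strictly positive")
  100 * (male - female) / male
}

#' Expression fraction relative to a reference count
#'
#' `100 * a / ref`, e.g. glia as a fraction of neurons, or the number of
#' neurons expressing a channel as a fraction of all neurons.
#'
#' @param a count of interest.
#' @param ref reference count (> 0).
#' @param digits rounding of the reported percent (`NULL` = unrounded).
#' @return percent.
#' @examples
#' fraction_of_reference(3860, 10312, digits = 0) # glia are 37% of neurons
#' @export
fraction_of_reference <- function(a, ref, digits = NULL) {
  stopifnot_scalar_number(a, "a", min = 0)
  stopifnot_scalar_number(ref, "ref")
  if (ref <= 0) stop("`ref` must be strictly positive")
  out <- 100 * a / ref
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' One-way ANOVA with Tukey's HSD post-hoc test
#'
#' Classical ordinary one-way ANOVA across groups of per-animal counts,
#' followed by Tukey's honestly-significant-difference test for the
#' pairwise comparisons.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `p`, `df`, and `pairwise` (data frame of Tukey
#'   HSD comparisons with adjusted p-values).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs at least 2 observations")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1))))
  )
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- data.frame(
    comparison = rownames(tk), diff = tk[, "diff"],
    p_adjusted = tk[, "p adj"], row.names = NULL
  )
  list(
    F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
    df = c(an[["Df"]][1], an[["Df"]][2]), pairwise = pairwise
  )
}

#' Two-sided unpaired Student t-test
#'
#' Equal-variance two-sample t-test (the classical "unpaired t-test").
#'
#' @param a,b numeric vectors, each n >= 2.
#' @return list with `t`, `p`, `df`.
#' @export
unpaired_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Published per-line count summaries of the larval CNS census
#'
#' The per-line summary table (mean count, CV%, n) for the neuronal
#' reporter lines (brp, Syt1, nSyb), the glial line (repo) and the
#' voltage-gated potassium channel lines (Sh, Shal, Shab, Shaw; males
#' only, Sh being X-linked), as published. Serves as the input for the
#' census arithmetic.
#'
#' @return data frame with columns `line`, `sex`, `cell_type`,
#'   `mean_count`, `cv_percent`, `n_animals`.
#' @export
cns_line_counts <- function() {
  utils::read.csv(
    system.file("extdata", "cns_line_counts.csv", package = "cnscensus"),
    stringsAsFactors = FALSE
  )
}

#' Published pooled (sample-size-weighted) counts
#'
#' The published whole-CNS pooled neuron counts per sex. Note the male
#' pooled mean was computed from the raw per-animal counts and is 9396,
#' whereas pooling the printed (rounded) line means gives 9395.33; the
#' rounding discrepancy of <1 count is inherent to working from printed
#' summaries.
#'
#' @return data frame with columns `sex`, `cell_type`, `mean_count`,
#'   `cv_percent`, `n_animals`.
#' @export
cns_pooled_counts <- function() {
  utils::read.csv(
    system.file("extdata", "cns_pooled_counts.csv", package = "cnscensus"),
    stringsAsFactors = FALSE
  )
}

#' Full census arithmetic report
#'
#' From a table of per-line summaries (and optionally published pooled
#' means), derives the quantities a census report states: pooled neuron
#' means per sex, line-vs-line percent differences within sex
#' ([pct_diff_line()]), male-female percent differences overall and per
#' line ([pct_diff_sex()]), the glia/neuron fractions, and the expression
#' fraction of each channel line relative to all neurons of its sex.
#'
#' @param lines data frame as returned by [cns_line_counts()].
#' @param pooled optional data frame as returned by [cns_pooled_counts()];
#'   when supplied, its pooled neuron means are used as the reference for
#'   sex differences and expression fractions (they derive from raw
#'   per-animal data); otherwise pooled means are computed from `lines`.
#' @return a list of class `census_report`; see `print()` output for the
#'   layout.
#' @export
census_report <- function(lines = cns_line_counts(), pooled = NULL) {
  stopifnot(is.data.frame(lines))
  need <- c("line", "sex", "cell_type", "mean_count", "cv_percent", "n_animals")
  if (!all(need %in% names(lines))) {
    stop("`lines` must have columns: ", paste(need, collapse = ", "))
  }
  neu <- lines[lines$cell_type == "neuron", ]
  glia <- lines[lines$cell_type == "glia", ]
  chan <- lines[lines$cell_type == "channel", ]

  pool <- list()
  for (s in unique(neu$sex)) {
    pool[[s]] <- weighted_mean_count(neu[neu$sex == s, ])
  }
  ref <- pool
  if (!is.null(pooled)) {
    for (i in seq_len(nrow(pooled))) {
      if (pooled$cell_type[i] == "neuron") ref[[pooled$sex[i]]] <- pooled$mean_count[i]
    }
  }

  line_vs_line <- NULL
  for (s in unique(neu$sex)) {
    sub <- neu[neu$sex == s, ]
    if (nrow(sub) < 2) next
    cmb <- utils::combn(nrow(sub), 2)
    for (j in seq_len(ncol(cmb))) {
      a <- sub[cmb[1, j], ]
      b <- sub[cmb[2, j], ]
      line_vs_line <- rbind(line_vs_line, data.frame(
        sex = s, line_a = a$line, line_b = b$line,
        pct = pct_diff_line(a$mean_count, b$mean_count)
      ))
    }
  }

  sex_diff <- NULL
  if (all(c("male", "female") %in% names(ref))) {
    sex_diff <- rbind(sex_diff, data.frame(
      what = "all neurons",
      pct = pct_diff_sex(ref[["male"]], ref[["female"]])
    ))
    for (ln in unique(neu$line)) {
      mm <- neu$mean_count[neu$line == ln & neu$sex == "male"]
      ff <- neu$mean_count[neu$line == ln & neu$sex == "female"]
      if (length(mm) == 1 && length(ff) == 1) {
        sex_diff <- rbind(sex_diff, data.frame(
          what = ln, pct = pct_diff_sex(mm, ff)
        ))
      }
    }
    gm <- glia$mean_count[glia$sex == "male"]
    gf <- glia$mean_count[glia$sex == "female"]
    if (length(gm) == 1 && length(gf) == 1) {
      sex_diff <- rbind(sex_diff, data.frame(
        what = "glia", pct = pct_diff_sex(gm, gf)
      ))
    }
  }

  glia_fraction <- NULL
  for (i in seq_len(nrow(glia))) {
    s <- glia$sex[i]
    if (!is.null(ref[[s]])) {
      glia_fraction <- rbind(glia_fraction, data.frame(
        sex = s,
        pct = fraction_of_reference(glia$mean_count[i], ref[[s]])
      ))
    }
  }

  channel <- NULL
  for (i in seq_len(nrow(chan))) {
    s <- chan$sex[i]
    if (is.null(ref[[s]])) next
    channel <- rbind(channel, data.frame(
      line = chan$line[i], sex = s,
      fraction_pct = fraction_of_reference(chan$mean_count[i], ref[[s]]),
      vs_all_neurons_pct = pct_diff_line(chan$mean_count[i], ref[[s]])
    ))
  }

  structure(
    list(
      pooled_neurons = pool, reference_neurons = ref,
      line_vs_line = line_vs_line, sex_diff = sex_diff,
      glia_fraction = glia_fraction, channel = channel,
      lines = lines
    ),
    class = "census_report"
  )
}

#' @export
print.census_report <- function(x, ...) {
  cat("Census arithmetic report\n")
  cat("  pooled neuron means:\n")
  for (s in names(x$pooled_neurons)) {
    cat(sprintf("    %-7s %8.2f (reference used: %8.2f)\n", s,
                x$pooled_neurons[[s]], x$reference_neurons[[s]]))
  }
  if (!is.null(x$line_vs_line)) {
    cat("  line vs line (within sex, % of second line):\n")
    for (i in seq_len(nrow(x$line_vs_line))) {
      r <- x$line_vs_line[i, ]
      cat(sprintf("    %-7s %-5s vs %-5s %+6.2f%%\n", r$sex, r$line_a,
                  r$line_b, r$pct))
    }
  }
  if (!is.null(x$sex_diff)) {
    cat("  male vs female (% of male mean):\n")
    for (i in seq_len(nrow(x$sex_diff))) {
      cat(sprintf("    %-12s %+6.2f%%\n", x$sex_diff$what[i], x$sex_diff$pct[i]))
    }
  }
  if (!is.null(x$glia_fraction)) {
    cat("  glia as % of neurons:\n")
    for (i in seq_len(nrow(x$glia_fraction))) {
      cat(sprintf("    %-7s %5.1f%%\n", x$glia_fraction$sex[i],
                  x$glia_fraction$pct[i]))
    }
  }
  if (!is.null(x$channel)) {
    cat("  channel expression (% of all neurons of that sex):\n")
    for (i in seq_len(nrow(x$channel))) {
      r <- x$channel[i, ]
      cat(sprintf("    %-5s %5.1f%%  (vs all neurons %+6.1f%%)\n",
                  r$line, r$fraction_pct, r$vs_all_neurons_pct))
    }
  }
  invisible(x)
}
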