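# Group statistics and table aggregation: per-rat-per-day min-max
# normalization, one-way ANOVA, Tukey-Kramer post hoc, MANOVA (Wilks), and
# the per-subject band-power summary table.

#' Min-max normalize features within groups
#'
#' Rescales each (group, feature) cell of a long feature table to the unit interval
#' via `(v - min) / (max - min)`, computed independently per group —
#' normalizing each experiment day of each rat to a common scale. A
#' constant group (max == min) maps to missing values with a warning.
#'
#' @param table Long tibble with at least `value` plus the grouping
#'   columns.
#' @param group_keys Character vector of grouping columns (default
#'   `c("subject", "day", "feature")`).
#' @return The table with `value` rescaled and the group min/max retained
#'   in columns `.min`/`.max` (so the mapping is invertible).
#' @export
minmax_normalize <- function(table, group_keys = c("subject", "day", "feature")) {
  missing_keys <- setdiff(group_keys, names(table))
  if (length(missing_keys)) {
    abort(paste("missing grouping columns:", paste(missing_keys, collapse = ", ")))
  }
  out <- table %>%
    group_by(across(dplyr::all_of(group_keys))) %>%
    mutate(.min = min(.data$value), .max = max(.data$value),
           value = ifelse(.data$.max > .data$.min,
                          (.data$value - .data$.min) / (.data$.max - .data$.min),
                          NA_real_)) %>%
    ungroup()
  if (anyNA(out$value) && !anyNA(table$value)) {
    warn("constant group(s) produced missing normalized values")
  }
  out
}

#' One-way ANOVA
#'
#' Classic equal-variance between/within F test across condition groups.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor/character vector of group labels, same length.
#' @return One-row tibble: `test_name`, `statistic` (F), `df1`, `df2`,
#'   `p_value`, `comparison`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("each group needs at least 2 values")
  fit <- oneway.test(values ~ groups, var.equal = TRUE)
  tibble(test_name = "ANOVA",
         statistic = unname(fit$statistic),
         df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
         p_value = unname(fit$p.value),
         comparison = paste(levels(groups), collapse = " vs "))
}

#' Tukey-Kramer post hoc comparisons
#'
#' All pairwise comparisons with the studentized-range statistic and the
#' Tukey-Kramer standard error for unequal group sizes (reducing to plain
#' Tukey HSD when groups are balanced).
#'
#' @param values,groups As in [anova_oneway()].
#' @return Tibble with one row per pair: `test_name`, `comparison`, `diff`,
#'   `statistic` (q), `p_value`.
#' @export
tukey_kramer <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 1)) abort("empty group")
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  fit <- aov(values ~ groups)
  hsd <- TukeyHSD(fit)$groups
  mse <- sum(stats::resid(fit)^2) / stats::df.residual(fit)
  ns <- table(groups)
  mns <- tapply(values, groups, mean)
  pairs <- utils::combn(levels(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
    q <- abs(mns[[b]] - mns[[a]]) / se
    row <- paste(b, a, sep = "-")
    tibble(test_name = "TukeyKramer",
           comparison = paste(a, "vs", b),
           diff = unname(mns[[b]] - mns[[a]]),
           statistic = unname(q),
           p_value = unname(hsd[row, "p adj"]))
  })
}

#' MANOVA with Wilks' lambda
#'
#' Multivariate comparison of condition groups; a single-feature input
#' reduces to the one-way ANOVA.
#'
#' @param feature_matrix Numeric matrix/data frame, observations in rows,
#'   features in columns.
#' @param groups Group labels, one per row.
#' @return One-row tibble: `test_name`, `statistic` (Wilks' lambda, or F
#'   for the univariate reduction), `p_value`, `comparison`.
#' @export
manova_wilks <- function(feature_matrix, groups) {
  m <- as.matrix(feature_matrix)
  groups <- factor(groups)
  if (min(table(groups)) <= ncol(m)) {
    abort("each group needs more observations than features")
  }
  if (ncol(m) == 1) {
    out <- anova_oneway(m[, 1], groups)
    out$test_name <- "MANOVA"
    return(select(out, "test_name", "statistic", "p_value", "comparison"))
  }
  fit <- manova(m ~ groups)
  s <- summary(fit, test = "Wilks")$stats
  tibble(test_name = "MANOVA",
         statistic = s["groups", "Wilks"],
         p_value = s["groups", "Pr(>F)"],
         comparison = paste(levels(groups), collapse = " vs "))
}

#' Aggregate a per-subject band-power table
#'
#' Column means per condition plus the min-max range, in the layout of a
#' per-subject VLF/LF/HF/LF-HF summary table (the `average` and `range`
#' rows).
#'
#' @param per_subject Tibble with columns `subject`, `condition`, and the
#'   value columns to aggregate (any of `vlf_pct`, `lf_pct`, `hf_pct`,
#'   `lf_hf_ratio` present are used). Missing cells are excluded, with the
#'   per-column count of used values reported.
#' @return Tibble with one row per (condition, column): `condition`,
#'   `column`, `mean`, `min`, `max`, `range_label`, `n_used`.
#' @export
aggregate_band_table <- function(per_subject) {
  value_cols <- intersect(c("vlf_pct", "lf_pct", "hf_pct", "lf_hf_ratio"),
                          names(per_subject))
  if (!length(value_cols)) abort("no band-power columns found")
  per_subject %>%
    tidyr::pivot_longer(dplyr::all_of(value_cols), names_to = "column") %>%
    group_by(.data$condition, .data$column) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              min = min(.data$value, na.rm = TRUE),
              max = max(.data$value, na.rm = TRUE),
              n_used = sum(is.finite(.data$value)),
              .groups = "drop") %>%
    mutate(range_label = sprintf("(%.1f-%.1f)", .data$min, .data$max),
           column = factor(.data$column, levels = value_cols)) %>%
    arrange(.data$column, .data$condition) %>%
    mutate(column = as.character(.data$column))
}

#' Read the bundled per-subject band-power fixture
#'
#' Nine-subject VLF/LF/HF percentage and LF/HF ratio table (baseline and
#' AD conditions) shipped as a plain-text fixture for the reporting and
#' aggregation examples.
#'
#' @return Long tibble: `subject`, `condition`, `vlf_pct`, `lf_pct`,
#'   `hf_pct`, `lf_hf_ratio`.
#' @export
band_power_fixture <- function() {
  f <- system.file("extdata", "band_powers_per_subject.csv", package = "sknahrv")
  readr::read_csv(f, col_types = readr::cols(
    subject = readr::col_integer(), condition = readr::col_character(),
    vlf_pct = readr::col_double(), lf_pct = readr::col_double(),
    hf_pct = readr::col_double(), lf_hf_ratio = readr::col_double()))
}
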