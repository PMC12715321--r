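# Reporting layer: group comparisons, Spearman correlations, and a
# summary-table builder over pipeline outputs.

#' Compare a variable between two groups
#'
#' Dispatches to the classical two-sample tests: equal-variance Student t
#' (`parametric`), Mann-Whitney U / Wilcoxon signed-rank (`rank`), or a
#' chi-square test of independence (`categorical`). All tests are
#' two-sided; rank tests use the normal approximation.
#'
#' @param data Data frame in long format.
#' @param value Column holding the measurement (or category for
#'   `family = "categorical"`).
#' @param group Two-level grouping column.
#' @param design `"unpaired"` or `"paired"`; paired designs align
#'   observations by `id` and require equal group sizes.
#' @param family `"parametric"`, `"rank"` or `"categorical"`.
#' @param id Subject identifier column, required for paired designs.
#' @return One-row tibble: variable, test, per-group n/mean/sd,
#'   statistic, p_value.
#' @export
compare_groups <- function(data, value, group,
                           design = c("unpaired", "paired"),
                           family = c("parametric", "rank", "categorical"),
                           id = NULL) {
  design <- match.arg(design)
  family <- match.arg(family)
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  glev <- sort(unique(g))
  if (length(glev) != 2) stop_config("group must contain exactly two levels")
  vname <- as_name(enquo(value))

  if (family == "categorical") {
    ht <- chisq.test(table(v, g), correct = FALSE)
    return(tibble::tibble(
      variable = vname, test = "chi_square",
      group1 = glev[1], group2 = glev[2],
      n1 = sum(g == glev[1]), n2 = sum(g == glev[2]),
      mean1 = NA_real_, sd1 = NA_real_, mean2 = NA_real_, sd2 = NA_real_,
      statistic = unname(ht$statistic), p_value = ht$p.value))
  }

  x <- v[g == glev[1]]
  y <- v[g == glev[2]]
  if (length(x) < 2 || length(y) < 2)
    stop_config("each group needs at least two observations")

  if (design == "paired") {
    idq <- enquo(id)
    if (rlang::quo_is_null(idq))
      stop_config("paired design requires an id column")
    ids <- as.character(dplyr::pull(data, !!idq))
    if (length(x) != length(y) ||
        !setequal(ids[g == glev[1]], ids[g == glev[2]]))
      stop_config("paired design requires matched samples of equal length")
    ord1 <- order(ids[g == glev[1]]); ord2 <- order(ids[g == glev[2]])
    x <- x[ord1]; y <- y[ord2]
  }

  ht <- if (family == "parametric") {
    if (design == "paired") t.test(x, y, paired = TRUE)
    else t.test(x, y, var.equal = TRUE)
  } else {
    wilcox.test(x, y, paired = design == "paired", exact = FALSE,
                correct = TRUE)
  }
  test_name <- if (family == "parametric") {
    if (design == "paired") "paired_t" else "unpaired_t"
  } else {
    if (design == "paired") "wilcoxon_signed_rank" else "mann_whitney"
  }
  tibble::tibble(
    variable = vname, test = test_name,
    group1 = glev[1], group2 = glev[2],
    n1 = length(x), n2 = length(y),
    mean1 = mean(x), sd1 = sd(x), mean2 = mean(y), sd2 = sd(y),
    statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Spearman rank correlation
#'
#' Rho is the product-moment correlation of the (average-tie) ranks; the
#' p-value uses the t approximation. Zero rank variance in either
#' variable yields `NA` with a warning (undefined, not an error).
#'
#' @param data Data frame.
#' @param x,y Numeric columns.
#' @return One-row tibble: var_x, var_y, n, spearman_rho, p_value.
#' @export
correlate <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) != length(yv) || length(xv) < 3)
    stop_config("x and y must have equal length >= 3")
  out <- tibble::tibble(var_x = as_name(enquo(x)), var_y = as_name(enquo(y)),
                        n = length(xv), spearman_rho = NA_real_,
                        p_value = NA_real_)
  if (sd(rank(xv)) == 0 || sd(rank(yv)) == 0) {
    warn("zero rank variance: Spearman correlation undefined")
    return(out)
  }
  ht <- suppressWarnings(cor.test(xv, yv, method = "spearman", exact = FALSE))
  out$spearman_rho <- unname(ht$estimate)
  out$p_value <- ht$p.value
  out
}

#' Build the report tables for a pipeline run
#'
#' Produces (1) a per-group summary (mean +/- SD) of the consistent
#' micrographia area and the sequence effect, (2) pairwise unpaired-t
#' group comparisons of both measures, and (3) Spearman correlations
#' between patient likelihood-ratio scores and both measures.
#'
#' @param micro Per-subject summary from [summarize_micrographia()]; must
#'   carry a `group` column.
#' @param scores Optional patient scores (`subject_id`, `lr`), e.g. from
#'   [cross_validate()].
#' @return An `hw_report` list of tibbles: `group_summary`,
#'   `comparisons`, `correlations`.
#' @export
build_report <- function(micro, scores = NULL) {
  if (!"group" %in% names(micro))
    stop_config("micro must carry a 'group' column")
  long <- micro |>
    tidyr::pivot_longer(dplyr::all_of(c("consistent_area_mm2", "sequence_effect")),
                        names_to = "variable", values_to = "value")
  group_summary <- long |>
    dplyr::group_by(.data$variable, .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")

  groups <- sort(unique(micro$group))
  comparisons <- NULL
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    comparisons <- purrr::map_dfr(pairs, function(pr) {
      d <- dplyr::filter(long, .data$group %in% pr)
      purrr::map_dfr(unique(d$variable), function(vb) {
        dd <- dplyr::filter(d, .data$variable == vb)
        out <- compare_groups(dd, value, group)
        out$variable <- vb
        out
      })
    })
  }

  correlations <- NULL
  if (!is.null(scores)) {
    joined <- dplyr::inner_join(micro, scores, by = "subject_id")
    orphans <- setdiff(scores$subject_id, micro$subject_id)
    if (length(orphans) > 0)
      stop_config(sprintf("scores without metrics for subject(s): %s",
                          paste(orphans, collapse = ", ")))
    if (nrow(joined) >= 3) {
      correlations <- dplyr::bind_rows(
        correlate(joined, lr, consistent_area_mm2),
        correlate(joined, lr, sequence_effect)
      )
    }
  }

  structure(list(group_summary = group_summary, comparisons = comparisons,
                 correlations = correlations), class = "hw_report")
}

#' @export
print.hw_report <- function(x, ...) {
  cat("<hw_report>\n-- group summary --\n")
  print(x$group_summary)
  if (!is.null(x$comparisons)) {
    cat("-- comparisons --\n")
    print(dplyr::select(x$comparisons, "variable", "test", "group1", "group2",
                        "statistic", "p_value"))
  }
  if (!is.null(x$correlations)) {
    cat("-- correlations (LR vs metrics) --\n")
    print(x$correlations)
  }
  invisible(x)
}
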