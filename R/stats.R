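# Statistical comparison procedures and Tukey-box summary conventions.

#' Sidak correction for multiple comparisons
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to 1. `m` defaults to the number of
#' p-values supplied.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param m number of comparisons.
#' @return adjusted p-values.
#' @examples
#' sidak_correct(0.01, m = 5) # 1 - 0.99^5 ~ 0.049
#' @export
sidak_correct <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  pmin(1, 1 - (1 - p)^m)
}

#' Games-Howell post hoc comparisons
#'
#' All pairwise comparisons after a Welch ANOVA, for unequal variances and
#' sizes: Welch-type standard errors and degrees of freedom with
#' studentized-range (Tukey) reference distribution.
#'
#' @param values numeric vector.
#' @param groups grouping vector (same length).
#' @return tibble: `group1`, `group2`, `estimate` (mean difference),
#'   `statistic` (t), `df`, `p_adj`.
#' @export
games_howell <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  stats <- tibble(
    g = levels(groups),
    n = as.integer(table(groups)),
    m = as.numeric(tapply(values, groups, mean)),
    v = as.numeric(tapply(values, groups, var))
  )
  if (any(stats$n < 2)) abort("Each group needs n >= 2.")
  pairs <- utils::combn(seq_len(k), 2)
  purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se2 <- stats$v[i1] / stats$n[i1] + stats$v[i2] / stats$n[i2]
    tstat <- (stats$m[i1] - stats$m[i2]) / sqrt(se2)
    df <- se2^2 / ((stats$v[i1] / stats$n[i1])^2 / (stats$n[i1] - 1) +
                     (stats$v[i2] / stats$n[i2])^2 / (stats$n[i2] - 1))
    p <- ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                lower.tail = FALSE)
    tibble(group1 = stats$g[i1], group2 = stats$g[i2],
           estimate = stats$m[i1] - stats$m[i2],
           statistic = tstat, df = df, p_adj = p)
  }) |> list_rbind()
}

#' Group comparisons with the study's reporting conventions
#'
#' Omnibus test followed by the matching pairwise post hoc procedure, with
#' significance stars at p < 0.05 (*), < 0.01 (**), < 0.001 (***):
#'
#' * `student_t_2tail` / `welch_t`: two groups, two-tailed t-test (pooled or
#'   Welch variance).
#' * `welch_anova_games_howell`: Welch's ANOVA, then [games_howell()].
#' * `kruskal_wallis_mwu_sidak`: Kruskal-Wallis, then pairwise two-sided
#'   Mann-Whitney U tests with [sidak_correct()] over the number of pairs;
#'   pairs with a group of n < 3 are skipped and flagged.
#'
#' @param data a data frame.
#' @param value,group column names (strings or bare names) of the measured
#'   values and the group labels.
#' @param method one of the four procedures above.
#' @return object of class `test_report`: list with `omnibus` and
#'   `pairwise` tibbles (raw and adjusted p, stars), the `method`, and group
#'   sizes. `tidy()` returns the pairwise table, `glance()` the omnibus row.
#' @export
compare_groups <- function(data, value, group,
                           method = c("student_t_2tail", "welch_t",
                                      "welch_anova_games_howell",
                                      "kruskal_wallis_mwu_sidak")) {
  method <- match.arg(method)
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  v <- data[[value]]
  g <- factor(data[[group]])
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2) abort("Need at least 2 groups.")
  sizes <- tibble(group = levels(g), n = as.integer(table(g)))

  parametric <- method %in% c("student_t_2tail", "welch_t",
                              "welch_anova_games_howell")
  if (parametric) {
    vs <- tapply(v, g, var)
    if (any(vs == 0)) {
      abort(paste0("Zero-variance group(s): ",
                   paste(names(vs)[vs == 0], collapse = ", ")))
    }
    if (any(table(g) < 3)) abort("Parametric methods need n >= 3 per group.")
  }

  if (method %in% c("student_t_2tail", "welch_t")) {
    if (k != 2) abort("t-tests compare exactly 2 groups.")
    tt <- t.test(v ~ g, var.equal = method == "student_t_2tail")
    omnibus <- tibble(method = method, statistic = unname(tt$statistic),
                      df = unname(tt$parameter), p_value = tt$p.value,
                      stars = stars_for(tt$p.value))
    pairwise <- tibble(group1 = levels(g)[1], group2 = levels(g)[2],
                       statistic = unname(tt$statistic),
                       p_raw = tt$p.value, p_adj = tt$p.value,
                       stars = stars_for(tt$p.value), skipped = FALSE)
  } else if (method == "welch_anova_games_howell") {
    om <- oneway.test(v ~ g, var.equal = FALSE)
    gh <- games_howell(v, g)
    omnibus <- tibble(method = "welch_anova",
                      statistic = unname(om$statistic),
                      df = unname(om$parameter[2]), p_value = om$p.value,
                      stars = stars_for(om$p.value))
    pairwise <- gh |>
      mutate(p_raw = .data$p_adj, stars = stars_for(.data$p_adj),
             skipped = FALSE) |>
      select("group1", "group2", "statistic", "p_raw", "p_adj", "stars",
             "skipped")
  } else {
    om <- kruskal.test(v, g)
    pairs <- utils::combn(levels(g), 2)
    m <- ncol(pairs)
    pairwise <- purrr::map(seq_len(m), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      x1 <- v[g == g1]; x2 <- v[g == g2]
      if (length(x1) < 3 || length(x2) < 3) {
        return(tibble(group1 = g1, group2 = g2, statistic = NA_real_,
                      p_raw = NA_real_, skipped = TRUE))
      }
      wt <- suppressWarnings(wilcox.test(x1, x2, exact = FALSE))
      tibble(group1 = g1, group2 = g2, statistic = unname(wt$statistic),
             p_raw = wt$p.value, skipped = FALSE)
    }) |> list_rbind()
    pairwise$p_adj <- ifelse(pairwise$skipped, NA_real_,
                             sidak_correct(dplyr::coalesce(pairwise$p_raw, 0),
                                           m = m))
    pairwise$p_adj[pairwise$skipped] <- NA_real_
    pairwise$stars <- ifelse(is.na(pairwise$p_adj), "",
                             stars_for(pairwise$p_adj))
    omnibus <- tibble(method = "kruskal_wallis",
                      statistic = unname(om$statistic),
                      df = unname(om$parameter), p_value = om$p.value,
                      stars = stars_for(om$p.value))
  }
  structure(
    list(omnibus = omnibus, pairwise = as_tibble(pairwise),
         method = method, sizes = sizes),
    class = "test_report"
  )
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s | omnibus p = %.3g %s\n", x$method,
              x$omnibus$p_value, x$omnibus$stars))
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_groups
#' @param x a `test_report`.
#' @param ... unused.
#' @export
tidy.test_report <- function(x, ...) x$pairwise

#' @rdname compare_groups
#' @export
glance.test_report <- function(x, ...) x$omnibus

#' Tukey box-and-whisker summary
#'
#' Quartiles with linear interpolation between order statistics (R quantile
#' type 7), whiskers extending to the most extreme data point within
#' 1.5 x IQR of the box, the mean alongside the median, and a box width
#' proportional to sqrt(n).
#'
#' @param data data frame, or a numeric vector.
#' @param value,group column names when `data` is a data frame (group
#'   optional).
#' @return tibble per group: `n`, `q1`, `median`, `q3`, `mean`,
#'   `whisker_low`, `whisker_high`, `box_width` (= sqrt(n), to be scaled by
#'   the caller).
#' @export
tukey_box <- function(data, value = NULL, group = NULL) {
  if (is.numeric(data)) {
    groups <- list(all = data)
  } else {
    value <- rlang::as_name(rlang::ensym(value))
    v <- data[[value]]
    gq <- rlang::enquo(group)
    if (!rlang::quo_is_null(gq)) {
      group <- rlang::as_name(rlang::quo_get_expr(gq))
      groups <- split(v, data[[group]])
    } else {
      groups <- list(all = v)
    }
  }
  tukey_box_list(groups)
}

tukey_box_list <- function(groups) {
  purrr::imap(groups, function(x, nm) {
    x <- x[is.finite(x)]
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    tibble(
      group = nm, n = length(x),
      q1 = q[1], median = q[2], q3 = q[3], mean = mean(x),
      whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
      whisker_high = max(x[x <= q[3] + 1.5 * iqr]),
      box_width = sqrt(length(x))
    )
  }) |> list_rbind()
}
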