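# Two-group nonparametric comparison (Mann-Whitney U with exact enumeration
# for small untied samples) and box-whisker summaries with 1.5*IQR whiskers.

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties
#' (`U = R1 - n1(n1+1)/2`, the number of (x, y) pairs with x > y counting
#' ties as half). For pooled `n1 + n2 <= 12` without ties the p-value is
#' obtained by exact enumeration of all `choose(n1+n2, n1)` labelings;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. Two-sided p is twice the smaller tail, capped at 1.
#'
#' @param x,y Numeric samples (non-empty).
#' @param tails `"two"` (default), `"less"` (x shifted below y) or
#'   `"greater"`.
#' @param exact_max Pooled size up to which the exact enumeration is used
#'   (default 12).
#' @return An object of class `mw_test`: `U`, `p_value`, `tails`, `n1`,
#'   `n2`, `direction` (sign of median(x) - median(y)) and `method`.
#' @export
mann_whitney <- function(x, y, tails = c("two", "less", "greater"),
                         exact_max = 12) {
  tails <- match.arg(tails)
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  n <- n1 + n2
  if (!ties && n <= exact_max) {
    # exact: U depends only on which rank positions are x's
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(seq_len(n)[combos], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p_less <- mean(u_all <= u)
    p_greater <- mean(u_all >= u)
    p <- switch(tails,
                two = min(1, 2 * min(p_less, p_greater)),
                less = p_less,
                greater = p_greater)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tt <- table(pooled)
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1))))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- u - mu
      p <- switch(tails,
                  two = {
                    zc <- (z - sign(z) * 0.5) / sigma
                    min(1, 2 * min(stats::pnorm(zc),
                                   stats::pnorm(zc, lower.tail = FALSE)))
                  },
                  less = stats::pnorm((z + 0.5) / sigma),
                  greater = stats::pnorm((z - 0.5) / sigma,
                                         lower.tail = FALSE))
    }
    method <- "normal"
  }
  structure(
    list(U = u, p_value = p, tails = tails, n1 = n1, n2 = n2,
         direction = sign(stats::median(x) - stats::median(y)),
         method = method),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, n = %d vs %d, %s-tailed %s P = %.4g\n",
              x$U, x$n1, x$n2, x$tails, x$method, x$p_value))
  invisible(x)
}

#' Box-whisker summary with 1.5*IQR whiskers
#'
#' Quartiles by linear interpolation; whiskers are the most extreme data
#' points within `[q1 - 1.5 IQR, q3 + 1.5 IQR]`; points outside are listed
#' as outliers.
#'
#' @param x Numeric sample (n >= 1).
#' @return An object of class `box_summary`: `q1`, `median`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `outliers`, `n`.
#' @export
box_summary <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  if (length(x) < 1) stop("sample must be non-empty")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  structure(
    list(q1 = q[1], median = q[2], q3 = q[3],
         whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
         outliers = sort(x[!inside]), n = length(x)),
    class = "box_summary"
  )
}

# Significance stars for the study's bands.
.stars <- function(p, bands = c(0.05, 0.01, 0.001)) {
  if (is.na(p)) return("")
  paste(rep("*", sum(p < bands)), collapse = "")
}

#' Two-group study report over a cohort metric table
#'
#' For every metric column, computes group box summaries and a Mann-Whitney
#' test with the configured tails, flags significance per the bands
#' (default * P < 0.05, ** P < 0.01, *** P < 0.001), and logs N (patients)
#' and n (cells) per metric.
#'
#' @param cohort Data frame with columns `patient_id`, `cell_id`, `group`
#'   (two levels) and numeric metric columns.
#' @param tails Named list/character of per-metric tails; unnamed metrics use
#'   `"two"`.
#' @param bands Significance bands (decreasing P thresholds).
#' @param group_levels Order of the two groups; x = first level in each test.
#' @return An object of class `study_report`: `table` (one row per metric)
#'   and `boxes` (per-metric pair of [box_summary()]).
#' @export
run_study <- function(cohort, tails = list(), bands = c(0.05, 0.01, 0.001),
                      group_levels = NULL) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  if (is.null(group_levels)) group_levels <- unique(as.character(cohort$group))
  if (length(group_levels) != 2) stop("group must have exactly two levels")
  id_cols <- intersect(c("patient_id", "cell_id", "group"), names(cohort))
  metrics <- setdiff(names(cohort), id_cols)
  metrics <- metrics[vapply(cohort[metrics], is.numeric, logical(1))]
  rows <- list(); boxes <- list()
  for (m in metrics) {
    g1 <- cohort[[m]][cohort$group == group_levels[1]]
    g2 <- cohort[[m]][cohort$group == group_levels[2]]
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    if (length(g1) == 0 || length(g2) == 0) {
      warning(sprintf("metric %s skipped: one group empty", m))
      next
    }
    tl <- if (!is.null(tails[[m]])) tails[[m]] else "two"
    tst <- mann_whitney(g1, g2, tails = tl)
    n_pat <- if ("patient_id" %in% names(cohort))
      c(length(unique(cohort$patient_id[cohort$group == group_levels[1] &
                                          !is.na(cohort[[m]])])),
        length(unique(cohort$patient_id[cohort$group == group_levels[2] &
                                          !is.na(cohort[[m]])])))
    else c(NA_integer_, NA_integer_)
    rows[[m]] <- data.frame(
      metric = m,
      n1 = tst$n1, n2 = tst$n2, N1 = n_pat[1], N2 = n_pat[2],
      median1 = stats::median(g1), median2 = stats::median(g2),
      U = tst$U, p_value = tst$p_value, tails = tl,
      direction = tst$direction, stars = .stars(tst$p_value, bands),
      stringsAsFactors = FALSE)
    boxes[[m]] <- list(box_summary(g1), box_summary(g2))
    names(boxes[[m]]) <- group_levels
  }
  structure(list(table = do.call(rbind, rows), boxes = boxes,
                 group_levels = group_levels, bands = bands),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %s vs %s\n", x$group_levels[1], x$group_levels[2]))
  print(x$table[, c("metric", "n1", "n2", "median1", "median2",
                    "p_value", "stars")], row.names = FALSE)
  invisible(x)
}

#' Write a study report to CSV and JSON
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(groups = report$group_levels, bands = report$bands,
         metrics = report$table,
         boxes = lapply(report$boxes, function(b)
           lapply(b, function(s) s[c("q1", "median", "q3",
                                     "whisker_lo", "whisker_hi",
                                     "outliers", "n")]))),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
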