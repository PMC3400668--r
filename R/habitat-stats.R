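# The inferential layer: Pearson correlations with exact t-transform
# p-values, unbalanced two-/three-way fixed-effects ANOVA that tolerates
# a structurally missing cell, and Duncan's multiple range test with
# letter displays.

#' Two-sided p-value for a Pearson correlation coefficient
#'
#' The t-transform: `t = r * sqrt((n - 2) / (1 - r^2))` referred to a
#' t distribution with `n - 2` degrees of freedom, doubled for the
#' two-sided probability. `|r| >= 1` is handled as the boundary `p = 0`.
#'
#' @param r Pearson correlation coefficient.
#' @param n Sample size (>= 3).
#' @return Two-sided p-value in `[0, 1]`.
#' @examples
#' p_from_r(0.367, 5)
#' @export
p_from_r <- function(r, n) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || abs(r) > 1) {
    stop("`r` must be a correlation coefficient in [-1, 1]", call. = FALSE)
  }
  n <- check_count(n, "n", min = 3L)
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Pearson correlation with its exact p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite, with
#'   non-zero variance.
#' @return A `corr_result`: list with `r`, `n`, `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in `x` or `y`", call. = FALSE)
  }
  r <- stats::cor(x, y)
  structure(list(r = r, n = n, p = p_from_r(r, n)),
            class = "corr_result")
}

#' Unbalanced fixed-effects factorial ANOVA
#'
#' Fits the full-factorial linear model for two or three crossed factors
#' and tests every term with a marginal model-comparison F test: the
#' extra sum of squares gained by adding the term to the model holding
#' all terms that do not contain it, referred to the full-factorial
#' residual mean square. On a balanced design this reproduces the
#' classical ANOVA decomposition exactly. A structurally missing cell
#' (e.g. a reach x stream design with no upper-reach tributary) does not
#' abort the analysis: aliased interaction contrasts are dropped by the
#' fit, so the term is tested on its estimable part with visibly reduced
#' numerator degrees of freedom, and a note names the empty cells.
#'
#' @param data Data frame of individual observations.
#' @param response Response column name.
#' @param factors Character vector of 2 or 3 factor column names.
#' @return An `anova_result`: data frame with one row per term (`term`,
#'   `df1`, `df2`, `F`, `p`, `ss`), attributes `residual_df`,
#'   `residual_ss` and `missing_cells`. A term whose contrasts are all
#'   aliased gets `df1 = 0` and `NA` statistics.
#' @export
factorial_anova <- function(data, response, factors) {
  if (!response %in% names(data)) {
    stop(sprintf("response `%s` not found", response), call. = FALSE)
  }
  if (!length(factors) %in% c(2L, 3L)) {
    stop("`factors` must name 2 or 3 columns", call. = FALSE)
  }
  if (!all(factors %in% names(data))) {
    stop("all `factors` must be columns of `data`", call. = FALSE)
  }
  df <- data[stats::complete.cases(data[c(response, factors)]), ,
             drop = FALSE]
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2L) {
      stop(sprintf("factor `%s` needs at least 2 observed levels", f),
           call. = FALSE)
    }
  }
  cells <- table(df[factors])
  missing_cells <- which(cells == 0L, arr.ind = TRUE)
  missing_lbl <- if (length(missing_cells)) {
    unname(apply(missing_cells, 1L, function(ix) {
      paste(mapply(function(f, i) paste0(f, "=", dimnames(cells)[[f]][i]),
                   factors, ix), collapse = ":")
    }))
  } else character(0)

  all_terms <- attr(stats::terms(
    stats::reformulate(paste(factors, collapse = " * "))), "term.labels")
  full <- stats::lm(stats::reformulate(all_terms, response = response),
                    data = df)
  if (full$df.residual < 1L) {
    stop("no residual degrees of freedom", call. = FALSE)
  }
  rss_full <- stats::deviance(full)
  mse <- rss_full / full$df.residual
  y <- df[[response]]
  tss <- sum((y - mean(y))^2)
  # a constant response carries no evidence about any term
  constant_y <- tss <= .Machine$double.eps^0.5 * max(1, sum(y^2))

  contains <- function(a, b) {    # does term b contain term a?
    all(strsplit(a, ":")[[1L]] %in% strsplit(b, ":")[[1L]])
  }
  rows <- lapply(all_terms, function(tm) {
    base <- all_terms[!vapply(all_terms, contains, logical(1), a = tm)]
    m0 <- if (length(base)) {
      stats::lm(stats::reformulate(base, response = response), data = df)
    } else {
      stats::lm(stats::reformulate("1", response = response), data = df)
    }
    m1 <- stats::lm(stats::reformulate(c(base, tm), response = response),
                    data = df)
    df1 <- m0$df.residual - m1$df.residual
    ss <- stats::deviance(m0) - stats::deviance(m1)
    if (df1 < 1L) {
      data.frame(term = tm, df1 = 0L, df2 = full$df.residual,
                 F = NA_real_, p = NA_real_, ss = NA_real_,
                 stringsAsFactors = FALSE)
    } else if (constant_y) {
      data.frame(term = tm, df1 = df1, df2 = full$df.residual,
                 F = 0, p = 1, ss = 0, stringsAsFactors = FALSE)
    } else {
      # a factor-perfect fit has zero residual MS and infinite evidence
      Fv <- if (mse == 0) Inf else (ss / df1) / mse
      data.frame(term = tm, df1 = df1, df2 = full$df.residual,
                 F = Fv, p = stats::pf(Fv, df1, full$df.residual,
                                       lower.tail = FALSE),
                 ss = ss, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (any(out$df1 == 0L)) {
    warning(sprintf(
      "term(s) %s have no estimable contrasts with the observed cells%s",
      paste(out$term[out$df1 == 0L], collapse = ", "),
      if (length(missing_lbl)) {
        sprintf(" (%s empty)", paste(missing_lbl, collapse = "; "))
      } else ""), call. = FALSE)
  }
  structure(out, residual_df = full$df.residual, residual_ss = rss_full,
            missing_cells = missing_lbl,
            class = c("anova_result", "data.frame"))
}

# least significant ranges for Duncan's test: span p = 2..n_means
duncan_ranges <- function(n_means, df_error, se, alpha) {
  p <- 2:n_means
  level <- 1 - (1 - alpha)^(p - 1)            # Duncan's protection level
  q <- stats::qtukey(1 - level, p, df_error)
  stats::setNames(q * se, p)
}

#' Duncan's multiple range test with letter display
#'
#' Group means are ranked and compared with least significant ranges
#' from the studentized range distribution at Duncan's span-adjusted
#' level `1 - (1 - alpha)^(p - 1)` for a span of `p` means, using the
#' pooled one-way ANOVA mean square error (harmonic mean group size for
#' unequal n). Any ranked span whose extreme means differ by less than
#' its least significant range is declared homogeneous, and every
#' maximal homogeneous span receives one letter; two groups sharing no
#' letter differ significantly at level `alpha`.
#'
#' @param values Numeric observations.
#' @param groups Group label per observation (>= 2 groups, each with
#'   >= 2 observations).
#' @param alpha Significance level (default 0.05).
#' @return Data frame (class `duncan_result`) ordered by decreasing
#'   mean: `group`, `n`, `mean`, `letters`; attributes `mse`,
#'   `df_error`, `ranges`.
#' @export
duncan_letters <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  fit <- stats::aov(values ~ factor(groups))
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  df_error <- fit$df.residual
  means <- tapply(values, groups, mean)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; ns <- as.integer(tab[names(m)])
  g <- length(m)
  nh <- g / sum(1 / ns)                        # harmonic mean group size
  se <- sqrt(mse / nh)
  ranges <- duncan_ranges(g, df_error, se, alpha)

  # a ranked span [a, b] is homogeneous when its extremes differ by no
  # more than the least significant range for its width; letters go to
  # maximal homogeneous spans (singletons covered by none get their own)
  homog <- matrix(FALSE, g, g)
  for (a in seq_len(g - 1L)) {
    for (b in (a + 1L):g) {
      homog[a, b] <- (m[a] - m[b]) <= ranges[as.character(b - a + 1L)]
    }
  }
  spans <- list()
  for (a in seq_len(g)) {
    b_max <- a
    for (b in seq_len(g)[-seq_len(a)]) if (homog[a, b]) b_max <- b
    # keep only spans homogeneous across their full width
    if (b_max > a && homog[a, b_max]) spans[[length(spans) + 1L]] <-
        c(a, b_max)
  }
  # drop spans contained in another span
  if (length(spans)) {
    keep <- vapply(seq_along(spans), function(i) {
      !any(vapply(seq_along(spans), function(j) {
        j != i && spans[[j]][1L] <= spans[[i]][1L] &&
          spans[[j]][2L] >= spans[[i]][2L]
      }, logical(1)))
    }, logical(1))
    spans <- spans[keep]
  }
  covered <- rep(FALSE, g)
  for (sp in spans) covered[sp[1L]:sp[2L]] <- TRUE
  for (i in which(!covered)) spans[[length(spans) + 1L]] <- c(i, i)
  spans <- spans[order(vapply(spans, `[`, numeric(1), 1L))]
  letter_of <- letters[seq_along(spans)]
  lab <- vapply(seq_len(g), function(i) {
    paste(letter_of[vapply(spans, function(sp) {
      sp[1L] <= i && i <= sp[2L]
    }, logical(1))], collapse = "")
  }, character(1))

  structure(
    data.frame(group = names(m), n = ns, mean = as.numeric(m),
               letters = lab, row.names = NULL,
               stringsAsFactors = FALSE),
    mse = mse, df_error = df_error, ranges = ranges,
    class = c("duncan_result", "data.frame")
  )
}
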