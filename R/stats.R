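#' @include parameters.R
NULL

.boxcox <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

# Box-Cox profile log-likelihood at lambda (MLE variance form)
.boxcoxLogLik <- function(y, lambda) {
  n <- length(y)
  z <- .boxcox(y, lambda)
  s2 <- sum((z - mean(z))^2) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(y))
}

#' Select a normalizing transformation for one parameter
#'
#' Implements the transformation-selection step of the EPG statistical
#' workflow: proportion-typed parameters (percentages in [0, 100]) are first
#' mapped by \eqn{\arcsin\sqrt{x/100}}; a shift equal to half the smallest
#' positive value is added when zeros (or non-positive values) are present;
#' then the Box-Cox exponent \eqn{\lambda} is chosen from the grid
#' \eqn{-3, -2.75, \ldots, 3} by maximizing the profile log-likelihood
#' (\eqn{\lambda = 0} meaning log). The Shapiro-Wilk statistic of the
#' transformed sample is reported for audit in place of visual Q-Q
#' inspection.
#'
#' @param values numeric vector, at least 4 finite values, non-negative.
#' @param proportionTyped logical; TRUE for percentage parameters.
#' @return An object of class \code{epgTransformSpec}: list with
#'   \code{arcsine_first}, \code{lambda}, \code{shift},
#'   \code{selection_score} (profile log-likelihood at the optimum) and
#'   \code{shapiro_w}.
#' @export
#' @examples
#' spec <- selectTransform(rlnorm(50))
#' spec$lambda
selectTransform <- function(values, proportionTyped = FALSE) {
  y <- values[is.finite(values)]
  if (length(y) < 4L) stop("selectTransform requires at least 4 finite values")
  if (any(y < 0)) stop("negative values are not supported; ",
                       "declare and rescale the parameter appropriately")
  if (proportionTyped) {
    if (any(y > 100)) stop("proportion-typed values must lie in [0, 100]")
    y <- asin(sqrt(y / 100))
  }
  if (max(y) - min(y) < .Machine$double.eps * max(abs(y), 1))
    stop("degenerate sample: values are constant")
  shift <- 0
  if (min(y) <= 0) {
    pos <- y[y > 0]
    if (length(pos) == 0L) stop("degenerate sample: no positive values")
    shift <- min(pos) / 2
    y <- y + shift
  }
  grid <- seq(-3, 3, by = 0.25)
  ll <- vapply(grid, function(l) .boxcoxLogLik(y, l), 0)
  best <- which.max(ll)
  z <- .boxcox(y, grid[best])
  sw <- if (length(z) >= 4 && length(z) <= 5000 && stats::sd(z) > 0)
    unname(stats::shapiro.test(z)$statistic) else NA_real_
  structure(list(arcsine_first = isTRUE(proportionTyped),
                 lambda = grid[best], shift = shift,
                 selection_score = ll[best], shapiro_w = sw),
            class = "epgTransformSpec")
}

#' Apply a selected transformation to new values
#'
#' @param spec an \code{epgTransformSpec} from \code{\link{selectTransform}}.
#' @param values numeric vector on the original scale.
#' @return transformed values.
#' @export
applyTransform <- function(spec, values) {
  y <- values
  if (spec$arcsine_first) y <- asin(sqrt(y / 100))
  .boxcox(y + spec$shift, spec$lambda)
}

#' @export
print.epgTransformSpec <- function(x, ...) {
  cat(sprintf("Transform: %slambda = %.2f, shift = %g (Shapiro W = %.3f)\n",
              if (x$arcsine_first) "arcsine then " else "",
              x$lambda, x$shift, x$shapiro_w))
  invisible(x)
}

#' Tukey-Kramer all-pairs comparisons
#'
#' One-way fixed-effects comparison of group means with studentized-range
#' adjusted p-values and the Kramer correction for unequal group sizes:
#' for groups i, j with means \eqn{m_i, m_j} and sizes \eqn{n_i, n_j},
#' \eqn{q_{ij} = |m_i - m_j| / \sqrt{(s^2/2)(1/n_i + 1/n_j)}} with the pooled
#' error variance \eqn{s^2} on \eqn{N - k} degrees of freedom, referred to
#' the studentized-range distribution with \eqn{k} means.
#'
#' @param groups named list of numeric vectors (at least 2 groups, each with
#'   at least 2 values).
#' @param alpha significance level (stored for letter display).
#' @return An object of class \code{epgTukey}: list with \code{p} (symmetric
#'   adjusted p-value matrix, unit diagonal), \code{means}, \code{n},
#'   \code{s2}, \code{df}, \code{alpha}.
#' @export
#' @examples
#' g <- list(a = c(1, 2, 3), b = c(5, 6, 7), c = c(1.5, 2.5, 2))
#' tukeyKramer(g)$p
tukeyKramer <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("tukeyKramer requires at least 2 groups")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  small <- names(groups)[vapply(groups, length, 0L) < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 values: ", paste(small, collapse = ", "))
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  N <- sum(n)
  df <- N - k
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / df
  p <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    diff <- abs(m[i] - m[j])
    if (diff == 0) {
      pij <- 1
    } else if (s2 <= 0) {
      pij <- 0
    } else {
      q <- diff / sqrt(s2 / 2 * (1 / n[i] + 1 / n[j]))
      pij <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    p[i, j] <- p[j, i] <- pij
  }
  structure(list(p = p, means = m, n = n, s2 = s2, df = df, alpha = alpha),
            class = "epgTukey")
}

#' @export
print.epgTukey <- function(x, ...) {
  cat(sprintf("Tukey-Kramer comparisons: %d groups, pooled df = %d\n",
              length(x$means), x$df))
  print(round(x$p, 4))
  invisible(x)
}

#' Compact letter display by insert-and-absorb
#'
#' Builds the Piepho-style compact letter display from a significance
#' pattern: start from a single column containing all labels; for each
#' significant pair, split every column containing both members into two
#' copies, one without each member; absorb columns whose membership is a
#' subset of another's; assign letters to the surviving columns in
#' first-appearance order. The display satisfies, by construction, the
#' defining property that two labels share at least one letter if and only
#' if their pair is not significant. Discontinuous letter strings (such as
#' \code{"ac"}) arise naturally when standard errors differ between pairs.
#'
#' @param labels character vector of group labels.
#' @param significant symmetric logical matrix (FALSE diagonal); entry
#'   \code{[i, j]} TRUE when groups i and j differ significantly.
#' @return named character vector of letter strings, one per label.
#' @export
#' @examples
#' sig <- matrix(FALSE, 3, 3)
#' sig[1, 3] <- sig[3, 1] <- TRUE
#' piephoLetters(c("x", "y", "z"), sig)
piephoLetters <- function(labels, significant) {
  k <- length(labels)
  if (!is.matrix(significant) || any(dim(significant) != k))
    stop("significance matrix must be ", k, " x ", k)
  if (!isTRUE(all(significant == t(significant))))
    stop("significance matrix must be symmetric")
  if (any(diag(significant)))
    stop("significance matrix must have a FALSE diagonal")

  cols <- list(seq_len(k))
  pairs <- which(upper.tri(significant) & significant, arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      newCols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          newCols <- c(newCols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          newCols <- c(newCols, list(col))
        }
      }
      # absorb: drop any column contained in another
      keep <- rep(TRUE, length(newCols))
      for (a in seq_along(newCols)) {
        for (b in seq_along(newCols)) {
          if (a != b && keep[b] &&
              all(newCols[[a]] %in% newCols[[b]]) &&
              (length(newCols[[a]]) < length(newCols[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- newCols[keep]
    }
  }
  ord <- order(vapply(cols, min, 0L))
  cols <- cols[ord]
  alphabet <- c(letters, LETTERS)
  if (length(cols) > length(alphabet))
    stop("too many letter columns for the display alphabet")
  out <- vapply(seq_len(k), function(i)
    paste(alphabet[which(vapply(cols, function(col) i %in% col, TRUE))],
          collapse = ""), "")
  stats::setNames(out, labels)
}

#' Compare experimental groups on every EPG parameter
#'
#' Runs the full statistical workflow for each parameter of a per-insect
#' parameter table: drop missing values, select the transformation
#' (arcsine-first for proportion-typed parameters, then Box-Cox by profile
#' likelihood), fit the one-way fixed-effects comparison with Tukey-Kramer
#' adjusted p-values, and derive the compact letter display. Group means are
#' reported on the original scale beside the letters; means and confidence
#' intervals on the transformed scale are kept for the supplementary sheet.
#'
#' A parameter that cannot be analysed (a whole group missing, fewer than
#' two usable groups, or a degenerate constant sample) is reported with a
#' skip flag and reason rather than raising an error.
#'
#' @param table parameter table from \code{\link{parametersToTable}} (seconds
#'   units), with an \code{insect_id} column.
#' @param metadata metadata table from \code{\link{readMetadata}}.
#' @param factor name of the grouping column in \code{metadata}.
#' @param alpha significance level (default 0.05).
#' @param proportionParams names of percentage parameters to arcsine-transform
#'   first (default \code{"pct_E1_phloem"}).
#' @param parameters which parameters to analyse (default: all).
#' @return list of \code{epgGroupComparison} objects, one per parameter.
#' @export
groupCompare <- function(table, metadata, factor, alpha = 0.05,
                         proportionParams = "pct_E1_phloem",
                         parameters = NULL) {
  if (!factor %in% names(metadata))
    stop("factor '", factor, "' not found in metadata")
  merged <- merge(table, metadata[, c("insect_id", factor)], by = "insect_id")
  fac <- droplevels(base::factor(merged[[factor]]))
  if (nlevels(fac) < 2L) stop("factor must have at least 2 levels")
  if (is.null(parameters)) parameters <- setdiff(names(table), "insect_id")

  lapply(parameters, function(p) {
    vals <- merged[[p]]
    groups <- split(vals, fac)
    groups <- lapply(groups, function(g) g[is.finite(g)])
    usable <- vapply(groups, length, 0L) >= 2L
    dropped <- names(groups)[!usable]
    groups <- groups[usable]
    skipRes <- function(reason) structure(
      list(parameter = p, skipped = TRUE, reason = reason,
           dropped_groups = dropped, alpha = alpha),
      class = "epgGroupComparison")
    if (length(groups) < 2L)
      return(skipRes("fewer than 2 groups with at least 2 non-missing values"))
    trans <- tryCatch(
      selectTransform(unlist(groups), proportionTyped = p %in% proportionParams),
      error = function(e) conditionMessage(e))
    if (is.character(trans)) return(skipRes(trans))
    tgroups <- lapply(groups, function(g) applyTransform(trans, g))
    tk <- tukeyKramer(tgroups, alpha = alpha)
    sig <- tk$p < alpha
    diag(sig) <- FALSE
    letters <- piephoLetters(names(groups), sig)
    tcrit <- stats::qt(1 - alpha / 2, df = tk$df)
    gtab <- data.frame(
      group = names(groups),
      n = vapply(groups, length, 0L),
      mean_original = vapply(groups, mean, 0),
      mean_transformed = tk$means,
      ci_lo_transformed = tk$means - tcrit * sqrt(tk$s2 / tk$n),
      ci_hi_transformed = tk$means + tcrit * sqrt(tk$s2 / tk$n),
      letters = unname(letters),
      stringsAsFactors = FALSE
    )
    rownames(gtab) <- NULL
    structure(list(parameter = p, skipped = FALSE, reason = NA_character_,
                   dropped_groups = dropped, transform = trans,
                   groups = gtab, p = tk$p, alpha = alpha),
              class = "epgGroupComparison")
  })
}

#' @export
print.epgGroupComparison <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("%s: skipped (%s)\n", x$parameter, x$reason))
  } else {
    cat(sprintf("%s (lambda = %.2f%s):\n", x$parameter, x$transform$lambda,
                if (x$transform$arcsine_first) ", arcsine first" else ""))
    print(x$groups[, c("group", "n", "mean_original", "letters")])
  }
  invisible(x)
}

#' Flatten group comparisons to report tables
#'
#' \code{statsToTable} gives the main sheet (original-scale means with
#' letters and the transformation used); \code{statsToSupplement} the
#' transformed-scale means and confidence intervals.
#'
#' @param comparisons list of \code{epgGroupComparison} objects from
#'   \code{\link{groupCompare}}.
#' @return data.frame.
#' @export
statsToTable <- function(comparisons) {
  rows <- lapply(comparisons, function(x) {
    if (x$skipped)
      return(data.frame(parameter = x$parameter, group = NA_character_,
                        n = NA_integer_, mean_original = NA_real_,
                        letters = NA_character_, lambda = NA_real_,
                        shift = NA_real_, arcsine = NA,
                        skipped = TRUE, reason = x$reason,
                        stringsAsFactors = FALSE))
    data.frame(parameter = x$parameter, group = x$groups$group,
               n = x$groups$n, mean_original = x$groups$mean_original,
               letters = x$groups$letters, lambda = x$transform$lambda,
               shift = x$transform$shift, arcsine = x$transform$arcsine_first,
               skipped = FALSE, reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname statsToTable
#' @export
statsToSupplement <- function(comparisons) {
  rows <- lapply(comparisons, function(x) {
    if (x$skipped) return(NULL)
    data.frame(parameter = x$parameter, group = x$groups$group,
               mean_transformed = x$groups$mean_transformed,
               ci_lo = x$groups$ci_lo_transformed,
               ci_hi = x$groups$ci_hi_transformed,
               lambda = x$transform$lambda, shift = x$transform$shift,
               arcsine = x$transform$arcsine_first,
               shapiro_w = x$transform$shapiro_w,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(parameter = character(), group = character(),
                      mean_transformed = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), lambda = numeric(), shift = numeric(),
                      arcsine = logical(), shapiro_w = numeric())
  rownames(out) <- NULL
  out
}
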