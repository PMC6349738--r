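test_that("Box-Cox selection recovers the generating transformation", {
  set.seed(101)
  logn <- exp(rnorm(500))
  spec <- selectTransform(logn)
  expect_true(spec$lambda >= -0.25 && spec$lambda <= 0.25)
  expect_false(spec$arcsine_first)
  expect_equal(spec$shift, 0)

  # for an already-normal sample with small coefficient of variation the
  # profile likelihood is nearly flat, so lambda is assessed on the average
  # over fixed-seed replicates
  gaussLambda <- vapply(1:20, function(s) {
    set.seed(200 + s)
    selectTransform(rnorm(500, mean = 100, sd = 5))$lambda
  }, 0)
  expect_true(mean(gaussLambda) >= 0.5 && mean(gaussLambda) <= 1.75)
})

test_that("profile log-likelihood agrees with the MASS implementation", {
  skip_if_not_installed("MASS")
  set.seed(103)
  y <- rgamma(80, shape = 2, rate = 0.1)
  grid <- seq(-3, 3, by = 0.25)
  ours <- vapply(grid, function(l) epgtools:::.boxcoxLogLik(y, l), 0)
  ref <- MASS::boxcox(y ~ 1, lambda = grid, plotit = FALSE)
  expect_equal(grid[which.max(ours)], ref$x[which.max(ref$y)])
  # same shape up to an additive constant
  expect_lt(max(abs((ours - mean(ours)) - (ref$y - mean(ref$y)))), 1e-6)
})

test_that("zeros trigger a recorded positive shift; degenerate input errors", {
  spec <- selectTransform(c(0, 2, 4, 8, 16, 32))
  expect_gt(spec$shift, 0)
  expect_equal(spec$shift, 1)  # half the smallest positive value
  expect_error(selectTransform(rep(5, 10)), "degenerate")
  expect_error(selectTransform(c(1, 2, 3)), "at least 4")
  expect_error(selectTransform(c(-1, 2, 3, 4)), "negative")
})

test_that("proportion-typed parameters are arcsine-transformed first", {
  set.seed(104)
  prop <- 100 * rbeta(200, 2, 2)
  spec <- selectTransform(prop, proportionTyped = TRUE)
  expect_true(spec$arcsine_first)
  z <- applyTransform(spec, prop)
  expect_true(all(is.finite(z)))
  expect_error(selectTransform(c(10, 50, 120, 30), proportionTyped = TRUE),
               "\\[0, 100\\]")
})

test_that("Tukey-Kramer handles null, separated, and two-group cases", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_equal(unname(tukeyKramer(g)$p[1, 2]), 1)

  far <- list(a = rnorm(5, 0, 1e-4), b = rnorm(5, 10, 1e-4),
              c = rnorm(5, 20, 1e-4))
  expect_true(all(tukeyKramer(far)$p[upper.tri(diag(3))] < 1e-6))

  # balanced two-group case reduces to the pooled t-test
  set.seed(105)
  x <- rnorm(8); y <- rnorm(8, 1)
  pT <- t.test(x, y, var.equal = TRUE)$p.value
  pQ <- tukeyKramer(list(x = x, y = y))$p[1, 2]
  expect_equal(unname(pQ), pT, tolerance = 1e-10)

  expect_error(tukeyKramer(list(a = 1, b = c(1, 2))), "fewer than 2 values: a")
  expect_error(tukeyKramer(list(a = c(1, 2))), "at least 2 groups")
})

test_that("Tukey-Kramer matches TukeyHSD on unbalanced data", {
  set.seed(106)
  vals <- c(rnorm(6, 0), rnorm(9, 0.8), rnorm(4, 1.6))
  grp <- factor(rep(c("a", "b", "c"), c(6, 9, 4)))
  ours <- tukeyKramer(split(vals, grp))$p
  ref <- TukeyHSD(aov(vals ~ grp))$grp[, "p adj"]
  expect_equal(unname(ours["a", "b"]), unname(ref["b-a"]), tolerance = 1e-8)
  expect_equal(unname(ours["a", "c"]), unname(ref["c-a"]), tolerance = 1e-8)
  expect_equal(unname(ours["b", "c"]), unname(ref["c-b"]), tolerance = 1e-8)
})

letters_property_ok <- function(lets, sig) {
  k <- length(lets)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    share <- length(intersect(strsplit(lets[i], "")[[1]],
                              strsplit(lets[j], "")[[1]])) > 0
    if (share == sig[i, j]) return(FALSE)  # share letter iff NOT significant
  }
  TRUE
}

test_that("letter display satisfies its defining property on simple cases", {
  none <- matrix(FALSE, 3, 3)
  expect_equal(unname(piephoLetters(c("x", "y", "z"), none)),
               c("a", "a", "a"))

  one <- matrix(FALSE, 3, 3)
  one[1, 3] <- one[3, 1] <- TRUE
  expect_equal(unname(piephoLetters(c("x", "y", "z"), one)),
               c("a", "ab", "b"))

  m <- matrix(FALSE, 4, 4)
  m[1, 4] <- m[4, 1] <- TRUE
  m[2, 4] <- m[4, 2] <- TRUE
  lets <- piephoLetters(letters[1:4], m)
  expect_true(letters_property_ok(lets, m))

  expect_error(piephoLetters(c("x", "y"), matrix(c(FALSE, TRUE, FALSE, FALSE), 2)),
               "symmetric")
})

test_that("letter display property holds for random significance patterns", {
  set.seed(107)
  for (rep in 1:60) {
    k <- sample(2:8, 1)
    sig <- matrix(FALSE, k, k)
    pairs <- which(upper.tri(sig), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.35
    for (r in which(on)) {
      sig[pairs[r, 1], pairs[r, 2]] <- TRUE
      sig[pairs[r, 2], pairs[r, 1]] <- TRUE
    }
    lets <- piephoLetters(paste0("g", seq_len(k)), sig)
    expect_true(letters_property_ok(lets, sig))
  }
})

test_that("discontinuous letter strings arise for crossed significance patterns", {
  sig <- matrix(FALSE, 4, 4)
  sig[1, 2] <- sig[2, 1] <- TRUE
  sig[3, 4] <- sig[4, 3] <- TRUE
  lets <- piephoLetters(paste0("g", 1:4), sig)
  expect_true(letters_property_ok(lets, sig))
  has_gap <- function(s) {
    idx <- sort(match(strsplit(s, "")[[1]], c(letters, LETTERS)))
    length(idx) > 1 && any(diff(idx) > 1)
  }
  expect_true(any(vapply(lets, has_gap, TRUE)))
})

test_that("letters are invariant to affine rescaling of the response", {
  set.seed(108)
  groups <- list(a = rnorm(8, 0), b = rnorm(8, 1), c = rnorm(8, 1.2),
                 d = rnorm(8, 3))
  lett <- function(g) {
    tk <- tukeyKramer(g)
    sig <- tk$p < 0.05; diag(sig) <- FALSE
    piephoLetters(names(g), sig)
  }
  base <- lett(groups)
  expect_identical(base, lett(lapply(groups, function(v) 3.7 * v - 12)))
  expect_identical(base, lett(lapply(groups, function(v) 0.01 * v + 5)))
})

test_that("familywise error of the letter display is near alpha under the null", {
  set.seed(109)
  reject <- logical(500)
  for (r in seq_len(500)) {
    g <- split(rnorm(40), rep(1:4, each = 10))
    tk <- tukeyKramer(g)
    reject[r] <- any(tk$p[upper.tri(tk$p)] < 0.05)
  }
  expect_gt(mean(reject), 0.01)
  expect_lt(mean(reject), 0.12)
})

test_that("groupCompare runs the full workflow and flags unusable parameters", {
  set.seed(110)
  tab <- data.frame(
    insect_id = sprintf("i%02d", 1:20),
    dur_total_E2 = c(rlnorm(10, log(20000), 0.3), rlnorm(10, log(1500), 0.4)),
    pct_E1_phloem = c(100 * rbeta(10, 1, 20), 100 * rbeta(10, 8, 8)),
    dur_second_probe = c(rlnorm(10, 5, 0.3), rep(NA, 10)),
    n_G = rep(0, 20))
  md <- readMetadata(data.frame(
    insect_id = tab$insect_id, file = "x", status = "completed",
    group = rep(c("adapted", "rejecting"), each = 10)))
  res <- groupCompare(tab, md, "group")
  names(res) <- vapply(res, `[[`, "", "parameter")

  e2 <- res[["dur_total_E2"]]
  expect_false(e2$skipped)
  expect_true(e2$groups$letters[1] != e2$groups$letters[2])
  expect_equal(e2$groups$mean_original,
               as.numeric(tapply(tab$dur_total_E2, md$group, mean)),
               tolerance = 1e-12)

  expect_true(res[["pct_E1_phloem"]]$transform$arcsine_first)
  # one whole group missing -> skip flag, not an exception
  expect_true(res[["dur_second_probe"]]$skipped)
  # constant parameter -> degenerate-sample skip
  expect_true(res[["n_G"]]$skipped)

  expect_error(groupCompare(tab, md, "nonexistent"), "not found")

  flat <- statsToTable(res)
  expect_true(all(c("parameter", "group", "letters", "lambda") %in% names(flat)))
  supp <- statsToSupplement(res)
  expect_true(all(supp$ci_lo <= supp$mean_transformed))
})
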