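# Batched fitting engines behind run_scan().
#
# A phenome scan fits ~2 x 1951 single-predictor models per cohort; calling
# stats::lm()/glm() per item dominates runtime at calibration scale (hundreds
# of replicate cohorts).  These engines compute identical statistics from
# sufficient statistics: closed-form simple-regression algebra for the linear
# fits, and logistic IRLS on per-category aggregated counts (exact for the
# likelihood, so coefficients, Wald SEs and p-values match the per-item glm
# route).  Tests assert per-item agreement between the two routes.

# Simple linear regression of y on each column of X (NA-aware), returning
# slope, SE, t-based CI/p per column.  Used for the repeat-on-score trend
# test (y = repeat count) and, with y and X roles swapped at the call site,
# for the continuous-item group comparison.
.batch_simple_lm <- function(y, X) {
  n_all <- length(y)
  w <- as.numeric(!is.na(y))
  y0 <- ifelse(is.na(y), 0, y)
  M <- (!is.na(X)) * w                    # complete-case indicator per cell
  X0 <- X; X0[is.na(X0)] <- 0
  Xw <- X0 * M
  nj <- colSums(M)
  Sx <- colSums(Xw)
  Sxx <- colSums(Xw * X0)
  Sy <- colSums(M * y0)
  Syy <- colSums(M * y0^2)
  Sxy <- colSums(Xw * y0)
  Sxx_c <- Sxx - Sx^2 / nj
  Syy_c <- Syy - Sy^2 / nj
  Sxy_c <- Sxy - Sx * Sy / nj
  b <- Sxy_c / Sxx_c
  sse <- pmax(Syy_c - b^2 * Sxx_c, 0)
  df <- nj - 2
  sigma2 <- sse / df
  se <- sqrt(sigma2 / Sxx_c)
  tstat <- b / se
  p <- 2 * stats::pt(-abs(tstat), df)
  tcrit <- stats::qt(0.975, df)
  list(n = nj, b = b, se = se, p = p,
       ci_low = b - tcrit * se, ci_high = b + tcrit * se,
       sxx_c = Sxx_c, syy_c = Syy_c)
}

# Aggregate per-category respondent and high-group counts for categorical
# columns of X.  Returns K x m matrices N (respondents) and E (high-group).
.aggregate_counts <- function(X, high, K) {
  ok <- !is.na(high)
  wA <- as.numeric(ok)
  wE <- as.numeric(ok & !is.na(high) & high)
  N <- matrix(0, K, ncol(X)); E <- matrix(0, K, ncol(X))
  for (c in seq_len(K) - 1L) {
    Ic <- X == c
    Ic[is.na(Ic)] <- FALSE
    N[c + 1L, ] <- colSums(Ic * wA)
    E[c + 1L, ] <- colSums(Ic * wE)
  }
  list(N = N, E = E)
}

# Logistic fit of aggregated binomial counts on category scores via
# stats::glm.fit; Wald SE from the final IRLS QR factorization (as
# summary.glm computes it).
.logit_fit_agg <- function(scores, N, E, family = stats::binomial()) {
  keep <- N > 0
  xs <- scores[keep]; Nk <- N[keep]; Ek <- E[keep]
  if (length(xs) < 2)
    return(list(estimable = FALSE, reason = "zero-variance item", n = sum(Nk)))
  if (sum(Ek) == 0 || sum(Ek) == sum(Nk))
    return(list(estimable = FALSE, reason = "empty group", n = sum(Nk)))
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, xs), Ek / Nk, weights = Nk, family = family,
                   control = stats::glm.control(epsilon = 1e-10, maxit = 50)))
  eta_max <- max(abs(fit$linear.predictors))
  if (!fit$converged || eta_max > 30)
    return(list(estimable = FALSE, reason = "separation or non-convergence",
                n = sum(Nk)))
  R <- qr.R(fit$qr)
  covb <- chol2inv(R)
  b <- fit$coefficients[2]; se <- sqrt(covb[2, 2])
  if (!is.finite(se) || se == 0)
    return(list(estimable = FALSE, reason = "degenerate fit", n = sum(Nk)))
  list(estimable = TRUE, n = sum(Nk), b = b, se = se,
       p = 2 * stats::pnorm(-abs(b / se)))
}

# Batched binary-split test over all items.  Returns a tibble in run_scan's
# column contract (method = "binary_split").
.batch_binary_split <- function(X, items, high) {
  m <- ncol(X)
  out <- list(n_used = integer(m), effect = rep(NA_real_, m),
              ci_low = rep(NA_real_, m), ci_high = rep(NA_real_, m),
              p_value = rep(NA_real_, m), direction = rep(NA_integer_, m),
              estimable = rep(TRUE, m), reason = rep(NA_character_, m))
  set_bad <- function(j, n, reason) {
    out$n_used[j] <<- n; out$estimable[j] <<- FALSE; out$reason[j] <<- reason
  }
  is_cont <- items$type == "continuous"
  z <- stats::qnorm(0.975)

  if (any(!is_cont)) {
    jj <- which(!is_cont)
    K <- max(items$n_categories[jj])
    agg <- .aggregate_counts(X[, jj, drop = FALSE], high, K)
    scores <- seq_len(K) - 1
    fam <- stats::binomial()
    for (k in seq_along(jj)) {
      j <- jj[k]
      f <- .logit_fit_agg(scores, agg$N[, k], agg$E[, k], family = fam)
      if (!f$estimable) { set_bad(j, f$n, f$reason); next }
      out$n_used[j] <- f$n
      out$effect[j] <- exp(f$b)
      out$ci_low[j] <- exp(f$b - z * f$se)
      out$ci_high[j] <- exp(f$b + z * f$se)
      out$p_value[j] <- f$p
      out$direction[j] <- sign(f$b)
    }
  }

  if (any(is_cont)) {
    jj <- which(is_cont)
    Xc <- X[, jj, drop = FALSE]
    hnum <- as.numeric(high)                 # NA kept; .batch_simple_lm masks
    # regression of item on group indicator == pooled two-group comparison;
    # roles swapped relative to .batch_simple_lm's signature, so regress each
    # item column on h via the same sufficient statistics with y <- item.
    # .batch_simple_lm regresses a single y on many x; here each column has
    # its own y (the item) and shared x (h).  Reuse by swapping: slope of
    # item~h computed directly below.
    okh <- !is.na(hnum)
    wh <- as.numeric(okh)
    h0 <- ifelse(okh, hnum, 0)
    M <- (!is.na(Xc)) * wh
    V0 <- Xc; V0[is.na(V0)] <- 0
    Vw <- V0 * M
    nj <- colSums(M)
    n1 <- colSums(M * h0)
    n0 <- nj - n1
    Sh <- n1
    Shh <- n1
    Sv <- colSums(Vw)
    Svv <- colSums(Vw * V0)
    Shv <- colSums(Vw * h0)
    Shh_c <- Shh - Sh^2 / nj
    Svv_c <- Svv - Sv^2 / nj
    Shv_c <- Shv - Sh * Sv / nj
    b <- Shv_c / Shh_c
    sse <- pmax(Svv_c - b^2 * Shh_c, 0)
    df <- nj - 2
    se <- sqrt((sse / df) / Shh_c)
    tstat <- b / se
    p <- 2 * stats::pt(-abs(tstat), df)
    tcrit <- stats::qt(0.975, df)
    for (k in seq_along(jj)) {
      j <- jj[k]
      if (is.na(n1[k]) || n1[k] < 2 || n0[k] < 2) {
        set_bad(j, nj[k], "fewer than 2 complete cases in a group"); next
      }
      if (Svv_c[k] <= 0) { set_bad(j, nj[k], "zero-variance item"); next }
      if (!is.finite(se[k]) || se[k] == 0) {
        set_bad(j, nj[k], "degenerate fit"); next
      }
      out$n_used[j] <- nj[k]
      out$effect[j] <- b[k]
      out$ci_low[j] <- b[k] - tcrit[k] * se[k]
      out$ci_high[j] <- b[k] + tcrit[k] * se[k]
      out$p_value[j] <- p[k]
      out$direction[j] <- sign(b[k])
    }
  }

  tibble::tibble(item_id = items$item_id, method = "binary_split",
                 n_used = out$n_used, effect = out$effect,
                 ci_low = out$ci_low, ci_high = out$ci_high,
                 p_value = out$p_value, direction = out$direction,
                 estimable = out$estimable, reason = out$reason)
}

# Batched linear-trend test (repeat count regressed on item score).
.batch_linear_trend <- function(X, items, repeats) {
  fit <- .batch_simple_lm(repeats, X)
  m <- ncol(X)
  estimable <- rep(TRUE, m)
  reason <- rep(NA_character_, m)
  bad_n <- fit$n < 3
  bad_x <- !bad_n & (!is.finite(fit$sxx_c) | fit$sxx_c <= 0)
  bad_y <- !bad_n & !bad_x & (fit$syy_c <= 0)
  bad_se <- !bad_n & !bad_x & !bad_y & (!is.finite(fit$se) | fit$se == 0)
  estimable[bad_n | bad_x | bad_y | bad_se] <- FALSE
  reason[bad_n] <- "fewer than 3 complete cases"
  reason[bad_x] <- "zero-variance item"
  reason[bad_y] <- "zero-variance repeat counts"
  reason[bad_se] <- "degenerate fit"
  tibble::tibble(item_id = items$item_id, method = "linear_trend",
                 n_used = as.integer(fit$n),
                 effect = ifelse(estimable, fit$b, NA_real_),
                 ci_low = ifelse(estimable, fit$ci_low, NA_real_),
                 ci_high = ifelse(estimable, fit$ci_high, NA_real_),
                 p_value = ifelse(estimable, fit$p, NA_real_),
                 direction = ifelse(estimable, as.integer(sign(fit$b)),
                                    NA_integer_),
                 estimable = estimable, reason = reason)
}
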